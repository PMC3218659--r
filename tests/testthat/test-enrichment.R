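test_that("window extension follows the floor/ceiling rule and clips", {
  w <- extend_windows(1000L, width = 200L)
  expect_equal(w$start, 899)
  expect_equal(w$end, 1099)
  w90 <- extend_windows(1000L, width = 90L)
  expect_equal(w90$end - w90$start, 90)
  # odd width centers the SNP exactly
  w5 <- extend_windows(1000L, width = 5L)
  expect_equal(w5$start, 997)
  expect_equal(w5$end, 1002)
  # nearby SNPs keep overlapping windows (no merging)
  w2 <- extend_windows(c(1000L, 1010L), width = 200L)
  expect_identical(nrow(w2), 2L)
  expect_lt(w2$start[2L], w2$end[1L])
  expect_message(wc <- extend_windows(40L, width = 200L), "clipping")
  expect_equal(wc$start, 0)
})

test_that("overlap counting uses half-open hit semantics", {
  win <- data.frame(chrom = "c", start = 0, end = 200)
  expect_equal(count_overlaps(win, data.frame(chrom = "c", start = 100,
                                              end = 150))$hits, 1L)
  expect_equal(count_overlaps(win, data.frame(chrom = "c", start = 200,
                                              end = 300))$hits, 0L)
  # different chromosome never hits
  expect_equal(count_overlaps(win, data.frame(chrom = "d", start = 0,
                                              end = 300))$hits, 0L)
})

test_that("overlap counting equals the quadratic oracle on random sets", {
  set.seed(19)
  for (rep in 1:3) {
    ws <- sort(sample.int(10000L, 50L))
    windows <- data.frame(chrom = "c", start = ws, end = ws + 120L)
    fs <- sort(sample.int(10000L, 30L))
    features <- data.frame(chrom = "c", start = fs,
                           end = fs + sample.int(400L, 30L, replace = TRUE))
    got <- count_overlaps(windows, features)
    oracle <- vapply(seq_len(nrow(windows)), function(i)
      any(features$start < windows$end[i] &
          features$end > windows$start[i]), TRUE)
    expect_identical(got$hit_flags, oracle)
    expect_identical(got$hits + got$misses, nrow(windows))
  }
})

test_that("one-sided Fisher test equals the hypergeometric tail", {
  expect_equal(signif(fisher_greater(178, 320, 165, 439), 3), 0.00165)
  expect_equal(signif(fisher_greater(25, 473, 17, 587), 3), 0.0408)
  expect_equal(fisher_greater(0, 10, 0, 20), 1)

  # oracle: stats::fisher.test over random small tables
  set.seed(23)
  for (i in 1:20) {
    tb <- matrix(rpois(4L, 12) , 2L)
    got <- fisher_greater(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    oracle <- fisher.test(tb, alternative = "greater")$p.value
    expect_equal(got, oracle, tolerance = 1e-10)
  }
  # enumeration oracle for all tables with total <= 200 margins fixed
  set.seed(29)
  for (i in 1:10) {
    counts <- as.vector(stats::rmultinom(1L, sample(40:200, 1L),
                                         rep(0.25, 4L)))
    ch <- counts[1]; cm <- counts[2]; kh <- counts[3]; km <- counts[4]
    K <- ch + kh; N <- sum(counts); n <- ch + cm
    enum <- sum(vapply(ch:min(n, K), function(k)
      dhyper(k, K, N - K, n), 0))
    expect_equal(fisher_greater(ch, cm, kh, km), enum, tolerance = 1e-12)
  }
})

test_that("pair distances are signed, zero inside, and count SNPs", {
  hs <- data.frame(start = 5000, end = 7000, peak_center = 6000)
  positions <- c(1000, 2000, 3000, 4000, 5500, 6500, 8000, 9000, 11000)
  expect_equal(unname(pair_distances(5500, hs, positions)), c(0, 0))
  d <- pair_distances(1000, hs, positions)
  expect_equal(unname(d[1L]), -5000)
  expect_equal(unname(d[2L]), 3)   # SNPs at 2000, 3000, 4000 in between
  dr <- pair_distances(11000, hs, positions)
  expect_equal(unname(dr[1L]), 5000)
  expect_equal(unname(dr[2L]), 2)  # SNPs at 8000, 9000
  # symmetric SNPs left/right have equal absolute bp distance
  expect_equal(abs(pair_distances(1000, hs, positions)[1L]),
               abs(pair_distances(11000, hs, positions)[1L]))
})

test_that("derived temperature tabulation equals a hand tally", {
  tests <- data.frame(
    snp = 1:6,
    rho0 = c(1, 2, 3, 1, 5, 2),
    rho1 = c(2, 1, 1, 4, 5, 1),
    q_value = c(0.005, 0.02, 0.2, 0.7, 0.005, 0.3),
    dist_bp = c(0, 20000, -60000, 150000, 0, 30000))
  m <- matrix(0L, 10, 6)
  m[1:5, ] <- 1L
  panel <- haplotype_panel(m, positions = (1:6) * 1000L,
                           ancestral_state = c("allele0", "allele0",
                                               "allele1", "allele1",
                                               "unknown", "allele0"))
  out <- derived_temperature_table(tests, panel)
  expect_identical(out$n_skipped, 1L)
  tab <- out$table
  # snp1: derived=allele1, rho1=2 > rho0=1 -> derived-hot, q<0.01, inside
  expect_equal(tab$derived_hot[tab$q_bin == "q<0.01" &
                               tab$dist_bin == "inside"], 1)
  # snp2: derived=1, rho1=1 < rho0=2 -> cold, q in [0.01,0.05), <=50kb
  expect_equal(tab$derived_cold[tab$q_bin == "0.01<=q<0.05" &
                                tab$dist_bin == "0<D<=50kb"], 1)
  # snp3: derived=0, rho0=3 > rho1=1 -> hot, q in [0.05,0.5), 50-100kb
  expect_equal(tab$derived_hot[tab$q_bin == "0.05<=q<0.5" &
                               tab$dist_bin == "50kb<D<=100kb"], 1)
  # snp4: derived=0, rho0=1 < rho1=4 -> cold, q>=0.5, >100kb
  expect_equal(tab$derived_cold[tab$q_bin == "q>=0.5" &
                                tab$dist_bin == "D>100kb"], 1)
  # snp6: derived=1, rho1=1 < rho0=2 -> cold
  expect_equal(tab$derived_cold[tab$q_bin == "0.05<=q<0.5" &
                                tab$dist_bin == "0<D<=50kb"], 1)
  expect_equal(sum(tab$derived_cold) + sum(tab$derived_hot), 5)
})

test_that("BED interval files round trip", {
  iv <- data.frame(chrom = "chr6", start = c(0, 500), end = c(100, 900),
                   label = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, path)
  iv2 <- read_bed(path)
  expect_equal(iv2$start, iv$start)
  expect_equal(iv2$end, iv$end)
  expect_identical(iv2$label, iv$label)
})

test_that("candidate/control selection distance-matches control blocks", {
  # geometry: hotspot centered at 10 kb; candidates at 8 and 30 kb;
  # controls available at 6, 14, 28, 60 kb -- matching must pick the
  # controls whose |distance - candidate distance| is smallest
  set.seed(41)
  L <- 8L
  m <- matrix(rbinom(40L * L, 1L, 0.5), 40L, L)
  positions <- c(6000L, 8000L, 14000L, 28000L, 30000L, 60000L, 70000L,
                 80000L)
  # decorrelate columns enough that each SNP is its own LD block
  p <- haplotype_panel(m, positions = positions)
  tests <- data.frame(snp = 1:6,
                      snp_id = p$snps$snp_id[1:6],
                      position = positions[1:6],
                      hotspot = 1L,
                      q_value = c(0.6, 0.005, 0.7, 0.9, 0.002, 0.8))
  hotspots <- data.frame(peak_center = 10000, start = 9000, end = 11000)
  sel <- select_candidates_controls(tests, p, hotspots,
                                    r2_threshold = 0.999)
  expect_setequal(sel$candidates$snp, c(2L, 5L))
  # candidate at 8k (dist 2k): nearest control dists from {4k(6k),4k(14k),
  # 18k(28k),50k(60k)} -> controls 6k and 14k; candidate at 30k (dist 20k):
  # remaining controls {28k(d18), 60k(d50)} -> picks both
  expect_setequal(sel$controls$snp, c(1L, 3L, 4L, 6L))
  # exhaustive check of the matching criterion for the first candidate
  d_cand <- abs(8000 - 10000)
  d_ctrl <- abs(c(6000, 14000, 28000, 60000) - 10000)
  picked <- order(abs(d_ctrl - d_cand))[1:2]
  expect_setequal(c(6000, 14000, 28000, 60000)[picked], c(6000, 14000))
})

test_that("enrichment_test assembles counts and the Fisher p", {
  set.seed(51)
  cands <- data.frame(position = seq(1000L, 20000L, by = 1000L))
  ctrls <- data.frame(position = seq(1500L, 40000L, by = 1500L))
  feats <- data.frame(chrom = "chr", start = c(500, 5000, 9000),
                      end = c(1500, 5600, 12000))
  out <- enrichment_test(cands, ctrls, feats, width = 200L)
  expect_identical(out$candidate_hits + out$candidate_misses, nrow(cands))
  expect_identical(out$control_hits + out$control_misses, nrow(ctrls))
  expect_equal(out$p_fisher_greater,
               fisher_greater(out$candidate_hits, out$candidate_misses,
                              out$control_hits, out$control_misses))
})

test_that("window sequences export to FASTA from a reference", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", paste(rep("ACGTACGTAC", 10), collapse = "")), fa)
  win <- data.frame(chrom = "chrT", start = c(0, 10), end = c(4, 15),
                    label = c("w1", "w2"))
  out <- withr::local_tempfile(fileext = ".fa")
  extract_window_fasta(win, fa, out)
  lines <- readLines(out)
  expect_identical(lines[1], ">w1")
  expect_identical(lines[2], "ACGT")
  expect_identical(lines[4], "ACGTA")
})
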