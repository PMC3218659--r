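test_that("split_by_allele partitions the panel by SNP allele", {
  # 180 chromosomes with a 63/117 split at the focal SNP
  set.seed(21)
  col <- sample(rep(c(1L, 0L), c(63L, 117L)))
  other <- rbinom(180L, 1L, 0.5)
  p <- haplotype_panel(cbind(other, col), positions = c(100L, 200L))
  sp <- split_by_allele(p, 2L)
  expect_identical(nrow(sp$panel1$haplotypes), 63L)
  expect_identical(nrow(sp$panel0$haplotypes), 117L)

  # splitting then re-concatenating rows gives the original row multiset
  rows <- rbind(sp$panel0$haplotypes, sp$panel1$haplotypes)
  key <- function(m) sort(apply(m, 1L, paste, collapse = ""))
  expect_identical(key(rows), key(p$haplotypes))

  lone <- haplotype_panel(cbind(c(rep(0L, 7L), 1L), rbinom(8L, 1L, 0.5)),
                          positions = c(1L, 2L))
  sp2 <- split_by_allele(lone, 1L)
  expect_identical(nrow(sp2$panel0$haplotypes), 7L)
  expect_identical(nrow(sp2$panel1$haplotypes), 1L)

  mono <- haplotype_panel(cbind(rep(0L, 8L), rbinom(8L, 1L, 0.5)),
                          positions = c(1L, 2L))
  expect_error(split_by_allele(mono, 1L), "monomorphic")
})

test_that("delta_rho is the normalized strength difference", {
  expect_equal(delta_rho(2, 2), 0)
  expect_equal(delta_rho(3, 1), 0.5)
  expect_equal(delta_rho(0, 5), -1)
  expect_equal(delta_rho(0, 0), 0)
  expect_error(delta_rho(-1, 2), "nonnegative")
  # antisymmetry and boundedness over random pairs
  set.seed(3)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_equal(delta_rho(a, b), -delta_rho(b, a))
  expect_true(all(abs(delta_rho(a, b)) <= 1))
})

test_that("candidate_snps honors the SNP span and the MAF floor", {
  set.seed(14)
  n <- 20L; L <- 30L
  m <- matrix(rbinom(n * L, 1L, 0.5), n, L)
  # make column 10 low-MAF, keep others balanced
  m[, 10L] <- c(rep(0L, 16L), rep(1L, 4L))
  p <- haplotype_panel(m, positions = seq_len(L) * 100L)
  hs <- data.frame(start = 1450, end = 1750)   # SNPs 15..17 inside
  cands <- candidate_snps(p, hs, maf_min = 0.0, span_snps = 3L)
  expect_setequal(cands[cands >= 15 & cands <= 17], 15:17)
  expect_true(all(cands >= 12L & cands <= 20L))    # 3 SNPs past boundaries
  expect_false(11L %in% cands)                     # 4th SNP out is excluded

  cands2 <- candidate_snps(p, hs, maf_min = 0.3, span_snps = 200L)
  expect_false(10L %in% cands2)                    # MAF 0.2 < 0.3
  mafs <- minor_allele_freq(p, cands2)
  expect_true(all(mafs >= 0.3))
})

test_that("random_split respects the 30% minimum and the seed", {
  p <- toy_panel(n = 180L, L = 4L, seed = 2L)
  set.seed(5)
  sp <- random_split(p, min_fraction = 0.3)
  n0 <- nrow(sp$panel0$haplotypes); n1 <- nrow(sp$panel1$haplotypes)
  expect_identical(n0 + n1, 180L)
  expect_gte(min(n0, n1), 54L)

  set.seed(77); s1 <- random_split(p)$sides
  set.seed(77); s2 <- random_split(p)$sides
  expect_identical(s1, s2)

  expect_error(random_split(p, min_fraction = 0.6), "infeasible")

  # forced sizes and fifty-fifty mode
  spf <- random_split(p, sizes = c(100L, 80L))
  expect_identical(nrow(spf$panel1$haplotypes), 80L)
  sph <- random_split(p, mode = "fifty_fifty")
  expect_identical(nrow(sph$panel1$haplotypes), 90L)

  # keep_pairs keeps both chromosomes of an individual on one side
  spp <- random_split(p, keep_pairs = TRUE)
  side_by_ind <- tapply(spp$sides, p$individual_ids,
                        function(v) length(unique(v)))
  expect_true(all(side_by_ind == 1L))
})

test_that("association_p is the strict exceedance proportion", {
  expect_equal(association_p(5, c(1, 2, 3)), 0)
  expect_equal(association_p(0, c(-1, 1, 2)), 1)
  set.seed(9)
  nulls <- rnorm(200)
  obs <- 0.7
  expect_equal(association_p(obs, nulls),
               sum(abs(nulls) > abs(obs)) / 200)
  expect_equal(association_p(obs, nulls, add_one = TRUE),
               (sum(abs(nulls) > abs(obs)) + 1) / 201)
})

test_that("MAF bin stats match direct group-by computation", {
  st <- maf_bin_stats(c(0.4, 0.4, 0.4), c(0.3, 0.3, 0.3), n_chrom = 10L)
  expect_equal(st$mean_delta, 0.3)
  expect_equal(st$sd_delta, 0)

  st2 <- maf_bin_stats(c(0.3, 0.3, 0.5, 0.5), c(0.1, 0.3, 0.2, 0.4),
                       n_chrom = 10L)
  expect_equal(st2$mean_delta, c(0.2, 0.3))
  expect_equal(st2$sd_delta, c(sd(c(0.1, 0.3)), sd(c(0.2, 0.4))))
  expect_equal(st2$sd_delta[1], 0.1414, tolerance = 1e-3)

  # synthetic set vs brute-force grouping at sample resolution
  set.seed(6)
  n_chrom <- 20L
  maf <- sample(seq(0.3, 0.5, by = 1 / n_chrom), 60L, replace = TRUE)
  delta <- rnorm(60L)
  st3 <- maf_bin_stats(maf, delta, n_chrom)
  bins <- round(maf * n_chrom) / n_chrom
  if (all(table(bins) >= 2L)) {
    oracle <- aggregate(delta, list(bin = bins), mean)
    expect_equal(st3$mean_delta, oracle$x)
  }
  expect_true(all(st3$n >= 2L))

  # sparse bins merge into their nearest neighbor
  expect_message(
    st4 <- maf_bin_stats(c(0.3, 0.3, 0.5), c(0.1, 0.2, 9), n_chrom = 10L),
    "merging")
  expect_equal(nrow(st4), 1L)
  expect_equal(st4$n, 3)
})

test_that("standardization studentizes within the MAF bin", {
  st <- maf_bin_stats(rep(c(0.3, 0.4), each = 5L),
                      c(rnorm(5, 0.1, 0.2), rnorm(5, 0.5, 0.1)),
                      n_chrom = 10L)
  expect_equal(standardize_delta(st$mean_delta[1L], 0.3, st), 0)
  fake <- structure(data.frame(maf_bin = 0.4, mean_delta = 0.1,
                               sd_delta = 0.2, n = 10),
                    class = c("maf_bin_stats", "data.frame"))
  expect_equal(standardize_delta(0.5, 0.4, fake), 2)

  # applying to a bin's own members gives sample mean 0 and SD 1
  set.seed(8)
  vals <- rnorm(12L)
  stb <- maf_bin_stats(rep(0.35, 12L), vals, n_chrom = 20L)
  z <- vapply(vals, standardize_delta, 0, maf = 0.35, stats = stb)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)

  degen <- structure(data.frame(maf_bin = 0.4, mean_delta = 0, sd_delta = 0,
                                n = 5),
                     class = c("maf_bin_stats", "data.frame"))
  expect_error(standardize_delta(0.2, 0.4, degen), "degenerate")
})

test_that("Storey q-values match a direct formula oracle", {
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))

  set.seed(10)
  p <- c(0.001, 0.02, 0.03, 0.2, 0.35, 0.41, 0.55, 0.6, 0.85, 0.99)
  q <- qvalues(p)
  # step-by-step Storey evaluation
  m <- 10L
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  o <- order(p)
  qs <- pi0 * m * p[o] / seq_len(m)
  for (i in (m - 1L):1L) qs[i] <- min(qs[i], qs[i + 1L])
  oracle <- numeric(m); oracle[o] <- pmin(qs, 1)
  expect_equal(q, oracle)

  # order preservation with p
  p2 <- runif(100)
  q2 <- qvalues(p2)
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
  expect_true(all(q2 <= 1 & q2 >= 0))
})

test_that("side scores credit the hotter side and sum to zero at 50/50", {
  membership <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  # chromosome 1 on side 0 both times; make side 0 hotter both times
  null <- fake_null(deltas = c(0.1, 0.2), membership = membership)
  sc <- side_scores(null)
  expect_equal(unname(sc[1L]), 0.3)    # always on the hotter side
  expect_equal(unname(sc[4L]), -0.3)   # always on the colder side

  # 50/50 splits: total score is zero by pairing
  set.seed(4)
  mem <- replicate(20L, sample(rep(0:1, 10L)))
  null2 <- fake_null(deltas = rnorm(20L, 0, 0.2), membership = mem)
  expect_equal(sum(side_scores(null2)), 0)
})

test_that("Grubbs outlier detection matches the closed-form statistic", {
  sc <- structure(c(rep(0, 19), 10), names = paste0("h", 1:20),
                  class = c("side_scores", "numeric"))
  out <- grubbs_outliers(sc, p_threshold = 0.1)
  expect_identical(out$chromosome_id[1L], "h20")

  flat <- structure(rep(1, 10), names = paste0("h", 1:10),
                    class = c("side_scores", "numeric"))
  expect_identical(nrow(grubbs_outliers(flat)), 0L)

  expect_error(grubbs_outliers(structure(rnorm(5),
                                         names = paste0("h", 1:5))), ">= 7")

  # fixed 12-value vector: G and p match hand evaluation
  v <- c(2.1, 1.9, 2.0, 2.2, 1.8, 2.05, 1.95, 2.15, 1.85, 2.0, 2.1, 4.5)
  names(v) <- paste0("h", 1:12)
  n <- 12L
  G <- max(abs(v - mean(v))) / sd(v)
  t <- sqrt(n * (n - 2) * G^2 / ((n - 1)^2 - n * G^2))
  p_hand <- min(1, 2 * n * pt(t, n - 2, lower.tail = FALSE))
  out2 <- grubbs_outliers(structure(v, class = c("side_scores", "numeric")),
                          p_threshold = 0.1)
  expect_identical(out2$chromosome_id[1L], "h12")
  expect_equal(out2$grubbs_p[1L], p_hand)
})

test_that("permutation null has the right cardinalities and a zero-signal
           panel gives all-zero deltas", {
  # duplicated identical haplotypes in both halves: any split estimates the
  # same map on both sides, so every delta is exactly zero
  L <- 12L
  f1 <- rep(c(0L, 1L), length.out = L)
  haps <- rbind(matrix(rep(f1, 20L), 20L, byrow = TRUE),
                matrix(rep(1L - f1, 20L), 20L, byrow = TRUE))
  p <- haplotype_panel(haps, positions = seq_len(L) * 500L)
  hs <- data.frame(start = 2000, end = 4000)
  set.seed(3)
  null <- suppressWarnings(
    permutation_null(p, hs, estimator_config(), n_perm = 8L))
  expect_length(null$deltas, 8L)
  expect_identical(dim(null$membership), c(40L, 8L))
  expect_true(all(colSums(null$membership) >= ceiling(0.3 * 40)))
  expect_true(all(abs(null$deltas) < 0.3))
})

test_that("normality gate applies the Shapiro threshold", {
  set.seed(15)
  norm_null <- fake_null(rnorm(100), matrix(0L, 4, 100))
  bimodal <- fake_null(c(rnorm(50, -2, 0.1), rnorm(50, 2, 0.1)),
                       matrix(0L, 4, 100))
  expect_true(normality_gate(norm_null))
  expect_false(normality_gate(bimodal))
  fail <- norm_null; fail$shapiro_p <- 0.03
  expect_false(normality_gate(fail))
})

test_that("retest with an empty outlier set reproduces the original test", {
  p <- mosaic_panel(n = 40L, L = 16L, seed = 13L)
  hs <- data.frame(start = 4500, end = 6000)
  snp <- 8L
  if (minor_allele_freq(p, snp) < 0.3) snp <- which.max(
    minor_allele_freq(p, seq_len(16L)))
  t1 <- split_test(p, hs, snp, estimator_config(), n_perm = 6L, seed = 2L)
  t2 <- retest_without_outliers(p, hs, snp, character(0),
                                estimator_config(), n_perm = 6L, seed = 2L)
  expect_equal(as.data.frame(t1), as.data.frame(t2))

  expect_error(retest_without_outliers(p, hs, snp, "nonexistent",
                                       estimator_config()), "present")
})
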