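#' Read/write genomic intervals as BED
#'
#' Intervals are handled as plain data frames with columns `chrom`, `start`,
#' `end` (0-based half-open) and optional `label`.
#'
#' @param path File path.
#' @return `read_bed`: a data frame of intervals.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "label"
  if (any(df$start >= df$end)) stop("BED intervals must have start < end")
  df
}

#' @rdname read_bed
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `label`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "label"), names(intervals))
  utils::write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extend SNPs to fixed-width windows
#'
#' Each SNP at 1-based position `p` becomes the 0-based half-open interval
#' `[p - 1 - floor(width/2), p - 1 + ceiling(width/2))` of length `width`
#' (for even widths the SNP sits one base right of center).  Windows running
#' past the contig start are clipped at 0 with a message.
#'
#' @param positions 1-based SNP positions.
#' @param width Window width in bp (>= 2).
#' @param chrom Chromosome name.
#' @param labels Optional window labels.
#' @return Interval data frame (`chrom`, `start`, `end`, `label`).
#' @export
extend_windows <- function(positions, width = 200L, chrom = "chr",
                           labels = NULL) {
  stopifnot(width >= 2)
  p0 <- as.numeric(positions) - 1
  start <- p0 - floor(width / 2)
  end <- p0 + ceiling(width / 2)
  if (any(start < 0)) {
    message("clipping ", sum(start < 0), " window(s) at the contig start")
    start <- pmax(start, 0)
  }
  data.frame(chrom = chrom, start = start, end = end,
             label = if (is.null(labels))
               paste0("win", seq_along(positions)) else labels,
             stringsAsFactors = FALSE)
}

#' Count windows overlapping a feature set
#'
#' A window is a hit when it shares at least 1 bp with any feature
#' (half-open intervals: abutting intervals do not overlap).  Counted per
#' window; `hits + misses` always equals the number of windows.
#'
#' @param windows,features Interval data frames (`chrom`, `start`, `end`).
#' @return List with `hits`, `misses` and the per-window logical
#'   `hit_flags`.
#' @export
count_overlaps <- function(windows, features) {
  hit <- logical(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    f <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0L) next
    o <- order(f$start)
    fs <- f$start[o]
    fe_cummax <- cummax(f$end[o])
    # features with start < window end, among them need max end > window start
    idx <- findInterval(windows$end[wi] - 1e-9, fs)
    ok <- idx > 0L
    hit[wi[ok]] <- fe_cummax[idx[ok]] > windows$start[wi[ok]]
  }
  list(hits = sum(hit), misses = sum(!hit), hit_flags = hit)
}

#' One-sided Fisher enrichment test (greater)
#'
#' Tests whether candidate windows hit a feature more often than control
#' windows: the p-value is the hypergeometric upper-tail probability of
#' observing at least `candidate_hits` hits among the candidate row, with
#' margins fixed.  Computed by direct tail summation in log space.
#'
#' @param candidate_hits,candidate_misses,control_hits,control_misses
#'   Contingency counts (Table rows: candidate/control; columns:
#'   hit/miss).
#' @return One-sided p-value.
#' @export
fisher_greater <- function(candidate_hits, candidate_misses,
                           control_hits, control_misses) {
  ch <- candidate_hits; cm <- candidate_misses
  kh <- control_hits; km <- control_misses
  stopifnot(ch >= 0, cm >= 0, kh >= 0, km >= 0)
  K <- ch + kh            # total hits
  N <- ch + cm + kh + km  # grand total
  n <- ch + cm            # candidate row total
  if (K == 0L || n == 0L) return(1)
  kmax <- min(n, K)
  ks <- ch:kmax
  lp <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  min(1, sum(exp(lp)))
}

#' Signed distance of a SNP to a hotspot
#'
#' Physical distance (bp) from the SNP to the hotspot center, negative when
#' the SNP lies left of the hotspot, and the number of SNPs strictly between
#' the SNP and the proximal hotspot boundary; both 0 when the SNP is inside
#' the hotspot.
#'
#' @param snp_position 1-based SNP position.
#' @param hotspot One-row data frame (or list) with `start`, `end` and
#'   optionally `peak_center` (defaults to the interval midpoint).
#' @param positions All panel SNP positions (for the SNP-count distance).
#' @return Numeric `c(dist_bp, dist_snps)`.
#' @export
pair_distances <- function(snp_position, hotspot, positions) {
  center <- if (!is.null(hotspot$peak_center)) hotspot$peak_center
            else (hotspot$start + hotspot$end) / 2
  if (snp_position >= hotspot$start && snp_position < hotspot$end)
    return(c(dist_bp = 0, dist_snps = 0))
  dist_bp <- snp_position - center
  if (snp_position < hotspot$start) {
    k <- sum(positions > snp_position & positions < hotspot$start)
  } else {
    k <- sum(positions > hotspot$end & positions < snp_position)
  }
  c(dist_bp = dist_bp, dist_snps = k)
}

#' Select distance-matched candidate and control tag SNPs
#'
#' Splits tested SNPs into candidates (`q <= q_candidate`) and controls
#' (`q > q_control`), clusters each pool into LD blocks (r^2 >=
#' `r2_threshold`), and for every candidate block of a hotspot picks up to
#' `n_controls` control blocks whose block-center distances to the hotspot
#' center are closest to the candidate block's distance.  Each block is
#' represented by its tag SNP, the member with the smallest q-value.
#'
#' @param tests An [ldsplit_scan()] (or compatible data frame with `snp`,
#'   `hotspot`, `position`, `q_value`).
#' @param panel The panel the scan was run on.
#' @param hotspots The `hotspot_set` used.
#' @param q_candidate,q_control Thresholds (defaults 0.01 and 0.5).
#' @param r2_threshold LD-block threshold (default 0.8).
#' @param n_controls Control blocks per candidate block (default 2).
#' @return List with data frames `candidates` and `controls` (columns `snp`,
#'   `snp_id`, `position`, `hotspot`); hotspots without available controls
#'   keep their candidates and are reported in `unmatched`.
#' @export
select_candidates_controls <- function(tests, panel, hotspots,
                                       q_candidate = 0.01, q_control = 0.5,
                                       r2_threshold = 0.8, n_controls = 2L) {
  cand_pool <- tests[tests$q_value <= q_candidate, , drop = FALSE]
  ctrl_pool <- tests[tests$q_value > q_control, , drop = FALSE]
  empty <- data.frame(snp = integer(0), snp_id = character(0),
                      position = numeric(0), hotspot = integer(0),
                      stringsAsFactors = FALSE)
  out <- list(candidates = empty, controls = empty, unmatched = integer(0))
  if (nrow(cand_pool) == 0L) return(out)

  tag_of <- function(block, pool) {
    members <- match(block$member_snps, pool$snp)
    members[which.min(pool$q_value[members])]
  }
  block_rows <- function(pool, h) {
    sub <- pool[pool$hotspot == h, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    blocks <- select_ld_blocks(panel, sub$snp, r2_threshold)
    lapply(blocks, function(b) {
      i <- tag_of(b, sub)
      center <- mean(panel$snps$position[b$member_snps])
      list(row = sub[i, , drop = FALSE], center = center)
    })
  }
  for (h in unique(cand_pool$hotspot)) {
    hcenter <- hotspots$peak_center[h]
    cand_blocks <- block_rows(cand_pool, h)
    ctrl_blocks <- block_rows(ctrl_pool, h)
    if (is.null(ctrl_blocks) || length(ctrl_blocks) == 0L) {
      out$unmatched <- c(out$unmatched, h)
      for (cb in cand_blocks)
        out$candidates <- rbind(out$candidates,
                                cb$row[, c("snp", "snp_id", "position",
                                           "hotspot")])
      next
    }
    used <- logical(length(ctrl_blocks))
    ctrl_dist <- vapply(ctrl_blocks, function(b) abs(b$center - hcenter), 0)
    for (cb in cand_blocks) {
      out$candidates <- rbind(out$candidates,
                              cb$row[, c("snp", "snp_id", "position",
                                         "hotspot")])
      d <- abs(cb$center - hcenter)
      avail <- which(!used)
      if (length(avail) == 0L) next
      pick <- avail[order(abs(ctrl_dist[avail] - d))]
      pick <- pick[seq_len(min(n_controls, length(pick)))]
      used[pick] <- TRUE
      for (i in pick)
        out$controls <- rbind(out$controls,
                              ctrl_blocks[[i]]$row[, c("snp", "snp_id",
                                                       "position",
                                                       "hotspot")])
    }
  }
  out
}

#' Tabulate derived-allele temperature by q-value and distance
#'
#' For each hotspot-SNP pair with a known ancestral state, the derived allele
#' is "cold" when its subpopulation has the smaller hotspot strength and
#' "hot" otherwise.  Counts of derived-cold versus derived-hot pairs are
#' tabulated over q-value bins (`< 0.01`, `[0.01, 0.05)`, `[0.05, 0.5)`,
#' `>= 0.5`) and hotspot-distance bins (inside, `<= 50 kb`, `<= 100 kb`,
#' `> 100 kb`).  Pairs with unknown ancestral state are skipped and tallied.
#'
#' @param tests An [ldsplit_scan()]-compatible data frame (`snp`, `rho0`,
#'   `rho1`, `q_value`, `dist_bp`).
#' @param panel The panel (source of `ancestral_state` per SNP).
#' @return List with `table` (data frame: `q_bin`, `dist_bin`, `derived_cold`,
#'   `derived_hot`, `ratio`) and `n_skipped` (unknown ancestral states).
#' @export
derived_temperature_table <- function(tests, panel) {
  anc <- panel$snps$ancestral_state[tests$snp]
  known <- anc != "unknown"
  n_skipped <- sum(!known)
  t2 <- tests[known, , drop = FALSE]
  anc <- anc[known]
  # derived allele is the one opposite the ancestral state
  derived_is_1 <- anc == "allele0"
  derived_rho <- ifelse(derived_is_1, t2$rho1, t2$rho0)
  other_rho <- ifelse(derived_is_1, t2$rho0, t2$rho1)
  derived_cold <- derived_rho < other_rho
  q_bin <- cut(t2$q_value, c(-Inf, 0.01, 0.05, 0.5, Inf),
               labels = c("q<0.01", "0.01<=q<0.05", "0.05<=q<0.5", "q>=0.5"),
               right = FALSE)
  d <- abs(t2$dist_bp)
  dist_bin <- ifelse(d == 0, "inside",
                     ifelse(d <= 50000, "0<D<=50kb",
                            ifelse(d <= 100000, "50kb<D<=100kb", "D>100kb")))
  dist_bin <- factor(dist_bin, levels = c("inside", "0<D<=50kb",
                                          "50kb<D<=100kb", "D>100kb"))
  grid <- expand.grid(q_bin = levels(q_bin), dist_bin = levels(dist_bin),
                      stringsAsFactors = FALSE)
  grid$derived_cold <- mapply(function(q, dd)
    sum(derived_cold & q_bin == q & dist_bin == dd), grid$q_bin,
    grid$dist_bin)
  grid$derived_hot <- mapply(function(q, dd)
    sum(!derived_cold & q_bin == q & dist_bin == dd), grid$q_bin,
    grid$dist_bin)
  grid$ratio <- ifelse(grid$derived_hot > 0,
                       grid$derived_cold / grid$derived_hot, NA_real_)
  list(table = grid, n_skipped = n_skipped)
}

#' Enrichment report for a feature track
#'
#' Builds fixed-width windows around candidate and control tag SNPs, counts
#' overlaps with a feature interval set, and computes the one-sided Fisher
#' enrichment p-value.
#'
#' @param candidates,controls Data frames with a `position` column (from
#'   [select_candidates_controls()]).
#' @param features Interval data frame (e.g. from [read_bed()]).
#' @param width Window width in bp (default 200).
#' @param chrom Chromosome name of the SNPs.
#' @return One-row data frame: hit/miss counts for both groups and
#'   `p_fisher_greater` (reported at 3 significant figures in `print`).
#' @export
enrichment_test <- function(candidates, controls, features, width = 200L,
                            chrom = "chr") {
  wc <- extend_windows(candidates$position, width, chrom)
  wk <- extend_windows(controls$position, width, chrom)
  oc <- count_overlaps(wc, features)
  ok <- count_overlaps(wk, features)
  data.frame(candidate_hits = oc$hits, candidate_misses = oc$misses,
             control_hits = ok$hits, control_misses = ok$misses,
             p_fisher_greater = fisher_greater(oc$hits, oc$misses,
                                               ok$hits, ok$misses))
}

#' Extract window sequences to FASTA
#'
#' Pulls the reference sequence under each interval (0-based half-open) and
#' writes a FASTA file, e.g. to feed flanking windows of candidate SNPs to
#' external motif-discovery tools.  Requires the \pkg{Biostrings} package.
#'
#' @param windows Interval data frame (`chrom`, `start`, `end`, optional
#'   `label`).
#' @param genome_fasta Path to the reference FASTA (sequence names must
#'   match `chrom`).
#' @param out_fasta Output FASTA path.
#' @return `out_fasta`, invisibly.
#' @export
extract_window_fasta <- function(windows, genome_fasta, out_fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("extract_window_fasta requires the Biostrings package")
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(windows$chrom), names(genome))
  if (length(missing) > 0L)
    stop("sequences absent from the FASTA: ", paste(missing, collapse = ", "))
  seqs <- vapply(seq_len(nrow(windows)), function(i) {
    as.character(Biostrings::subseq(genome[[windows$chrom[i]]],
                                    start = windows$start[i] + 1L,
                                    end = windows$end[i]))
  }, "")
  labels <- if ("label" %in% names(windows)) windows$label
            else paste0("win", seq_len(nrow(windows)))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- labels
  Biostrings::writeXStringSet(out, out_fasta)
  invisible(out_fasta)
}
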