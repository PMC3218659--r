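#' Empirical delta-rho moments per minor-allele-frequency bin
#'
#' The more frequent allele of a SNP tends to be older and to have
#' accumulated more historical crossovers, so it systematically appears
#' "hotter" than the rare allele.  To correct this allele-age bias, the
#' frequency-oriented delta-rho (strength of the frequent allele minus the
#' rare allele, normalized) is centered and scaled by the empirical mean and
#' SD among SNPs of equal MAF.  "Equal" is exact at the sample's natural
#' resolution: MAF is rounded to the nearest `1/n_chrom` (`= 1/(2n)` for `n`
#' individuals); bins with fewer than 2 entries are merged with the nearest
#' bin.
#'
#' @param maf Vector of minor allele frequencies, one per test.
#' @param delta Matching vector of frequency-oriented delta-rho values.
#' @param n_chrom Number of chromosomes in the panel (sets the bin
#'   resolution).
#' @return Data frame of class `maf_bin_stats` with columns `maf_bin`,
#'   `mean_delta`, `sd_delta`, `n`.
#' @export
maf_bin_stats <- function(maf, delta, n_chrom) {
  stopifnot(length(maf) == length(delta), n_chrom >= 2)
  bin <- round(maf * n_chrom) / n_chrom
  agg <- function(b) {
    tapply(delta, b, function(v)
      c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        n = length(v)))
  }
  stats_list <- agg(bin)
  df <- data.frame(
    maf_bin = as.numeric(names(stats_list)),
    mean_delta = vapply(stats_list, `[[`, 0, "mean"),
    sd_delta = vapply(stats_list, `[[`, 0, "sd"),
    n = vapply(stats_list, `[[`, 0, "n"),
    row.names = NULL
  )
  # merge sparse bins (< 2 entries) into their nearest neighbor
  while (nrow(df) > 1L && any(df$n < 2L)) {
    i <- which(df$n < 2L)[1L]
    others <- setdiff(seq_len(nrow(df)), i)
    j <- others[which.min(abs(df$maf_bin[others] - df$maf_bin[i]))]
    sel <- bin %in% c(df$maf_bin[i], df$maf_bin[j])
    merged_bin <- df$maf_bin[j]          # keep the larger bin's label
    bin[sel] <- merged_bin
    v <- delta[sel]
    df$mean_delta[j] <- mean(v)
    df$sd_delta[j] <- if (length(v) > 1L) stats::sd(v) else NA_real_
    df$n[j] <- length(v)
    message("merging sparse MAF bin ", df$maf_bin[i], " into ", merged_bin)
    df <- df[-i, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("maf_bin_stats", "data.frame")
  df
}

#' Standardize a frequency-oriented delta-rho by its MAF bin
#'
#' `z = (delta - E(delta)) / SD(delta)` with moments taken from the test's
#' MAF bin (nearest bin in `stats`).
#'
#' @param delta_freq_oriented Frequent-minus-rare normalized strength
#'   difference.
#' @param maf The SNP's minor allele frequency.
#' @param stats A [maf_bin_stats()] table.
#' @return Standardized value z.
#' @export
standardize_delta <- function(delta_freq_oriented, maf, stats) {
  stopifnot(inherits(stats, "maf_bin_stats"))
  i <- which.min(abs(stats$maf_bin - maf))
  sdv <- stats$sd_delta[i]
  if (is.na(sdv) || sdv == 0)
    stop("degenerate MAF bin (SD = 0) at maf ", maf)
  (delta_freq_oriented - stats$mean_delta[i]) / sdv
}

#' Storey q-values
#'
#' Maps p-values to q-values with the Storey procedure: the null proportion
#' pi0 is estimated at lambda = 0.5 as `#{p > 0.5} / (0.5 m)` (capped at 1),
#' and `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` over the p-value ranks.
#' Q-values are monotone non-decreasing in p and bounded by 1; selecting
#' tests with `q <= alpha` bounds the expected false-discovery proportion by
#' `alpha`.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param lambda Tuning point for the pi0 estimate (default 0.5).
#' @return Vector of q-values, same order as the input.
#' @export
qvalues <- function(pvalues, lambda = 0.5) {
  p <- as.numeric(pvalues)
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
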