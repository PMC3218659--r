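#' Permutation null distribution of delta-rho for a hotspot
#'
#' Simulates the null hypothesis of no strength difference: the sample of
#' chromosomes is split at random `n_perm` times (each side at least
#' `min_fraction` of chromosomes), the hotspot boundaries are held fixed, the
#' rate map is re-estimated for each side with the same estimator, and the
#' normalized strength difference is recorded, together with the side
#' membership of every chromosome (needed for outlier-chromosome detection).
#'
#' @param panel A [haplotype_panel()] covering the estimation window.
#' @param hotspot One-row data frame (or list) with `start`, `end` in bp; the
#'   boundaries are fixed throughout.
#' @param config An [estimator_config()].
#' @param n_perm Number of random permutations (default 200).
#' @param min_fraction Minimum fraction of chromosomes per side.
#' @param mode,sizes,keep_pairs Passed to [random_split()].
#' @return Object of class `permutation_null`: list with `deltas` (delta-rho
#'   per split, side-0 minus side-1), `deltas_size_oriented` (larger side
#'   minus smaller side), `rho0`, `rho1`, `membership` (chromosomes x
#'   `n_perm` matrix of side labels), `hotter_side` (per split), `shapiro_p`
#'   (normality of `deltas`), `hotspot`, `n_perm`, `chromosome_ids`.
#' @export
permutation_null <- function(panel, hotspot, config = estimator_config(),
                             n_perm = 200L, min_fraction = 0.3,
                             mode = c("ideal", "fifty_fifty"), sizes = NULL,
                             keep_pairs = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  mode <- match.arg(mode)
  n <- nrow(panel$haplotypes)
  interval <- c(hotspot$start, hotspot$end)
  membership <- matrix(0L, n, n_perm)
  deltas <- numeric(n_perm)
  rho0 <- numeric(n_perm); rho1 <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    sides <- .random_sides(n, min_fraction, mode, sizes,
                           panel$individual_ids, keep_pairs)
    membership[, i] <- sides
    s0 <- .window_strength(subset_panel(panel, rows = which(sides == 0L)),
                           interval, config)
    s1 <- .window_strength(subset_panel(panel, rows = which(sides == 1L)),
                           interval, config)
    rho0[i] <- s0; rho1[i] <- s1
    deltas[i] <- delta_rho(s0, s1)
  }
  n1 <- colSums(membership)
  n0 <- n - n1
  # orient by subsample size: frequent(larger) side minus rare(smaller) side
  flip <- n1 > n0
  deltas_size <- ifelse(flip, -deltas, deltas)
  structure(list(
    deltas = deltas,
    deltas_size_oriented = deltas_size,
    rho0 = rho0, rho1 = rho1,
    membership = membership,
    hotter_side = ifelse(rho0 == rho1, NA_integer_,
                         ifelse(rho0 > rho1, 0L, 1L)),
    shapiro_p = if (length(unique(deltas)) < 3L) NA_real_ else
      stats::shapiro.test(deltas)$p.value,
    hotspot = hotspot, n_perm = n_perm,
    chromosome_ids = panel$chromosome_ids
  ), class = "permutation_null")
}

# hotspot strength of a subpanel: estimate rates over the subpanel and
# integrate over the fixed hotspot interval
.window_strength <- function(subpanel, interval, config) {
  prof <- estimate_rates(subpanel, config)
  hotspot_strength(prof, interval)
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null: ", x$n_perm, " random splits of ",
      nrow(x$membership), " chromosomes\n", sep = "")
  cat("  hotspot [", x$hotspot$start, ", ", x$hotspot$end, ") bp\n", sep = "")
  cat("  delta-rho: mean ", signif(mean(x$deltas), 3), ", sd ",
      signif(stats::sd(x$deltas), 3), "\n", sep = "")
  cat("  Shapiro normality p = ", signif(x$shapiro_p, 3), "\n", sep = "")
  invisible(x)
}

#' Normality gate for a permutation null
#'
#' Hotspots whose random delta-rho distribution deviates from normality
#' (Shapiro test p below `alpha`) are rejected from the scan: the p-value
#' model assumes random splits scatter delta-rho normally around zero, and
#' deviations typically indicate a few outlier chromosomes.
#'
#' @param null A [permutation_null()].
#' @param alpha Significance level (default 0.05).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
normality_gate <- function(null, alpha = 0.05) {
  stopifnot(inherits(null, "permutation_null"), length(null$deltas) >= 3L)
  # a degenerate null (all deltas identical) carries no usable p-values
  !is.na(null$shapiro_p) && null$shapiro_p >= alpha
}

#' Empirical association p-value
#'
#' The proportion of null statistics whose absolute value strictly exceeds
#' the observed absolute value, over the number of permutations.  Applied to
#' standardized values by default in the scan; the raw delta-rho comparison is
#' available through `compare = "raw"` there.
#'
#' @param observed Observed statistic (standardized delta-rho or raw).
#' @param null_values Vector of null statistics.
#' @return p in `[0, 1]`.  Zero is reported as 0 (`count / n_perm`); an
#'   optional add-one correction `(k + 1) / (n + 1)` is applied when
#'   `add_one = TRUE`.
#' @param add_one Use the `(k+1)/(n+1)` small-sample correction.
#' @export
association_p <- function(observed, null_values, add_one = FALSE) {
  stopifnot(length(null_values) > 0L)
  k <- sum(abs(null_values) > abs(observed))
  if (add_one) (k + 1) / (length(null_values) + 1) else k / length(null_values)
}

#' Side scores of chromosomes over a permutation null
#'
#' For each permutation a chromosome gains `|delta_rho|` when it sat in the
#' subpopulation with the higher hotspot strength and loses `|delta_rho|`
#' otherwise; the side score is the sum over permutations.  A chromosome that
#' is individually much hotter or colder than the rest accumulates an extreme
#' score.
#'
#' @param null A [permutation_null()] with membership recorded.
#' @return Named numeric vector of scores (one per chromosome), class
#'   `side_scores`.
#' @export
side_scores <- function(null) {
  stopifnot(inherits(null, "permutation_null"))
  adr <- abs(null$deltas)
  hot <- null$hotter_side
  sc <- rep(0, nrow(null$membership))
  for (i in seq_len(null$n_perm)) {
    if (is.na(hot[i]) || adr[i] == 0) next
    on_hot <- null$membership[, i] == hot[i]
    sc <- sc + ifelse(on_hot, adr[i], -adr[i])
  }
  names(sc) <- null$chromosome_ids
  class(sc) <- c("side_scores", class(sc))
  sc
}

# two-sided Grubbs statistic p-value via the t distribution
.grubbs_p <- function(G, n) {
  num <- n * (n - 2) * G^2
  den <- (n - 1)^2 - n * G^2
  if (den <= 0) return(0)
  t <- sqrt(num / den)
  min(1, 2 * n * stats::pt(t, df = n - 2, lower.tail = FALSE))
}

#' Grubbs outlier detection on side scores
#'
#' Iterative one-at-a-time Grubbs test: the statistic is the maximum
#' studentized deviation `G = max |S - mean(S)| / sd(S)`, its p-value comes
#' from the t-based Grubbs distribution, and the most extreme chromosome is
#' removed and the test repeated while `p < p_threshold`.
#'
#' @param scores A [side_scores()] vector (at least 7 chromosomes).
#' @param p_threshold Flagging threshold (default 0.1, permissive enough to
#'   catch borderline outliers near p = 0.05).
#' @return Data frame with columns `chromosome_id`, `score`, `grubbs_p` of
#'   flagged chromosomes, in removal order (possibly empty).
#' @export
grubbs_outliers <- function(scores, p_threshold = 0.1) {
  s <- as.numeric(scores)
  ids <- names(scores)
  if (length(s) < 7L) stop("Grubbs outlier detection needs >= 7 chromosomes")
  out <- data.frame(chromosome_id = character(0), score = numeric(0),
                    grubbs_p = numeric(0), stringsAsFactors = FALSE)
  while (length(s) >= 3L) {
    sdv <- stats::sd(s)
    if (sdv == 0) break
    dev <- abs(s - mean(s))
    i <- which.max(dev)
    G <- dev[i] / sdv
    p <- .grubbs_p(G, length(s))
    if (p >= p_threshold) break
    out <- rbind(out, data.frame(chromosome_id = ids[i], score = s[i],
                                 grubbs_p = p, stringsAsFactors = FALSE))
    s <- s[-i]; ids <- ids[-i]
  }
  out
}

#' Test one hotspot-SNP pair
#'
#' The single-pair pipeline: split the panel by the SNP's alleles, estimate
#' the rate map of each subpopulation with the same estimator, integrate the
#' fixed hotspot boundaries into strengths, and compare the observed
#' delta-rho against a fresh permutation null (raw comparison; the
#' chromosome-wide MAF-matched standardization needs the full scan and is
#' applied there).
#'
#' @param panel A [haplotype_panel()].
#' @param hotspot One-row data frame (or list) with `start`, `end` in bp.
#' @param snp SNP column index (polymorphic, MAF >= `min_fraction`).
#' @param config An [estimator_config()].
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation RNG.
#' @param min_fraction Minimum side fraction.
#' @param mode Permutation size mode, see [random_split()].
#' @return A one-row data frame (class `split_test`) with `snp`, `snp_id`,
#'   `maf`, `n0`, `n1`, `rho0`, `rho1`, `delta_rho`, `delta_freq_oriented`,
#'   `p_value`, `shapiro_p`; the null is attached as attribute `"null"`.
#' @export
split_test <- function(panel, hotspot, snp, config = estimator_config(),
                       n_perm = 200L, seed = 1L, min_fraction = 0.3,
                       mode = c("ideal", "fifty_fifty")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  mode <- match.arg(mode)
  maf <- minor_allele_freq(panel, snp)
  if (maf < min_fraction)
    stop("SNP MAF ", signif(maf, 3), " below the minimum side fraction ",
         min_fraction)
  interval <- c(hotspot$start, hotspot$end)
  sp <- split_by_allele(panel, snp)
  n0 <- nrow(sp$panel0$haplotypes); n1 <- nrow(sp$panel1$haplotypes)
  rho0 <- .window_strength(sp$panel0, interval, config)
  rho1 <- .window_strength(sp$panel1, interval, config)
  d <- delta_rho(rho0, rho1)
  d_freq <- if (n0 >= n1) d else -d
  null <- .with_local_seed(seed, {
    permutation_null(panel, hotspot, config, n_perm = n_perm,
                     min_fraction = min_fraction, mode = mode)
  })
  res <- data.frame(snp = snp, snp_id = panel$snps$snp_id[snp], maf = maf,
                    n0 = n0, n1 = n1, rho0 = rho0, rho1 = rho1,
                    delta_rho = d, delta_freq_oriented = d_freq,
                    p_value = association_p(d, null$deltas),
                    shapiro_p = null$shapiro_p,
                    stringsAsFactors = FALSE)
  class(res) <- c("split_test", "data.frame")
  attr(res, "null") <- null
  res
}

#' Re-test a hotspot-SNP pair after removing outlier chromosomes
#'
#' Drops the flagged chromosomes from the panel and reruns the single-pair
#' pipeline ([split_test()]) on the reduced panel, returning the new test and
#' the new normality p-value.  With an empty outlier set the result equals
#' the original test exactly.
#'
#' @param panel A [haplotype_panel()].
#' @param hotspot One-row data frame (or list) with `start`, `end`.
#' @param snp SNP column index.
#' @param outliers Character vector of chromosome ids (e.g. from
#'   [grubbs_outliers()]); must be a subset of the panel's.
#' @param config,n_perm,seed,min_fraction,mode Passed to [split_test()].
#' @return A `split_test` (see [split_test()]).
#' @export
retest_without_outliers <- function(panel, hotspot, snp, outliers,
                                    config = estimator_config(),
                                    n_perm = 200L, seed = 1L,
                                    min_fraction = 0.3,
                                    mode = c("ideal", "fifty_fifty")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  outliers <- as.character(outliers)
  if (!all(outliers %in% panel$chromosome_ids))
    stop("outliers must be chromosome ids present in the panel")
  keep <- !(panel$chromosome_ids %in% outliers)
  reduced <- if (all(keep)) panel else subset_panel(panel, rows = which(keep))
  split_test(reduced, hotspot, snp, config = config, n_perm = n_perm,
             seed = seed, min_fraction = min_fraction, mode = mode)
}
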