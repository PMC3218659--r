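#' Hot/cold direction test at the causal SNP of a simulated panel
#'
#' Splits a simulated benchmark panel by the alleles of its (annotated)
#' causal SNP and compares the estimated hotspot strengths of the hot-allele
#' and cold-allele subpopulations.  The hotspot interval is taken from a
#' [call_hotspots()] run on the combined panel (the call nearest the true
#' hotspot center); when no hotspot is called, a fallback interval of
#' `fallback_halfwidth` on each side of the true center is used so the
#' direction is still scored.
#'
#' @param panel A panel from [sample_panels()] (carries a `"truth"`
#'   attribute).
#' @param config An [estimator_config()].
#' @param window_segments,trim_segments Sliding-window parameters as in
#'   [ldsplit_scan()].
#' @param fallback_halfwidth Half-width (bp) of the fallback hotspot
#'   interval.
#' @return One-row data frame with `rho_hot`, `rho_cold`, `correct`
#'   (`rho_hot > rho_cold`; ties count as incorrect), `hotspot_called`,
#'   `low_maf`; or `NULL` when the causal SNP is absent from the panel or its
#'   MAF is below the evaluation threshold (flagged upstream).
#' @export
direction_test <- function(panel, config = estimator_config(),
                           window_segments = 500L, trim_segments = 50L,
                           fallback_halfwidth = 5000) {
  truth <- attr(panel, "truth")
  if (is.null(truth)) stop("panel carries no simulation truth")
  if (is.na(truth$causal_col) || isTRUE(truth$low_maf)) return(NULL)
  cc <- truth$causal_col
  if (panel$snps$monomorphic[cc]) return(NULL)

  prof <- estimate_rates(panel, config)
  calls <- call_hotspots(prof, config$Ne)
  called <- FALSE
  if (nrow(calls) > 0L) {
    i <- which.min(abs(calls$peak_center - truth$hotspot_center))
    interval <- c(calls$start[i], calls$end[i])
    called <- TRUE
  } else {
    interval <- truth$hotspot_center + c(-1, 1) * fallback_halfwidth
  }

  w <- .window_cols(ncol(panel$haplotypes), cc, window_segments,
                    trim_segments)
  wpanel <- subset_panel(panel, cols = w$cols)
  sp <- split_by_allele(wpanel, match(cc, w$cols))
  hot_is_1 <- truth$hot_allele == 1L
  rho1 <- .window_strength(sp$panel1, interval, config)
  rho0 <- .window_strength(sp$panel0, interval, config)
  rho_hot <- if (hot_is_1) rho1 else rho0
  rho_cold <- if (hot_is_1) rho0 else rho1
  data.frame(rho_hot = rho_hot, rho_cold = rho_cold,
             correct = rho_hot > rho_cold, hotspot_called = called,
             low_maf = FALSE)
}

#' Fraction of samples with the correct hot/cold direction
#'
#' A sample counts as a correct direction call when the hot-allele
#' subpopulation's estimated hotspot strength strictly exceeds the
#' cold-allele subpopulation's (ties count as incorrect: conservative, and
#' measure-zero for continuous estimators).
#'
#' @param rho_hot,rho_cold Vectors of subpopulation strengths across
#'   evaluated samples.
#' @return Fraction of correct direction calls.
#' @export
direction_accuracy <- function(rho_hot, rho_cold) {
  stopifnot(length(rho_hot) == length(rho_cold), length(rho_hot) > 0L)
  mean(rho_hot > rho_cold)
}

#' Tag-SNP confusion counts against simulation truth
#'
#' De-duplicates linked association signals by LD blocks: from each block the
#' tag is the causal SNP if it is a member, otherwise the member with the
#' smallest p-value (ties broken by smallest SNP index).  A tag is "true" iff
#' it is the causal SNP, and "positive" iff its p-value is below `alpha`.
#'
#' @param tests Data frame with columns `snp` and `p_value` (e.g. an
#'   [ldsplit_scan()]).
#' @param causal_snp Column index of the true causal SNP.
#' @param blocks LD blocks from [select_ld_blocks()] (built at r^2 >= 0.8
#'   over the tested SNPs).
#' @param alpha Positive-call threshold (default 0.05).
#' @return List of class `confusion_counts`: `TP`, `FP`, `TN`, `FN`.
#' @export
classify_tests <- function(tests, causal_snp, blocks, alpha = 0.05) {
  counts <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (b in blocks) {
    members <- intersect(b$member_snps, tests$snp)
    if (length(members) == 0L) next
    if (causal_snp %in% members) {
      tag <- causal_snp
    } else {
      pm <- tests$p_value[match(members, tests$snp)]
      tag <- min(members[pm == min(pm)])
    }
    p <- tests$p_value[match(tag, tests$snp)]
    truth <- tag == causal_snp
    positive <- p < alpha
    key <- if (truth && positive) "TP"
           else if (truth) "FN"
           else if (positive) "FP"
           else "TN"
    counts[[key]] <- counts[[key]] + 1L
  }
  structure(counts, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Tag-SNP confusion: TP=", x$TP, " FP=", x$FP, " TN=", x$TN,
      " FN=", x$FN, "\n", sep = "")
  invisible(x)
}

#' Sensitivity, specificity and PPV from confusion counts
#'
#' `TP/(TP+FN)`, `TN/(TN+FP)` and `TP/(TP+FP)`.  A ratio with a zero
#' denominator is undefined and reported as `NA`, not 0.
#'
#' @param counts A [classify_tests()] result.
#' @return Named numeric vector `c(sensitivity, specificity, ppv)`.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = ratio(counts$TP, counts$TP + counts$FN),
    specificity = ratio(counts$TN, counts$TN + counts$FP),
    ppv = ratio(counts$TP, counts$TP + counts$FP))
}
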