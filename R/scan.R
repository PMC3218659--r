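# sliding estimation window: SNP columns centered at a focal column,
# extended if needed so that the columns in cover_cols (the hotspot span)
# stay inside it -- a window that misses the hotspot would integrate to a
# zero strength.  trim_segments are discarded from each end that did not
# hit the panel edge, because rate estimates near a window edge depend on
# SNPs outside it.
.window_cols <- function(L, center_col, window_segments, trim_segments,
                         cover_cols = integer(0)) {
  half <- floor(window_segments / 2)
  lo <- max(1L, min(c(center_col - half, cover_cols)))
  hi <- min(L, max(c(center_col + half, cover_cols)))
  list(cols = lo:hi,
       trim_lo = if (lo > 1L) trim_segments else 0L,
       trim_hi = if (hi < L) trim_segments else 0L)
}

# columns overlapping a hotspot interval (at least one on each side)
.hotspot_cols <- function(positions, hotspot) {
  lo <- max(1L, sum(positions < hotspot$start))
  hi <- min(length(positions), sum(positions < hotspot$end) + 1L)
  lo:hi
}

#' Scan hotspots for SNP-allele association
#'
#' The full association engine.  For every hotspot (called from the panel's
#' own rate map unless supplied): build a permutation null of delta-rho from
#' random splits with the hotspot boundaries fixed, reject the hotspot if the
#' null fails Shapiro normality, and for every candidate SNP (inside the
#' hotspot or within `span_snps` SNPs of a boundary, MAF >= `maf_min`) split
#' the chromosomes by allele, re-estimate the rate map of each subpopulation
#' over a sliding window centered at the SNP, and compare the normalized
#' strength difference -- after MAF-matched standardization -- against the
#' standardized null.  P-values are mapped to Storey q-values globally over
#' all hotspot-SNP pairs of the run.
#'
#' The scan is reproducible bit-for-bit from `(panel, config, seed)`.
#'
#' @param panel A [haplotype_panel()].
#' @param hotspots Optional `hotspot_set` (data frame with `peak_center`,
#'   `start`, `end`).  When `NULL`, hotspots are called from a rate map of
#'   the full panel via [call_hotspots()].
#' @param config An [estimator_config()] used for every rate estimate of the
#'   run (observed splits and permutations alike; the contrast only requires
#'   the same estimator on both sides).
#' @param n_perm Random permutations per hotspot (default 200).
#' @param seed Master seed for all split randomness.
#' @param maf_min Candidate MAF floor (default 0.3; also guarantees each
#'   allele side holds at least 30% of chromosomes).
#' @param span_snps Candidate search span beyond each hotspot boundary in
#'   SNPs (default 200).
#' @param window_segments,trim_segments Sliding-window size and per-end trim,
#'   in segments (defaults 500 and 50).
#' @param alpha_shapiro Normality-gate level (default 0.05).
#' @param mode Permutation size mode, see [random_split()].
#' @param compare `"standardized"` (default): observed and null values are
#'   standardized before comparison; `"raw"`: compare raw delta-rho.
#' @param keep_pairs Keep homologous chromosomes of an individual together in
#'   permutations.
#' @return An object of class `ldsplit_scan`: a data frame with one row per
#'   hotspot-SNP pair (`hotspot`, `snp`, `snp_id`, `position`, `maf`, `n0`,
#'   `n1`, `rho0`, `rho1`, `delta_rho`, `delta_freq_oriented`, `z`,
#'   `p_value`, `q_value`, `dist_bp`, `dist_snps`) and attributes `hotspots`,
#'   `gated` (per-hotspot Shapiro gate results), `nulls`, `maf_stats`,
#'   `params`.
#' @export
ldsplit_scan <- function(panel, hotspots = NULL, config = estimator_config(),
                         n_perm = 200L, seed = 1L, maf_min = 0.3,
                         span_snps = 200L, window_segments = 500L,
                         trim_segments = 50L, alpha_shapiro = 0.05,
                         mode = c("ideal", "fifty_fifty"),
                         compare = c("standardized", "raw"),
                         keep_pairs = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  mode <- match.arg(mode)
  compare <- match.arg(compare)
  L <- ncol(panel$haplotypes)
  n_chrom <- nrow(panel$haplotypes)

  .with_local_seed(seed, {
    if (is.null(hotspots)) {
      prof <- estimate_rates(panel, config)
      hotspots <- call_hotspots(prof, config$Ne)
    }
    gated <- data.frame(hotspot = integer(0), shapiro_p = numeric(0),
                        pass = logical(0))
    nulls <- list()
    rows <- list()
    if (nrow(hotspots) > 0L) for (h in seq_len(nrow(hotspots))) {
      hs <- hotspots[h, ]
      ctr_col <- which.min(abs(panel$snps$position - hs$peak_center))
      w <- .window_cols(L, ctr_col, window_segments, trim_segments)
      wpanel <- subset_panel(panel, cols = w$cols)
      null_h <- permutation_null(wpanel, hs, config, n_perm = n_perm,
                                 mode = mode, keep_pairs = keep_pairs)
      nulls[[h]] <- null_h
      pass <- normality_gate(null_h, alpha_shapiro)
      gated <- rbind(gated, data.frame(hotspot = h,
                                       shapiro_p = null_h$shapiro_p,
                                       pass = pass))
      if (!pass) next
      cands <- candidate_snps(panel, hs, maf_min = maf_min,
                              span_snps = span_snps)
      hcols <- .hotspot_cols(panel$snps$position, hs)
      for (s in cands) {
        ws <- .window_cols(L, s, window_segments, trim_segments, hcols)
        spanel <- subset_panel(panel, cols = ws$cols)
        s_local <- match(s, ws$cols)
        sp <- split_by_allele(spanel, s_local)
        interval <- c(hs$start, hs$end)
        rho0 <- .window_strength(sp$panel0, interval, config)
        rho1 <- .window_strength(sp$panel1, interval, config)
        n0 <- nrow(sp$panel0$haplotypes)
        n1 <- nrow(sp$panel1$haplotypes)
        d <- delta_rho(rho0, rho1)
        dist <- pair_distances(panel$snps$position[s], hs,
                               panel$snps$position)
        rows[[length(rows) + 1L]] <- data.frame(
          hotspot = h, snp = s, snp_id = panel$snps$snp_id[s],
          position = panel$snps$position[s],
          maf = minor_allele_freq(panel, s),
          n0 = n0, n1 = n1, rho0 = rho0, rho1 = rho1,
          delta_rho = d,
          delta_freq_oriented = if (n0 >= n1) d else -d,
          dist_bp = dist[1L], dist_snps = dist[2L],
          stringsAsFactors = FALSE)
      }
    }

    if (length(rows) == 0L) {
      tests <- data.frame(hotspot = integer(0), snp = integer(0))
      maf_stats <- NULL
    } else {
      tests <- do.call(rbind, rows)
      maf_stats <- maf_bin_stats(tests$maf, tests$delta_freq_oriented,
                                 n_chrom)
      tests$z <- vapply(seq_len(nrow(tests)), function(i) {
        tryCatch(standardize_delta(tests$delta_freq_oriented[i],
                                   tests$maf[i], maf_stats),
                 error = function(e) NA_real_)
      }, 0)
      tests$p_value <- vapply(seq_len(nrow(tests)), function(i) {
        null_h <- nulls[[tests$hotspot[i]]]
        if (compare == "standardized" && !is.na(tests$z[i])) {
          zn <- vapply(null_h$deltas_size_oriented, function(dn) {
            tryCatch(standardize_delta(dn, tests$maf[i], maf_stats),
                     error = function(e) NA_real_)
          }, 0)
          association_p(tests$z[i], zn[!is.na(zn)])
        } else {
          association_p(tests$delta_rho[i], null_h$deltas)
        }
      }, 0)
      tests$q_value <- qvalues(tests$p_value)
    }
    structure(tests,
              class = c("ldsplit_scan", "data.frame"),
              hotspots = hotspots, gated = gated, nulls = nulls,
              maf_stats = maf_stats,
              params = list(config = config, n_perm = n_perm, seed = seed,
                            maf_min = maf_min, span_snps = span_snps,
                            window_segments = window_segments,
                            trim_segments = trim_segments,
                            alpha_shapiro = alpha_shapiro, mode = mode,
                            compare = compare, keep_pairs = keep_pairs,
                            n_chrom = n_chrom))
  })
}

#' Size-matched random-split null scan
#'
#' For every hotspot-SNP pair of a real scan, performs one random
#' pseudo-split of the chromosomes into sides of exactly the real sizes
#' `(n0, n1)` and recomputes delta-rho, standardization, p and q identically.
#' Under no true association the pseudo and real runs should look alike; with
#' real signal the pseudo q-values pile up near 1.
#'
#' @param panel The panel the scan was run on.
#' @param scan An [ldsplit_scan()] result.
#' @param seed Seed for the pseudo-split randomness.
#' @return An `ldsplit_scan`-shaped data frame of pseudo tests, one per real
#'   test.
#' @export
null_scan <- function(panel, scan, seed = 1L) {
  stopifnot(inherits(scan, "ldsplit_scan"))
  par <- attr(scan, "params")
  hotspots <- attr(scan, "hotspots")
  nulls <- attr(scan, "nulls")
  maf_stats <- attr(scan, "maf_stats")
  config <- par$config
  L <- ncol(panel$haplotypes)
  .with_local_seed(seed, {
    if (nrow(scan) == 0L) return(scan)
    rows <- lapply(seq_len(nrow(scan)), function(i) {
      t0 <- scan[i, ]
      hs <- hotspots[t0$hotspot, ]
      ws <- .window_cols(L, t0$snp, par$window_segments, par$trim_segments,
                         .hotspot_cols(panel$snps$position, hs))
      spanel <- subset_panel(panel, cols = ws$cols)
      sp <- random_split(spanel, min_fraction = par$maf_min,
                         sizes = c(t0$n0, t0$n1))
      interval <- c(hs$start, hs$end)
      rho0 <- .window_strength(sp$panel0, interval, config)
      rho1 <- .window_strength(sp$panel1, interval, config)
      d <- delta_rho(rho0, rho1)
      out <- t0
      out$rho0 <- rho0; out$rho1 <- rho1
      out$delta_rho <- d
      out$delta_freq_oriented <- if (t0$n0 >= t0$n1) d else -d
      out
    })
    tests <- do.call(rbind, rows)
    tests$z <- vapply(seq_len(nrow(tests)), function(i) {
      tryCatch(standardize_delta(tests$delta_freq_oriented[i], tests$maf[i],
                                 maf_stats),
               error = function(e) NA_real_)
    }, 0)
    tests$p_value <- vapply(seq_len(nrow(tests)), function(i) {
      null_h <- nulls[[tests$hotspot[i]]]
      if (par$compare == "standardized" && !is.na(tests$z[i])) {
        zn <- vapply(null_h$deltas_size_oriented, function(dn) {
          tryCatch(standardize_delta(dn, tests$maf[i], maf_stats),
                   error = function(e) NA_real_)
        }, 0)
        association_p(tests$z[i], zn[!is.na(zn)])
      } else {
        association_p(tests$delta_rho[i], null_h$deltas)
      }
    }, 0)
    tests$q_value <- qvalues(tests$p_value)
    attr(tests, "pseudo") <- TRUE
    tests
  })
}

#' @export
print.ldsplit_scan <- function(x, ...) {
  gated <- attr(x, "gated")
  cat("Allele-split hotspot association scan\n")
  cat("  hotspots: ", nrow(attr(x, "hotspots")),
      " (", sum(gated$pass), " passed the normality gate)\n", sep = "")
  cat("  hotspot-SNP pairs tested: ", nrow(x), "\n", sep = "")
  if (nrow(x) > 0L) {
    cat("  pairs with q < 0.01: ", sum(x$q_value < 0.01), "\n", sep = "")
    top <- x[order(x$p_value), ][seq_len(min(5L, nrow(x))), ]
    cat("  top pairs:\n")
    print.data.frame(top[, c("hotspot", "snp_id", "position", "maf",
                             "delta_rho", "p_value", "q_value")],
                     digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.ldsplit_scan <- function(object, ...) {
  gated <- attr(object, "gated")
  out <- list(
    n_hotspots = nrow(attr(object, "hotspots")),
    n_gated_pass = sum(gated$pass),
    n_tests = nrow(object),
    n_q01 = if (nrow(object)) sum(object$q_value < 0.01) else 0L,
    n_q05 = if (nrow(object)) sum(object$q_value < 0.05) else 0L,
    hotspots_with_hit = if (nrow(object))
      length(unique(object$hotspot[object$q_value < 0.01])) else 0L
  )
  class(out) <- "summary.ldsplit_scan"
  out
}

#' @export
print.summary.ldsplit_scan <- function(x, ...) {
  cat("Scan summary\n")
  cat("  hotspots called:       ", x$n_hotspots, "\n")
  cat("  passed normality gate: ", x$n_gated_pass, "\n")
  cat("  hotspot-SNP pairs:     ", x$n_tests, "\n")
  cat("  pairs q < 0.01:        ", x$n_q01, "\n")
  cat("  pairs q < 0.05:        ", x$n_q05, "\n")
  cat("  hotspots with a hit:   ", x$hotspots_with_hit, "\n")
  invisible(x)
}

#' @export
plot.ldsplit_scan <- function(x, ...) {
  if (nrow(x) == 0L) {
    warning("empty scan; nothing to plot")
    return(invisible(x))
  }
  hotspots <- attr(x, "hotspots")
  graphics::plot(x$position / 1000, -log10(pmax(x$p_value, 1e-4)),
                 xlab = "position (kb)",
                 ylab = expression(-log[10](p)),
                 pch = 16, col = ifelse(x$q_value < 0.01, "firebrick",
                                        "grey40"), ...)
  for (h in unique(x$hotspot)) {
    graphics::rect(hotspots$start[h] / 1000, graphics::par("usr")[3L],
                   hotspots$end[h] / 1000, graphics::par("usr")[4L],
                   col = grDevices::adjustcolor("steelblue", 0.15),
                   border = NA)
  }
  invisible(x)
}

#' Write scan results as TSV
#'
#' One row per hotspot-SNP pair with all test fields.
#'
#' @param scan An [ldsplit_scan()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
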