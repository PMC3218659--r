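#' Locate candidate peaks in a piecewise-constant rate map
#'
#' A peak is a segment (or plateau of equal-rate segments) whose rate strictly
#' exceeds both neighboring segments -- the discrete analogue of a zero first
#' derivative with negative second derivative.  Plateaus report their physical
#' midpoint, since the derivative criterion is ill-defined on a piecewise
#' constant map.
#'
#' @param profile A `rate_profile` with at least 3 segments.
#' @return Numeric vector of candidate peak centers (bp), in coordinate order.
#' @export
find_peaks <- function(profile) {
  stopifnot(inherits(profile, "rate_profile"))
  rho <- profile$rho_per_kb
  if (length(rho) < 3L) stop("need at least 3 segments to find peaks")
  r <- rle(rho)
  nruns <- length(r$values)
  if (nruns < 3L) return(numeric(0))
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  centers <- numeric(0)
  for (i in 2:(nruns - 1L)) {
    if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L]) {
      centers <- c(centers,
                   (profile$starts[run_start[i]] + profile$ends[run_end[i]]) / 2)
    }
  }
  centers
}

#' Fit a normal density to the rate map around a peak
#'
#' Least-squares fit of `amplitude * dnorm(x; center, sigma) + baseline` to
#' the rate map restricted to the 50-kb window centered on the candidate peak
#' (clipped at the profile ends).  Segment midpoints are the abscissae,
#' weighted by overlapped segment length.
#'
#' @param profile A `rate_profile`.
#' @param center Candidate peak center in bp, inside the profile.
#' @param half_window Half-width of the fit window in bp (default 25,000, i.e.
#'   a 50-kb window).
#' @return A list of class `peak_fit`: `center` (fitted), `sigma` (bp), `fwhm`
#'   (`2*sqrt(2*log(2))*sigma`), `fit_window`, `amplitude`, `baseline`, and
#'   `degenerate` (TRUE when the fit collapsed: flat window, sigma at zero or
#'   wider than the window -- such peaks are dropped by the caller).
#' @export
fit_peak <- function(profile, center, half_window = 25000) {
  stopifnot(inherits(profile, "rate_profile"))
  span <- c(profile$starts[1L], profile$ends[length(profile$ends)])
  if (center < span[1L] || center > span[2L])
    stop("peak center outside profile span")
  win <- c(max(span[1L], center - half_window),
           min(span[2L], center + half_window))
  ov <- pmin(profile$ends, win[2L]) - pmax(profile$starts, win[1L])
  sel <- ov > 0
  x <- (pmax(profile$starts, win[1L]) + pmin(profile$ends, win[2L]))[sel] / 2
  y <- profile$rho_per_kb[sel]
  w <- ov[sel]
  out <- list(center = center, sigma = NA_real_, fwhm = NA_real_,
              fit_window = win, amplitude = NA_real_, baseline = NA_real_,
              degenerate = TRUE)
  class(out) <- "peak_fit"
  ry <- diff(range(y))
  if (length(y) < 4L || ry <= 0) return(out)

  obj <- function(par) {
    mu <- par[1L]; sig <- exp(par[2L]); amp <- exp(par[3L]); base <- par[4L]
    pred <- amp * stats::dnorm(x, mu, sig) + base
    sum(w * (y - pred)^2)
  }
  # multi-start over the initial scale: Nelder-Mead from a single width
  # guess stalls when the true peak is much narrower or wider
  fit <- NULL
  for (sig0 in c(500, 2000, 8000)) {
    amp0 <- max(ry, 1e-6) * sqrt(2 * pi) * sig0
    f <- stats::optim(c(center, log(sig0), log(amp0), min(y)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  mu <- fit$par[1L]; sig <- exp(fit$par[2L]); amp <- exp(fit$par[3L])
  height <- amp * stats::dnorm(0, 0, sig)
  if (sig <= 1 || sig >= diff(win) || height < 0.05 * ry ||
      mu < win[1L] || mu > win[2L])
    return(out)
  out$center <- mu
  out$sigma <- sig
  out$fwhm <- 2 * sqrt(2 * log(2)) * sig
  out$amplitude <- amp
  out$baseline <- fit$par[4L]
  out$degenerate <- FALSE
  out
}

#' Delimit hotspot boundaries around a fitted peak
#'
#' Within the window of length `L = min(2*sigma, fwhm, 50 kb)` centered at the
#' fitted peak (under the default `"2sigma"` reading; the alternative
#' `"2fwhm"` reading uses `min(2*fwhm, fwhm, 50 kb)`), boundaries include the
#' maximal run of contiguous segments containing the peak whose rate exceeds
#' the length-weighted mean rate of the 50-kb fit window.  (The reference
#' mean is taken over the fit window rather than the span window itself:
#' on blocky piecewise-constant maps a flat-topped peak can fill the whole
#' span window, where it would never exceed its own mean.)  Boundaries snap
#' to segment (SNP) coordinates.
#'
#' @param profile A `rate_profile`.
#' @param fit A non-degenerate [fit_peak()] result.
#' @param reading Which interpretation of "2 x fitted peak width" to use.
#' @return Numeric `c(start, end)` (half-open, bp), or `NULL` when no segment
#'   in the window exceeds the window mean (the peak is dropped).
#' @export
delimit_hotspot <- function(profile, fit, reading = c("2sigma", "2fwhm")) {
  stopifnot(inherits(fit, "peak_fit"), !fit$degenerate)
  reading <- match.arg(reading)
  first_cand <- if (reading == "2sigma") 2 * fit$sigma else 2 * fit$fwhm
  span_len <- min(first_cand, fit$fwhm, 50000)
  win <- c(fit$center - span_len / 2, fit$center + span_len / 2)
  ov <- pmin(profile$ends, win[2L]) - pmax(profile$starts, win[1L])
  sel <- which(ov > 0)
  if (length(sel) == 0L) return(NULL)
  ref <- fit$fit_window
  ov_ref <- pmin(profile$ends, ref[2L]) - pmax(profile$starts, ref[1L])
  refsel <- ov_ref > 0
  mean_rho <- sum(profile$rho_per_kb[refsel] * ov_ref[refsel]) /
    sum(ov_ref[refsel])
  above <- profile$rho_per_kb[sel] > mean_rho
  # segment containing the peak center
  peak_seg <- which(profile$starts <= fit$center & profile$ends > fit$center)
  if (length(peak_seg) == 0L)
    peak_seg <- sel[which.min(abs((profile$starts + profile$ends)[sel] / 2 -
                                  fit$center))]
  ip <- match(peak_seg, sel)
  if (is.na(ip) || !above[ip]) return(NULL)
  lo <- ip
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- ip
  while (hi < length(sel) && above[hi + 1L]) hi <- hi + 1L
  c(profile$starts[sel[lo]], profile$ends[sel[hi]])
}

#' Resolve overlapping adjacent hotspots
#'
#' For each overlapping adjacent pair, both boundaries are moved to the
#' midpoint of the minimum-rate segment in the valley between the two peak
#' centers, applied left to right along the coordinate-sorted list.
#'
#' @param hotspots Data frame with columns `peak_center`, `start`, `end`,
#'   coordinate-sorted by peak center.
#' @param profile The `rate_profile` the hotspots were called from.
#' @return The data frame with non-overlapping boundaries.
#' @export
resolve_overlaps <- function(hotspots, profile) {
  if (nrow(hotspots) < 2L) return(hotspots)
  for (i in seq_len(nrow(hotspots) - 1L)) {
    if (hotspots$end[i] > hotspots$start[i + 1L]) {
      lo <- hotspots$peak_center[i]; hi <- hotspots$peak_center[i + 1L]
      sel <- which(profile$ends > lo & profile$starts < hi)
      valley <- sel[which.min(profile$rho_per_kb[sel])]
      mid <- (max(profile$starts[valley], lo) +
              min(profile$ends[valley], hi)) / 2
      hotspots$end[i] <- mid
      hotspots$start[i + 1L] <- mid
    }
  }
  hotspots
}

#' Call recombination hotspots from a rate profile
#'
#' The full calling pipeline: locate peaks, fit a normal density in the 50-kb
#' window around each, delimit boundaries, resolve overlaps at valley
#' midpoints, and keep calls with width at most 20 kb and average rate above
#' 1 cM/Mb.
#'
#' @param profile A `rate_profile`.
#' @param Ne Effective population size for the cM/Mb conversion of the
#'   average-rate filter.
#' @param max_width_bp Maximum hotspot width (default 20,000 bp).
#' @param min_avg_cm_mb Minimum average rate in cM/Mb (default 1).
#' @param reading Passed to [delimit_hotspot()].
#' @return A data frame of class `hotspot_set` with columns `peak_center`,
#'   `start`, `end`, `width`, `strength` (rho x kb), `avg_rate_cm_mb`,
#'   `sigma`, `fwhm`; disjoint and coordinate-sorted.
#' @export
call_hotspots <- function(profile, Ne = 10000, max_width_bp = 20000,
                          min_avg_cm_mb = 1, reading = c("2sigma", "2fwhm")) {
  stopifnot(inherits(profile, "rate_profile"))
  reading <- match.arg(reading)
  empty <- data.frame(peak_center = numeric(0), start = numeric(0),
                      end = numeric(0), width = numeric(0),
                      strength = numeric(0), avg_rate_cm_mb = numeric(0),
                      sigma = numeric(0), fwhm = numeric(0))
  class(empty) <- c("hotspot_set", "data.frame")
  if (length(profile$rho_per_kb) < 3L) return(empty)
  centers <- find_peaks(profile)
  if (length(centers) == 0L) return(empty)
  rows <- list()
  for (ctr in centers) {
    fit <- fit_peak(profile, ctr)
    if (fit$degenerate) next
    bounds <- delimit_hotspot(profile, fit, reading = reading)
    if (is.null(bounds)) next
    rows[[length(rows) + 1L]] <- data.frame(
      peak_center = fit$center, start = bounds[1L], end = bounds[2L],
      sigma = fit$sigma, fwhm = fit$fwhm)
  }
  if (length(rows) == 0L) return(empty)
  hs <- do.call(rbind, rows)
  hs <- hs[order(hs$peak_center), , drop = FALSE]
  hs <- resolve_overlaps(hs, profile)
  hs$width <- hs$end - hs$start
  hs$strength <- vapply(seq_len(nrow(hs)), function(i)
    hotspot_strength(profile, c(hs$start[i], hs$end[i])), 0)
  hs$avg_rate_cm_mb <- rho_to_cm_per_mb(hs$strength / (hs$width / 1000), Ne)
  keep <- hs$width > 0 & hs$width <= max_width_bp &
    hs$avg_rate_cm_mb > min_avg_cm_mb &
    hs$start <= hs$peak_center & hs$peak_center < hs$end
  hs <- hs[keep, c("peak_center", "start", "end", "width", "strength",
                   "avg_rate_cm_mb", "sigma", "fwhm"), drop = FALSE]
  rownames(hs) <- NULL
  class(hs) <- c("hotspot_set", "data.frame")
  hs
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("Hotspot calls: ", nrow(x), "\n", sep = "")
  if (nrow(x) > 0L) print.data.frame(x, digits = 4)
  invisible(x)
}

#' Export hotspot calls as BED
#'
#' Internal coordinates are 1-based; BED output is 0-based half-open, with
#' strength and average rate as extra columns.
#'
#' @param hotspots A `hotspot_set`.
#' @param path Output path.
#' @param chrom Chromosome name for the first BED column.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(hotspots, path, chrom = "chr") {
  bed <- data.frame(
    chrom = chrom,
    start = floor(hotspots$start) - 1L,
    end = ceiling(hotspots$end) - 1L,
    name = sprintf("hotspot_%d", seq_len(nrow(hotspots))),
    score = 0L,
    strand = ".",
    strength = signif(hotspots$strength, 6),
    avg_rate_cm_mb = signif(hotspots$avg_rate_cm_mb, 6)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
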