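#' Configuration for the haplotype-copying rate estimator
#'
#' The per-segment population recombination rate map is estimated by a
#' penalized composite likelihood under a haplotype-copying model: each
#' haplotype is modeled as an imperfect mosaic of the haplotypes preceding it
#' in a random ordering, with per-segment switching intensity proportional to
#' the segment's rho.  The log composite likelihood, averaged over
#' `n_orderings` seeded random orderings, minus `block_penalty` times the
#' number of distinct adjacent rate levels, is maximized over per-segment
#' log-rho (grid line search per segment combined with an exact fused dynamic
#' program for the penalty, iterated `n_iterations` times).
#'
#' @param n_orderings Number of random haplotype orderings averaged in the
#'   composite likelihood (>= 1).
#' @param block_penalty Nonnegative penalty per change of rate level between
#'   adjacent segments, in log-likelihood units.  Larger values give smoother,
#'   blockier maps.
#' @param n_iterations Number of forward-backward / segmentation refinement
#'   cycles (>= 1).
#' @param Ne Effective population size, used only to convert rho to cM/Mb for
#'   the hotspot average-rate filter.  Default 10,000, the conventional human
#'   value.
#' @param seed Integer seed controlling all stochasticity of the estimator
#'   (the random orderings); recorded in the output profile metadata so that
#'   permutation p-values are reproducible.
#' @param rho_grid Grid of candidate per-kb rates (log-spaced).  The smallest
#'   value is the estimator's lower boundary, reported for segments carrying
#'   no recombination signal.
#' @param min_chromosomes Minimum number of chromosomes required for
#'   estimation; LD-based rate estimation is underpowered on tiny
#'   subpopulations.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(n_orderings = 6L, block_penalty = 5,
                             n_iterations = 4L, Ne = 10000L, seed = 1L,
                             rho_grid = exp(seq(log(0.01), log(100),
                                                length.out = 25L)),
                             min_chromosomes = 10L) {
  stopifnot(n_orderings >= 1L, n_iterations >= 1L, block_penalty >= 0,
            Ne > 0, all(rho_grid > 0), !is.unsorted(rho_grid))
  structure(list(n_orderings = as.integer(n_orderings),
                 block_penalty = block_penalty,
                 n_iterations = as.integer(n_iterations),
                 Ne = as.integer(Ne), seed = as.integer(seed),
                 rho_grid = rho_grid,
                 min_chromosomes = as.integer(min_chromosomes)),
            class = "estimator_config")
}

.panel_hash <- function(panel) {
  x <- c(dim(panel$haplotypes), panel$snps$position,
         panel$haplotypes[seq(1L, length(panel$haplotypes), by = 7L)])
  sprintf("%08x",
          as.integer(sum(as.numeric(x) * (seq_along(x) %% 97 + 1)) %% 2^31))
}

#' Estimate a piecewise-constant recombination-rate map
#'
#' Fits per-segment population rates rho = 4*Ne*r (in units of rho per kb)
#' between consecutive SNPs of the panel, under the penalized
#' haplotype-copying composite likelihood described in [estimator_config()].
#'
#' The result is deterministic given `(panel, config)`: haplotype rows are
#' first sorted into a canonical (lexicographic) order, so the estimate is
#' exactly invariant to the row order of the input panel, and the random
#' orderings are drawn from `config$seed` without touching the caller's RNG
#' state.
#'
#' @param panel A [haplotype_panel()] with at least `config$min_chromosomes`
#'   chromosomes and 3 SNPs.
#' @param config An [estimator_config()].
#' @return An object of class `rate_profile`: list with `starts`, `ends`
#'   (half-open segment bounds in bp, tiling `[first SNP, last SNP)`),
#'   `rho_per_kb`, and `meta` (estimator id, seed, panel hash, config).
#' @export
estimate_rates <- function(panel, config = estimator_config()) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(config, "estimator_config"))
  haps <- panel$haplotypes
  n <- nrow(haps); L <- ncol(haps)
  if (n < config$min_chromosomes)
    stop("only ", n, " chromosomes; rate estimation on subpopulations ",
         "smaller than ", config$min_chromosomes,
         " chromosomes is unreliable and is refused")
  if (L < 3L) stop("need at least 3 SNPs to estimate a rate map")

  # canonical row order: exact invariance to input row permutation
  ord_canon <- do.call(order, c(as.data.frame(haps),
                                list(method = "radix")))
  haps <- haps[ord_canon, , drop = FALSE]

  pos <- panel$snps$position
  seg_kb <- diff(pos) / 1000
  S <- L - 1L
  grid <- config$rho_grid
  V <- length(grid)
  grid_seg <- outer(seg_kb, grid)          # candidate total rho per segment

  orderings <- .with_local_seed(config$seed, {
    vapply(seq_len(config$n_orderings),
           function(i) sample.int(n) - 1L, integer(n))
  })

  # Iterated refinement: each cycle computes exact per-segment profile
  # scores at the current map and proposes a new map by the fused DP.  The
  # scores are exact only for single-coordinate moves, so jumping straight
  # to the proposal can overshoot (all segments move at once); instead the
  # penalized likelihood is evaluated along a log-space line search between
  # the current and proposed maps and the best visited map overall wins.
  n_blocks <- function(r) 1L + sum(diff(r) != 0)
  penalized <- function(ll, r) ll - config$block_penalty * (n_blocks(r) - 1L)
  rho_per_kb <- rep(1, S)                  # flat start
  best_obj <- penalized(pac_loglik(haps, rho_per_kb * seg_kb, orderings),
                        rho_per_kb)
  best_rho <- rho_per_kb
  for (it in seq_len(config$n_iterations)) {
    res <- pac_grid_scores(haps, rho_per_kb * seg_kb, grid_seg, orderings)
    prop <- grid[.fused_dp(res$scores, config$block_penalty)]
    if (identical(prop, rho_per_kb)) break
    step_obj <- -Inf
    step_rho <- rho_per_kb
    for (a in c(0.25, 0.5, 0.75, 1)) {
      cand <- exp((1 - a) * log(rho_per_kb) + a * log(prop))
      obj <- penalized(pac_loglik(haps, cand * seg_kb, orderings), cand)
      if (obj > step_obj) {
        step_obj <- obj
        step_rho <- cand
      }
    }
    rho_per_kb <- step_rho
    if (step_obj > best_obj) {
      best_obj <- step_obj
      best_rho <- step_rho
    }
  }
  rho_per_kb <- best_rho

  structure(list(starts = pos[-L], ends = pos[-1L],
                 rho_per_kb = rho_per_kb,
                 meta = list(estimator = "pac", seed = config$seed,
                             panel_hash = .panel_hash(panel),
                             n_orderings = config$n_orderings,
                             block_penalty = config$block_penalty,
                             n_iterations = config$n_iterations,
                             Ne = config$Ne)),
            class = "rate_profile")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# exact maximization of sum_j score[j, v_j] - penalty * #{j : v_j != v_{j+1}}
# by dynamic programming over segment levels
.fused_dp <- function(scores, penalty) {
  S <- nrow(scores); V <- ncol(scores)
  if (S == 1L) return(which.max(scores[1L, ]))
  best <- scores[1L, ]
  back <- matrix(0L, S, V)
  for (j in 2:S) {
    top <- which.max(best)
    alt <- best[top] - penalty
    stay <- best >= alt
    prev <- ifelse(stay, best, alt)
    back[j, ] <- ifelse(stay, seq_len(V), top)
    best <- scores[j, ] + prev
  }
  levels <- integer(S)
  levels[S] <- which.max(best)
  for (j in S:2) levels[j - 1L] <- back[j, levels[j]]
  levels
}

#' @export
print.rate_profile <- function(x, ...) {
  cat("Recombination rate profile (", length(x$rho_per_kb), " segments, ",
      x$starts[1L], "-", x$ends[length(x$ends)], " bp)\n", sep = "")
  cat("  rho/kb: min ", signif(min(x$rho_per_kb), 3), ", median ",
      signif(stats::median(x$rho_per_kb), 3), ", max ",
      signif(max(x$rho_per_kb), 3), "\n", sep = "")
  cat("  estimator: ", x$meta$estimator, " (seed ", x$meta$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Hotspot strength over an interval of a rate profile
#'
#' The strength of an interval is the sum over segments of rho_per_kb times
#' the overlapped physical length in kb (i.e. the integral of the rate map,
#' in rho x kb units).  Partial segment overlaps are pro-rated; the measure is
#' additive over a partition of the interval.
#'
#' @param profile A `rate_profile`.
#' @param interval Numeric `c(start, end)` in bp, half-open, within the
#'   profile span.
#' @return Strength in rho x kb units (0 for a zero-length interval).
#' @export
hotspot_strength <- function(profile, interval) {
  stopifnot(inherits(profile, "rate_profile"), length(interval) == 2L)
  if (interval[2L] < interval[1L]) stop("inverted interval")
  ov <- pmin(profile$ends, interval[2L]) - pmax(profile$starts, interval[1L])
  ov[ov < 0] <- 0
  sum(profile$rho_per_kb * ov / 1000)
}

#' Convert a population rate to cM/Mb
#'
#' rho = 4*Ne*r with r the per-generation recombination fraction per bp, so
#' `r = rho_per_kb / (4 * Ne * 1000)` and 1 cM/Mb corresponds to r = 1e-8/bp.
#'
#' @param rho_per_kb Population rate in rho (=4 Ne r) per kb.
#' @param Ne Effective population size (> 0).
#' @return Rate in cM/Mb.
#' @export
rho_to_cm_per_mb <- function(rho_per_kb, Ne = 10000) {
  stopifnot(Ne > 0)
  rho_per_kb / (4 * Ne * 1000) * 1e8
}

#' Read/write a rate profile as TSV
#'
#' Columns `start`, `end`, `rho_per_kb` with estimator metadata in `#key=value`
#' header lines.  Profiles produced by external estimators can be supplied in
#' the same format, so real-data users may plug in their preferred rate maps.
#'
#' @param profile A `rate_profile`.
#' @param path File path.
#' @return `write_rate_profile`: `path` invisibly; `read_rate_profile`: a
#'   `rate_profile`.
#' @export
write_rate_profile <- function(profile, path) {
  stopifnot(inherits(profile, "rate_profile"))
  meta <- profile$meta[!vapply(profile$meta, is.null, TRUE)]
  hdr <- paste0("#", names(meta), "=",
                vapply(meta, function(x) paste(x, collapse = ","), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(start = profile$starts, end = profile$ends,
               rho_per_kb = profile$rho_per_kb),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_profile
#' @export
read_rate_profile <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  rate_profile(df$start, df$end, df$rho_per_kb, meta = meta)
}

#' Assemble a rate profile from raw segment data
#'
#' @param starts,ends Segment bounds in bp (consecutive, half-open tiling).
#' @param rho_per_kb Nonnegative per-segment rates.
#' @param meta Optional metadata list.
#' @return A `rate_profile`.
#' @export
rate_profile <- function(starts, ends, rho_per_kb, meta = list()) {
  stopifnot(length(starts) == length(ends),
            length(starts) == length(rho_per_kb),
            all(ends > starts), all(rho_per_kb >= 0))
  if (length(starts) > 1L && any(starts[-1L] != ends[-length(ends)]))
    stop("segments must tile the span contiguously")
  structure(list(starts = as.numeric(starts), ends = as.numeric(ends),
                 rho_per_kb = as.numeric(rho_per_kb), meta = meta),
            class = "rate_profile")
}
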