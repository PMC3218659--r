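# Shared fixture builders: everything is generated in code at test time.

# random biallelic panel with positions on a rough grid
toy_panel <- function(n = 20L, L = 12L, seed = 1L, spacing = 1000L) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n * L, 1L, 0.4), n, L)
    f <- colMeans(m)
    if (all(f > 0 & f < 1)) break   # polymorphic everywhere, simpler tests
  }
  haplotype_panel(m, positions = seq_len(L) * spacing)
}

# panel built as mosaics of two founder haplotypes with crossovers placed
# inside one segment: that segment carries all four gametes with its
# neighbors; per-haplotype private mutations keep recombinants distinct so
# the copying model cannot sidestep the switch
mosaic_panel <- function(n = 40L, L = 20L, hot_segment = 10L, seed = 1L,
                         n_recomb = 16L, spacing = 500L) {
  set.seed(seed)
  f1 <- rep(c(0L, 1L), length.out = L)
  f2 <- 1L - f1
  haps <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    base <- if (i %% 2L == 0L) f1 else f2
    haps[i, ] <- base
  }
  # recombinants switch founders after the hot segment
  for (i in seq_len(n_recomb)) {
    left <- if (i %% 2L == 0L) f1 else f2
    right <- if (i %% 2L == 0L) f2 else f1
    haps[i, ] <- c(left[seq_len(hot_segment)],
                   right[(hot_segment + 1L):L])
  }
  # sprinkle private mutations (about one per haplotype)
  flip <- runif(length(haps)) < 1 / L
  haps[flip] <- 1L - haps[flip]
  haplotype_panel(haps, positions = seq_len(L) * spacing)
}

# piecewise-constant profile with a Gaussian bump of the given peak height
# (rho/kb units) on a flat baseline
gaussian_profile <- function(center = 50000, sigma = 2000, height = 10,
                             baseline = 0.1, span = 100000,
                             seg_len = 500) {
  starts <- seq(0, span - seg_len, by = seg_len) + 1
  ends <- starts + seg_len
  mid <- (starts + ends) / 2
  rho <- baseline + height * exp(-(mid - center)^2 / (2 * sigma^2))
  rate_profile(starts, ends, rho)
}

# small forward-simulation config for fast integration tests
tiny_sim_config <- function(...) {
  args <- list(pop_size = 120L, generations = 80L, mutation_rate = 0.15,
               trajectory_tol = 0.06)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# a fabricated permutation_null object with fully controlled internals
fake_null <- function(deltas, membership, rho0 = NULL, rho1 = NULL,
                      ids = NULL) {
  n_perm <- length(deltas)
  if (is.null(rho0)) rho0 <- ifelse(deltas >= 0, 1 + deltas, 1)
  if (is.null(rho1)) rho1 <- ifelse(deltas >= 0, 1, 1 - deltas)
  if (is.null(ids)) ids <- paste0("hap", seq_len(nrow(membership)))
  n1 <- colSums(membership)
  n0 <- nrow(membership) - n1
  structure(list(
    deltas = deltas,
    deltas_size_oriented = ifelse(n1 > n0, -deltas, deltas),
    rho0 = rho0, rho1 = rho1,
    membership = membership,
    hotter_side = ifelse(rho0 == rho1, NA_integer_,
                         ifelse(rho0 > rho1, 0L, 1L)),
    shapiro_p = if (n_perm >= 3L) shapiro.test(deltas)$p.value else NA_real_,
    hotspot = data.frame(start = 0, end = 1000),
    n_perm = n_perm,
    chromosome_ids = ids
  ), class = "permutation_null")
}
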