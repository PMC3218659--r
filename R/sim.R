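#' Configuration of the forward-time crossover/BGC simulator
#'
#' A constant-size diploid population evolves neutrally on a region (default
#' 200 kb) with at most one crossover per meiosis.  A hotspot centered in the
#' region is controlled by a planted causal SNP: with two cold alleles the
#' crossover probability in the region is the background value and the
#' breakpoint is uniform; a heterozygote is 10x hotter and a hot homozygote
#' 20x, with breakpoints drawn from a normal around the hotspot center.
#' Biased gene conversion is modeled as the initiating (hot) haplotype
#' repairing a Gaussian-length tract around the breakpoint by copying from
#' its homolog, so a heterozygous causal SNP inside the tract converts
#' hot to cold.  Neutral mutations follow an infinite-site Poisson process
#' and fixed or lost sites are removed.  The hot-allele frequency follows a
#' linear trajectory between `start_hot_freq` and `end_hot_freq`, enforced by
#' rejection sampling of whole offspring generations ("cooling" when it
#' falls from 1, "heating" when it rises from 0).
#'
#' @param pop_size Number of diploid individuals (default 5,000).
#' @param generations Number of generations (default 3,000).
#' @param region_length Region length in bp (default 200,000).
#' @param background_crossover_prob Per-meiosis crossover probability in the
#'   region for cold homozygotes (default 0.001: one crossover per 200-Mb
#'   genome scaled to 200 kb).
#' @param het_multiplier,hom_hot_multiplier Crossover-probability multipliers
#'   for causal heterozygotes (10) and hot homozygotes (20).
#' @param causal_position Position of the causal SNP in bp (default 100,000;
#'   `NA` simulates a null region with no causal SNP and no hotspot).
#' @param hotspot_center Hotspot center in bp (default 100,000).
#' @param breakpoint_sigma SD of the hotspot breakpoint normal in bp
#'   (default 1,000; truncated to the region).
#' @param bgc_prob Probability of biased gene conversion conditional on a
#'   crossover (default 0.5, which makes 75% of recombinant gametes from
#'   heterozygous parents carry the cold allele when the tract covers the
#'   causal SNP).
#' @param tract_mean,tract_sigma Mean and SD of the Gaussian conversion-tract
#'   length in bp (defaults 500 and `tract_mean/5`; negative draws are
#'   truncated at 0).
#' @param mutation_rate Expected new mutations per haplotype per generation
#'   over the region (default 0.05, calibrated so that scaled runs carry on
#'   the order of a couple hundred segregating sites with MAF >= 0.05 at
#'   sampling time).
#' @param start_hot_freq,end_hot_freq Hot-allele frequencies at the start and
#'   end of the linear trajectory (defaults 1.0 and 0.5: the cooling model).
#' @param recurrent_causal_mutation Allow the causal site to mutate
#'   hot <-> cold recurrently at 10x the background per-site rate.
#' @param trajectory_tol Acceptance half-width around the trajectory target
#'   frequency (default 0.02).
#' @param max_tries Rejection budget per generation (default 200).
#' @param seed Master seed for [evolve_population()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pop_size = 5000L, generations = 3000L,
                       region_length = 200000L,
                       background_crossover_prob = 0.001,
                       het_multiplier = 10, hom_hot_multiplier = 20,
                       causal_position = 100000L, hotspot_center = 100000L,
                       breakpoint_sigma = 1000, bgc_prob = 0.5,
                       tract_mean = 500, tract_sigma = tract_mean / 5,
                       mutation_rate = 0.05,
                       start_hot_freq = 1.0, end_hot_freq = 0.5,
                       recurrent_causal_mutation = FALSE,
                       trajectory_tol = 0.02, max_tries = 200L, seed = 1L) {
  stopifnot(pop_size >= 2L, generations >= 1L, region_length > 0,
            background_crossover_prob >= 0, het_multiplier >= 1,
            hom_hot_multiplier >= 1, bgc_prob >= 0, bgc_prob <= 1,
            start_hot_freq >= 0, start_hot_freq <= 1,
            end_hot_freq >= 0, end_hot_freq <= 1,
            mutation_rate >= 0, trajectory_tol > 0)
  structure(list(
    pop_size = as.integer(pop_size), generations = as.integer(generations),
    region_length = as.numeric(region_length),
    background_crossover_prob = background_crossover_prob,
    het_multiplier = het_multiplier, hom_hot_multiplier = hom_hot_multiplier,
    causal_position = causal_position, hotspot_center = hotspot_center,
    breakpoint_sigma = breakpoint_sigma, bgc_prob = bgc_prob,
    tract_mean = tract_mean, tract_sigma = tract_sigma,
    mutation_rate = mutation_rate,
    start_hot_freq = start_hot_freq, end_hot_freq = end_hot_freq,
    recurrent_causal_mutation = isTRUE(recurrent_causal_mutation),
    trajectory_tol = trajectory_tol, max_tries = as.integer(max_tries),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Construct a simulator population
#'
#' @param haps Integer 0/1 matrix, two rows per individual (derived allele
#'   coded 1).
#' @param positions Site positions in bp, strictly increasing, one per
#'   column.
#' @param causal_col Column index of the causal SNP (`NA` if absent).
#' @param hot_allele Allele value (0/1) that is hot at the causal SNP.
#' @param sex Integer vector (0 = female, 1 = male), one per individual.
#' @param generation Generation counter.
#' @return A list of class `sim_population`.
#' @export
sim_population <- function(haps, positions, causal_col = NA_integer_,
                           hot_allele = 0L, sex = NULL, generation = 0L) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  n_ind <- nrow(haps) / 2L
  stopifnot(nrow(haps) %% 2L == 0L, length(positions) == ncol(haps))
  if (is.null(sex)) sex <- rep_len(c(0L, 1L), n_ind)
  structure(list(haps = haps, positions = as.numeric(positions),
                 causal_col = causal_col, hot_allele = as.integer(hot_allele),
                 sex = as.integer(sex), generation = as.integer(generation)),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Forward-sim population: ", nrow(x$haps) / 2L, " diploids, ",
      ncol(x$haps), " segregating sites, generation ", x$generation, "\n",
      sep = "")
  if (!is.na(x$causal_col))
    cat("  causal SNP at ", x$positions[x$causal_col], " bp; hot-allele ",
        "frequency ", signif(hot_freq(x), 4), "\n", sep = "")
  invisible(x)
}

#' Hot-allele frequency at the causal SNP
#' @param pop A `sim_population` with a causal SNP.
#' @return Frequency in `[0, 1]`.
#' @export
hot_freq <- function(pop) {
  stopifnot(!is.na(pop$causal_col))
  mean(pop$haps[, pop$causal_col] == pop$hot_allele)
}

.initial_population <- function(config) {
  N <- config$pop_size
  if (is.na(config$causal_position)) {
    pop <- sim_population(matrix(0L, 2L * N, 0L), numeric(0))
  } else {
    # derived allele (coded 1) enters as a single copy; with a cooling model
    # the ancestral allele is hot, with a heating model the derived one is
    col <- integer(2L * N)
    col[sample.int(2L * N, 1L)] <- 1L
    hot_allele <- if (config$start_hot_freq >= 0.5) 0L else 1L
    pop <- sim_population(matrix(col, ncol = 1L),
                          positions = config$causal_position,
                          causal_col = 1L, hot_allele = hot_allele)
  }
  pop$sex <- .draw_sexes(N)
  pop
}

.draw_sexes <- function(N) {
  repeat {
    sex <- as.integer(stats::runif(N) < 0.5)
    if (any(sex == 0L) && any(sex == 1L)) return(sex)
  }
}

#' Crossover probability for a causal genotype
#'
#' @param genotype One of `"cold/cold"`, `"het"`, `"hot/hot"`.
#' @param config A [sim_config()].
#' @return Per-meiosis crossover probability in the region (0.001 / 0.01 /
#'   0.02 under the defaults).
#' @export
crossover_probability <- function(genotype = c("cold/cold", "het", "hot/hot"),
                                  config = sim_config()) {
  genotype <- match.arg(genotype)
  mult <- switch(genotype, "cold/cold" = 1,
                 "het" = config$het_multiplier,
                 "hot/hot" = config$hom_hot_multiplier)
  config$background_crossover_prob * mult
}

#' Sample crossover breakpoints
#'
#' Background meioses place the breakpoint uniformly on the region; hotspot
#' meioses draw from a normal centered at the hotspot (truncated to the
#' region).
#'
#' @param is_hot_meiosis Logical.
#' @param config A [sim_config()].
#' @param n Number of draws.
#' @return Breakpoint positions in bp, inside `[0, region_length)`.
#' @export
sample_breakpoint <- function(is_hot_meiosis, config = sim_config(), n = 1L) {
  if (!is_hot_meiosis) return(stats::runif(n, 0, config$region_length))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, config$hotspot_center, config$breakpoint_sigma)
    out <- c(out, x[x > 0 & x < config$region_length])
  }
  out[seq_len(n)]
}

#' Simulate meioses of one parent
#'
#' Runs the meiosis operator (crossover decision, breakpoint draw, biased
#' gene conversion, flank exchange) `n` times on one individual of a
#' population and returns the gametes with their event records.
#'
#' @param pop A [sim_population()].
#' @param individual Individual index (1-based).
#' @param config A [sim_config()].
#' @param n Number of meioses.
#' @return List with `gametes` (n x sites matrix) and `events` (data frame
#'   with `recombinant`, `causal_allele`, `transmitted_hot`, `bgc`,
#'   `breakpoint`, `het`).
#' @export
meiosis <- function(pop, individual = 1L, config = sim_config(), n = 1L) {
  stopifnot(inherits(pop, "sim_population"))
  rows <- c(2L * individual - 1L, 2L * individual)
  haps <- pop$haps[rows, , drop = FALSE]
  n_off <- as.integer(ceiling(n / 2))
  res <- sim_gametes(
    haps, pop$positions,
    causal_col = if (is.na(pop$causal_col)) -1L else pop$causal_col - 1L,
    hot_allele = pop$hot_allele,
    parents = matrix(0L, n_off, 2L),
    p_background = config$background_crossover_prob,
    het_mult = config$het_multiplier, hom_mult = config$hom_hot_multiplier,
    hotspot_center = config$hotspot_center,
    bp_sigma = config$breakpoint_sigma,
    bgc_prob = config$bgc_prob, tract_mean = config$tract_mean,
    tract_sigma = config$tract_sigma,
    region_length = config$region_length)
  keep <- seq_len(n)
  ev <- data.frame(recombinant = res$recombinant[keep] == 1L,
                   causal_allele = res$causal_allele[keep],
                   bgc = res$bgc[keep] == 1L,
                   breakpoint = res$breakpoint[keep],
                   het = res$het[keep] == 1L)
  ev$transmitted_hot <- ev$causal_allele == pop$hot_allele
  list(gametes = res$gametes[keep, , drop = FALSE], events = ev)
}

#' Apply one generation of mutation and site bookkeeping
#'
#' Adds Poisson(`mutation_rate`) new infinite-site mutations per haplotype at
#' fresh positions, optionally applies recurrent hot/cold mutation at the
#' causal site, and removes sites that are fixed or lost across the
#' population.
#'
#' @param pop A [sim_population()].
#' @param config A [sim_config()].
#' @return The mutated `sim_population`.
#' @export
mutate_population <- function(pop, config) {
  haps <- pop$haps
  n_hap <- nrow(haps)
  counts <- stats::rpois(n_hap, config$mutation_rate)
  total <- sum(counts)
  positions <- pop$positions
  causal_col <- pop$causal_col
  if (total > 0L) {
    # fresh integer positions not yet segregating (infinite sites); columns
    # are appended unsorted -- meiosis treats sites independently, so site
    # order only matters when a panel is assembled (see sort_sites())
    newpos <- integer(0)
    while (length(newpos) < total) {
      cand <- sample.int(config$region_length, total - length(newpos))
      cand <- setdiff(cand, c(positions, newpos))
      newpos <- c(newpos, cand)
    }
    carriers <- rep.int(seq_len(n_hap), counts)
    newcols <- matrix(0L, n_hap, total)
    newcols[cbind(carriers, seq_len(total))] <- 1L
    haps <- cbind(haps, newcols)
    positions <- c(positions, newpos)
  }
  if (config$recurrent_causal_mutation && !is.na(causal_col)) {
    rate <- 10 * config$mutation_rate / config$region_length
    flips <- which(stats::runif(n_hap) < rate)
    if (length(flips) > 0L)
      haps[flips, causal_col] <- 1L - haps[flips, causal_col]
  }
  freq <- colMeans(haps)
  keep <- freq > 0 & freq < 1
  if (!all(keep)) {
    if (!is.na(causal_col) && !keep[causal_col]) causal_col <- NA_integer_
    else if (!is.na(causal_col))
      causal_col <- causal_col - sum(!keep[seq_len(causal_col)])
    haps <- haps[, keep, drop = FALSE]
    positions <- positions[keep]
  }
  pop$haps <- haps
  pop$positions <- positions
  pop$causal_col <- causal_col
  pop
}

# one unconstrained offspring generation: parent choice, gametes, mutation
.next_generation <- function(pop, config) {
  N <- length(pop$sex)
  females <- which(pop$sex == 0L) - 1L
  males <- which(pop$sex == 1L) - 1L
  mothers <- females[sample.int(length(females), N, replace = TRUE)]
  fathers <- males[sample.int(length(males), N, replace = TRUE)]
  res <- sim_gametes(
    pop$haps, pop$positions,
    causal_col = if (is.na(pop$causal_col)) -1L else pop$causal_col - 1L,
    hot_allele = pop$hot_allele,
    parents = cbind(mothers, fathers),
    p_background = config$background_crossover_prob,
    het_mult = config$het_multiplier, hom_mult = config$hom_hot_multiplier,
    hotspot_center = config$hotspot_center,
    bp_sigma = config$breakpoint_sigma,
    bgc_prob = config$bgc_prob, tract_mean = config$tract_mean,
    tract_sigma = config$tract_sigma,
    region_length = config$region_length)
  off <- pop
  off$haps <- res$gametes
  off$sex <- .draw_sexes(N)
  off$generation <- pop$generation + 1L
  off <- mutate_population(off, config)
  attr(off, "n_crossovers") <- sum(res$recombinant)
  attr(off, "n_bgc") <- sum(res$bgc)
  off
}

#' Sort population sites by position
#'
#' During evolution new mutation columns are appended unsorted (meiosis
#' treats sites independently); panels require increasing positions.
#'
#' @param pop A [sim_population()].
#' @return The population with columns in increasing position order.
#' @export
sort_sites <- function(pop) {
  if (!is.unsorted(pop$positions)) return(pop)
  ord <- order(pop$positions)
  if (!is.na(pop$causal_col))
    pop$causal_col <- match(pop$causal_col, ord)
  pop$haps <- pop$haps[, ord, drop = FALSE]
  pop$positions <- pop$positions[ord]
  pop
}

#' Trajectory target frequency
#'
#' Linear interpolation between the start and end hot-allele frequencies.
#'
#' @param config A [sim_config()].
#' @param generation Generation index in `[0, generations]`.
#' @return Target hot-allele frequency.
#' @export
trajectory_target <- function(config, generation) {
  config$start_hot_freq +
    (config$end_hot_freq - config$start_hot_freq) *
    generation / config$generations
}

#' Draw one offspring generation under the trajectory constraint
#'
#' Resamples whole offspring generations (parents, gametes, mutations) until
#' the hot-allele frequency lies within `trajectory_tol` of the linear
#' trajectory target for this generation and the causal SNP still segregates.
#'
#' @param pop A [sim_population()].
#' @param generation Target generation index (`pop$generation + 1`).
#' @param config A [sim_config()].
#' @return The accepted offspring `sim_population` (attribute `"tries"`
#'   records the number of draws).
#' @export
enforce_trajectory <- function(pop, generation, config) {
  target <- trajectory_target(config, generation)
  for (try in seq_len(config$max_tries)) {
    off <- .next_generation(pop, config)
    if (is.na(pop$causal_col)) {
      attr(off, "tries") <- try
      return(off)
    }
    if (!is.na(off$causal_col)) {
      f <- hot_freq(off)
      if (f > 0 && f < 1 && abs(f - target) <= config$trajectory_tol) {
        attr(off, "tries") <- try
        return(off)
      }
    }
  }
  stop("trajectory rejection budget exceeded at generation ", generation,
       " (target ", signif(target, 4), ", tolerance ", config$trajectory_tol,
       "); increase max_tries or the tolerance")
}

#' Evolve a population under the forward model
#'
#' Runs the full forward simulation: random mating of opposite-sex parent
#' pairs, meiosis with hotspot crossovers and biased gene conversion,
#' infinite-site mutation, and rejection-enforced linear trajectory of the
#' hot-allele frequency.  Deterministic given the config (seeded internally).
#'
#' @param config A [sim_config()].
#' @return A list of class `ldsplit_sim` with `population` (final
#'   [sim_population()]), `log` (per-generation data frame: `generation`,
#'   `n_crossovers`, `n_bgc`, `hot_freq`, `n_sites`, `tries`) and `config`.
#' @export
evolve_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_local_seed(config$seed, {
    pop <- .initial_population(config)
    G <- config$generations
    log <- data.frame(generation = seq_len(G), n_crossovers = NA_integer_,
                      n_bgc = NA_integer_, hot_freq = NA_real_,
                      n_sites = NA_integer_, tries = NA_integer_)
    for (t in seq_len(G)) {
      pop <- enforce_trajectory(pop, t, config)
      log$n_crossovers[t] <- attr(pop, "n_crossovers")
      log$n_bgc[t] <- attr(pop, "n_bgc")
      log$hot_freq[t] <- if (!is.na(pop$causal_col)) hot_freq(pop) else NA
      log$n_sites[t] <- ncol(pop$haps)
      log$tries[t] <- attr(pop, "tries")
    }
    pop <- sort_sites(pop)
    structure(list(population = pop, log = log, config = config),
              class = "ldsplit_sim")
  })
}

#' @export
print.ldsplit_sim <- function(x, ...) {
  cat("Forward simulation (", x$config$generations, " generations, ",
      x$config$pop_size, " diploids)\n", sep = "")
  print(x$population)
  cat("  total crossovers: ", sum(x$log$n_crossovers), " (",
      sum(x$log$n_bgc), " with BGC)\n", sep = "")
  invisible(x)
}

#' Sample benchmark haplotype panels from an evolved population
#'
#' Randomly samples subsets of individuals and packages their haplotypes as
#' [haplotype_panel()] objects.  Each panel carries a `"truth"` attribute
#' with the causal SNP column (in panel coordinates), the hot allele, the
#' hotspot center, and `low_maf` flagging samples in which the causal MAF
#' fell below the threshold (such samples are discarded from evaluation).
#'
#' @param pop A [sim_population()] (or an `ldsplit_sim`).
#' @param n_subsets Number of panels (default 10).
#' @param subset_size Individuals per panel (default 90, i.e. 180
#'   haplotypes).
#' @param maf_threshold Causal-MAF flag threshold (default 0.3).
#' @param config The [sim_config()] used (for the hotspot center); taken
#'   from an `ldsplit_sim` automatically.
#' @return List of `haplotype_panel` objects.
#' @export
sample_panels <- function(pop, n_subsets = 10L, subset_size = 90L,
                          maf_threshold = 0.3, config = NULL) {
  if (inherits(pop, "ldsplit_sim")) {
    config <- pop$config
    pop <- pop$population
  }
  stopifnot(inherits(pop, "sim_population"))
  pop <- sort_sites(pop)
  N <- nrow(pop$haps) / 2L
  if (subset_size > N) stop("subset_size exceeds the population size")
  lapply(seq_len(n_subsets), function(i) {
    ind <- sample.int(N, subset_size)
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    haps <- pop$haps[rows, , drop = FALSE]
    panel <- haplotype_panel(
      haps, positions = pop$positions,
      snp_ids = paste0("s", pop$positions),
      chromosome_ids = paste0("ind", rep(ind, each = 2L), c("_a", "_b")),
      individual_ids = paste0("ind", rep(ind, each = 2L)),
      chrom_name = "simregion")
    causal_col <- pop$causal_col
    truth <- list(
      causal_col = causal_col,
      causal_position = if (!is.na(causal_col)) pop$positions[causal_col]
                        else NA,
      hot_allele = pop$hot_allele,
      hotspot_center = if (!is.null(config)) config$hotspot_center else NA,
      low_maf = if (!is.na(causal_col))
        minor_allele_freq(panel, causal_col) < maf_threshold else NA
    )
    attr(panel, "truth") <- truth
    panel
  })
}

#' Export simulation truth and event log
#'
#' Writes the ground truth of a simulation (causal position, hot allele,
#' hotspot center, trajectory endpoints) as JSON and the per-generation event
#' log as TSV.
#'
#' @param sim An `ldsplit_sim`.
#' @param truth_path JSON output path (`NULL` to skip).
#' @param log_path TSV output path (`NULL` to skip).
#' @return `NULL`, invisibly.
#' @export
write_sim_truth <- function(sim, truth_path = NULL, log_path = NULL) {
  stopifnot(inherits(sim, "ldsplit_sim"))
  if (!is.null(truth_path)) {
    pop <- sim$population
    truth <- list(
      causal_position = if (!is.na(pop$causal_col))
        pop$positions[pop$causal_col] else NA,
      hot_allele = pop$hot_allele,
      hotspot_center = sim$config$hotspot_center,
      start_hot_freq = sim$config$start_hot_freq,
      end_hot_freq = sim$config$end_hot_freq,
      final_hot_freq = if (!is.na(pop$causal_col)) hot_freq(pop) else NA,
      seed = sim$config$seed
    )
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(log_path))
    utils::write.table(sim$log, log_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(NULL)
}
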