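test_that("crossover probability follows the genotype multipliers", {
  cfg <- sim_config()
  expect_equal(crossover_probability("cold/cold", cfg), 0.001)
  expect_equal(crossover_probability("het", cfg), 0.01)
  expect_equal(crossover_probability("hot/hot", cfg), 0.02)
})

test_that("breakpoints follow the background and hotspot distributions", {
  cfg <- sim_config()
  set.seed(2)
  bg <- sample_breakpoint(FALSE, cfg, n = 1e5)
  expect_true(all(bg >= 0 & bg < cfg$region_length))
  se <- cfg$region_length / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(bg) - 1e5), 3 * se)
  expect_gt(ks.test(bg / cfg$region_length, "punif")$p.value, 0.001)

  hot <- sample_breakpoint(TRUE, cfg, n = 2e4)
  expect_true(all(hot > 0 & hot < cfg$region_length))
  expect_lt(abs(mean(hot) - cfg$hotspot_center),
            3 * cfg$breakpoint_sigma / sqrt(2e4))
})

test_that("mutation adds Poisson sites and removes fixed ones", {
  cfg <- tiny_sim_config(mutation_rate = 0)
  pop <- sim_population(matrix(c(0L, 1L), 10L, 2L), positions = c(50L, 99L))
  set.seed(1)
  pop2 <- mutate_population(pop, cfg)
  expect_identical(pop2$haps, pop$haps)

  # a site carried by every haplotype disappears
  popf <- sim_population(cbind(rep(1L, 10L), c(rep(0L, 5L), rep(1L, 5L))),
                         positions = c(10L, 20L))
  popf2 <- mutate_population(popf, tiny_sim_config(mutation_rate = 0))
  expect_identical(ncol(popf2$haps), 1L)
  expect_identical(popf2$positions, 20)

  # Poisson moment check on the number of new sites per haplotype
  cfg3 <- tiny_sim_config(mutation_rate = 0.4)
  set.seed(7)
  n_hap <- 2000L
  pop3 <- sim_population(matrix(integer(0), n_hap, 0L), positions = numeric(0))
  pop4 <- mutate_population(pop3, cfg3)
  mean_new <- ncol(pop4$haps) / n_hap   # each new site has one carrier
  se <- sqrt(0.4 / n_hap)
  expect_lt(abs(mean_new - 0.4), 3 * se)
})

test_that("meiosis transmits Mendelian alleles without BGC and biased with", {
  pop <- sim_population(matrix(c(0L, 1L), nrow = 2), positions = 100000,
                        causal_col = 1L, hot_allele = 0L)
  cfg0 <- sim_config(tract_mean = 20000, tract_sigma = 1, bgc_prob = 0)
  set.seed(11)
  m0 <- meiosis(pop, 1L, cfg0, n = 4e5)
  rec0 <- m0$events[m0$events$recombinant, ]
  expect_gt(nrow(rec0), 2000L)
  cold0 <- mean(!rec0$transmitted_hot)
  expect_lt(abs(cold0 - 0.5), 3 * sqrt(0.25 / nrow(rec0)))

  # bgc_prob = 1 with a covering tract: every recombinant carries cold
  cfg1 <- sim_config(tract_mean = 20000, tract_sigma = 1, bgc_prob = 1)
  m1 <- meiosis(pop, 1L, cfg1, n = 4e5)
  rec1 <- m1$events[m1$events$recombinant, ]
  expect_gt(nrow(rec1), 2000L)
  expect_equal(mean(!rec1$transmitted_hot), 1)

  # non-recombinant gametes are exact copies of one homolog
  expect_true(all(m0$gametes[!m0$events$recombinant, 1L] %in% c(0L, 1L)))
})

test_that("trajectory target is the linear interpolant", {
  cfg <- sim_config(generations = 100L, start_hot_freq = 1, end_hot_freq = 0)
  expect_equal(trajectory_target(cfg, 50L), 0.5)
  expect_equal(trajectory_target(cfg, 0L), 1)
  expect_equal(trajectory_target(cfg, 100L), 0)
})

test_that("a scaled cooling run hits its target frequency and stays sized", {
  cfg <- tiny_sim_config(seed = 5L, end_hot_freq = 0.5)
  sim <- evolve_population(cfg)
  pop <- sim$population
  expect_identical(nrow(pop$haps), 2L * cfg$pop_size)
  expect_false(is.na(pop$causal_col))
  expect_lt(abs(hot_freq(pop) - 0.5), cfg$trajectory_tol + 1e-9)
  # trajectory audit: per-generation frequency stays inside the band
  tgt <- trajectory_target(cfg, sim$log$generation)
  expect_true(all(abs(sim$log$hot_freq - tgt) <= cfg$trajectory_tol + 1e-9))

  # determinism: same seed, same population
  sim2 <- evolve_population(cfg)
  expect_identical(sim2$population$haps, pop$haps)
  expect_identical(sim2$population$positions, pop$positions)
})

test_that("a heating run rises monotonically within the tolerance band", {
  cfg <- tiny_sim_config(seed = 9L, start_hot_freq = 0, end_hot_freq = 0.5)
  sim <- evolve_population(cfg)
  tgt <- trajectory_target(cfg, sim$log$generation)
  expect_true(all(abs(sim$log$hot_freq - tgt) <= cfg$trajectory_tol + 1e-9))
  expect_lt(abs(hot_freq(sim$population) - 0.5), cfg$trajectory_tol + 1e-9)
})

test_that("event-log crossover counts track the mean crossover probability", {
  cfg <- tiny_sim_config(seed = 3L)
  sim <- evolve_population(cfg)
  n_gam <- 2L * cfg$pop_size * cfg$generations
  # crude bound: rate between background and hot-homozygote everywhere
  expect_gt(sum(sim$log$n_crossovers), 0)
  expect_lt(sum(sim$log$n_crossovers),
            n_gam * cfg$background_crossover_prob *
              cfg$hom_hot_multiplier * 2)
})

test_that("sample_panels returns properly sized annotated panels", {
  cfg <- tiny_sim_config(seed = 5L)
  sim <- evolve_population(cfg)
  set.seed(2)
  panels <- sample_panels(sim, n_subsets = 4L, subset_size = 30L)
  expect_length(panels, 4L)
  for (pn in panels) {
    expect_identical(nrow(pn$haplotypes), 60L)
    truth <- attr(pn, "truth")
    expect_false(is.null(truth))
    if (!is.na(truth$causal_col)) {
      # the flag agrees with a direct recount of the causal MAF
      maf <- minor_allele_freq(pn, truth$causal_col)
      expect_identical(truth$low_maf, maf < 0.3)
      expect_identical(pn$snps$position[truth$causal_col],
                       as.integer(cfg$causal_position))
    }
  }
  # subset_size = population size returns the whole population
  whole <- sample_panels(sim$population, n_subsets = 1L,
                         subset_size = cfg$pop_size, config = cfg)
  expect_identical(nrow(whole[[1L]]$haplotypes), 2L * cfg$pop_size)
})

test_that("null simulations carry no causal SNP and no hotspot", {
  cfg <- tiny_sim_config(seed = 4L, causal_position = NA)
  sim <- evolve_population(cfg)
  expect_true(is.na(sim$population$causal_col))
  expect_gt(ncol(sim$population$haps), 0L)
})

test_that("simulation truth and log export round trip", {
  cfg <- tiny_sim_config(seed = 5L)
  sim <- evolve_population(cfg)
  tj <- withr::local_tempfile(fileext = ".json")
  tl <- withr::local_tempfile(fileext = ".tsv")
  write_sim_truth(sim, tj, tl)
  truth <- jsonlite::read_json(tj)
  expect_equal(truth$causal_position, cfg$causal_position)
  expect_equal(truth$hotspot_center, cfg$hotspot_center)
  log <- read.table(tl, header = TRUE, sep = "\t")
  expect_identical(nrow(log), cfg$generations)
})

test_that("without a causal SNP allele frequencies drift without bias", {
  # one offspring generation from a fixed parental population, replicated:
  # the mean frequency change at a mid-frequency site is zero (martingale)
  cfg <- sim_config(pop_size = 200L, mutation_rate = 0,
                    causal_position = NA)
  set.seed(33)
  haps <- matrix(rbinom(400L * 3L, 1L, 0.5), 400L, 3L)
  pop <- sim_population(haps, positions = c(50000, 100000, 150000))
  f0 <- colMeans(pop$haps)
  changes <- replicate(150L, {
    off <- ldsplit:::.next_generation(pop, cfg)
    mean(colMeans(off$haps) - f0)
  })
  se <- sd(changes) / sqrt(length(changes))
  expect_lt(abs(mean(changes)), 3.5 * se + 1e-4)
})
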