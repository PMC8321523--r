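test_that("genotype_spec and population_state enforce their invariants", {
  expect_error(genotype_spec("g", pi = 1.2), "\\[0, 1\\]")
  expect_error(genotype_spec("g", pi = 0.1, w = 0), "w must be")
  expect_error(genotype_spec("g", pi = 0.1, k_n = 1, k_p = 2), "k_p <= k_n")
  gt <- data.frame(id = "a", pi = 1e-4, w = 1, k_n = 2, k_p = 0.02,
                   is_control = FALSE)
  expect_error(population_state(gt, -1), "nonnegative")
  expect_error(population_state(gt, 1.5), "integers")
  p0 <- population_state(gt, 0)
  expect_true(p0$extinct)
  expect_false(population_state(gt, 10)$extinct)
})

test_that("survival_fraction follows the biphasic kill model", {
  g <- genotype_spec("x", pi = 0.01, k_n = 2, k_p = 0.05)
  expect_equal(survival_fraction(g, 0), 1)
  # direct evaluation of the two-term formula
  expect_equal(survival_fraction(g, 5),
               0.99 * exp(-10) + 0.01 * exp(-0.25))
  expect_equal(survival_fraction(g, 5), 7.833e-3, tolerance = 1e-4)
  # pure persister population: single exponential
  gp <- genotype_spec("p", pi = 1, k_n = 2, k_p = 0.05)
  tt <- seq(0, 10, by = 0.5)
  expect_equal(survival_fraction(gp, tt), exp(-0.05 * tt))
  # equal rates collapse to one exponential regardless of pi
  ge <- genotype_spec("e", pi = 0.3, k_n = 1.5, k_p = 1.5)
  expect_equal(survival_fraction(ge, tt), exp(-1.5 * tt))
  # monotone nonincreasing, in (0, 1]
  s <- survival_fraction(g, tt)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s > 0 & s <= 1))
  expect_error(survival_fraction(g, -1), ">= 0")
})

test_that("bottleneck_sample is a per-genotype binomial thinning", {
  gt <- data.frame(id = c("A", "B"), pi = 1e-4, w = 1, k_n = 2, k_p = 0.02,
                   is_control = FALSE)
  pop <- population_state(gt, c(1000, 500))
  # identity at D = 1
  same <- bottleneck_sample(pop, 1)
  expect_identical(same$counts, pop$counts)
  expect_identical(same$phase, "post-bottleneck")
  # binomial expectation oracle: mean over many draws within 3 SE of D * n
  set.seed(101)
  draws <- replicate(1e4, bottleneck_sample(pop, 0.1)$counts)
  se <- sqrt(c(1000, 500) * 0.1 * 0.9 / 1e4)
  expect_true(all(abs(rowMeans(draws) - c(100, 50)) < 3 * se))
  # errors and extinction
  expect_error(bottleneck_sample(pop, 0), "\\(0, 1\\]")
  expect_error(bottleneck_sample(pop, 1.5), "\\(0, 1\\]")
  dead <- population_state(gt, c(0, 0))
  expect_true(dead$extinct)
  expect_error(bottleneck_sample(dead, 0.5), "extinct")
})

test_that("antibiotic_kill survival matches the endpoint model", {
  cfg <- regime_config(D = 0.1, N_stat = 1e6)
  mk <- function(pi, n) population_state(
    data.frame(id = "g", pi = pi, w = 1, k_n = 2, k_p = 0.02,
               is_control = FALSE), n)
  # pi = 1: Binomial(n, 1), all survive; pi = 0: none
  expect_equal(antibiotic_kill(mk(1, 12345), cfg)$counts, 12345)
  killed0 <- antibiotic_kill(mk(0, 12345), cfg)
  expect_equal(killed0$counts, 0)
  expect_true(killed0$extinct)
  # binomial expectation oracle: n = 1e6, pi = 1.5e-4 -> mean ~ 150
  set.seed(7)
  surv <- replicate(1e3, antibiotic_kill(mk(1.5e-4, 1e6), cfg)$counts)
  se <- sqrt(1e6 * 1.5e-4 / 1e3)  # binomial SE of the mean, p small
  expect_lt(abs(mean(surv) - 150), 3 * se)
  # phase bookkeeping
  expect_error(antibiotic_kill(antibiotic_kill(mk(0.5, 10), cfg), cfg),
               "stationary")
})

test_that("regrow_and_mutate has the closed-form odds update", {
  gt2 <- data.frame(id = c("a", "b"), pi = 1e-4, w = c(1, 1.05), k_n = 2,
                    k_p = 0.02, is_control = FALSE)
  # G = 10 doublings: N_stat = 1024 * N_seed
  n_seed <- 1000
  cfg <- regime_config(D = 0.1, N_stat = 1024 * n_seed, mu = 0)
  set.seed(23)
  freqs <- replicate(1e3, {
    pop <- population_state(gt2, c(n_seed / 2, n_seed / 2),
                            phase = "post-bottleneck")
    rg <- regrow_and_mutate(pop, cfg)
    rg$pop$counts[2] / sum(rg$pop$counts)
  })
  expected <- 1.05^10 / (1 + 1.05^10)
  expect_equal(expected, 0.6196, tolerance = 1e-4)
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - expected), 3 * se + 1e-5)

  # N_seed = N_stat: G = 0, no divisions, no mutants even with mu > 0
  cfg0 <- regime_config(D = 0.1, N_stat = 1e4, mu = 0.5)
  pop <- population_state(gt2, c(5e3, 5e3), phase = "post-bottleneck")
  rg <- regrow_and_mutate(pop, cfg0)
  expect_equal(rg$generations, 0)
  expect_equal(nrow(rg$pop$genotypes), 2)
  expect_equal(sum(rg$pop$counts), 1e4)

  # generations definition
  cfgG <- regime_config(D = 0.1, N_stat = 1e6, mu = 0)
  popG <- population_state(gt2[1, ], 100, phase = "post-bottleneck")
  expect_equal(regrow_and_mutate(popG, cfgG)$generations, log2(1e4))

  dead <- population_state(gt2, c(0, 0), phase = "post-bottleneck")
  expect_error(regrow_and_mutate(dead, cfgG), "extinct")
})

test_that("mutations carry the persistence/growth trade-off of the DFE", {
  cfg <- regime_config(D = 0.1, N_stat = 1e5, mu = 1e-3, seed = 5)
  set.seed(5)
  pop <- population_state(
    data.frame(id = "anc", pi = 1.5e-4, w = 1, k_n = 2, k_p = 0.02,
               is_control = FALSE), 100, phase = "post-bottleneck")
  rg <- regrow_and_mutate(pop, cfg)
  gt <- rg$pop$genotypes
  mut <- gt[gt$id != "anc", ]
  expect_gt(nrow(mut), 10)
  phi <- mut$pi / 1.5e-4
  expect_true(all(phi >= 2 - 1e-9 & phi <= 1000 + 1e-9))
  # growth cost increases with the persistence gain
  expect_equal(mut$w, pmax(0.05, 1 - 0.03 * log10(phi)))
  expect_true(all(mut$w < 1))
})

test_that("run_evolution is seed-deterministic and records coherent cycles", {
  cfg <- regime_config(D = 0.1, N_stat = 1e6, n_cycles = 10, seed = 99)
  r1 <- run_evolution(cfg)
  r2 <- run_evolution(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$composition, r2$composition)
  rec <- r1$records
  expect_equal(rec$persister_fraction, rec$n_after / rec$n_before)
  expect_true(all(rec$generations >= 0))
  # composition frequencies sum to 1 at every recorded cycle
  for (cmp in r1$composition) if (length(cmp)) expect_equal(sum(cmp), 1)
  # child streams: replicate i is independent of how many replicates run
  cfg$seed <- 1
  a <- run_evolution_replicates(cfg, 2)
  b <- run_evolution_replicates(cfg, 3)
  expect_identical(a[[2]]$records, b[[2]]$records)
})

test_that("no adaptation without mutation: flat persister trajectory", {
  cfg <- regime_config(D = 0.1, N_stat = 1e6, n_cycles = 18, mu = 0,
                       seed = 12)
  r <- run_evolution(cfg)
  expect_false(r$extinct)
  pf <- r$records$persister_fraction
  # regression slope CI covers 0 (no trend beyond binomial noise)
  fit <- lm(pf ~ r$records$cycle)
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("strong dilution of a small culture is an extinction trap", {
  # expected transfer ~ 1e5 * 1.5e-4 * 0.002 = 0.003 cells per cycle
  cfg <- regime_config(D = 0.002, N_stat = 1e5, n_cycles = 18, seed = 3)
  runs <- run_evolution_replicates(cfg, 100)
  expect_gte(mean(vapply(runs, `[[`, logical(1), "extinct")), 0.99)
  # extinction is recorded, not thrown
  expect_true(all(vapply(runs, function(r) nrow(r$records) >= 1, logical(1))))
})

test_that("persistence rises at least tenfold under a permissive bottleneck", {
  cfg <- regime_config(D = 0.1, N_stat = 1e7, n_cycles = 18, seed = 8)
  runs <- run_evolution_replicates(cfg, 20)
  alive <- runs[!vapply(runs, `[[`, logical(1), "extinct")]
  ratio <- vapply(alive, function(r) {
    pf <- r$records$persister_fraction
    pf[length(pf)] / pf[1]
  }, numeric(1))
  expect_gte(median(ratio), 10)
})

test_that("generation bookkeeping matches the dilution arithmetic", {
  # constant transfer ratio R over 18 cycles -> 18 log2(R)
  rec <- data.frame(cycle = 1:18, n_before = 1e6, n_after = 1e3,
                    n_transferred = 1e6 / 2^16,
                    persister_fraction = 1e-3, generations = 16)
  expect_equal(cumulative_generations(rec), 18 * 16)
  # extinct cycles are excluded
  rec$n_transferred[18] <- 0
  expect_equal(cumulative_generations(rec), 17 * 16)
  # N_transferred = N_stat every cycle -> 0 doublings
  rec0 <- data.frame(cycle = 1:5, n_before = 1e6, n_after = 1e6,
                     n_transferred = 1e6, persister_fraction = 1,
                     generations = 0)
  expect_equal(cumulative_generations(rec0), 0)
})

test_that("simulate_library_selection: neutral growth-only control is flat", {
  lib <- library_config(n_designs = 50L, n_controls = 5L,
                        effect_table = data.frame(pi_mult = rep(1, 50),
                                                  w_mult = rep(1, 50)),
                        n_replicates = 4L, depth = 2e6, rounds = 2L,
                        with_treatment = FALSE)
  cfg <- regime_config(D = 0.1, N_stat = 1e8, seed = 61)
  tab <- simulate_library_selection(lib, cfg)
  freq <- sweep(tab$counts, 2, colSums(tab$counts), "/")
  before <- freq[, tab$sample_meta$timepoint == "before"]
  after <- freq[, tab$sample_meta$timepoint == "after"]
  # all designs start and stay near 1/50; multinomial + drift noise only
  expect_lt(max(abs(after - before)), 6 * sqrt(0.02 * 0.98 / (2e6 * 0.1 * 0.02)))
  expect_lt(max(abs(colMeans(abs(after - before)))), 0.002)
})

test_that("a persistence-enhancing design wins the fold-change race", {
  lib <- library_config(n_designs = 100L, n_controls = 10L,
                        effect_table = spiked_effects(100, 5, pi_mult = 10),
                        n_replicates = 8L, depth = 1e5, rounds = 2L)
  cfg <- regime_config(D = 0.1, N_stat = 1e8, seed = 33)
  tab <- simulate_library_selection(lib, cfg)
  lfc <- replicate_lfc(tab)
  expect_gte(sum(apply(lfc, 2, which.max) == 5), 7)
  expect_error(
    library_config(n_designs = 10L, n_controls = 2L, depth = 0),
    "depth")
})

test_that("library output satisfies the count-table contract", {
  lib <- library_config(n_designs = 40L, n_controls = 4L, n_replicates = 3L,
                        depth = 1e4, rounds = 2L)
  cfg <- regime_config(D = 0.02, N_stat = 1e6, seed = 5)
  tab <- simulate_library_selection(lib, cfg)
  expect_s3_class(tab, "barcode_count_table")
  expect_equal(dim(tab$counts), c(40L, 6L))
  expect_true(all(tab$counts >= 0))
  expect_true(all(tab$counts == floor(tab$counts)))
  expect_equal(sum(tab$design_meta$is_control), 4L)
  # every before-sample carries full depth
  expect_true(all(colSums(tab$counts[, tab$sample_meta$timepoint == "before"]) == 1e4))
  # determinism
  tab2 <- simulate_library_selection(lib, cfg)
  expect_identical(tab$counts, tab2$counts)
})
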