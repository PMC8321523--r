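## Serial-passage evolution simulator: daily bactericidal treatment of a
## stationary culture, dilution bottleneck, regrowth to stationary phase with
## de novo beneficial mutations. Cell-count bookkeeping is per genotype;
## growth is realized as a single multinomial redraw at stationary size with
## fitness-weighted odds, which has the correct expectations at a fraction of
## the cost of division-level simulation.

#' Genotype specification
#'
#' A heritable type in the simulator: its persister fraction, relative
#' growth fitness, and kill kinetics under bactericidal treatment.
#'
#' @param id Character label.
#' @param pi Persister fraction in \[0, 1\]: probability that a cell is in
#'   the protected, slow-killed state when treatment starts.
#' @param w Relative growth fitness (> 0; ancestor = 1), acting per doubling
#'   during regrowth.
#' @param k_n Kill rate of normal cells under treatment, per hour (>= 0).
#' @param k_p Kill rate of persister cells, per hour (0 <= k_p <= k_n).
#' @param is_control Logical; an inert (barcode-only) design.
#' @return An object of class `"genotype_spec"`.
#' @export
genotype_spec <- function(id, pi, w = 1, k_n = 2, k_p = 0.02,
                          is_control = FALSE) {
  if (!is.finite(pi) || pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (!is.finite(w) || w <= 0) stop("w must be > 0")
  if (k_n < 0 || k_p < 0) stop("kill rates must be >= 0")
  if (k_p > k_n) stop("persisters must die no faster than normal cells (k_p <= k_n)")
  structure(list(id = as.character(id), pi = pi, w = w, k_n = k_n, k_p = k_p,
                 is_control = isTRUE(is_control)),
            class = "genotype_spec")
}

#' Biphasic survival fraction under bactericidal treatment
#'
#' Fraction of a genotype's cells surviving `t` hours of treatment under the
#' two-subpopulation kill model
#' `S(t) = (1 - pi) exp(-k_n t) + pi exp(-k_p t)`:
#' normal cells die fast (rate `k_n`), the persister subpopulation slowly
#' (rate `k_p`). S is 1 at t = 0 and monotone nonincreasing in t; with
#' `k_n = k_p` it reduces to a single exponential regardless of `pi`.
#'
#' @param g A [genotype_spec()] (or any list with `pi`, `k_n`, `k_p`).
#' @param t Treatment duration in hours (>= 0); vectorized.
#' @return Survival fraction(s) in (0, 1\].
#' @examples
#' g <- genotype_spec("x", pi = 0.01, k_n = 2, k_p = 0.05)
#' survival_fraction(g, 5)  # 7.833e-3
#' @export
survival_fraction <- function(g, t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("treatment duration must be >= 0")
  .surv(g$pi, g$k_n, g$k_p, t)
}

.surv <- function(pi, k_n, k_p, t) {
  (1 - pi) * exp(-k_n * t) + pi * exp(-k_p * t)
}

#' Selection-regime configuration
#'
#' Parameters of one serial-transfer regime. Defaults describe the
#' experimental setting this simulator emulates: 500 ul stationary cultures
#' at ~1e9 CFU/ml (`N_stat = 5e8`), a 5 h high-dose bactericidal treatment
#' each cycle, dilution bottlenecks between 1:10 and 1:5000, and 18 cycles.
#'
#' The distribution of fitness effects (`dfe`) of beneficial mutations is a
#' log-uniform persister-fold-increase `phi` on \[`phi_min`, `phi_max`\]
#' applied multiplicatively to pi (capped at 1), with a pleiotropic growth
#' cost `w <- w (1 - gamma log10 phi)` encoding the persistence/growth
#' trade-off.
#'
#' @param D Dilution ratio in (0, 1); 1:500 transfer is D = 0.002.
#' @param n_cycles Number of serial-transfer cycles (default 18).
#' @param N_stat Stationary population size in cells (default 5e8).
#' @param treat_hours Treatment duration per cycle in hours (default 5).
#' @param kill_model `"endpoint"` (survival probability = pi; default) or
#'   `"biphasic"` (survival = [survival_fraction()] at `treat_hours`).
#' @param mu Beneficial-mutation probability per cell division
#'   (default 1e-5).
#' @param dfe List with `phi_min`, `phi_max`, `gamma` (defaults 2, 1000,
#'   0.03).
#' @param ancestor Ancestral [genotype_spec()]; default pi = 1.5e-4,
#'   k_n = 2/h, k_p = 0.02/h (5 h endpoint survival ~ pi).
#' @param seed Optional integer RNG seed; child streams for replicate
#'   populations are derived from it by stable indexing.
#' @return An object of class `"regime_config"`.
#' @export
regime_config <- function(D, n_cycles = 18L, N_stat = 5e8, treat_hours = 5,
                          kill_model = c("endpoint", "biphasic"),
                          mu = 1e-5,
                          dfe = list(phi_min = 2, phi_max = 1000, gamma = 0.03),
                          ancestor = genotype_spec("anc", pi = 1.5e-4, w = 1,
                                                   k_n = 2, k_p = 0.02),
                          seed = NULL) {
  kill_model <- match.arg(kill_model)
  if (!is.finite(D) || D <= 0 || D >= 1) stop("D must lie strictly inside (0, 1)")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  if (!is.finite(N_stat) || N_stat < 1) stop("N_stat must be >= 1")
  if (N_stat > 2^31 - 1) stop("N_stat must fit a 32-bit integer draw")
  if (treat_hours < 0) stop("treatment duration must be >= 0")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  stopifnot(is.list(dfe), all(c("phi_min", "phi_max", "gamma") %in% names(dfe)))
  if (dfe$phi_min < 1 || dfe$phi_max < dfe$phi_min) stop("invalid DFE bounds")
  structure(list(D = D, n_cycles = n_cycles, N_stat = N_stat,
                 treat_hours = treat_hours, kill_model = kill_model, mu = mu,
                 dfe = dfe, ancestor = ancestor, seed = seed),
            class = "regime_config")
}

#' Population state
#'
#' Per-genotype cell counts of one population at one point in a cycle.
#'
#' @param genotypes Data frame with columns `id`, `pi`, `w`, `k_n`, `k_p`,
#'   `is_control` (one row per genotype).
#' @param counts Nonnegative cell counts, one per genotype row.
#' @param cycle Cycle index (>= 0).
#' @param phase One of `"stationary"`, `"post-treatment"`,
#'   `"post-bottleneck"`.
#' @return An object of class `"population_state"` with an `extinct` flag
#'   (TRUE iff the total count is zero).
#' @export
population_state <- function(genotypes, counts,
                             cycle = 0L,
                             phase = c("stationary", "post-treatment",
                                       "post-bottleneck")) {
  phase <- match.arg(phase)
  stopifnot(is.data.frame(genotypes),
            all(c("id", "pi", "w", "k_n", "k_p", "is_control") %in%
                  names(genotypes)),
            nrow(genotypes) == length(counts))
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be nonnegative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  structure(list(genotypes = genotypes, counts = counts,
                 cycle = as.integer(cycle), phase = phase,
                 extinct = sum(counts) == 0),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population (cycle %d, %s): %d genotype(s), %.4g cells%s\n",
              x$cycle, x$phase, nrow(x$genotypes), sum(x$counts),
              if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}

.ancestral_population <- function(cfg) {
  g <- cfg$ancestor
  population_state(
    data.frame(id = g$id, pi = g$pi, w = g$w, k_n = g$k_n, k_p = g$k_p,
               is_control = g$is_control, stringsAsFactors = FALSE),
    counts = cfg$N_stat, cycle = 0L, phase = "stationary")
}

# Drop genotypes with zero cells (keeps the state small over long runs).
.prune <- function(pop) {
  keep <- pop$counts > 0
  if (all(keep)) return(pop)
  pop$genotypes <- pop$genotypes[keep, , drop = FALSE]
  rownames(pop$genotypes) <- NULL
  pop$counts <- pop$counts[keep]
  pop$extinct <- sum(pop$counts) == 0
  pop
}

#' Dilution bottleneck
#'
#' Transfers each genotype independently through a dilution bottleneck:
#' post-bottleneck counts are Binomial(n_g, D) draws, so the expected count
#' is D times the pre-bottleneck count. `D = 1` is the identity transfer.
#'
#' @param pop A [population_state()], not extinct.
#' @param D Dilution ratio in (0, 1\].
#' @return The bottlenecked [population_state()] (phase
#'   `"post-bottleneck"`), possibly extinct.
#' @export
bottleneck_sample <- function(pop, D) {
  if (!is.finite(D) || D <= 0 || D > 1) stop("D must lie in (0, 1]")
  if (pop$extinct) stop("population is extinct")
  counts <- if (D == 1) pop$counts
            else as.numeric(stats::rbinom(length(pop$counts), pop$counts, D))
  out <- pop
  out$counts <- counts
  out$phase <- "post-bottleneck"
  out$extinct <- sum(counts) == 0
  out
}

#' Bactericidal treatment of a stationary population
#'
#' Survivors per genotype are Binomial(n_g, s_g): under the default
#' `"endpoint"` model the per-cell survival probability is the persister
#' fraction `s_g = pi_g` (only persisters survive the full treatment); under
#' `"biphasic"` it is [survival_fraction()] evaluated at `treat_hours`.
#'
#' @param pop A [population_state()] in stationary phase.
#' @param cfg A [regime_config()].
#' @return Post-treatment [population_state()].
#' @export
antibiotic_kill <- function(pop, cfg) {
  if (pop$phase != "stationary")
    stop("treatment applies to a stationary-phase population")
  if (cfg$treat_hours < 0) stop("treatment duration must be >= 0")
  s <- switch(cfg$kill_model,
              endpoint = pop$genotypes$pi,
              biphasic = .surv(pop$genotypes$pi, pop$genotypes$k_n,
                               pop$genotypes$k_p, cfg$treat_hours))
  counts <- as.numeric(stats::rbinom(length(pop$counts), pop$counts, s))
  out <- pop
  out$counts <- counts
  out$phase <- "post-treatment"
  out$extinct <- sum(counts) == 0
  out
}

#' Regrowth to stationary phase with de novo mutation
#'
#' Regrows a seeded population to `N_stat` cells. The reference number of
#' doublings is `G = log2(N_stat / N_seed)`; genotype odds are updated by
#' `w_g^G` relative to the ancestor and realized by one multinomial draw of
#' `N_stat` cells. New beneficial mutants arise as
#' Poisson(`mu * (N_stat - N_seed)`) single cells, each drawn from the DFE
#' applied to a parent chosen proportionally to final abundance.
#'
#' @param pop A [population_state()] with >= 1 cell.
#' @param cfg A [regime_config()].
#' @return List with `pop` (stationary [population_state()]) and
#'   `generations` (the reference doublings G).
#' @export
regrow_and_mutate <- function(pop, cfg) {
  n_seed <- sum(pop$counts)
  if (n_seed == 0) stop("cannot regrow an extinct population")
  G <- max(0, log2(cfg$N_stat / n_seed))
  odds <- pop$counts * pop$genotypes$w^G
  counts <- as.numeric(stats::rmultinom(1, cfg$N_stat, odds))

  n_div <- max(0, cfg$N_stat - n_seed)
  n_mut <- stats::rpois(1, cfg$mu * n_div)
  gt <- pop$genotypes
  if (n_mut > 0) {
    parents <- sample.int(length(counts), n_mut, replace = TRUE, prob = counts)
    take <- tabulate(parents, nbins = length(counts))
    take <- pmin(take, counts)           # cannot mutate more cells than exist
    n_mut <- sum(take)
    if (n_mut > 0) {
      parent_idx <- rep(seq_along(counts), take)
      phi <- exp(stats::runif(n_mut, log(cfg$dfe$phi_min),
                              log(cfg$dfe$phi_max)))
      new <- data.frame(
        id = sprintf("m%d.%d", pop$cycle + 1L, seq_len(n_mut)),
        pi = pmin(1, gt$pi[parent_idx] * phi),
        w = pmax(0.05, gt$w[parent_idx] * (1 - cfg$dfe$gamma * log10(phi))),
        k_n = gt$k_n[parent_idx], k_p = gt$k_p[parent_idx],
        is_control = FALSE, stringsAsFactors = FALSE)
      counts <- c(counts - take, rep(1, n_mut))
      gt <- rbind(gt, new)
    }
  }
  out <- population_state(gt, counts, cycle = pop$cycle + 1L,
                          phase = "stationary")
  list(pop = .prune(out), generations = G)
}

#' Run one serial-transfer evolution experiment
#'
#' Iterates treatment, bottleneck, and regrowth-with-mutation for
#' `n_cycles`, starting from an isogenic ancestral population at stationary
#' size. Extinction (zero cells at any phase) halts the run and is recorded
#' as an outcome, not an error — under strong dilution most populations are
#' expected to die out.
#'
#' @param cfg A [regime_config()]. If `cfg$seed` is set the RNG is seeded.
#' @return An object of class `"evolution_run"`: list with
#'   `records` (data frame: cycle, n_before, n_after, n_transferred,
#'   persister_fraction, generations), `composition` (per recorded cycle, a
#'   named genotype-frequency vector at the regrown stationary state),
#'   `extinct`, `extinct_cycle` (NA if survived), `final_pop`, `cfg`.
#' @export
run_evolution <- function(cfg) {
  stopifnot(inherits(cfg, "regime_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- .ancestral_population(cfg)
  rec <- vector("list", cfg$n_cycles)
  comp <- vector("list", cfg$n_cycles)
  extinct_cycle <- NA_integer_
  for (cy in seq_len(cfg$n_cycles)) {
    n_before <- sum(pop$counts)
    killed <- antibiotic_kill(pop, cfg)
    n_after <- sum(killed$counts)
    pf <- if (n_before > 0) n_after / n_before else NA_real_
    if (killed$extinct) {
      rec[[cy]] <- data.frame(cycle = cy, n_before = n_before,
                              n_after = 0, n_transferred = 0,
                              persister_fraction = pf, generations = 0)
      comp[[cy]] <- stats::setNames(numeric(0), character(0))
      extinct_cycle <- cy; pop <- killed; break
    }
    bott <- bottleneck_sample(killed, cfg$D)
    n_trans <- sum(bott$counts)
    if (bott$extinct) {
      rec[[cy]] <- data.frame(cycle = cy, n_before = n_before,
                              n_after = n_after, n_transferred = 0,
                              persister_fraction = pf, generations = 0)
      comp[[cy]] <- stats::setNames(numeric(0), character(0))
      extinct_cycle <- cy; pop <- bott; break
    }
    rg <- regrow_and_mutate(bott, cfg)
    pop <- rg$pop
    rec[[cy]] <- data.frame(cycle = cy, n_before = n_before,
                            n_after = n_after, n_transferred = n_trans,
                            persister_fraction = pf,
                            generations = rg$generations)
    comp[[cy]] <- stats::setNames(pop$counts / sum(pop$counts),
                                  pop$genotypes$id)
  }
  done <- !vapply(rec, is.null, logical(1))
  structure(list(records = do.call(rbind, rec[done]),
                 composition = comp[done],
                 extinct = !is.na(extinct_cycle),
                 extinct_cycle = extinct_cycle,
                 final_pop = pop, cfg = cfg),
            class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  nr <- nrow(x$records)
  cat(sprintf("Evolution run: D = %.4g, %d/%d cycle(s)%s\n", x$cfg$D, nr,
              x$cfg$n_cycles,
              if (x$extinct) sprintf(", extinct at cycle %d", x$extinct_cycle)
              else ""))
  if (nr > 0)
    cat(sprintf("  persister fraction: %.3g -> %.3g\n",
                x$records$persister_fraction[1],
                x$records$persister_fraction[nr]))
  invisible(x)
}

#' Replicate evolution runs with stable child seeds
#'
#' Runs `n_replicates` independent populations under the same regime. Each
#' replicate uses the child seed `child_seed(cfg$seed, i)`, so adding
#' replicates never perturbs earlier ones.
#'
#' @param cfg A [regime_config()] with `seed` set.
#' @param n_replicates Number of parallel populations.
#' @return List of [run_evolution()] results.
#' @export
run_evolution_replicates <- function(cfg, n_replicates) {
  if (is.null(cfg$seed)) stop("cfg$seed must be set for replicate runs")
  lapply(seq_len(n_replicates), function(i) {
    ci <- cfg
    ci$seed <- child_seed(cfg$seed, i)
    run_evolution(ci)
  })
}

#' Stable child seed derivation
#'
#' Deterministic 32-bit-safe child seed for replicate population `index`
#' under top-level seed `seed`.
#'
#' @param seed Integer top-level seed.
#' @param index Positive integer replicate index.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
child_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 + 104729 * as.double(index)) %%
               2147483647)
}

#' Cumulative generations over a run
#'
#' Total reference doublings `sum log2(N_stat / N_transferred)` across
#' recorded cycles; cycles with zero transferred cells (extinction) are
#' excluded. For two regimes sharing identical survivor pools the per-cycle
#' difference equals `log2(D_large / D_small)` — see
#' [regime_generation_difference()].
#'
#' @param run An `"evolution_run"` or its `records` data frame.
#' @return Total doublings.
#' @export
cumulative_generations <- function(run) {
  rec <- if (inherits(run, "evolution_run")) run$records else run
  if (is.null(rec) || nrow(rec) == 0) stop("no recorded cycles")
  ok <- rec$n_transferred > 0
  sum(rec$generations[ok])
}

#' Generation-count difference between two dilution regimes
#'
#' With identical survivor pools each cycle, a regime diluting by
#' `D_small` must regrow `log2(D_large / D_small)` doublings more per cycle
#' than one diluting by `D_large`. E.g. 18 cycles at 1:10 totalling 288
#' doublings imply 288 + 18 log2(50) ~ 390 at 1:500.
#'
#' @param D_large,D_small Dilution ratios (D_large > D_small).
#' @param n_cycles Number of cycles (default 18).
#' @return Additional doublings of the `D_small` regime.
#' @export
regime_generation_difference <- function(D_large, D_small, n_cycles = 18L) {
  if (D_small <= 0 || D_large <= D_small) stop("need D_large > D_small > 0")
  n_cycles * log2(D_large / D_small)
}

#' Knockout-library configuration
#'
#' Describes a pooled barcoded knockout library subjected to rounds of the
#' selection regime. Defaults mirror a genome-wide gene KO library: 4128
#' designs of which 17% of barcode-carrying cells actually bear the edit,
#' eight replicate populations, two selection rounds. (The companion ncRNA
#' KO library is 87 designs at 36% edited.)
#'
#' @param n_designs Number of barcoded designs (default 4128).
#' @param edit_fraction Fraction of a design's cells carrying the intended
#'   edit (default 0.17); the remainder carry the barcode but keep the
#'   ancestral phenotype.
#' @param n_controls Number of inert control designs (default 15), taken as
#'   the last `n_controls` designs and forced phenotypically neutral.
#' @param effect_table Optional data frame with columns `pi_mult`, `w_mult`
#'   (one row per design): multipliers applied to the ancestral persister
#'   fraction and growth fitness of edited cells. `NULL` draws a default
#'   random effect table (see [default_library_effects()]).
#' @param n_replicates Parallel populations per condition (default 8).
#' @param depth Sequencing reads per sample (default 1e6).
#' @param rounds Selection rounds (default 2).
#' @param with_treatment FALSE runs the growth-only control arm in which the
#'   treatment step is skipped.
#' @return An object of class `"library_config"`.
#' @export
library_config <- function(n_designs = 4128L, edit_fraction = 0.17,
                           n_controls = 15L, effect_table = NULL,
                           n_replicates = 8L, depth = 1e6, rounds = 2L,
                           with_treatment = TRUE) {
  n_designs <- as.integer(n_designs); n_controls <- as.integer(n_controls)
  if (n_designs < 2L) stop("need >= 2 designs")
  if (n_controls < 0L || n_controls >= n_designs)
    stop("n_controls must be < n_designs")
  if (edit_fraction < 0 || edit_fraction > 1)
    stop("edit_fraction must lie in [0, 1]")
  if (depth < 1) stop("depth must be >= 1")
  if (rounds < 1L) stop("rounds must be >= 1")
  if (!is.null(effect_table)) {
    stopifnot(is.data.frame(effect_table),
              all(c("pi_mult", "w_mult") %in% names(effect_table)),
              nrow(effect_table) == n_designs)
    if (any(effect_table$pi_mult < 0) || any(effect_table$w_mult <= 0))
      stop("effect multipliers must be positive")
  }
  structure(list(n_designs = n_designs, edit_fraction = edit_fraction,
                 n_controls = n_controls, effect_table = effect_table,
                 n_replicates = as.integer(n_replicates), depth = depth,
                 rounds = as.integer(rounds),
                 with_treatment = isTRUE(with_treatment)),
            class = "library_config")
}

#' Default random effect table for a knockout library
#'
#' Phenotypic effects of library designs when none are supplied: 90% of
#' designs are neutral, 5% increase the persister fraction by a log-uniform
#' fold on \[2, 100\] (with the pleiotropic growth cost
#' `w = 1 - gamma log10(fold)`), and 5% reduce survival (pi multiplier
#' uniform on \[0.1, 0.5\]). Control designs are always neutral. Drawn from
#' the current RNG state.
#'
#' @param n_designs,n_controls As in [library_config()].
#' @param frac_beneficial,frac_deleterious Fractions of non-neutral designs.
#' @param gamma Growth-cost coefficient (default 0.03).
#' @return Data frame with `pi_mult` and `w_mult`, one row per design.
#' @export
default_library_effects <- function(n_designs, n_controls = 0L,
                                    frac_beneficial = 0.05,
                                    frac_deleterious = 0.05, gamma = 0.03) {
  cls <- sample(c("neutral", "beneficial", "deleterious"), n_designs,
                replace = TRUE,
                prob = c(1 - frac_beneficial - frac_deleterious,
                         frac_beneficial, frac_deleterious))
  if (n_controls > 0)
    cls[(n_designs - n_controls + 1L):n_designs] <- "neutral"
  pi_mult <- rep(1, n_designs)
  nb <- sum(cls == "beneficial")
  pi_mult[cls == "beneficial"] <- exp(stats::runif(nb, log(2), log(100)))
  pi_mult[cls == "deleterious"] <- stats::runif(sum(cls == "deleterious"),
                                                0.1, 0.5)
  w_mult <- rep(1, n_designs)
  w_mult[cls == "beneficial"] <-
    pmax(0.05, 1 - gamma * log10(pi_mult[cls == "beneficial"]))
  data.frame(pi_mult = pi_mult, w_mult = w_mult)
}

#' Simulate barcoded-library selection
#'
#' Initializes `n_designs` barcoded genotypes at equal frequency — each
#' design phenotypically effective in only `edit_fraction` of its cells, the
#' remainder carrying the barcode with the ancestral phenotype — and runs
#' `rounds` cycles of (treatment unless the growth-only control arm),
#' dilution bottleneck, and regrowth, in `n_replicates` parallel
#' populations. Read counts per design are emitted before and after
#' selection as Multinomial(depth, design frequencies); an extinct replicate
#' yields an all-zero after-sample.
#'
#' @param lib A [library_config()].
#' @param cfg A [regime_config()] providing D, N_stat, treat_hours,
#'   kill model, ancestor phenotype, and the seed.
#' @return A [barcode_count_table()].
#' @export
simulate_library_selection <- function(lib, cfg) {
  stopifnot(inherits(lib, "library_config"), inherits(cfg, "regime_config"))
  if (lib$depth < 1) stop("depth must be >= 1")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- lib$n_designs
  eff <- lib$effect_table
  if (is.null(eff)) eff <- default_library_effects(k, lib$n_controls)
  ids <- sprintf("d%04d", seq_len(k))
  is_control <- c(rep(FALSE, k - lib$n_controls), rep(TRUE, lib$n_controls))
  anc <- cfg$ancestor

  # two phenotype classes per design: edited cells, then unedited carriers
  pi_cls <- c(pmin(1, anc$pi * eff$pi_mult), rep(anc$pi, k))
  w_cls <- c(anc$w * eff$w_mult, rep(anc$w, k))
  s_cls <- switch(cfg$kill_model,
                  endpoint = pi_cls,
                  biphasic = .surv(pi_cls, anc$k_n, anc$k_p, cfg$treat_hours))
  init_prob <- c(rep(lib$edit_fraction / k, k),
                 rep((1 - lib$edit_fraction) / k, k))

  n_samp <- 2L * lib$n_replicates
  counts_out <- matrix(0, nrow = k, ncol = n_samp,
                       dimnames = list(ids, NULL))
  sample_id <- character(n_samp)
  for (r in seq_len(lib$n_replicates)) {
    if (!is.null(cfg$seed)) set.seed(child_seed(cfg$seed, r))
    cells <- as.numeric(stats::rmultinom(1, cfg$N_stat, init_prob))
    design_tot <- cells[1:k] + cells[(k + 1):(2 * k)]
    before <- as.numeric(stats::rmultinom(1, lib$depth, design_tot))
    for (rd in seq_len(lib$rounds)) {
      if (lib$with_treatment)
        cells <- as.numeric(stats::rbinom(2L * k, cells, s_cls))
      cells <- as.numeric(stats::rbinom(2L * k, cells, cfg$D))
      tot <- sum(cells)
      if (tot == 0) break
      G <- max(0, log2(cfg$N_stat / tot))
      cells <- as.numeric(stats::rmultinom(1, cfg$N_stat, cells * w_cls^G))
    }
    design_tot <- cells[1:k] + cells[(k + 1):(2 * k)]
    after <- if (sum(design_tot) == 0) rep(0, k)
             else as.numeric(stats::rmultinom(1, lib$depth, design_tot))
    cb <- 2L * r - 1L; ca <- 2L * r
    counts_out[, cb] <- before; counts_out[, ca] <- after
    sample_id[c(cb, ca)] <- sprintf("rep%d_%s", r, c("before", "after"))
  }
  colnames(counts_out) <- sample_id
  barcode_count_table(
    counts = counts_out,
    design_meta = data.frame(id = ids, is_control = is_control,
                             pi_mult = eff$pi_mult, w_mult = eff$w_mult,
                             stringsAsFactors = FALSE),
    sample_meta = data.frame(
      sample_id = sample_id,
      replicate = rep(seq_len(lib$n_replicates), each = 2L),
      timepoint = rep(c("before", "after"), lib$n_replicates),
      bottleneck = cfg$D,
      arm = if (lib$with_treatment) "selection" else "growth-control",
      stringsAsFactors = FALSE))
}
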