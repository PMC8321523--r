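# persevol

Simulation and analysis of experimental evolution of **antibiotic
persistence** under serial-transfer regimes with **population
bottlenecks**.

Persistence is phenotypic tolerance: a small subpopulation of cells (the
persisters, fraction π of the population) survives a bactericidal
treatment that kills normal cells, without any MIC change. A
serial-transfer regime — daily high-dose treatment of a stationary
culture, dilution by a ratio *D* (1:500 → *D* = 0.002), regrowth — selects
for higher π, while the treatment and dilution bottlenecks set the
strength of genetic drift and the mutational supply. `persevol` is for
researchers who run or reason about such experiments: it provides

- a stochastic **serial-passage simulator** (per-genotype binomial
  treatment survival `s = π` or the biphasic kill curve
  `S(t) = (1−π)e^(−k_n t) + π e^(−k_p t)`; binomial dilution; Wright–Fisher
  style multinomial regrowth with fitness odds `w^G`,
  `G = log2(N_stat/N_seed)`; Poisson beneficial mutation with a
  persistence/growth trade-off), including pooled barcoded
  knockout-library selections with partial edit fractions;
- the **adaptation-trajectory fit**
  `p(t) = L + (U−L)/(1 + e^(−S(t−λ)))` on log10 persister fractions
  (steepness *S* = rate of adaptation, λ = lag), with a strict
  two-parameter mode for (0,1)-normalized data;
- **fitness estimators**: trapezoidal AUC of growth curves, the
  competition coefficient *c* solving
  `AUC_mixed = c·AUC_mono + (1−c)·AUC_anc`, the odds-ratio relative
  fitness `W_A`, and the deterministic bottleneck-corrected spread
  recurrence `p(T+1) = W_eff p(T)/(W_eff p(T) + q(T))` with
  `W_eff = 1 + (W_A − 1)·D(ln D)²`;
- **barcode count-table analytics**: control-design median-of-ratios
  normalization, enrichment/depletion calls (one-sample t on replicate
  log2 fold-changes, BH-adjusted) with growth-control filtering,
  retained-mutant fractions (count ≥ 3 rule), replicate-pair Pearson
  correlations and top-hit tallies;
- a **small statistics toolkit** with exact small-sample Spearman
  permutation p-values (full n! enumeration for n ≤ 8), Welch t,
  variance F-test, and Benjamini–Hochberg adjustment.

## Worked example

```r
library(persevol)

# one population, 1:50 dilution, 18 daily cycles (scaled to 1e8 cells)
cfg <- regime_config(D = 0.02, N_stat = 1e8, n_cycles = 18, seed = 42)
run <- run_evolution(cfg)
run
#> Evolution run: D = 0.02, 18/18 cycle(s)
#>   persister fraction: 0.000149 -> 0.985

fit <- fit_adaptation_sigmoid(run$records$cycle,
                              log10(run$records$persister_fraction),
                              n_boot = 100)
fit
#> Adaptation trajectory fit (n = 18)
#>   S = 2.036 per cycle, lambda = 3.893 cycles
#>   asymptotes: L = -3.92, U = -0.4177 (log10), RSS = 1.709

mutant_spread(W_A = 1.5, D = 0.02, p0 = 1e-8, T_max = 18)
#> Mutant spread: W_A = 1.5, D = 0.02 (correction 0.306078, W_eff 1.15304, selection-coefficient)
#>   p(0) = 1e-08 -> p(18) = 1.29776e-07

spearman_exact(c(0.002, 0.01, 0.02, 0.1), c(0.21, 0.48, 0.66, 1.02))
#> Spearman rank correlation (exact, n = 4)
#>   rho = 1.0000, two-sided p = 0.08333
```

The simulated population adapts from the ancestral persister fraction
1.5×10⁻⁴ to near-complete persistence; the sigmoid fit summarizes that
trajectory as a steepness of ~2 per cycle after a lag of ~4 cycles. The
deterministic recurrence shows how slowly even a 50%-fitter mutant spreads
through a 1:50 bottleneck (13-fold in 18 rounds from one cell in 10⁸).
The exact Spearman test on four bottleneck sizes illustrates the
small-sample permutation p-value: a perfect rank correlation over four
groups can never beat p = 2/24 ≈ 0.083.

## Command line

A thin CLI wraps the same functions (subcommands `simulate-evolution`,
`simulate-library`, `fit-trajectory`, `competition-coef`,
`relative-fitness`, `mutant-spread`, `library-analyze`, `diversity`,
`heterogeneity`, `correlate`, `make-fixtures`; global flags `--seed`,
`--config`, `--out-dir`, `--log-level`). All inputs and outputs are
header-rowed TSV; every run writes a manifest with seed, version, and file
digests.

```sh
Rscript inst/scripts/persevol simulate-evolution --D 0.002 --n-populations 40 --seed 1 --out-dir out/
```

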