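# targetmr

Drug-target Mendelian randomization (MR), phenome-wide scanning and
Bayesian colocalization for GWAS summary statistics — with a synthetic
summary-statistics generator so every stage can be validated against known
ground truth.

## Who this is for and what it does

Genetic variants in or near the gene encoding a drug's target act as
lifelong "genetic mimics" of pharmacological modulation. Comparing their
predicted effects on lifespan, a panel of a priori outcomes, and a
phenome-wide catalog gives a confounding-robust early read on a drug's
intended and adverse effects. `targetmr` implements that workflow for
analysts working from published GWAS summary statistics:

* **gwas_io** — read/validate/harmonize summary-statistics tables (TSV/CSV,
  gzip-transparent) and LD matrices; allele alignment with strand-flip
  resolution, a configurable palindromic-SNP policy, and LD-proxy
  substitution (r² > 0.8) with sign handling.
* **instruments** — cis instrument selection (gene ± 1 Mb, MAF > 1%,
  p < 5×10⁻⁸, greedy clumping at r² < 0.001) and per-SNP F-statistic
  screening (weak if F ≤ 10); published SNP lists supported verbatim.
* **mr_engine** — Wald ratios (`β_Y/β_X`, delta-method SE), IVW with fixed
  effects for ≤ 3 SNPs and multiplicative random effects (dispersion
  floored at 1) for ≥ 4, generalized least squares for correlated
  instruments (`Ω = σᵢσⱼρᵢⱼ`), unit rescaling (e.g. log protection
  ratio × 10 → life-years), the linear-to-odds-ratio conversion
  `log OR = β/(μ(1−μ))` for binary traits analysed by linear regression,
  and two-sided z-tests for differences between estimates.
* **coloc_engine** — enumeration colocalization from Wakefield log-ABFs
  (`½(log(1−r) + rZ²)`, r = w/(V+w)) with priors 1e-4/1e-4/1e-5, prior
  sensitivity grids, per-variant shared posteriors, and the conditional
  probability PP4/(PP3+PP4).
* **phewas_scan** — catalog filtering with flowchart-style exclusion
  counts, single-instrument scans across thousands of phenotypes,
  Benjamini–Hochberg FDR at 5%, strata comparison, Manhattan-ready tables.
* **synthetic_gwas** — regional summary statistics from
  `MVN(Rb, SRS)` with AR(1) LD, two-sample MR draws with known causal
  effect, phenomes with known null labels, and colocalization pairs with
  planted shared or distinct causal variants.
* **pipeline** — `run_study()` drives the four stages (mortality →
  a priori outcomes → PheWAS → colocalization of significant hits) from a
  JSON/YAML config, with skip logs, outcome-conservation checks and
  byte-reproducible outputs; a thin CLI lives in `inst/cli/targetmr.R`.

All drug-mimicking estimates are reported **per SD decrease** in the
exposure, the direction a drug would move it.

## Worked example

```r
library(targetmr)

# Two-sample MR with a known causal effect of 0.3, five instruments
sim <- simulate_two_sample(two_sample_config(theta = 0.3, k = 5, seed = 1))
e <- sim$exposure$records; o <- sim$outcome$records
ivw(data.frame(beta = o$beta / e$beta, se = o$se / abs(e$beta)))
#> <mr_estimate> ivw_random (5 SNPs): 0.3098 (95% CI 0.2706 to 0.3490), p = 3.72e-54 [SD]
```

The IVW estimate (0.31, CI 0.27–0.35) covers the simulated truth of 0.3;
with five instruments the multiplicative random-effects rule applies
automatically.

```r
# Colocalization of two traits sharing one causal variant in a 50-variant
# region with AR(1) LD (rho = 0.9)
pair <- simulate_coloc_pair(shared = TRUE, m = 50, rho = 0.9, seed = 7)
coloc_abf(pair$region1, pair$region2)
#> <coloc_result> 50 variants
#> PP0 PP1 PP2 PP3 PP4
#>   0   0   0   0   1
#> conditional PP4: 1  top shared variant: rs42
```

PP4 ≈ 1 says the data overwhelmingly favour a single shared causal
variant, and the top shared variant is the planted one
(`pair$causal`).

```r
# A linear-regression effect on a binary trait (case fraction 0.1)
linear_to_logistic(0.009, 0.0018, 0.1)
#>   log_or se_log_or       or or_ci_low or_ci_high
#> 1    0.1      0.02 1.105171  1.062687   1.149353
```

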