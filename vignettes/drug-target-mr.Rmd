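---
title: "Drug-target Mendelian randomization with targetmr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with targetmr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem

Genetic variants in or near the gene encoding a drug's molecular target can
be used as instrumental variables that mimic lifelong pharmacological
modulation of that target. Comparing the genetically predicted effects of
such "genetic mimics" on lifespan, a panel of a priori outcomes, and a
phenome-wide catalog of traits gives an early, confounding-robust read on
both intended effects and potential adverse effects of a drug — for
example, inhibitors of a hepatic lipid-regulating receptor assessed through
their LDL-cholesterol-lowering variants. `targetmr` implements the full
summary-statistics workflow for such a study: harmonization of exposure and
outcome GWAS tables, cis instrument selection, Wald-ratio and
inverse-variance-weighted (IVW) causal estimation, a phenome-wide
association scan (PheWAS) with false-discovery-rate control, and
enumeration-based Bayesian colocalization — plus a synthetic
summary-statistics generator so that every stage can be validated against
known ground truth without any external downloads.

## Estimation model

For one variant with exposure association $\hat\beta_X$ and outcome
association $\hat\beta_Y$ (standard error $\sigma_Y$), the Wald ratio is

$$\hat\theta = \hat\beta_Y / \hat\beta_X, \qquad
\mathrm{se}(\hat\theta) = \sigma_Y / |\hat\beta_X|.$$

The standard error is the first-order delta-method form: uncertainty in
$\hat\beta_X$ is ignored. This is the convention that matches the
estimator as used in two-sample drug-target MR, and it is anti-conservative
only to order $(\sigma_X/\hat\beta_X)^2$ — negligible for the strong cis
instruments this package targets (the per-SNP F-statistic
$(\hat\beta_X/\sigma_X)^2$ is screened, with $F \le 10$ flagged as weak).

Independent ratios are pooled by IVW with weights $w_j = 1/\mathrm{se}_j^2$.
With three instruments or fewer the fixed-effects standard error
$(\sum_j w_j)^{-1/2}$ is reported; with four or more, a multiplicative
random-effects model inflates it by $\max\{1, \sqrt{Q/(k-1)}\}$ where $Q$
is Cochran's heterogeneity statistic. Two points are deliberate design
choices rather than forced by the literature:

* the random-effects dispersion is *multiplicative* with a floor at 1
  (never deflating below the fixed-effects error), the behaviour of the
  standard implementation of the 3-or-fewer/4-or-more rule; an additive
  DerSimonian–Laird alternative would also have been defensible, and the
  fixed/random switch is overridable via the `random` argument;
* confidence intervals use the exact normal quantile `qnorm(0.975)`, not
  1.96.

For instrument sets in mutual LD, `ivw_correlated()` fits generalized
least squares through the origin with covariance
$\Omega_{ij} = \sigma_{Y,i}\,\sigma_{Y,j}\,\rho_{ij}$ built from the signed
LD correlation matrix. With $\rho = I$ this is algebraically identical to
fixed-effects IVW (the test suite asserts agreement to ten significant
digits); at the $\rho \to 1$ boundary the matrix is ridge-jittered
(starting at $10^{-8}$, escalating tenfold to at most $10^{-4}$ before
failing), so duplicated instruments add no spurious precision.

All drug-mimicking estimates are reported **per SD decrease** in the
exposure — the direction a drug would move it — by negating the
per-SD-increase ratio. The convention is explicit in the output `scale`
labels, never implicit. A lifespan effect on the log protection ratio
scale is converted to approximate life-years by multiplying estimate, SE
and CI by 10 via `rescale()`.

Binary outcomes analysed by linear regression on a 0/1 trait are converted
to the log-odds scale with the established approximation
$\log \mathrm{OR} = \beta / (\mu(1-\mu))$, where $\mu$ is the case
fraction; the same divisor applies to the SE. The divisor is isolated in
`linear_to_logistic()` so a refined approximation could be substituted in
one place. The conversion round-trips exactly on analytically constructed
inputs and agrees with a direct logistic fit on simulated individual-level
data within sampling error.

## Harmonization rules

Variants are matched across datasets by rsID, not position (positions are
carried as 1-based metadata; no liftover is attempted). For each shared
variant the outcome coding is classified as identical, swapped (beta
negated, EAF reflected), or resolvable by strand complementation before
the swap test; anything else is dropped with a reason. Indels are matched
by exact string only. Palindromic (A/T, C/G) variants cannot be
strand-resolved from alleles alone, so the default policy aligns them by
allele frequency but drops them as ambiguous when the minor-allele
frequency exceeds 0.42 in either dataset; a stricter drop-all policy is
available because upstream tools differ on this point and the choice is
genuinely open. Instruments missing from an outcome are replaced by the
best available LD proxy with $r^2 > 0.8$ (ties broken by genomic distance,
then ID), with the proxy's effect sign-flipped when the LD correlation is
negative. Every rejected row, dropped variant and proxy substitution is
counted and reported — never silent.

## Instrument selection

`select_instruments()` restricts to the gene body ± 1 Mb (the conventional
cis window), keeps common (MAF > 1%) genome-wide-significant
(p < 5×10⁻⁸) variants, and clumps greedily: candidates ranked by ascending
p-value are retained only if their $r^2$ with every previously retained
variant stays below 0.001. Ties in p (which occur in simulation) are
broken by $|\beta|/\mathrm{se}$ descending, then variant ID, making the
output invariant to input row order. MAF is recomputed from EAF rather
than trusted from a separate column. Published instrument lists can be
supplied verbatim through `named_instruments()`, mirroring the common
practice of reusing established genetic mimics for each drug class.

## Colocalization

`coloc_abf()` implements single-causal-variant enumeration
colocalization. Per-variant evidence uses the Wakefield approximate Bayes
factor: with $V = \mathrm{se}^2$, $r = w/(V+w)$ and $Z = \beta/\mathrm{se}$,

$$\log \mathrm{ABF} = \tfrac12\left(\log(1-r) + r Z^2\right),$$

with prior effect variance $w = (0.2\,\mathrm{sd}_Y)^2$ for quantitative
traits ($\mathrm{sd}_Y = 1$ when traits are standardized) and $w = 0.15^2$
on the log-odds scale for binary traits — the cited framework's defaults.
Binary traits arriving on the linear scale are first converted with
`linear_to_logistic()` (messaged, since upstream practice is not
documented). Hypothesis sums are accumulated entirely in log space with
log-sum-exp; the two-distinct-variants term H3 is the log-difference
$\log(e^{L_1+L_2} - e^{L_{12}})$ evaluated stably, with negative round-off
clamped to $-\infty$ so H3 is never negative and is exactly zero for a
single-variant region. Priors default to $p_1 = p_2 = 10^{-4}$ and
$p_{12} = 10^{-5}$, with a standard sensitivity grid down to $10^{-6}$
(`coloc_sensitivity()` computes the ABFs once and reuses them). The
analysis window is the gene body ± 100 kb, inclusive.

Two summaries beyond PP0–PP4 are reported: the per-variant shared
posterior (softmax of $\mathrm{labf}_1 + \mathrm{labf}_2$), whose argmax
is the top shared variant, and the conditional colocalization probability
$\mathrm{PP4}/(\mathrm{PP3}+\mathrm{PP4})$ — the posterior for a shared
variant *given* that the outcome has a causal variant in the region,
useful when the outcome association is weak. A broader reading of
"conditional on the presence of a variant associated with the outcome"
would condition on $\{H_2, H_3, H_4\}$; the implemented ratio follows the
convention of the framework this statistic comes from, and since the full
PP vector is returned, the alternative is one line of arithmetic for any
user who prefers it. Variants with a missing or non-positive SE in either
trait are excluded (and counted) before ABF computation; a missing EAF is
tolerated because the ABF does not use it.

## PheWAS

`filter_phenotypes()` applies catalog-level inclusion rules in a fixed
order with per-rule counts, flowchart-style: duplicates, excluded
categories (external causes, socioeconomic factors, lifestyle, and
similar), availability of summary statistics, then power thresholds —
binary phenotypes need at least 100 cases and continuous/ordinal
phenotypes at least 10,000 samples. The thresholds are strict
("less than"), so boundary values are included. `run_phewas()` computes a
single-instrument Wald (or multi-instrument IVW) estimate per phenotype,
converts binary phenotypes to log-odds, and applies Benjamini–Hochberg
FDR at 5% across the scan. FDR families are per scan (overall, women,
men each separately; binary and continuous pooled within a scan), which is
the natural reading of separate sex-specific catalogs. q-values come from
`stats::p.adjust(method = "BH")`; the test suite checks them against a
literal $O(m^2)$ step-up implementation. Extremely small p-values are
floored at the smallest positive double so they remain valid inputs to
the step-up procedure.

## The synthetic generator

The generator works on the standardized-genotype scale: with unit-variance
genotypes and trait, the marginal truth in a region with LD matrix $R$ and
joint causal effects $b$ is $\beta_{\mathrm{marg}} = R b$, and one
region-wide draw of estimated betas comes from
$\mathcal N(\beta_{\mathrm{marg}},\, S R S)$ with $S = \mathrm{diag(se)}$
and $\mathrm{se} = 1/\sqrt n$. This parameterization was chosen for
analytic transparency — every estimator's sampling distribution is known
in closed form — and an allele-frequency-scaled mode
($\mathrm{se}_j = 1/\sqrt{2 n f_j (1-f_j)}$) is available for more
realistic I/O fixtures. Binary traits are emitted on the linear scale:
log-odds causal effects are shrunk by the Bernoulli variance $\mu(1-\mu)$
and the sampling variance uses the same trait variance, so the scan's OR
conversion is exercised end to end. LD is AR(1), $r_{ij} = \rho^{|i-j|}$,
positive definite by construction.

Default study conditions for the validation experiments: coverage uses a
true effect of 0.3 with five independent instruments of per-SD effects in
[0.05, 0.15] and $n = 10^5$ on both sides; colocalization calibration uses
50-variant regions, $\rho = 0.9$, effect 0.05 SD, $n = 5\times10^4$, with
distinct-causal pairs constrained to $r^2 < 0.1$; FDR control uses
2,000-phenotype phenomes, 90% null, non-null effects
$\mathcal N(0, 0.02^2)$, $n = 10^5$, 30% binary with case fraction 0.1,
and an instrument exposure effect of 0.3 SD (a strong cis effect), over
200 replicate seeds. These sizes make every recovery experiment
well-powered while keeping the full suite runnable on a laptop in a few
minutes. All generators draw under a local RNG state restored on exit, so
seeds are reproducible and no global state leaks between calls.

What the generator does *not* emulate: individual-level genotypes,
population structure, sample overlap between exposure and outcome GWAS,
winner's-curse in instrument discovery, assortative mating, and realistic
phenotype correlation across a phenome (phenotypes are simulated
independently). Passing recovery tests therefore demonstrate correctness
of the estimators and procedures under their stated assumptions, not
robustness of MR itself to violations of those assumptions on real
biobank data.

## Numerical and degenerate-input choices

* All colocalization arithmetic in log space; H3 clamped at zero from
  below; posteriors sum to one within $10^{-10}$.
* $\Omega$ inversion via Cholesky with escalating ridge jitter
  ($10^{-8} \to 10^{-4}$), then a named error.
* Clumping and proxy ties broken deterministically (p, then
  $|\beta|/\mathrm{se}$, then ID; r², then distance, then ID).
* Records failing invariants (se ≤ 0, EAF outside [0,1], identical
  alleles, p inconsistent with $|\beta/\mathrm{se}|$ by more than one
  order of magnitude) are rejected at ingest with a count.
* A zero exposure association makes the Wald ratio undefined and is an
  error, not an NA.
* Empty candidate sets after filtering return empty instrument tables
  with a warning so configured fallback SNP lists can take over.

## The four-stage pipeline

`run_study()` orchestrates the stages in order — mortality MR (plain 0.05
significance, life-year rescaling), the a priori outcome panel (BH-FDR
within each drug-by-stratum family), the PheWAS (BH-FDR within each scan),
and colocalization of every outcome flagged significant in stages 1–2 —
with drug-vs-drug and female-vs-male z-test tables, structured skip logs,
and an outcome-conservation check (every configured outcome appears in a
result table or the skip log). Reruns with the same config and seed are
byte-identical. A thin command-line wrapper over these functions ships in
`inst/cli/targetmr.R`.

## Known limitations

* Single-causal-variant colocalization only; no SuSiE-style multi-signal
  decomposition, no more than two traits.
* No MR-Egger or weighted-median estimators: with few, correlated cis
  instruments their assumptions are not satisfiable, so offering them
  would invite misuse.
* No multivariable MR, no trans instruments, no LD computation from
  genotypes, no remote LD/proxy services, no VCF ingestion.
* The linear-to-OR approximation degrades for very rare outcomes with
  rare variants; the package reports what the approximation gives and
  leaves judgement to the analyst.
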