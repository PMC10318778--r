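# Independent oracles used across the suite. These are deliberately naive
# implementations kept separate from the package's code paths.

# Enumeration-based colocalization oracle: walks every single-causal
# configuration (c1, c2) with c in {none, 1..m} for each trait, weighting
# by the priors and per-variant Bayes factors, and accumulates the five
# hypotheses. O(m^2); only for small regions.
coloc_enum_oracle <- function(labf1, labf2, p1, p2, p12) {
  m <- length(labf1)
  b1 <- exp(labf1)
  b2 <- exp(labf2)
  w <- c(PP0 = 1, PP1 = 0, PP2 = 0, PP3 = 0, PP4 = 0)
  for (i in seq_len(m)) w["PP1"] <- w["PP1"] + p1 * b1[i]
  for (j in seq_len(m)) w["PP2"] <- w["PP2"] + p2 * b2[j]
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) w["PP4"] <- w["PP4"] + p12 * b1[i] * b2[j]
      else w["PP3"] <- w["PP3"] + p1 * p2 * b1[i] * b2[j]
    }
  }
  w / sum(w)
}

# Wakefield log-ABF written out independently (variance form, not the
# shrinkage form used in the package).
labf_oracle <- function(beta, se, w) {
  v <- se^2
  0.5 * log(v / (v + w)) + (beta^2 / v) * (w / (v + w)) / 2
}

# O(m^2) Benjamini-Hochberg step-up: for each p-value, the q-value is the
# minimum of m * p_(i) / i over all sorted positions i at or above its own.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (i in k:m) best <- min(best, m * ps[i] / i)
    q[ord[k]] <- min(best, 1)
  }
  q
}

# greedy clump re-done literally from the rule statement
clump_oracle <- function(ids, pvals, betas, ses, ld, r2_max) {
  ord <- order(pvals, -abs(betas) / ses, ids)
  kept <- character()
  for (v in ids[ord]) {
    if (all(ld[v, kept]^2 < r2_max)) kept <- c(kept, v)
  }
  kept
}

# random trait pair with signal strengths kept inside the naive
# enumeration oracle's floating-point range (it exponentiates log-ABFs
# directly, so |labf| must stay well below log(.Machine$double.xmax))
oracle_pair <- function(m, seed) {
  set.seed(seed)
  mk <- function(id) {
    se <- runif(m, 0.012, 0.03)
    beta <- rnorm(m, 0, runif(1, 0.005, 0.04))
    summary_dataset(
      data.frame(variant_id = paste0("rs", seq_len(m)), chrom = "17",
                 pos = 7e6 + seq_len(m) * 1000, effect_allele = "A",
                 other_allele = "G", eaf = 0.3, beta = beta, se = se,
                 pvalue = 2 * pnorm(-abs(beta / se)), n = 5e4,
                 n_cases = NA),
      trait_id = id, validate = FALSE)
  }
  list(r1 = mk("t1"), r2 = mk("t2"))
}

# random small summary dataset over shared variants, for harmonization and
# coloc property tests
random_dataset <- function(m, trait_id, seed, beta_sd = 0.05, n = 5e4) {
  set.seed(seed)
  se <- runif(m, 0.003, 0.02)
  beta <- rnorm(m, 0, beta_sd)
  summary_dataset(
    data.frame(variant_id = paste0("rs", seq_len(m)), chrom = "17",
               pos = 7e6 + seq_len(m) * 1000,
               effect_allele = "A", other_allele = "G",
               eaf = runif(m, 0.05, 0.95), beta = beta, se = se,
               pvalue = 2 * pnorm(-abs(beta / se)), n = n, n_cases = NA),
    trait_id = trait_id, validate = FALSE)
}
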