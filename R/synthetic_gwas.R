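# ---- synthetic GWAS summary statistics with known ground truth ----------
#
# Generators for regional summary statistics, two-sample MR datasets,
# phenomes and colocalization pairs. The parameterization is the
# standardized-genotype one: with unit-variance genotypes and trait, the
# marginal truth in a region with LD matrix R and joint causal effects b is
# beta_marg = R b, and the estimated betas are one draw from
# MVN(beta_marg, R / n) with per-variant se = 1/sqrt(n). An
# allele-frequency-scaled mode (se_j = 1/sqrt(2 n f_j (1-f_j))) is offered
# for more realistic I/O fixtures.

#' AR(1) LD correlation matrix
#'
#' `r_ij = rho^|i-j|` with synthetic rsID dimnames; positive definite by
#' construction for `0 <= rho < 1`.
#'
#' @param m number of variants.
#' @param rho decay parameter in \[0,1).
#' @param variant_ids optional IDs (default `rs1..rsm`).
#' @return square correlation matrix.
#' @export
make_ld_matrix <- function(m, rho, variant_ids = paste0("rs", seq_len(m))) {
  stopifnot(m >= 1, rho >= 0, rho < 1, length(variant_ids) == m)
  idx <- seq_len(m)
  r <- rho^abs(outer(idx, idx, "-"))
  dimnames(r) <- list(variant_ids, variant_ids)
  r
}

#' Configuration for a synthetic regional GWAS
#'
#' @param m number of variants.
#' @param rho AR(1) LD decay.
#' @param causal data.frame with columns `index` (1-based, <= m) and
#'   `effect` (per-SD effect of the standardized genotype; log-odds scale
#'   for binary traits); `NULL` for a null region.
#' @param n GWAS sample size.
#' @param maf_range minor-allele-frequency range, within (0, 0.5\].
#' @param trait_type `"quantitative"` or `"binary_linear"`.
#' @param case_fraction case fraction mu for binary traits.
#' @param se_mode `"standardized"` (`se = 1/sqrt(n)`) or `"af_scaled"`
#'   (`se_j = 1/sqrt(2 n f_j (1-f_j))`).
#' @param seed RNG seed; every draw is deterministic given it.
#' @return Object of class `region_config`.
#' @export
region_config <- function(m, rho, causal = NULL, n = 50000,
                          maf_range = c(0.05, 0.5),
                          trait_type = "quantitative", case_fraction = NULL,
                          se_mode = c("standardized", "af_scaled"),
                          seed = 1L) {
  se_mode <- match.arg(se_mode)
  if (!is.null(causal)) stopifnot(all(causal$index >= 1), all(causal$index <= m))
  stopifnot(n > 0, maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(m = m, rho = rho, causal = causal, n = n,
                 maf_range = maf_range, trait_type = trait_type,
                 case_fraction = case_fraction, se_mode = se_mode,
                 seed = seed),
            class = "region_config")
}

#' Simulate regional GWAS summary statistics
#'
#' One region-wide draw of marginal association estimates from
#' `MVN(R b_marg, S R S)` where `b_marg = R b_causal` and `S = diag(se)`.
#' Two-sided normal p-values; EAFs drawn uniformly from the MAF range and
#' reflected to either allele with probability 1/2. Binary traits are
#' produced on the linear (case-probability) scale: the causal effects are
#' interpreted on the log-odds scale and shrunk by `mu (1-mu)`, and the
#' sampling variance uses the Bernoulli trait variance `mu (1-mu)`.
#'
#' @param cfg a [region_config()].
#' @param chrom,pos_start,pos_step genomic coordinates for the synthetic
#'   variants (defaults: chromosome 17, 1 kb spacing).
#' @param trait_id trait label.
#' @return list with `dataset` (a `summary_dataset`), `ld` (the LD
#'   matrix), and `beta_marg` (the true marginal effects on the emitted
#'   scale).
#' @export
simulate_region_stats <- function(cfg, chrom = "17", pos_start = 7e6,
                                  pos_step = 1000, trait_id = "synthetic") {
  stopifnot(inherits(cfg, "region_config"))
  m <- cfg$m
  ids <- paste0("rs", seq_len(m))
  r <- make_ld_matrix(m, cfg$rho, ids)
  with_seed(cfg$seed, {
    b_causal <- numeric(m)
    if (!is.null(cfg$causal)) b_causal[cfg$causal$index] <- cfg$causal$effect
    binary <- cfg$trait_type == "binary_linear"
    mu <- cfg$case_fraction %||% if (binary) 0.1 else NULL
    trait_var <- if (binary) mu * (1 - mu) else 1
    # linear-scale effect of a standardized genotype on a binary trait:
    # log-odds effect shrunk by the Bernoulli variance
    if (binary) b_causal <- b_causal * trait_var
    beta_marg <- drop(r %*% b_causal)

    maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    eaf <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
    se <- if (cfg$se_mode == "standardized") rep(sqrt(trait_var / cfg$n), m)
    else sqrt(trait_var / (2 * cfg$n * eaf * (1 - eaf)))
    ch <- chol(r)
    beta_hat <- beta_marg + se * drop(crossprod(ch, stats::rnorm(m)))
    pvalue <- 2 * stats::pnorm(-abs(beta_hat / se))

    rec <- data.frame(variant_id = ids, chrom = chrom,
                      pos = pos_start + (seq_len(m) - 1) * pos_step,
                      effect_allele = "A", other_allele = "G",
                      eaf = eaf, beta = beta_hat, se = se,
                      pvalue = pmax(pvalue, .Machine$double.xmin),
                      n = cfg$n,
                      n_cases = if (binary) round(mu * cfg$n) else NA)
    ds <- summary_dataset(rec, trait_id = trait_id,
                          trait_type = cfg$trait_type,
                          case_fraction = mu, validate = FALSE)
    list(dataset = ds, ld = r, beta_marg = beta_marg)
  })
}

#' Configuration for a two-sample MR simulation
#'
#' @param theta true causal effect of the exposure on the outcome.
#' @param k number of mutually independent instruments.
#' @param exp_effects true per-SD exposure effects of the instruments
#'   (length k); `NULL` draws them uniformly from \[0.05, 0.15\], the
#'   typical magnitude of strong cis variants.
#' @param n_exp,n_out GWAS sample sizes on each side.
#' @param pleiotropy_sd SD of per-instrument direct effects on the outcome
#'   (0 = all instruments valid).
#' @param seed RNG seed.
#' @return Object of class `two_sample_config`.
#' @export
two_sample_config <- function(theta, k, exp_effects = NULL, n_exp = 1e5,
                              n_out = 1e5, pleiotropy_sd = 0, seed = 1L) {
  stopifnot(k >= 1, n_exp > 0, n_out > 0, pleiotropy_sd >= 0)
  if (!is.null(exp_effects)) stopifnot(length(exp_effects) == k)
  structure(list(theta = theta, k = k, exp_effects = exp_effects,
                 n_exp = n_exp, n_out = n_out,
                 pleiotropy_sd = pleiotropy_sd, seed = seed),
            class = "two_sample_config")
}

#' Simulate a two-sample MR dataset with known causal effect
#'
#' Instrument j has true exposure effect `b_j`; its estimated exposure
#' association is `N(b_j, 1/n_exp)` and its estimated outcome association
#' is `N(theta * b_j + a_j, 1/n_out)` with direct (pleiotropic) effect
#' `a_j ~ N(0, pleiotropy_sd^2)`. Instruments are mutually independent.
#'
#' @param cfg a [two_sample_config()].
#' @return list with `exposure` and `outcome` `summary_dataset`s (aligned,
#'   same alleles) and `truth` (the drawn `exp_effects` and pleiotropic
#'   effects).
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "two_sample_config"))
  with_seed(cfg$seed, {
    k <- cfg$k
    b <- cfg$exp_effects %||% stats::runif(k, 0.05, 0.15)
    a <- if (cfg$pleiotropy_sd > 0) stats::rnorm(k, 0, cfg$pleiotropy_sd)
    else numeric(k)
    se_x <- rep(1 / sqrt(cfg$n_exp), k)
    se_y <- rep(1 / sqrt(cfg$n_out), k)
    bx <- stats::rnorm(k, b, se_x)
    by <- stats::rnorm(k, cfg$theta * b + a, se_y)
    maf <- stats::runif(k, 0.1, 0.5)
    base <- data.frame(variant_id = paste0("rs", seq_len(k)),
                       chrom = as.character(seq_len(k)),
                       pos = 1e6 * seq_len(k),
                       effect_allele = "A", other_allele = "G", eaf = maf)
    mk <- function(beta, se, n, id) summary_dataset(
      cbind(base, beta = beta, se = se,
            pvalue = 2 * stats::pnorm(-abs(beta / se)), n = n, n_cases = NA),
      trait_id = id, validate = FALSE)
    list(exposure = mk(bx, se_x, cfg$n_exp, "exposure"),
         outcome = mk(by, se_y, cfg$n_out, "outcome"),
         truth = list(exp_effects = b, pleiotropy = a, theta = cfg$theta))
  })
}

#' Simulate a phenome with known null labels
#'
#' Generates a single-instrument phenome for FDR and power experiments:
#' each phenotype's true causal effect is 0 with probability `frac_null`
#' and otherwise drawn `N(0, effect_sd^2)` (SD units for continuous, log
#' odds for binary phenotypes). Binary phenotypes are emitted on the
#' linear scale with known case fraction so the odds-ratio conversion is
#' exercised by the scan. The instrument's exposure association is a
#' strong cis effect (`exposure_beta` SD per allele).
#'
#' @param n_phenos number of phenotypes.
#' @param frac_null fraction of phenotypes with zero effect.
#' @param effect_sd SD of the non-null effects.
#' @param binary_fraction fraction of binary phenotypes.
#' @param n per-phenotype GWAS sample size.
#' @param seed RNG seed.
#' @param exposure_beta instrument's per-SD exposure association.
#' @param case_fraction case fraction for binary phenotypes.
#' @param categories category labels cycled over phenotypes.
#' @return list with `instrument` (1-row exposure record data.frame),
#'   `catalog`, `phenome` (list of `summary_dataset`s) and `truth`
#'   (data.frame of `pheno_id`, `theta`, `null`).
#' @export
simulate_phenome <- function(n_phenos, frac_null = 0.9, effect_sd = 0.02,
                             binary_fraction = 0.3, n = 1e5, seed = 1L,
                             exposure_beta = 0.3, case_fraction = 0.1,
                             categories = c("biomarkers", "physical measures",
                                            "circulatory", "digestive")) {
  stopifnot(n_phenos >= 1, frac_null >= 0, frac_null <= 1)
  with_seed(seed, {
    null <- stats::runif(n_phenos) < frac_null
    theta <- ifelse(null, 0, stats::rnorm(n_phenos, 0, effect_sd))
    binary <- stats::runif(n_phenos) < binary_fraction
    ids <- sprintf("pheno_%04d", seq_len(n_phenos))
    mu <- case_fraction
    se_q <- 1 / sqrt(n)
    se_b <- sqrt(mu * (1 - mu) / n)

    instrument <- data.frame(variant_id = "rs_instr", chrom = "17",
                             pos = 7.1e6, effect_allele = "A",
                             other_allele = "G", eaf = 0.25,
                             beta = exposure_beta, se = se_q,
                             pvalue = 2 * stats::pnorm(-abs(exposure_beta / se_q)),
                             n = n, n_cases = NA)

    truth_out <- ifelse(binary, theta * mu * (1 - mu), theta) * exposure_beta
    se_out <- ifelse(binary, se_b, se_q)
    beta_hat <- stats::rnorm(n_phenos, truth_out, se_out)
    pvals <- 2 * stats::pnorm(-abs(beta_hat / se_out))

    # all phenotype records at once, then one lightweight dataset each
    records <- data.frame(variant_id = "rs_instr", chrom = "17", pos = 7.1e6,
                          effect_allele = "A", other_allele = "G", eaf = 0.25,
                          beta = beta_hat, se = se_out, pvalue = pvals,
                          n = n, n_cases = ifelse(binary, round(mu * n), NA))
    phenome <- lapply(seq_len(n_phenos), function(i) {
      structure(list(trait_id = ids[i],
                     trait_type = if (binary[i]) "binary_linear"
                     else "quantitative",
                     records = records[i, , drop = FALSE],
                     sd_y = NULL,
                     case_fraction = if (binary[i]) mu else NULL),
                class = "summary_dataset")
    })
    catalog <- data.frame(pheno_id = ids, description = ids,
                          value_type = ifelse(binary, "binary", "continuous"),
                          n = n,
                          n_cases = ifelse(binary, round(mu * n), NA),
                          category = rep_len(categories, n_phenos),
                          sex_stratum = "both")
    list(instrument = instrument, catalog = catalog, phenome = phenome,
         truth = data.frame(pheno_id = ids, theta = theta, null = null))
  })
}

#' Simulate a colocalization trait pair
#'
#' Two regional GWAS over a common AR(1) LD structure. With
#' `shared = TRUE` both traits carry the same causal variant; otherwise
#' two causal indices are drawn (re-drawn until their LD satisfies
#' `r^2 < 0.1`) so the regional associations are driven by distinct
#' variants in low LD.
#'
#' @param shared do the traits share the causal variant?
#' @param m,rho region size and LD decay.
#' @param n1,n2 sample sizes of the two GWAS.
#' @param effect causal effect size (SD units) for both traits.
#' @param seed RNG seed.
#' @return list with `region1`, `region2` (`summary_dataset`s), `ld`, and
#'   `causal` (the planted indices for trait 1 and trait 2).
#' @export
simulate_coloc_pair <- function(shared, m = 50, rho = 0.9, n1 = 50000,
                                n2 = 50000, effect = 0.05, seed = 1L) {
  stopifnot(m >= 2 || shared)
  with_seed(seed, {
    i1 <- sample.int(m, 1)
    if (shared) {
      i2 <- i1
    } else {
      repeat {
        i2 <- sample.int(m, 1)
        if (rho^(2 * abs(i1 - i2)) < 0.1) break
      }
    }
    s1 <- sample.int(.Machine$integer.max, 1)
    s2 <- sample.int(.Machine$integer.max, 1)
    r1 <- simulate_region_stats(
      region_config(m, rho, causal = data.frame(index = i1, effect = effect),
                    n = n1, seed = s1), trait_id = "trait1")
    r2 <- simulate_region_stats(
      region_config(m, rho, causal = data.frame(index = i2, effect = effect),
                    n = n2, seed = s2), trait_id = "trait2")
    list(region1 = r1$dataset, region2 = r2$dataset, ld = r1$ld,
         causal = c(trait1 = i1, trait2 = i2))
  })
}
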