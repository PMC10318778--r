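#' Colocalization configuration
#'
#' Priors and window for enumeration-based colocalization of two traits
#' under the single-causal-variant assumption. Defaults follow the
#' conventional recommendation: 1e-4 for a variant associated with trait 1,
#' 1e-4 for trait 2, and 1e-5 for a variant associated with both; the usual
#' sensitivity analysis lowers the shared prior to 1e-6. The region window
#' is the gene body +/- 100 kb.
#'
#' @param p1,p2 per-variant prior probabilities of association with each
#'   trait.
#' @param p12 per-variant prior probability of association with both.
#' @param window_bp half-width of the analysis window around the gene body.
#' @param w1,w2 prior variances of the true effect for each trait; `NULL`
#'   selects the default at analysis time: `(0.2 * sd_y)^2` for
#'   quantitative traits (`sd_y = 1` when unknown, i.e. standardized) and
#'   `0.15^2` on the log-odds scale for binary traits.
#' @return Object of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, window_bp = 1e5,
                         w1 = NULL, w2 = NULL) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), p1 + p2 + p12 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12, window_bp = window_bp,
                 w1 = w1, w2 = w2), class = "coloc_config")
}

#' Wakefield log approximate Bayes factor
#'
#' Closed-form evidence for a variant-trait association from the estimated
#' effect, its standard error and a prior effect variance `w`: with
#' `V = se^2`, `r = w/(V+w)` and `Z = beta/se`, the log ABF is
#' `0.5 * (log(1-r) + r Z^2)`. Vectorized.
#'
#' @param beta,se estimate and standard error (se > 0).
#' @param w prior variance of the true effect (w >= 0).
#' @return numeric vector of log approximate Bayes factors.
#' @export
wakefield_labf <- function(beta, se, w) {
  stopifnot(all(se > 0), all(w >= 0))
  v <- se^2
  r <- w / (v + w)
  z2 <- (beta / se)^2
  0.5 * (log1p(-r) + r * z2)
}

default_prior_variance <- function(dataset, w_cfg) {
  if (!is.null(w_cfg)) return(w_cfg)
  if (dataset$trait_type == "quantitative")
    (0.2 * (dataset$sd_y %||% 1))^2
  else 0.15^2
}

# per-trait effect table on the ABF scale: binary traits analysed with
# linear regression are first converted to log odds ratios
abf_scale_records <- function(dataset) {
  rec <- dataset$records
  if (dataset$trait_type == "binary_linear") {
    mu <- dataset$case_fraction
    if (is.null(mu))
      stop("binary_linear trait '", dataset$trait_id,
           "' needs a case fraction for the log-odds conversion")
    conv <- linear_to_logistic(rec$beta, rec$se, mu)
    rec$beta <- conv$log_or
    rec$se <- conv$se_log_or
    message("coloc: converted '", dataset$trait_id,
            "' from the linear to the log-odds scale (mu = ",
            signif(mu, 3), ")")
  }
  rec
}

#' Enumeration-based colocalization of two traits
#'
#' Tests whether two traits share a single causal variant in a cis region.
#' Per-variant Wakefield log ABFs are computed for each trait and combined
#' over the five hypotheses (H0 no association; H1/H2 one trait only;
#' H3 two distinct causal variants; H4 one shared variant) by log-sum-exp,
#' with the H3 term evaluated as a stable log-difference. Variants with a
#' missing standard error or allele frequency in either trait are excluded
#' (messaged) before computation.
#'
#' @param region1,region2 `summary_dataset` objects for the two traits
#'   (typically already harmonized; only variants present in both are used).
#' @param region optional [gene_region()]; when supplied, variants are
#'   restricted to the gene body +/- `config$window_bp` (inclusive bounds).
#' @param config a [coloc_config()].
#' @return Object of class `coloc_result`: posterior probabilities
#'   `pp` (PP0..PP4), per-variant log-ABF vectors `labf1`, `labf2`,
#'   `top_shared_variant` (argmax of the per-variant shared posterior),
#'   `per_variant_pp4`, `conditional_pp4 = PP4/(PP3+PP4)`, `n_variants`.
#' @export
coloc_abf <- function(region1, region2, region = NULL,
                      config = coloc_config()) {
  stopifnot(inherits(region1, "summary_dataset"),
            inherits(region2, "summary_dataset"),
            inherits(config, "coloc_config"))
  rec1 <- abf_scale_records(region1)
  rec2 <- abf_scale_records(region2)
  shared <- intersect(rec1$variant_id, rec2$variant_id)
  if (!is.null(region)) {
    win <- gene_region(region$gene, region$chrom, region$start, region$end,
                       flank = config$window_bp)
    r1 <- rec1[match(shared, rec1$variant_id), ]
    shared <- shared[in_region(r1$chrom, r1$pos, win)]
  }
  if (!length(shared))
    stop("coloc_abf: no overlapping variants between '", region1$trait_id,
         "' and '", region2$trait_id, "'")
  r1 <- rec1[match(shared, rec1$variant_id), ]
  r2 <- rec2[match(shared, rec2$variant_id), ]
  usable <- !is.na(r1$se) & r1$se > 0 & !is.na(r2$se) & r2$se > 0
  if (any(!usable)) {
    message("coloc_abf: excluded ", sum(!usable),
            " variant(s) with missing/invalid se")
    r1 <- r1[usable, ]; r2 <- r2[usable, ]; shared <- shared[usable]
  }
  if (!length(shared)) stop("coloc_abf: no usable variants after exclusions")

  w1 <- default_prior_variance(region1, config$w1)
  w2 <- default_prior_variance(region2, config$w2)
  labf1 <- wakefield_labf(r1$beta, r1$se, w1)
  labf2 <- wakefield_labf(r2$beta, r2$se, w2)
  res <- coloc_posteriors(labf1, labf2, config)

  pv <- labf1 + labf2
  per_variant_pp4 <- exp(pv - logsumexp(pv))
  top <- shared[which.max(per_variant_pp4)]
  s34 <- res$pp["PP3"] + res$pp["PP4"]
  structure(list(pp = res$pp,
                 labf1 = stats::setNames(labf1, shared),
                 labf2 = stats::setNames(labf2, shared),
                 top_shared_variant = top,
                 per_variant_pp4 = stats::setNames(per_variant_pp4, shared),
                 conditional_pp4 = if (s34 > 0) unname(res$pp["PP4"] / s34)
                 else NA_real_,
                 n_variants = length(shared),
                 config = config),
            class = "coloc_result")
}

# hypothesis arithmetic in log space from per-variant log ABFs
coloc_posteriors <- function(labf1, labf2, config) {
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  h <- c(H0 = 0,
         H1 = log(config$p1) + l1,
         H2 = log(config$p2) + l2,
         H3 = if (length(labf1) > 1)
           log(config$p1) + log(config$p2) + logdiffexp(l1 + l2, l12)
         else -Inf,
         H4 = log(config$p12) + l12)
  pp <- exp(h - logsumexp(h))
  names(pp) <- paste0("PP", 0:4)
  list(pp = pp, log_h = h)
}

#' Conditional colocalization probability
#'
#' Posterior probability of a shared causal variant conditional on the
#' region containing a variant associated with the second trait:
#' `PP4 / (PP3 + PP4)`. Useful when power to detect colocalization is low
#' because the outcome association is weak.
#'
#' @param result a `coloc_result`.
#' @return numeric scalar, or `NA` when `PP3 + PP4 = 0`.
#' @export
conditional_coloc_prob <- function(result) {
  stopifnot(inherits(result, "coloc_result"))
  s <- result$pp["PP3"] + result$pp["PP4"]
  if (s == 0) return(NA_real_)
  unname(result$pp["PP4"] / s)
}

#' Prior sensitivity analysis for colocalization
#'
#' Re-evaluates the hypothesis posteriors over a grid of shared-variant
#' priors `p12`, computing the per-variant log ABFs once and reusing them.
#'
#' @inheritParams coloc_abf
#' @param p12_grid numeric vector of shared-variant priors.
#' @return data.frame with one row per prior: `p12`, `PP0`..`PP4`,
#'   `conditional_pp4`.
#' @export
coloc_sensitivity <- function(region1, region2, region = NULL,
                              config = coloc_config(),
                              p12_grid = c(1e-5, 1e-6)) {
  base <- coloc_abf(region1, region2, region = region, config = config)
  rows <- lapply(p12_grid, function(p12) {
    cfg <- coloc_config(p1 = config$p1, p2 = config$p2, p12 = p12,
                        window_bp = config$window_bp,
                        w1 = config$w1, w2 = config$w2)
    pp <- coloc_posteriors(base$labf1, base$labf2, cfg)$pp
    s34 <- pp["PP3"] + pp["PP4"]
    data.frame(p12 = p12, t(pp),
               conditional_pp4 = if (s34 > 0) unname(pp["PP4"] / s34)
               else NA_real_)
  })
  do.call(rbind, rows)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result>", x$n_variants, "variants\n")
  print(round(x$pp, 4))
  cat("conditional PP4:", round(x$conditional_pp4, 4),
      " top shared variant:", x$top_shared_variant, "\n")
  invisible(x)
}
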