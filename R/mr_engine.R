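#' Construct an MR estimate
#'
#' Container for a causal-effect estimate with normal-theory 95% confidence
#' interval and two-sided p-value. The CI uses the exact normal quantile.
#'
#' @param beta,se point estimate and standard error.
#' @param method one of `"wald"`, `"ivw_fixed"`, `"ivw_random"`,
#'   `"ivw_correlated"`.
#' @param n_snps number of instruments.
#' @param q_stat optional Cochran's Q heterogeneity statistic.
#' @param scale free-text unit label (e.g. `"SD"`, `"log-odds"`,
#'   `"life-years"`).
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(beta, se, method, n_snps, q_stat = NA_real_,
                        scale = "SD") {
  stopifnot(se >= 0)
  z <- stats::qnorm(0.975)
  structure(list(beta = beta, se = se,
                 ci_low = beta - z * se, ci_high = beta + z * se,
                 pvalue = if (se > 0)
                   max(2 * stats::pnorm(-abs(beta / se)),
                       .Machine$double.xmin)
                 else as.numeric(beta == 0),
                 method = method, n_snps = as.integer(n_snps),
                 q_stat = q_stat, scale = scale),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNP%s): %.4f (95%% CI %.4f to %.4f), p = %.3g [%s]\n",
              x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
              x$beta, x$ci_low, x$ci_high, x$pvalue, x$scale))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             q_stat = x$q_stat, scale = x$scale)
}

#' Single-instrument Wald ratio
#'
#' Causal estimate from one variant: the genetic association with the
#' outcome divided by the genetic association with the exposure, with a
#' first-order delta-method standard error `se_out / |beta_exp|` (exposure
#' uncertainty ignored, the convention matching the estimator).
#'
#' @param beta_exp SNP-exposure association (nonzero).
#' @param beta_out,se_out SNP-outcome association and standard error.
#' @param scale unit label for the result.
#' @return An `mr_estimate` with `method = "wald"`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out, scale = "SD") {
  if (beta_exp == 0) stop("wald_ratio undefined: exposure association is zero")
  mr_estimate(beta = beta_out / beta_exp, se = se_out / abs(beta_exp),
              method = "wald", n_snps = 1L, scale = scale)
}

#' Inverse-variance-weighted meta-analysis of Wald ratios
#'
#' Pools independent single-SNP ratio estimates with weights `1/se^2`.
#' Fixed effects are used for three SNPs or fewer and multiplicative random
#' effects for four or more (the automatic rule; override with `random`):
#' the random-effects standard error multiplies the fixed one by
#' `max(1, sqrt(Q/(k-1)))`, where Q is Cochran's heterogeneity statistic,
#' so the pooled standard error is never deflated below the fixed-effects
#' value.
#'
#' @param ratios list of `mr_estimate` objects, or a data.frame with
#'   columns `beta` and `se`.
#' @param random `"auto"` (default rule), `"fixed"`, or `"random"`.
#' @param scale unit label; defaults to the first ratio's label.
#' @return An `mr_estimate` with `method` `"ivw_fixed"` or `"ivw_random"`
#'   and `q_stat` filled.
#' @export
ivw <- function(ratios, random = c("auto", "fixed", "random"), scale = NULL) {
  random <- match.arg(random)
  if (inherits(ratios, "mr_estimate")) ratios <- list(ratios)
  if (is.data.frame(ratios)) {
    betas <- ratios$beta; ses <- ratios$se
    scale <- scale %||% "SD"
  } else {
    if (!length(ratios)) stop("ivw: empty ratio list")
    betas <- vapply(ratios, `[[`, numeric(1), "beta")
    ses <- vapply(ratios, `[[`, numeric(1), "se")
    scale <- scale %||% ratios[[1]]$scale
  }
  k <- length(betas)
  if (k == 0) stop("ivw: empty ratio list")
  stopifnot(all(ses > 0))
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (betas - beta)^2)
  use_random <- switch(random, auto = k >= 4, fixed = FALSE, random = TRUE)
  if (use_random && k >= 2) {
    se <- se_fixed * max(1, sqrt(q / (k - 1)))
    method <- "ivw_random"
  } else {
    se <- se_fixed
    method <- "ivw_fixed"
  }
  mr_estimate(beta, se, method = method, n_snps = k, q_stat = q, scale = scale)
}

#' IVW for correlated instruments (generalized least squares)
#'
#' For instrument sets in mutual LD, the pooled estimate is obtained by
#' generalized weighted regression of the outcome associations on the
#' exposure associations through the origin, with covariance
#' `Omega_ij = se_out_i * se_out_j * rho_ij` built from the signed LD
#' correlation matrix. With an identity correlation matrix this reduces
#' exactly to fixed-effects IVW of the Wald ratios.
#'
#' @param beta_exp,beta_out,se_out aligned per-variant vectors.
#' @param rho signed LD correlation matrix (ordered as the vectors) or a
#'   matrix with dimnames covering them.
#' @param scale unit label.
#' @param jitter ridge added to `rho`'s diagonal when it is numerically
#'   singular (escalated up to 1e-4 before failing).
#' @return An `mr_estimate` with `method = "ivw_correlated"`.
#' @export
ivw_correlated <- function(beta_exp, beta_out, se_out, rho, scale = "SD",
                           jitter = 1e-8) {
  k <- length(beta_exp)
  stopifnot(length(beta_out) == k, length(se_out) == k,
            nrow(rho) == k, ncol(rho) == k, all(se_out > 0))
  omega <- outer(se_out, se_out) * rho
  ch <- NULL
  j <- 0
  repeat {
    ch <- tryCatch(chol(omega + diag(j, k)), error = function(e) NULL)
    if (!is.null(ch)) break
    j <- if (j == 0) jitter else j * 10
    if (j > 1e-4)
      stop("ivw_correlated: covariance matrix Omega is singular beyond ",
           "jitter tolerance")
  }
  # GLS through the origin: beta = (X' Omega^-1 X)^-1 X' Omega^-1 y
  xi <- backsolve(ch, forwardsolve(t(ch), beta_exp))
  yi <- backsolve(ch, forwardsolve(t(ch), beta_out))
  xtox <- sum(beta_exp * xi)
  beta <- sum(beta_exp * yi) / xtox
  se <- sqrt(1 / xtox)
  mr_estimate(beta, se, method = "ivw_correlated", n_snps = k, scale = scale)
}

#' Rescale an MR estimate
#'
#' Multiplies beta, SE and CI bounds by a constant (CI bounds swap when the
#' factor is negative) and relabels the scale; the p-value is unchanged.
#' Typical uses: x10 to express a log protection ratio in life-years, and
#' x(-1) to switch between per-SD-increase and per-SD-decrease exposure
#' conventions.
#'
#' @param est an `mr_estimate`.
#' @param factor nonzero multiplier.
#' @param new_scale replacement unit label.
#' @return The rescaled `mr_estimate`.
#' @export
rescale <- function(est, factor, new_scale = est$scale) {
  stopifnot(inherits(est, "mr_estimate"), factor != 0)
  out <- est
  out$beta <- est$beta * factor
  out$se <- est$se * abs(factor)
  bounds <- sort(c(est$ci_low * factor, est$ci_high * factor))
  out$ci_low <- bounds[1]; out$ci_high <- bounds[2]
  out$scale <- new_scale
  out
}

#' Convert a linear-regression effect on a binary trait to an odds ratio
#'
#' GWAS of binary traits run with linear regression report effects on the
#' case-probability scale; with case fraction mu, the established
#' approximation divides beta and its SE by mu*(1-mu) to obtain the log
#' odds ratio.
#'
#' @param beta,se linear-scale effect and standard error (vectors allowed).
#' @param mu case fraction in (0,1).
#' @return data.frame with `log_or`, `se_log_or`, `or`, `or_ci_low`,
#'   `or_ci_high`.
#' @export
linear_to_logistic <- function(beta, se, mu) {
  if (any(mu <= 0 | mu >= 1)) stop("case fraction mu must lie in (0,1)")
  d <- mu * (1 - mu)
  log_or <- beta / d
  se_log_or <- se / d
  z <- stats::qnorm(0.975)
  data.frame(log_or = log_or, se_log_or = se_log_or, or = exp(log_or),
             or_ci_low = exp(log_or - z * se_log_or),
             or_ci_high = exp(log_or + z * se_log_or))
}

#' Two-sided z-test for a difference between two estimates
#'
#' Compares two independent estimates on the same scale (e.g. women vs men,
#' or two drug targets): `z = (a - b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param a,b `mr_estimate` objects or lists with `beta` and `se`.
#' @return list with `z` and `pvalue`.
#' @export
difference_z_test <- function(a, b) {
  z <- (a$beta - b$beta) / sqrt(a$se^2 + b$se^2)
  list(z = z, pvalue = 2 * stats::pnorm(-abs(z)))
}
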