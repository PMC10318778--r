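#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR control: q-values are the BH-adjusted p-values
#' (`stats::p.adjust(method = "BH")`) and a phenotype is declared
#' significant when its q-value is at most `q_level`.
#'
#' @param pvalues numeric vector in (0,1].
#' @param q_level target FDR (default 0.05).
#' @return list with `qvalues` and logical `rejected`.
#' @export
bh_fdr <- function(pvalues, q_level = 0.05) {
  stopifnot(all(pvalues > 0 & pvalues <= 1), q_level > 0, q_level < 1)
  q <- stats::p.adjust(pvalues, method = "BH")
  list(qvalues = q, rejected = q <= q_level)
}

#' Apply phenome-wide inclusion rules to a phenotype catalog
#'
#' Filters a phenotype catalog the way a PheWAS quality-control flowchart
#' does, in a fixed rule order with per-rule exclusion counts:
#' duplicates first, then excluded categories, then availability of summary
#' statistics, then power thresholds — binary phenotypes need at least
#' `min_cases` cases and continuous/ordinal phenotypes at least `min_n`
#' samples (strict "less than" rules: boundary values are included).
#'
#' @param catalog data.frame with columns `pheno_id`, `value_type`
#'   (`binary` / `continuous` / `ordinal`), `n`, `n_cases`, `category`,
#'   and optionally `available` (logical) and `duplicate_of`.
#' @param exclusion_categories character vector of categories to drop
#'   (e.g. external causes, socioeconomic factors, lifestyle).
#' @param min_cases,min_n power thresholds (defaults 100 and 10,000).
#' @return The included rows; `attr(, "exclusion_counts")` holds the
#'   flowchart counts per rule.
#' @export
filter_phenotypes <- function(catalog, exclusion_categories = character(),
                              min_cases = 100, min_n = 10000) {
  stopifnot(is.data.frame(catalog), nrow(catalog) > 0)
  counts <- c(duplicate = 0L, excluded_category = 0L, unavailable = 0L,
              too_few_cases = 0L, sample_too_small = 0L)
  keep <- catalog

  if ("duplicate_of" %in% names(keep)) {
    dup <- !is.na(keep$duplicate_of) & keep$duplicate_of != ""
    counts["duplicate"] <- sum(dup)
    keep <- keep[!dup, , drop = FALSE]
  }
  drop_cat <- keep$category %in% exclusion_categories
  counts["excluded_category"] <- sum(drop_cat)
  keep <- keep[!drop_cat, , drop = FALSE]
  if ("available" %in% names(keep)) {
    unav <- !keep$available
    counts["unavailable"] <- sum(unav)
    keep <- keep[!unav, , drop = FALSE]
  }
  binary <- keep$value_type == "binary"
  few <- binary & (is.na(keep$n_cases) | keep$n_cases < min_cases)
  counts["too_few_cases"] <- sum(few)
  keep <- keep[!few, , drop = FALSE]
  small <- keep$value_type != "binary" & keep$n < min_n
  counts["sample_too_small"] <- sum(small)
  keep <- keep[!small, , drop = FALSE]

  message("filter_phenotypes: ", nrow(catalog), " -> ", nrow(keep),
          " phenotypes (",
          paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  rownames(keep) <- NULL
  attr(keep, "exclusion_counts") <- counts
  keep
}

#' Phenome-wide MR scan of one instrument
#'
#' Runs a single-instrument Wald-ratio (or multi-instrument IVW) MR of the
#' exposure against every phenotype in the phenome, converts binary
#' phenotypes analysed by linear regression to the log-odds scale, and
#' corrects the resulting p-values with BH-FDR across the whole scan.
#' All estimates are reported per SD *decrease* in the exposure (the
#' drug-mimicking convention), i.e. the per-SD-increase ratio is negated.
#'
#' @param instrument data.frame of exposure-scale instrument records (rows
#'   as returned by [select_instruments()] or [named_instruments()]).
#' @param phenome list of `summary_dataset` objects (one per phenotype).
#' @param catalog optional catalog data.frame with `pheno_id` and
#'   `category`, joined onto the results.
#' @param q_level FDR level (default 0.05).
#' @param per_sd_decrease negate estimates to the per-SD-decrease
#'   convention? Default `TRUE`.
#' @return data.frame with one row per scanned phenotype: `pheno_id`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `qvalue`, `significant`,
#'   `scale`, `n_snps`, `category`; skipped phenotypes (instrument absent)
#'   are listed in `attr(, "skipped")`.
#' @export
run_phewas <- function(instrument, phenome, catalog = NULL, q_level = 0.05,
                       per_sd_decrease = TRUE) {
  if (!length(phenome)) stop("run_phewas: empty phenome")
  stopifnot(is.data.frame(instrument), nrow(instrument) >= 1)
  np <- length(phenome)
  id <- character(np); beta <- se <- numeric(np)
  scale <- character(np); n_snps <- integer(np)
  ok <- logical(np)
  for (i in seq_len(np)) {
    ds <- phenome[[i]]
    id[i] <- ds$trait_id
    est <- phenome_estimate(instrument, ds)
    if (is.null(est)) next
    ok[i] <- TRUE
    beta[i] <- est$beta; se[i] <- est$se
    scale[i] <- est$scale; n_snps[i] <- est$n_snps
  }
  skipped <- id[!ok]
  if (!any(ok)) stop("run_phewas: instrument absent from every phenotype")
  if (per_sd_decrease) beta <- -beta
  zq <- stats::qnorm(0.975)
  res <- data.frame(pheno_id = id[ok], beta = beta[ok], se = se[ok],
                    ci_low = beta[ok] - zq * se[ok],
                    ci_high = beta[ok] + zq * se[ok],
                    pvalue = pmax(2 * stats::pnorm(-abs(beta[ok] / se[ok])),
                                  .Machine$double.xmin),
                    scale = scale[ok], n_snps = n_snps[ok])
  fdr <- bh_fdr(res$pvalue, q_level = q_level)
  res$qvalue <- fdr$qvalues
  res$significant <- fdr$rejected
  res$category <- if (!is.null(catalog))
    catalog$category[match(res$pheno_id, catalog$pheno_id)] else NA_character_
  if (length(skipped))
    message("run_phewas: skipped ", length(skipped),
            " phenotype(s) missing the instrument")
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

# Wald/IVW estimate of one exposure instrument set on one phenotype; NULL
# when no instrument variant is present. Returns a lean list(beta, se,
# scale, n_snps); run_phewas handles CIs, p-values and sign convention.
phenome_estimate <- function(instrument, ds) {
  rec <- ds$records
  idx <- match(instrument$variant_id, rec$variant_id)
  ok <- !is.na(idx)
  if (!any(ok)) return(NULL)
  beta_exp <- instrument$beta[ok]
  beta_out <- rec$beta[idx[ok]]
  se_out <- rec$se[idx[ok]]
  # align outcome rows whose allele coding is swapped relative to the
  # instrument's exposure coding
  flip <- rec$effect_allele[idx[ok]] == instrument$other_allele[ok] &
    rec$other_allele[idx[ok]] == instrument$effect_allele[ok]
  beta_out[flip] <- -beta_out[flip]
  if (ds$trait_type == "binary_linear") {
    mu <- ds$case_fraction
    if (is.null(mu)) return(NULL)
    d <- mu * (1 - mu)
    beta_out <- beta_out / d
    se_out <- se_out / d
    scale <- "log-odds"
  } else scale <- if (ds$trait_type == "binary_logistic") "log-odds" else "SD"
  rb <- beta_out / beta_exp
  rs <- se_out / abs(beta_exp)
  if (length(rb) == 1)
    return(list(beta = rb, se = rs, scale = scale, n_snps = 1L))
  est <- ivw(data.frame(beta = rb, se = rs), scale = scale)
  list(beta = est$beta, se = est$se, scale = scale, n_snps = est$n_snps)
}

#' Compare two strata of PheWAS or outcome results
#'
#' Two-sided z-test of the difference in estimates for every phenotype
#' present in both strata (e.g. women vs men, or one drug target vs
#' another). Unmatched phenotypes are dropped with a message.
#'
#' @param results_a,results_b data.frames with `pheno_id`, `beta`, `se`.
#' @param label comparison label stored in the output.
#' @return data.frame with `pheno_id`, `beta_a`, `beta_b`, `z`, `p_diff`,
#'   `comparison`.
#' @export
compare_strata <- function(results_a, results_b, label = "a_vs_b") {
  shared <- intersect(results_a$pheno_id, results_b$pheno_id)
  n_drop <- length(union(results_a$pheno_id, results_b$pheno_id)) -
    length(shared)
  if (n_drop > 0)
    message("compare_strata: dropped ", n_drop, " unmatched phenotype(s)")
  if (!length(shared)) {
    warning("compare_strata: no shared phenotypes")
    return(data.frame(pheno_id = character(), beta_a = numeric(),
                      beta_b = numeric(), z = numeric(), p_diff = numeric(),
                      comparison = character()))
  }
  a <- results_a[match(shared, results_a$pheno_id), ]
  b <- results_b[match(shared, results_b$pheno_id), ]
  z <- (a$beta - b$beta) / sqrt(a$se^2 + b$se^2)
  data.frame(pheno_id = shared, beta_a = a$beta, beta_b = b$beta, z = z,
             p_diff = 2 * stats::pnorm(-abs(z)), comparison = label)
}

#' Plot-ready Manhattan table for a PheWAS
#'
#' Columns `pheno_id`, `category`, `neg_log10_p`, `significant`, and
#' `direction` (`"+"`/`"-"` by the sign of the estimate), sorted by
#' category then ascending p so category blocks are contiguous.
#'
#' @param results output of [run_phewas()].
#' @return data.frame ready for a Manhattan-style plot.
#' @export
manhattan_table <- function(results) {
  stopifnot(nrow(results) > 0)
  out <- data.frame(pheno_id = results$pheno_id,
                    category = as.character(results$category),
                    neg_log10_p = -log10(results$pvalue),
                    significant = results$significant,
                    direction = ifelse(results$beta >= 0, "+", "-"))
  out <- out[order(out$category, results$pvalue), ]
  rownames(out) <- NULL
  out
}
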