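# ---- config-driven orchestration of the four study stages ---------------
#
# Stage 1: drug-target MR on all-cause mortality (lifespan), rescaled to
#          life-years; plain 0.05 significance.
# Stage 2: MR on the a priori outcome panel, BH-FDR within the panel
#          (per drug target and sex stratum).
# Stage 3: phenome-wide scan, BH-FDR within each scan.
# Stage 4: colocalization of the exposure with every outcome flagged
#          significant in stages 2-3, in the cis window.

#' Read a run configuration from JSON or YAML
#'
#' @param path configuration file; format chosen by extension
#'   (`.json` vs `.yml`/`.yaml`).
#' @return nested list, validated by [validate_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  validate_run_config(config)
}

#' @rdname read_run_config
#' @param config nested configuration list (see [run_study()]).
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config), length(config$drug_targets) >= 1)
  config$q_level <- config$q_level %||% 0.05
  stopifnot(config$q_level > 0, config$q_level < 1)
  config$seed <- config$seed %||% 1L
  paths <- character()
  for (tg in config$drug_targets)
    paths <- c(paths, tg$exposure$path, tg$ld_matrix_path)
  if (!is.null(config$mortality$path))
    paths <- c(paths, config$mortality$path)
  for (oc in config$apriori_outcomes)
    if (!is.null(oc$path)) paths <- c(paths, oc$path)
  if (!is.null(config$phenome)) paths <- c(paths, config$phenome$catalog_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("run config references missing file(s): ",
         paste(missing, collapse = ", "))
  config
}

load_outcome <- function(oc) {
  read_summary_stats(oc$path, column_map = oc$column_map,
                     trait_id = oc$trait_id %||% basename(oc$path),
                     trait_type = oc$trait_type %||% "quantitative",
                     sd_y = oc$sd_y, case_fraction = oc$case_fraction)
}

# Instrumented MR of one exposure on one outcome dataset, reported per SD
# decrease in the exposure. Returns NULL when no instrument variant (or
# proxy) is present in the outcome.
mr_for_outcome <- function(exposure, instruments, outcome, ld = NULL,
                           correlated = FALSE) {
  pair <- tryCatch(
    suppressMessages(harmonize(exposure, outcome, ld = ld)),
    error = function(e) NULL)
  if (is.null(pair)) return(NULL)
  keep <- pair$variant_ids %in% instruments$variant_id
  if (!any(keep)) return(NULL)
  e <- pair$exposure$records[keep, , drop = FALSE]
  o <- pair$outcome$records[keep, , drop = FALSE]
  beta_out <- o$beta; se_out <- o$se
  scale <- "SD"
  if (outcome$trait_type == "binary_linear") {
    mu <- outcome$case_fraction
    if (is.null(mu)) return(NULL)
    conv <- linear_to_logistic(beta_out, se_out, mu)
    beta_out <- conv$log_or; se_out <- conv$se_log_or
    scale <- "log-odds"
  } else if (outcome$trait_type == "binary_logistic") scale <- "log-odds"
  est <- if (correlated && nrow(e) > 1 && !is.null(ld)) {
    ids <- e$variant_id
    ivw_correlated(e$beta, beta_out, se_out, rho = ld[ids, ids, drop = FALSE],
                   scale = scale)
  } else if (nrow(e) == 1) {
    wald_ratio(e$beta, beta_out, se_out, scale = scale)
  } else {
    ivw(data.frame(beta = beta_out / e$beta, se = se_out / abs(e$beta)),
        scale = scale)
  }
  rescale(est, -1)   # per SD *decrease* in the exposure
}

estimate_row <- function(drug, outcome_id, stratum, est) {
  cbind(data.frame(drug = drug, outcome = outcome_id, stratum = stratum),
        as.data.frame(est))
}

#' Run the full drug-target MR study
#'
#' Executes the four stages in order for every configured drug target,
#' writes per-stage TSV tables (plus a JSON mirror of the report and the
#' config fingerprint) under `output_dir`, and checks outcome
#' conservation: every configured outcome lands in a result table or a
#' skip log. Any stage failure aborts with a stage-tagged error and leaves
#' a `FAILED_<stage>` marker file next to the partial outputs.
#'
#' Expected config structure (JSON/YAML or a nested list):
#' \preformatted{
#' drug_targets: [{name, exposure: {path, trait_id, sd_y?, column_map?},
#'                 snp_list? | region: {gene, chrom, start, end, flank?},
#'                 ld_matrix_path?, correlated?}]
#' mortality: {path, trait_id, rescale_factor (default 10),
#'             scale_label (default "life-years")}
#' apriori_outcomes: [{path, trait_id, trait_type, case_fraction?, sex?}]
#' phenome: {catalog_path, exclusion_categories?, targets?}
#' coloc: {p1, p2, p12, window_bp, sensitivity_p12?, region: {...}}
#' q_level, seed, exposure_scale
#' }
#' Phenome catalogs carry a `path` column pointing at per-phenotype
#' summary-statistics files.
#'
#' @param config configuration list or path to a JSON/YAML file.
#' @param output_dir directory for result tables (created if absent).
#' @return A `run_report`: list of per-stage tables, skip logs, the seed
#'   and a config fingerprint hash.
#' @export
run_study <- function(config, output_dir = "targetmr_results") {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on_fail <- function(e) {
    file.create(file.path(output_dir, paste0("FAILED_", stage)))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch(run_study_impl(config, output_dir,
                          set_stage = function(s) stage <<- s),
           error = on_fail)
}

run_study_impl <- function(config, output_dir, set_stage) {
  q_level <- config$q_level
  skip_log <- data.frame(stage = character(), drug = character(),
                         outcome = character(), reason = character())
  note_skip <- function(stage, drug, outcome, reason)
    skip_log <<- rbind(skip_log, data.frame(stage = stage, drug = drug,
                                            outcome = outcome, reason = reason))

  set_stage("instruments")
  targets <- list()
  for (tg in config$drug_targets) {
    exposure <- load_outcome(tg$exposure)
    ld <- if (!is.null(tg$ld_matrix_path)) read_ld_matrix(tg$ld_matrix_path)
    ins <- if (!is.null(tg$snp_list)) {
      named_instruments(exposure, unlist(tg$snp_list))
    } else {
      rg <- tg$region
      select_instruments(exposure,
                         gene_region(rg$gene, rg$chrom, rg$start, rg$end,
                                     flank = rg$flank %||% 1e6),
                         ld = ld)
    }
    if (nrow(ins) == 0) stop("no instruments for drug target ", tg$name)
    if (any(ins$weak))
      message("run_study: weak instrument(s) (F <= 10) for ", tg$name)
    targets[[tg$name]] <- list(name = tg$name, exposure = exposure,
                               instruments = ins, ld = ld,
                               correlated = isTRUE(tg$correlated))
  }

  # stage 1: all-cause mortality -------------------------------------------
  set_stage("mortality")
  mortality_tab <- NULL
  if (!is.null(config$mortality)) {
    oc <- config$mortality
    outcome <- load_outcome(oc)
    rows <- list()
    for (tg in targets) {
      est <- mr_for_outcome(tg$exposure, tg$instruments, outcome, ld = tg$ld,
                            correlated = tg$correlated)
      if (is.null(est)) {
        note_skip("mortality", tg$name, outcome$trait_id, "instrument_absent")
        next
      }
      est <- rescale(est, oc$rescale_factor %||% 10,
                     new_scale = oc$scale_label %||% "life-years")
      row <- estimate_row(tg$name, outcome$trait_id, "both", est)
      row$significant <- row$pvalue < 0.05
      rows[[tg$name]] <- row
    }
    mortality_tab <- do.call(rbind, rows)
  }

  # stage 2: a priori outcomes ---------------------------------------------
  set_stage("apriori")
  apriori_tab <- NULL
  if (length(config$apriori_outcomes)) {
    rows <- list()
    for (oc in config$apriori_outcomes) {
      outcome <- load_outcome(oc)
      stratum <- oc$sex %||% "both"
      for (tg in targets) {
        est <- mr_for_outcome(tg$exposure, tg$instruments, outcome,
                              ld = tg$ld, correlated = tg$correlated)
        if (is.null(est)) {
          note_skip("apriori", tg$name, outcome$trait_id, "instrument_absent")
          next
        }
        rows[[length(rows) + 1L]] <-
          estimate_row(tg$name, outcome$trait_id, stratum, est)
      }
    }
    apriori_tab <- do.call(rbind, rows)
    if (!is.null(apriori_tab)) {
      # FDR within each drug x stratum family of a priori outcomes
      apriori_tab$qvalue <- NA_real_
      apriori_tab$significant <- NA
      for (key in unique(paste(apriori_tab$drug, apriori_tab$stratum))) {
        idx <- paste(apriori_tab$drug, apriori_tab$stratum) == key
        fdr <- bh_fdr(apriori_tab$pvalue[idx], q_level = q_level)
        apriori_tab$qvalue[idx] <- fdr$qvalues
        apriori_tab$significant[idx] <- fdr$rejected
      }
    }
  }

  # cross-drug and sex-difference z-tests ----------------------------------
  set_stage("differences")
  drug_diff_tab <- NULL
  sex_diff_tab <- NULL
  if (!is.null(apriori_tab) && length(targets) > 1) {
    both <- apriori_tab[apriori_tab$stratum == "both", ]
    ref <- names(targets)[1]
    rows <- lapply(setdiff(names(targets), ref), function(other) {
      cmp <- compare_strata(
        stats::setNames(both[both$drug == ref,
                             c("outcome", "beta", "se")],
                        c("pheno_id", "beta", "se")),
        stats::setNames(both[both$drug == other,
                             c("outcome", "beta", "se")],
                        c("pheno_id", "beta", "se")),
        label = paste0(ref, "_vs_", other))
      cmp
    })
    drug_diff_tab <- do.call(rbind, rows)
  }
  if (!is.null(apriori_tab) &&
      all(c("female", "male") %in% apriori_tab$stratum)) {
    rows <- lapply(names(targets), function(drug) {
      f <- apriori_tab[apriori_tab$stratum == "female" &
                         apriori_tab$drug == drug, ]
      m <- apriori_tab[apriori_tab$stratum == "male" &
                         apriori_tab$drug == drug, ]
      if (!nrow(f) || !nrow(m)) return(NULL)
      cmp <- compare_strata(
        stats::setNames(f[, c("outcome", "beta", "se")],
                        c("pheno_id", "beta", "se")),
        stats::setNames(m[, c("outcome", "beta", "se")],
                        c("pheno_id", "beta", "se")),
        label = paste0(drug, "_female_vs_male"))
      cmp
    })
    sex_diff_tab <- do.call(rbind, rows)
  }

  # stage 3: PheWAS ---------------------------------------------------------
  set_stage("phewas")
  phewas_tab <- NULL
  phewas_catalog <- NULL
  if (!is.null(config$phenome)) {
    phewas_catalog <- utils::read.table(config$phenome$catalog_path,
                                        header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE)
    included <- filter_phenotypes(
      phewas_catalog,
      exclusion_categories = unlist(config$phenome$exclusion_categories)
      %||% character())
    scan_targets <- unlist(config$phenome$targets) %||% names(targets)[1]
    rows <- list()
    for (name in scan_targets) {
      tg <- targets[[name]]
      phenome <- lapply(seq_len(nrow(included)), function(i) {
        read_summary_stats(
          included$path[i], trait_id = included$pheno_id[i],
          trait_type = if (included$value_type[i] == "binary")
            "binary_linear" else "quantitative")
      })
      res <- run_phewas(tg$instruments, phenome, catalog = included,
                        q_level = q_level)
      for (sk in attr(res, "skipped"))
        note_skip("phewas", name, sk, "instrument_absent")
      rows[[name]] <- cbind(drug = name, res)
    }
    phewas_tab <- do.call(rbind, rows)
  }

  # stage 4: colocalization of significant outcomes -------------------------
  set_stage("coloc")
  coloc_tab <- NULL
  if (!is.null(config$coloc)) {
    cc <- config$coloc
    cfg <- coloc_config(p1 = cc$p1 %||% 1e-4, p2 = cc$p2 %||% 1e-4,
                        p12 = cc$p12 %||% 1e-5,
                        window_bp = cc$window_bp %||% 1e5)
    region <- if (!is.null(cc$region))
      gene_region(cc$region$gene, cc$region$chrom, cc$region$start,
                  cc$region$end, flank = cfg$window_bp)
    queue <- character()
    if (!is.null(mortality_tab))
      queue <- c(queue, mortality_tab$outcome[mortality_tab$significant])
    if (!is.null(apriori_tab)) {
      sig <- apriori_tab$significant & apriori_tab$stratum == "both"
      queue <- c(queue, apriori_tab$outcome[sig])
    }
    queue <- unique(queue)
    exposure <- targets[[1]]$exposure
    outcome_paths <- c(
      if (!is.null(config$mortality))
        stats::setNames(list(config$mortality),
                        config$mortality$trait_id %||%
                          basename(config$mortality$path)),
      stats::setNames(config$apriori_outcomes,
                      vapply(config$apriori_outcomes, function(oc)
                        oc$trait_id %||% basename(oc$path), character(1))))
    rows <- list()
    for (outcome_id in queue) {
      oc <- outcome_paths[[outcome_id]]
      if (is.null(oc)) next
      res <- tryCatch(
        suppressMessages(coloc_abf(exposure, load_outcome(oc),
                                   region = region, config = cfg)),
        error = function(e) NULL)
      if (is.null(res)) {
        note_skip("coloc", targets[[1]]$name, outcome_id, "no_overlap")
        next
      }
      rows[[outcome_id]] <- data.frame(
        outcome = outcome_id, n_variants = res$n_variants, t(res$pp),
        conditional_pp4 = res$conditional_pp4,
        top_shared_variant = res$top_shared_variant, p12 = cfg$p12)
      if (!is.null(cc$sensitivity_p12)) {
        sens <- coloc_sensitivity(exposure, load_outcome(oc),
                                  region = region, config = cfg,
                                  p12_grid = cc$sensitivity_p12)
        rows[[paste0(outcome_id, "_sens")]] <- data.frame(
          outcome = outcome_id, n_variants = res$n_variants,
          sens[, paste0("PP", 0:4)],
          conditional_pp4 = sens$conditional_pp4,
          top_shared_variant = res$top_shared_variant, p12 = sens$p12)
      }
    }
    coloc_tab <- do.call(rbind, rows)
    if (!is.null(coloc_tab)) rownames(coloc_tab) <- NULL
  }

  # report -------------------------------------------------------------------
  set_stage("report")
  tables <- list(mortality = mortality_tab, apriori = apriori_tab,
                 drug_differences = drug_diff_tab,
                 sex_differences = sex_diff_tab,
                 phewas = phewas_tab, coloc = coloc_tab,
                 skip_log = skip_log)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    utils::write.table(tables[[nm]],
                       file.path(output_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  config_json <- file.path(output_dir, "config.json")
  jsonlite::write_json(config, config_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  fingerprint <- unname(tools::md5sum(config_json))
  jsonlite::write_json(
    list(seed = config$seed, fingerprint = fingerprint,
         package_version = as.character(utils::packageVersion("targetmr"))),
    file.path(output_dir, "run_report.json"), auto_unbox = TRUE)

  report <- structure(c(tables, list(seed = config$seed,
                                     fingerprint = fingerprint,
                                     output_dir = output_dir)),
                      class = "run_report")
  check_outcome_conservation(config, report)
  report
}

# every configured outcome must appear in a result table or the skip log
check_outcome_conservation <- function(config, report) {
  configured <- vapply(config$apriori_outcomes, function(oc)
    oc$trait_id %||% basename(oc$path), character(1))
  if (!is.null(config$mortality))
    configured <- c(configured,
                    config$mortality$trait_id %||%
                      basename(config$mortality$path))
  seen <- c(report$mortality$outcome, report$apriori$outcome,
            report$skip_log$outcome)
  missing <- setdiff(configured, seen)
  if (length(missing))
    stop("outcome conservation violated; missing: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "-> ", x$output_dir, "\n")
  for (nm in c("mortality", "apriori", "phewas", "coloc"))
    if (!is.null(x[[nm]])) cat(" ", nm, ":", nrow(x[[nm]]), "rows\n")
  invisible(x)
}

#' Forest-plot-ready table of MR estimates
#'
#' Rows are outcome-by-drug estimates with CI bounds and p-values; rows on
#' the log-odds scale additionally carry `or`, `or_ci_low`, `or_ci_high`.
#' All rows must share one exposure convention (the `scale` labels encode
#' it); mixing conventions is an error.
#'
#' @param estimates data.frame with columns `drug`, `outcome`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pvalue`, `scale` (e.g. a [run_study()]
#'   stage table).
#' @param convention exposure-convention label stamped on the table.
#' @return data.frame ordered by outcome then drug.
#' @export
forest_table <- function(estimates, convention = "per SD decrease") {
  need <- c("drug", "outcome", "beta", "ci_low", "ci_high", "pvalue", "scale")
  stopifnot(all(need %in% names(estimates)))
  if (!is.null(attr(estimates, "convention")) &&
      !identical(attr(estimates, "convention"), convention))
    stop("forest_table: mixed exposure conventions")
  out <- estimates[order(estimates$outcome, estimates$drug), need]
  is_or <- out$scale == "log-odds"
  out$or <- ifelse(is_or, exp(out$beta), NA_real_)
  out$or_ci_low <- ifelse(is_or, exp(out$ci_low), NA_real_)
  out$or_ci_high <- ifelse(is_or, exp(out$ci_high), NA_real_)
  rownames(out) <- NULL
  attr(out, "convention") <- convention
  out
}
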