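# Canonical column order for summary-statistics tables.
SUMSTATS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pvalue",
                      "n", "n_cases")

#' Construct a summary-statistics dataset
#'
#' Bundles a table of per-variant marginal associations for one trait with
#' trait-level metadata. This is the unit every downstream stage (instrument
#' selection, MR, colocalization, PheWAS) consumes.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   and optionally `n_cases`. Missing metadata columns (`chrom`, `pos`,
#'   `eaf`, `pvalue`, `n`) are tolerated and filled with `NA`.
#' @param trait_id character scalar naming the trait.
#' @param trait_type one of `"quantitative"`, `"binary_linear"`,
#'   `"binary_logistic"`. Binary traits analysed on the linear scale
#'   (`binary_linear`) can later be converted to odds ratios with
#'   [linear_to_logistic()].
#' @param sd_y optional trait standard deviation (quantitative traits).
#' @param case_fraction optional case fraction mu in (0,1) for binary
#'   traits; derived from `n_cases / n` when absent.
#' @param validate reject records violating the invariants (se > 0, eaf in
#'   \[0,1\], distinct alleles, pvalue in (0,1\])? Default `TRUE`;
#'   the number rejected is stored in `attr(, "n_rejected")` and messaged.
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_id, trait_type = "quantitative",
                            sd_y = NULL, case_fraction = NULL,
                            validate = TRUE) {
  trait_type <- match.arg(trait_type,
                          c("quantitative", "binary_linear", "binary_logistic"))
  stopifnot(is.data.frame(records))
  for (col in setdiff(SUMSTATS_COLUMNS, names(records))) {
    if (col %in% c("variant_id", "effect_allele", "other_allele", "beta", "se"))
      stop("records is missing required column '", col, "'")
    records[[col]] <- NA
  }
  records <- records[, SUMSTATS_COLUMNS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.numeric(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))

  n_rejected <- 0L
  if (validate && nrow(records)) {
    ok <- valid_association_rows(records)
    n_rejected <- sum(!ok)
    if (n_rejected > 0)
      message("summary_dataset('", trait_id, "'): rejected ", n_rejected,
              " record(s) failing invariants")
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) == 0)
    stop("no valid association records for trait '", trait_id, "'")
  if (anyDuplicated(records$variant_id))
    stop("duplicate variant_ids in trait '", trait_id, "'")
  rownames(records) <- NULL

  if (is.null(case_fraction) && startsWith(trait_type, "binary") &&
      all(!is.na(records$n_cases)) && all(!is.na(records$n)))
    case_fraction <- stats::median(records$n_cases / records$n)

  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records,
         sd_y = sd_y, case_fraction = case_fraction),
    n_rejected = n_rejected, class = "summary_dataset")
}

# Row-wise invariant screen used at ingest. A pvalue wildly inconsistent with
# |beta/se| under a two-sided normal reference is also rejected (log10 slack
# of 1 absorbs rounding in published tables).
valid_association_rows <- function(records) {
  ok <- !is.na(records$beta) & !is.na(records$se) & records$se > 0 &
    records$effect_allele != records$other_allele &
    (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)) &
    (is.na(records$pvalue) | (records$pvalue > 0 & records$pvalue <= 1))
  p_imp <- 2 * stats::pnorm(-abs(records$beta / records$se))
  has_both <- ok & !is.na(records$pvalue) & p_imp > 0
  bad_p <- has_both &
    abs(log10(pmax(records$pvalue, 1e-300)) - log10(pmax(p_imp, 1e-300))) > 1
  ok & !bad_p
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("<summary_dataset> trait:", x$trait_id, "(", x$trait_type, "),",
      nrow(x$records), "variants\n")
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table (transparently gzip-compressed when
#' the path ends in `.gz`), renames columns via `column_map`, upper-cases
#' alleles, drops rows failing the record invariants (count messaged), and
#' returns a [summary_dataset()].
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (`variant_id`, `beta`, `se`, ...) to the file's column names; canonical
#'   names already present need not be mapped.
#' @param trait_id,trait_type,sd_y,case_fraction passed to [summary_dataset()].
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `summary_dataset`.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = basename(path),
                               trait_type = "quantitative", sd_y = NULL,
                               case_fraction = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  open_con <- function() if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  if (is.null(sep)) {
    con <- open_con(); header <- readLines(con, n = 1); close(con)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(open_con(), header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(tab))
    if (length(missing_src))
      stop("mapped column(s) not in file: ", paste(missing_src, collapse = ", "))
    idx <- match(unname(column_map), names(tab))
    names(tab)[idx] <- names(column_map)
  }
  req <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  if (length(miss <- setdiff(req, names(tab))))
    stop("required column(s) absent after mapping: ", paste(miss, collapse = ", "))
  summary_dataset(tab, trait_id = trait_id, trait_type = trait_type,
                  sd_y = sd_y, case_fraction = case_fraction)
}

#' Write summary statistics in the canonical column order
#'
#' @param dataset a `summary_dataset`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_summary_stats <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(dataset$records[, SUMSTATS_COLUMNS], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an LD correlation matrix
#'
#' LD matrices are square tab-delimited tables of signed correlations with a
#' variant-ID header row and column. [validate_ld_matrix()] enforces symmetry,
#' unit diagonal, |r| <= 1 and positive semi-definiteness (within tolerance).
#'
#' @param path file path.
#' @return A square numeric matrix with variant-ID dimnames.
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  r <- as.matrix(tab)
  validate_ld_matrix(r)
  r
}

#' @rdname read_ld_matrix
#' @param r square correlation matrix with variant-ID dimnames.
#' @export
write_ld_matrix <- function(r, path) {
  validate_ld_matrix(r)
  tab <- data.frame(variant_id = rownames(r), r, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ld_matrix
#' @param tol numerical tolerance for symmetry and the smallest eigenvalue.
#' @export
validate_ld_matrix <- function(r, tol = 1e-8) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    stop("LD matrix needs identical variant-ID row and column names")
  if (max(abs(r - t(r))) > tol) stop("LD matrix not symmetric")
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + tol) stop("LD correlations must satisfy |r| <= 1")
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
    stop("LD matrix not positive semi-definite")
  invisible(r)
}

#' Find an LD proxy for a missing variant
#'
#' Returns the available variant in highest LD with the target, requiring
#' r^2 above `r2_min` (the conventional proxy threshold is r^2 > 0.8). Ties
#' are broken by smaller genomic distance (when `positions` are supplied),
#' then lexicographically by ID. The caller must negate the proxy's effect
#' when the returned `r` is negative.
#'
#' @param variant_id target variant (must be a row of `ld`).
#' @param ld signed LD correlation matrix.
#' @param available variant IDs present in the outcome dataset.
#' @param r2_min minimum r-squared, exclusive.
#' @param positions optional named vector of basepair positions for distance
#'   tie-breaking.
#' @return `list(proxy_id, r, sign_flipped)` or `NULL` when no candidate
#'   exceeds the threshold.
#' @export
find_proxy <- function(variant_id, ld, available, r2_min = 0.8,
                       positions = NULL) {
  if (!variant_id %in% rownames(ld))
    stop("variant ", variant_id, " not in LD matrix")
  cand <- intersect(setdiff(available, variant_id), rownames(ld))
  if (!length(cand)) return(NULL)
  r <- ld[variant_id, cand]
  r2 <- r^2
  keep <- r2 > r2_min
  if (!any(keep)) return(NULL)
  cand <- cand[keep]; r <- r[keep]; r2 <- r2[keep]
  dist <- if (!is.null(positions) && variant_id %in% names(positions))
    abs(positions[cand] - positions[variant_id]) else rep(0, length(cand))
  dist[is.na(dist)] <- Inf
  ord <- order(-r2, dist, cand)
  best <- ord[1]
  list(proxy_id = cand[best], r = unname(r[best]),
       sign_flipped = unname(r[best] < 0))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome dataset to the exposure's effect alleles, variant by
#' variant (matched on rsID). Swapped allele codings negate the outcome beta
#' and reflect the EAF; strand flips are resolved by complementing alleles
#' before the swap test; incompatible allele pairs are dropped with a reason.
#' Palindromic (A/T, C/G) variants are handled per `palindrome_policy`:
#' `"frequency"` aligns by allele frequency but drops variants whose minor
#' allele frequency exceeds `ambiguity_maf` in either dataset (frequency can
#' no longer identify the strand); `"drop"` removes all palindromic variants.
#' Exposure variants absent from the outcome are replaced by LD proxies
#' (r^2 > `r2_proxy`) when an LD matrix is supplied.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param ld optional signed LD matrix used for proxy search.
#' @param palindrome_policy `"frequency"` (default) or `"drop"`.
#' @param ambiguity_maf MAF above which frequency alignment is ambiguous.
#' @param r2_proxy minimum proxy r-squared.
#' @return A `harmonized_pair`: list with aligned `exposure` and `outcome`
#'   record tables (same variants, same effect alleles), a `proxy_log`
#'   data.frame and a `dropped` data.frame of (variant, reason).
#' @export
harmonize <- function(exposure, outcome, ld = NULL,
                      palindrome_policy = c("frequency", "drop"),
                      ambiguity_maf = 0.42, r2_proxy = 0.8) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  palindrome_policy <- match.arg(palindrome_policy)
  exp_rec <- exposure$records
  out_rec <- outcome$records
  rownames(out_rec) <- out_rec$variant_id

  proxy_log <- data.frame(requested = character(), proxy = character(),
                          r = numeric(), sign_flipped = logical())
  dropped <- data.frame(variant_id = character(), reason = character())
  drop_it <- function(v, why)
    dropped <<- rbind(dropped, data.frame(variant_id = v, reason = why))

  exp_keep <- list(); out_keep <- list()
  positions <- stats::setNames(exp_rec$pos, exp_rec$variant_id)

  for (i in seq_len(nrow(exp_rec))) {
    e <- exp_rec[i, ]
    o_id <- e$variant_id
    if (!o_id %in% out_rec$variant_id) {
      if (is.null(ld) || !e$variant_id %in% rownames(ld)) {
        drop_it(e$variant_id, "absent_from_outcome"); next
      }
      px <- find_proxy(e$variant_id, ld, available = out_rec$variant_id,
                       r2_min = r2_proxy, positions = positions)
      if (is.null(px)) { drop_it(e$variant_id, "no_proxy"); next }
      o <- out_rec[px$proxy_id, ]
      # express the proxy's effect on the scale of the requested variant:
      # a negative LD sign means the proxy's effect allele tags the other
      # allele of the target, so the beta flips
      if (px$sign_flipped) {
        o$beta <- -o$beta
        o$eaf <- 1 - o$eaf
      }
      o$variant_id <- e$variant_id
      o$effect_allele <- e$effect_allele
      o$other_allele <- e$other_allele
      proxy_log <- rbind(proxy_log,
                         data.frame(requested = e$variant_id,
                                    proxy = px$proxy_id, r = px$r,
                                    sign_flipped = px$sign_flipped))
      exp_keep[[length(exp_keep) + 1L]] <- e
      out_keep[[length(out_keep) + 1L]] <- o
      next
    }
    o <- out_rec[o_id, ]
    al <- align_alleles(e$effect_allele, e$other_allele,
                        o$effect_allele, o$other_allele)
    if (is.null(al)) { drop_it(e$variant_id, "allele_mismatch"); next }
    if (is_palindromic(e$effect_allele, e$other_allele)) {
      if (palindrome_policy == "drop") {
        drop_it(e$variant_id, "palindromic"); next
      }
      mafs <- c(min(e$eaf, 1 - e$eaf), min(o$eaf, 1 - o$eaf))
      if (any(is.na(mafs)) || any(mafs > ambiguity_maf)) {
        drop_it(e$variant_id, "palindromic_ambiguous"); next
      }
      # strand is unidentifiable from alleles; align by frequency instead:
      # the effect allele is on the same strand iff the EAFs agree in rarity
      swap <- (e$eaf < 0.5) != (o$eaf < 0.5)
    } else {
      swap <- al$swap
    }
    if (swap) {
      o$beta <- -o$beta
      o$eaf <- 1 - o$eaf
    }
    o$effect_allele <- e$effect_allele
    o$other_allele <- e$other_allele
    exp_keep[[length(exp_keep) + 1L]] <- e
    out_keep[[length(out_keep) + 1L]] <- o
  }

  if (!length(exp_keep))
    stop("harmonize: no shared variants between '", exposure$trait_id,
         "' and '", outcome$trait_id, "'")
  if (nrow(dropped))
    message("harmonize: dropped ", nrow(dropped), " variant(s) (",
            paste(unique(dropped$reason), collapse = ", "), ")")

  exp2 <- exposure; out2 <- outcome
  exp2$records <- do.call(rbind, exp_keep); rownames(exp2$records) <- NULL
  out2$records <- do.call(rbind, out_keep); rownames(out2$records) <- NULL
  structure(list(exposure = exp2, outcome = out2,
                 variant_ids = exp2$records$variant_id,
                 proxy_log = proxy_log, dropped = dropped),
            class = "harmonized_pair")
}

# Classify an outcome allele pair relative to the exposure's: identical,
# swapped, or either after strand complementation. NULL = irreconcilable.
# Indels (multi-base or non-ACGT codes) are matched by exact string only.
align_alleles <- function(e_ea, e_oa, o_ea, o_oa) {
  if (o_ea == e_ea && o_oa == e_oa) return(list(swap = FALSE))
  if (o_ea == e_oa && o_oa == e_ea) return(list(swap = TRUE))
  simple <- all(c(e_ea, e_oa, o_ea, o_oa) %in% c("A", "C", "G", "T"))
  if (simple) {
    f_ea <- complement_allele(o_ea); f_oa <- complement_allele(o_oa)
    if (f_ea == e_ea && f_oa == e_oa) return(list(swap = FALSE))
    if (f_ea == e_oa && f_oa == e_ea) return(list(swap = TRUE))
  }
  NULL
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("<harmonized_pair>", x$exposure$trait_id, "->", x$outcome$trait_id,
      ":", length(x$variant_ids), "variants,",
      nrow(x$proxy_log), "proxied,", nrow(x$dropped), "dropped\n")
  invisible(x)
}
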