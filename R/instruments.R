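#' Define a cis gene region
#'
#' Coordinates are 1-based inclusive; the flank (default 1 Mb, the usual
#' cis window for drug-target instrument selection) extends the gene body
#' on both sides. The genome build label is carried as opaque metadata.
#'
#' @param gene gene symbol.
#' @param chrom chromosome label (character, matched as-is).
#' @param start,end gene body bounds in basepairs.
#' @param flank flanking distance in basepairs.
#' @param build optional build label (metadata only; no liftover).
#' @return An object of class `gene_region`.
#' @export
gene_region <- function(gene, chrom, start, end, flank = 1e6, build = NULL) {
  stopifnot(start <= end, flank >= 0)
  structure(list(gene = gene, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 flank = as.numeric(flank), build = build),
            class = "gene_region")
}

in_region <- function(chrom, pos, region) {
  !is.na(pos) & chrom == region$chrom &
    pos >= region$start - region$flank & pos <= region$end + region$flank
}

#' Instrument-strength F-statistic
#'
#' Approximates the per-SNP F-statistic as the square of the SNP-exposure
#' association divided by the square of its standard error. Values of 10 or
#' less flag a weak instrument.
#'
#' @param beta,se SNP-exposure association and its standard error (vectors).
#' @return data.frame with columns `f_stat` and `weak`.
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  f <- (beta / se)^2
  data.frame(f_stat = f, weak = f <= 10)
}

#' Select cis instruments by significance, frequency and LD clumping
#'
#' Restricts exposure associations to the gene region (+/- flank), keeps
#' common (MAF > `maf_min`) genome-wide-significant (p < `p_max`) variants,
#' and greedily clumps them: candidates are ranked by ascending p-value
#' (ties by |beta|/se descending, then variant ID) and a candidate is
#' retained only if its r-squared with every previously retained variant is
#' below `r2_clump`. The defaults reproduce the conventional rule set:
#' MAF > 1%, p < 5e-8, r^2 < 0.001 within +/- 1 Mb of the target gene.
#'
#' @param exposure `summary_dataset` of SNP-exposure associations.
#' @param region a [gene_region()].
#' @param ld signed LD matrix covering the candidates; candidates missing
#'   from it are dropped with a message.
#' @param maf_min,p_max,r2_clump selection thresholds (all strict).
#' @return data.frame of retained instrument records with `f_stat` and
#'   `weak` columns appended; zero rows (with a warning) when nothing
#'   survives the filters.
#' @export
select_instruments <- function(exposure, region, ld, maf_min = 0.01,
                               p_max = 5e-8, r2_clump = 0.001) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(region, "gene_region"))
  rec <- exposure$records
  rec <- rec[in_region(rec$chrom, rec$pos, region), , drop = FALSE]
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  rec <- rec[!is.na(maf) & maf > maf_min & !is.na(rec$pvalue) &
               rec$pvalue < p_max, , drop = FALSE]
  if (nrow(rec) == 0) {
    warning("select_instruments: no candidates pass the filters in region ",
            region$gene)
    return(cbind(rec, f_stat = numeric(0), weak = logical(0)))
  }
  missing_ld <- setdiff(rec$variant_id, rownames(ld))
  if (length(missing_ld)) {
    message("select_instruments: ", length(missing_ld),
            " candidate(s) absent from LD matrix, dropped")
    rec <- rec[!rec$variant_id %in% missing_ld, , drop = FALSE]
  }
  if (nrow(rec) == 0) {
    warning("select_instruments: no candidates covered by the LD matrix")
    return(cbind(rec, f_stat = numeric(0), weak = logical(0)))
  }
  ord <- order(rec$pvalue, -abs(rec$beta) / rec$se, rec$variant_id)
  rec <- rec[ord, , drop = FALSE]
  kept <- character()
  for (v in rec$variant_id) {
    if (all(ld[v, kept]^2 < r2_clump)) kept <- c(kept, v)
  }
  out <- rec[rec$variant_id %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  cbind(out, f_statistic(out$beta, out$se))
}

#' Extract a named SNP instrument list from a dataset
#'
#' Mirrors the use of published instrument sets: instead of de novo
#' selection, pull the named variants from the exposure dataset (with an
#' error for any that are absent) and screen their strength.
#'
#' @param exposure `summary_dataset`.
#' @param snp_list character vector of variant IDs.
#' @return data.frame of instrument records with `f_stat`, `weak` appended.
#' @export
named_instruments <- function(exposure, snp_list) {
  rec <- exposure$records
  miss <- setdiff(snp_list, rec$variant_id)
  if (length(miss))
    stop("named instrument(s) absent from exposure: ",
         paste(miss, collapse = ", "))
  out <- rec[match(snp_list, rec$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  cbind(out, f_statistic(out$beta, out$se))
}
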