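# Per-sample consumer fraction (f_sidero) from classified metagenomic
# read counts: length-normalize counts within each gene family, then take
# total receptor abundance over the median single-copy core-gene abundance.

#' Length-normalize a gene-count table
#'
#' Each gene's count is rescaled by (median family length) / (gene length),
#' with medians computed within role and family across the reference genes,
#' so that genes of different length contribute comparably.
#'
#' @param counts sample x gene numeric matrix with column names matching
#'   `gene_meta$gene_id` (a single sample may be given as a named vector).
#' @param gene_meta data frame with `gene_id`, `length_nt`, `role`
#'   (`"receptor"` or `"core"`) and optionally `family` (defaults to one
#'   family per role).
#' @param family_median use per-family median lengths (default); `FALSE`
#'   uses a single global median per role.
#' @return normalized matrix of the same shape.
#' @export
length_normalize <- function(counts, gene_meta, family_median = TRUE) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1,
                     dimnames = list("sample1", names(counts)))
  }
  idx <- match(colnames(counts), gene_meta$gene_id)
  if (anyNA(idx)) {
    abort("no metadata for gene(s): %s",
          paste(colnames(counts)[is.na(idx)], collapse = ", "))
  }
  meta <- gene_meta[idx, , drop = FALSE]
  if (any(!is.finite(meta$length_nt) | meta$length_nt <= 0)) {
    bad <- meta$gene_id[!is.finite(meta$length_nt) | meta$length_nt <= 0]
    abort("missing or nonpositive length for gene(s): %s",
          paste(bad, collapse = ", "))
  }
  grp <- if (family_median && !is.null(meta$family)) {
    paste(meta$role, meta$family)
  } else {
    meta$role
  }
  med <- stats::ave(meta$length_nt, grp, FUN = stats::median)
  sweep(counts, 2, med / meta$length_nt, `*`)
}

#' Per-sample consumer trait fraction (f_sidero)
#'
#' For each sample: `median_core` is the median of normalized single-copy
#' core-gene counts, and `f_sidero` is the summed normalized receptor count
#' divided by `median_core`. Samples with `median_core < qc_min` fail QC
#' (the statistic is still reported, flagged). Receptor counts are summed
#' over receptor variants rather than resolved to clades. Values above
#' `flag_above` are flagged as anomalous but never clipped.
#'
#' @inheritParams length_normalize
#' @param qc_min minimum median core coverage for a sample to pass QC.
#' @param flag_above f_sidero above this value sets `anomalous = TRUE`.
#' @return data frame with `sample_id`, `f_sidero`, `median_core`,
#'   `qc_pass`, `anomalous`.
#' @export
#' @examples
#' sim <- simulate_metagenome(metagenome_sim_spec(4, true_fraction = 0.3,
#'                                                seed = 2))
#' trait_fraction(sim$counts, sim$gene_meta)
trait_fraction <- function(counts, gene_meta, family_median = TRUE,
                           qc_min = 100, flag_above = 1.2) {
  norm <- length_normalize(counts, gene_meta, family_median)
  meta <- gene_meta[match(colnames(norm), gene_meta$gene_id), , drop = FALSE]
  core <- meta$role == "core"
  rec <- meta$role == "receptor"
  if (!any(core)) abort("no core genes in the table")
  med_core <- apply(norm[, core, drop = FALSE], 1, stats::median)
  rec_sum <- if (any(rec)) rowSums(norm[, rec, drop = FALSE]) else
    rep(0, nrow(norm))
  f <- ifelse(med_core > 0, rec_sum / med_core, NA_real_)
  data.frame(sample_id = rownames(norm) %||% sprintf("sample%03d", seq_len(nrow(norm))),
             f_sidero = f,
             median_core = med_core,
             qc_pass = !is.na(f) & med_core >= qc_min,
             anomalous = !is.na(f) & f > flag_above,
             stringsAsFactors = FALSE, row.names = NULL)
}
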