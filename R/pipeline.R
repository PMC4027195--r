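#' Paired differential-signature pipeline
#'
#' The end-to-end matched-cohort analysis: optionally quantile-normalize the
#' two expression matrices within the cohort, fit one interaction signature
#' per sample, and run paired t tests on (a) the seed-matched interaction
#' probabilities, (b) gene expression and (c) miRNA expression, each
#' BH-adjusted. Optionally applies the sign-coherence filter
#' ([coherent_filter()]).
#'
#' @param mrna,mirna expression matrices (features x samples) covering all
#'   manifest samples.
#' @param seeds a [seed_matrix()] aligned to the two feature spaces (use
#'   [align_profiles()] first if needed).
#' @param pairs data.frame with columns `pair`, `sample_normal`,
#'   `sample_tumor` (see [read_manifest()]).
#' @param config [model_config()] for the per-sample fits.
#' @param model which probability matrix carries the signature
#'   (default `"mrna"`).
#' @param normalize quantile-normalize within the cohort first
#'   (default TRUE).
#' @param fdr_interaction,fdr_gene,fdr_mirna cutoffs for the coherence filter.
#' @param coherent apply the filter (default TRUE).
#' @return list with `diff_interactions`, `diff_genes`, `diff_mirnas`,
#'   `filtered` (NULL unless `coherent`), and `signatures` (per-sample list).
#' @export
run_differential <- function(mrna, mirna, seeds, pairs,
                             config = model_config(), model = "mrna",
                             normalize = TRUE, fdr_interaction = 0.05,
                             fdr_gene = 0.05, fdr_mirna = 0.05,
                             coherent = TRUE) {
  stopifnot(is_seed_matrix(seeds))
  samples <- c(pairs$sample_normal, pairs$sample_tumor)
  if (!all(samples %in% colnames(mrna)) || !all(samples %in% colnames(mirna)))
    stop("manifest samples missing from the expression matrices")
  if (normalize) {
    mrna <- quantile_normalize(mrna)
    mirna <- quantile_normalize(mirna)
  }
  sigs <- lapply(stats::setNames(samples, samples), function(s)
    infer_signature(mrna[rownames(seeds), s], mirna[colnames(seeds), s],
                    seeds, config))
  sig_mat <- stack_signatures(sigs, seeds, model = model)
  di <- paired_diff_table(sig_mat[, pairs$sample_normal, drop = FALSE],
                          sig_mat[, pairs$sample_tumor, drop = FALSE],
                          type = "probability")
  dg <- paired_diff_table(mrna[rownames(seeds), pairs$sample_normal, drop = FALSE],
                          mrna[rownames(seeds), pairs$sample_tumor, drop = FALSE],
                          type = "expression")
  dm <- paired_diff_table(mirna[colnames(seeds), pairs$sample_normal, drop = FALSE],
                          mirna[colnames(seeds), pairs$sample_tumor, drop = FALSE],
                          type = "expression")
  filtered <- if (coherent)
    coherent_filter(di, dg, dm, fdr_interaction, fdr_gene, fdr_mirna)
  list(diff_interactions = di, diff_genes = dg, diff_mirnas = dm,
       filtered = filtered, signatures = sigs)
}
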