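#' Paired t statistics, feature by feature
#'
#' For matched normal/tumor value matrices (features x pairs, column j of one
#' matched to column j of the other), computes per feature the paired t
#' statistic on the tumor-minus-normal differences, `t = mean(d) / (sd(d) /
#' sqrt(n))` with `df = n - 1` and a two-sided Student p-value - exactly the
#' classical paired t-test, vectorised over features. Features whose
#' differences have zero variance get an NaN statistic, are flagged and are
#' excluded from the FDR adjustment.
#'
#' @param normal,tumor numeric matrices with identical dimensions and row
#'   names; columns are matched pairs (n >= 2).
#' @param type `"expression"` computes a log2 fold-change with `pseudocount`;
#'   `"probability"` reports the difference of means instead (probabilities
#'   near 0 make ratios unstable) and leaves `log2_fc` NA when either mean
#'   is 0.
#' @param pseudocount added to both means for the expression fold-change
#'   (default 1).
#' @return data.frame with one row per feature: `feature`, `mean_normal`,
#'   `mean_tumor`, `delta_mean`, `log2_fc`, `t`, `df`, `p_value`, `fdr`,
#'   `zero_variance`.
#' @export
paired_diff_table <- function(normal, tumor,
                              type = c("expression", "probability"),
                              pseudocount = 1) {
  type <- match.arg(type)
  if (!identical(dim(normal), dim(tumor)) ||
      !identical(rownames(normal), rownames(tumor)))
    stop("normal and tumor matrices must have identical shape and row names")
  n <- ncol(normal)
  if (n < 2L) stop("need at least 2 matched pairs")
  d <- tumor - normal
  md <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - md)^2) / (n - 1L))
  zero_var <- sd_d == 0
  t_stat <- ifelse(zero_var, NaN, md / (sd_d / sqrt(n)))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  mn <- rowMeans(normal)
  mt <- rowMeans(tumor)
  l2fc <- if (type == "expression")
    log2((mt + pseudocount) / (mn + pseudocount))
  else
    ifelse(mn > 0 & mt > 0, log2(mt / mn), NA_real_)
  data.frame(feature = rownames(normal), mean_normal = mn, mean_tumor = mt,
             delta_mean = mt - mn, log2_fc = l2fc, t = t_stat,
             df = n - 1L, p_value = p, fdr = bh_fdr(p),
             zero_variance = zero_var, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; `NA` p-values (e.g. from
#' zero-variance features) are left `NA` and do not count towards the number
#' of tests.
#'
#' @param p vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted values, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Stack per-sample signatures into an interaction matrix
#'
#' Turns a list of fitted signatures (one per sample, all on the same seed
#' matrix) into a matrix of seed-matched interactions x samples, with row
#' names `gene|mirna`, ready for [paired_diff_table()].
#'
#' @param sigs named list of `"mmi_signature"` objects (names = sample ids).
#' @param seeds the common [seed_matrix()].
#' @param model which probability matrix to stack (default `"mrna"`, the
#'   representative model).
#' @return numeric matrix, interactions x samples.
#' @export
stack_signatures <- function(sigs, seeds, model = "mrna") {
  stopifnot(is_seed_matrix(seeds), length(sigs) >= 1L)
  idx <- which(as_plain_matrix(seeds) > 0L)
  keys <- paste(rownames(seeds)[row(seeds)[idx]],
                colnames(seeds)[col(seeds)[idx]], sep = "|")
  out <- vapply(sigs, function(s) signature_matrix(s, model)[idx],
                numeric(length(idx)))
  rownames(out) <- keys
  out
}

#' Sign-coherence filter for tumor-specific interactions
#'
#' Restricts differential interactions to those whose expression context is
#' mechanistically coherent: (i) the interaction, its gene and its miRNA must
#' all be significant at their FDR cutoffs; (ii) the interaction change must
#' have the same sign as the miRNA expression change (more miRNA, more
#' targeting); (iii) the interaction and miRNA change must be opposite in
#' sign to the gene expression change (effective targeting depletes the
#' target). Signs are taken from the paired t statistics. The filter screens
#' out interaction changes that merely echo a co-directional drift of both
#' expression profiles.
#'
#' @param diff_interactions [paired_diff_table()] output whose `feature` is
#'   `gene|mirna`.
#' @param diff_genes,diff_mirnas [paired_diff_table()] outputs keyed by gene
#'   and miRNA id.
#' @param fdr_interaction,fdr_gene,fdr_mirna per-table FDR cutoffs
#'   (default 0.05 each).
#' @return The qualifying rows of `diff_interactions`, with `gene`, `mirna`,
#'   `t_gene` and `t_mirna` columns added.
#' @export
coherent_filter <- function(diff_interactions, diff_genes, diff_mirnas,
                            fdr_interaction = 0.05, fdr_gene = 0.05,
                            fdr_mirna = 0.05) {
  key <- strsplit(diff_interactions$feature, "|", fixed = TRUE)
  if (any(lengths(key) != 2L))
    stop("interaction features must be 'gene|mirna'")
  gene <- vapply(key, `[[`, "", 1L)
  mirna <- vapply(key, `[[`, "", 2L)
  gi <- match(gene, diff_genes$feature)
  mi <- match(mirna, diff_mirnas$feature)
  if (anyNA(gi) || anyNA(mi))
    stop("every interaction must have a gene and miRNA differential row")
  t_int <- diff_interactions$t
  t_gene <- diff_genes$t[gi]
  t_mir <- diff_mirnas$t[mi]
  ok <- !is.na(diff_interactions$fdr) & diff_interactions$fdr <= fdr_interaction &
    !is.na(diff_genes$fdr[gi]) & diff_genes$fdr[gi] <= fdr_gene &
    !is.na(diff_mirnas$fdr[mi]) & diff_mirnas$fdr[mi] <= fdr_mirna &
    sign(t_int) == sign(t_mir) & sign(t_int) == -sign(t_gene) &
    t_int != 0 & t_gene != 0 & t_mir != 0
  ok[is.na(ok)] <- FALSE
  out <- diff_interactions[ok, , drop = FALSE]
  out$gene <- gene[ok]
  out$mirna <- mirna[ok]
  out$t_gene <- t_gene[ok]
  out$t_mirna <- t_mir[ok]
  out$fdr_gene <- diff_genes$fdr[gi][ok]
  out$fdr_mirna <- diff_mirnas$fdr[mi][ok]
  rownames(out) <- NULL
  out
}

#' Average a signature over miRNAs, per gene
#'
#' The per-gene summary used for gene-set analyses: the row mean of the
#' chosen probability matrix over all M miRNA columns, zeros (no-seed pairs)
#' included, so it measures the gene's overall load of predicted targeting.
#'
#' @param sig an `"mmi_signature"`.
#' @param model which matrix to average (default `"mrna"`).
#' @return Named numeric vector, one value per gene.
#' @export
average_signature_per_gene <- function(sig, model = "mrna") {
  rowMeans(signature_matrix(sig, model))
}

#' Export a filtered interaction set as a network edge table
#'
#' Writes a TSV loadable as a Cytoscape edge-attribute table: one row per
#' interaction with the paired t statistics and FDRs of the interaction and
#' its two endpoints.
#'
#' @param filtered output of [coherent_filter()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_edge_table <- function(filtered, path) {
  if (nrow(filtered) == 0L) stop("no interactions to export")
  cols <- c("gene", "mirna", "t", "fdr", "t_gene", "fdr_gene",
            "t_mirna", "fdr_mirna")
  tab <- filtered[, cols]
  names(tab)[names(tab) == "t"] <- "t_interaction"
  names(tab)[names(tab) == "fdr"] <- "fdr_interaction"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export gene scores as a .rnk file
#'
#' Two-column gene/score TSV sorted by descending score (ties broken by gene
#' id), the input format of preranked gene-set enrichment tools.
#'
#' @param scores named numeric vector (names = gene ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_rnk <- function(scores, path) {
  if (is.null(names(scores)) || nrow(tab <- data.frame(
    gene = names(scores), score = as.numeric(scores))) == 0L)
    stop("`scores` must be a non-empty named vector")
  tab <- tab[order(-tab$score, tab$gene, method = "radix"), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
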