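#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' per-rank means of the input columns. Tied values within a column all
#' receive the mean of the reference values at their tied ranks, so the
#' mapping is deterministic and rank order is preserved up to ties. This is
#' how RPKM/RPM matrices are made comparable across samples within a cohort
#' before signatures are inferred.
#'
#' mRNA and miRNA matrices are different platforms on different scales and
#' should be normalized separately.
#'
#' @param mat numeric matrix, features x samples, nonnegative and finite,
#'   with at least 2 columns.
#' @return A matrix of the same shape and dimnames; every column has the
#'   identical sorted multiset of values (exactly, when there are no ties).
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(8, 4, 6))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("`mat` must be a numeric matrix")
  if (ncol(mat) < 2L)
    stop("quantile normalization needs >= 2 samples; nothing to normalize against")
  if (any(!is.finite(mat))) stop("expression values must be finite (no NA/NaN)")
  if (any(mat < 0)) stop("expression values must be nonnegative")
  ref <- rowMeans(apply(mat, 2L, sort, method = "radix"))
  out <- apply(mat, 2L, function(x) {
    v <- ref[rank(x, ties.method = "first")]
    # tie groups (equal input values) share the mean of their reference values
    stats::ave(v, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Align expression matrices with a seed-match matrix
#'
#' Inner-joins the gene identifiers of the mRNA matrix and the miRNA
#' identifiers of the miRNA matrix with the seed-match matrix, and the sample
#' identifiers of the two expression matrices with each other. The returned
#' system is in the seed matrix's canonical (lexicographic) order; counts of
#' dropped features are reported via `message()`.
#'
#' @param mrna,mirna numeric matrices, features x samples, with feature ids as
#'   row names and sample ids as column names.
#' @param C a [seed_matrix()].
#' @return A list with elements `mrna`, `mirna` (matrices over the shared
#'   samples) and `seeds` (the subsetted [seed_matrix()]).
#' @export
align_profiles <- function(mrna, mirna, C) {
  stopifnot(is_seed_matrix(C))
  for (m in list(mrna, mirna))
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("expression matrices need feature row names and sample column names")
  samples <- intersect(colnames(mrna), colnames(mirna))
  if (!length(samples))
    stop("no shared sample ids between the mRNA and miRNA matrices")
  genes <- rownames(C)[rownames(C) %in% rownames(mrna)]
  mirnas <- colnames(C)[colnames(C) %in% rownames(mirna)]
  if (!length(genes))
    stop("no gene ids shared with the seed matrix (e.g. expression has '",
         rownames(mrna)[1L], "', seeds have '", rownames(C)[1L], "')")
  if (!length(mirnas))
    stop("no miRNA ids shared with the seed matrix (e.g. expression has '",
         rownames(mirna)[1L], "', seeds have '", colnames(C)[1L], "')")
  message(sprintf(
    "aligned %d genes (%d dropped from seeds, %d from expression), %d miRNAs (%d/%d dropped), %d samples",
    length(genes), nrow(C) - length(genes), nrow(mrna) - length(genes),
    length(mirnas), ncol(C) - length(mirnas), nrow(mirna) - length(mirnas),
    length(samples)))
  list(mrna = mrna[genes, samples, drop = FALSE],
       mirna = mirna[mirnas, samples, drop = FALSE],
       seeds = seed_matrix(as_plain_matrix(C)[genes, mirnas, drop = FALSE],
                           sort = FALSE))
}

#' Extract one sample's paired expression profile
#'
#' @param aligned the list returned by [align_profiles()].
#' @param sample a sample id present in both matrices.
#' @return A list with `x` (observed mRNA vector, named by gene), `z` (miRNA
#'   vector, named by miRNA) and `sample`.
#' @export
expression_pair <- function(aligned, sample) {
  if (!sample %in% colnames(aligned$mrna))
    stop("unknown sample id: ", sample)
  list(x = aligned$mrna[, sample], z = aligned$mirna[, sample],
       sample = sample)
}

#' Drop miRNAs that are not expressed
#'
#' Interactions involving a non-expressed miRNA are non-informative for the
#' competition model (the miRNA's exponent is 0) and are removed up front,
#' from both the miRNA vector and the seed-match columns. The default
#' threshold keeps strictly positive values only.
#'
#' @param z named nonnegative miRNA expression vector.
#' @param C a [seed_matrix()] whose columns match `names(z)`.
#' @param threshold keep miRNAs with `z > threshold` (default 0).
#' @return list with the filtered `z` and `seeds`; zero surviving miRNAs is
#'   allowed but warned about.
#' @export
filter_unexpressed <- function(z, C, threshold = 0) {
  stopifnot(is_seed_matrix(C), threshold >= 0)
  if (!identical(names(z), colnames(C)))
    stop("names(z) must match the seed matrix miRNA columns")
  keep <- z > threshold
  if (!any(keep)) warning("no miRNA expressed above threshold ", threshold)
  list(z = z[keep],
       seeds = seed_matrix(as_plain_matrix(C)[, keep, drop = FALSE],
                           sort = FALSE))
}

#' Read and write expression matrices
#'
#' Plain TSV: header row of sample ids, first column of feature ids, real
#' cells. `#`-prefixed lines are metadata comments.
#'
#' @param path file path.
#' @return `read_expression`: numeric matrix features x samples.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE, comment.char = "#")
  m <- as.matrix(tab)
  if (any(is.na(m))) stop("missing expression values in ", path,
                          "; imputation is not performed")
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  m
}

#' @rdname read_expression
#' @param mat matrix to serialise.
#' @param feature_col header for the id column (default "feature").
#' @export
write_expression <- function(mat, path, feature_col = "feature") {
  tab <- data.frame(rownames(mat), mat, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c(feature_col, colnames(mat)))
  invisible(path)
}

#' Read a matched-cohort manifest
#'
#' A manifest maps sample ids to their condition and matched pair:
#' columns `sample`, `condition` (normal/tumor) and `pair`.
#'
#' @param path TSV path with a header.
#' @return data.frame with one (normal, tumor) row per pair id.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "condition", "pair")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$condition %in% c("normal", "tumor")))
    stop("condition must be 'normal' or 'tumor'")
  wide <- merge(tab[tab$condition == "normal", c("pair", "sample")],
                tab[tab$condition == "tumor", c("pair", "sample")],
                by = "pair", suffixes = c("_normal", "_tumor"))
  if (anyDuplicated(wide$pair)) stop("pair ids must be unique per condition")
  wide[order(wide$pair, method = "radix"), ]
}
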