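#' Seed-match count matrices
#'
#' A seed-match matrix records, for every (gene, miRNA) pair, the number of
#' conserved seed-match sites in the gene's 3'UTR for that miRNA. It is the
#' sequence-level scaffold of the competition model: a pair with a zero count
#' can never receive a nonzero interaction probability.
#'
#' The object is a plain integer matrix of class `"seed_matrix"` with genes as
#' rows and miRNAs as columns. Identifiers are kept unique and sorted
#' lexicographically (C locale) so that serialisation is canonical.
#'
#' @param counts numeric matrix of nonnegative integers with unique, non-empty
#'   row names (gene ids) and column names (miRNA ids).
#' @param sort logical; reorder rows/columns lexicographically (default TRUE).
#' @return An integer matrix of class `"seed_matrix"`.
#' @examples
#' C <- seed_matrix(matrix(c(0, 2, 3, 0), 2, 2,
#'                         dimnames = list(c("g1", "g2"), c("m1", "m2"))))
#' binarize(C)
#' @export
seed_matrix <- function(counts, sort = TRUE) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("`counts` must have gene row names and miRNA column names")
  if (is.null(dimnames(counts)))
    dimnames(counts) <- list(character(0), character(0))
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate miRNA identifiers")
  if (any(!nzchar(rownames(counts))) || any(!nzchar(colnames(counts))))
    stop("empty identifiers are not allowed")
  if (any(!is.finite(counts))) stop("seed counts must be finite")
  if (any(counts < 0)) stop("seed counts must be nonnegative")
  if (any(counts != round(counts))) stop("seed counts must be integral")
  storage.mode(counts) <- "integer"
  if (sort) {
    counts <- counts[order_cloc(rownames(counts)),
                     order_cloc(colnames(counts)), drop = FALSE]
  }
  if (length(counts) && all(counts == 0L))
    warning("seed matrix is all zero")
  structure(counts, class = c("seed_matrix", class(unclass(counts))))
}

#' @rdname seed_matrix
#' @param x object to test or binarize.
#' @export
is_seed_matrix <- function(x) inherits(x, "seed_matrix")

# lexicographic order in the C locale, independent of the session locale
order_cloc <- function(ids) order(ids, method = "radix")

as_plain_matrix <- function(x) {
  class(x) <- "matrix"
  x
}

#' @export
print.seed_matrix <- function(x, ...) {
  cat(sprintf("seed_matrix: %d genes x %d miRNAs, %d nonzero pairs\n",
              nrow(x), ncol(x), sum(x > 0L)))
  invisible(x)
}

#' Build a seed-match matrix from site-level records
#'
#' Aggregates a table of per-transcript site counts into a gene x miRNA count
#' matrix. When a gene has several annotated transcripts, only the transcript
#' with the longest 3'UTR contributes (ties broken by the lexicographically
#' smallest transcript id, for determinism). Within the chosen transcript,
#' counts for the same miRNA are summed. miRNA family members are kept as
#' separate columns; they are never merged, so competition within a family is
#' retained.
#'
#' @param sites data.frame of site records.
#' @param gene,transcript,utr_length,mirna,site_count column names in `sites`
#'   holding the gene id, transcript id, 3'UTR length (nt), miRNA id and
#'   nonnegative site count. Defaults match the package's own conventions; set
#'   them to ingest TargetScan-style site tables with other headers.
#' @return A [seed_matrix()] covering every gene and miRNA seen in `sites`
#'   (pairs without a record get count 0).
#' @examples
#' sites <- data.frame(
#'   gene_id = c("G", "G"), transcript_id = c("T1", "T2"),
#'   utr_length = c(100L, 200L), mirna_id = c("miR-a", "miR-a"),
#'   site_count = c(2L, 1L))
#' build_seed_matrix(sites)["G", "miR-a"]  # 1: T2 has the longer UTR
#' @export
build_seed_matrix <- function(sites, gene = "gene_id",
                              transcript = "transcript_id",
                              utr_length = "utr_length",
                              mirna = "mirna_id",
                              site_count = "site_count") {
  need <- c(gene, transcript, utr_length, mirna, site_count)
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("missing columns in site table: ", paste(miss, collapse = ", "))
  if (nrow(sites) == 0L) stop("site table is empty")
  rec <- data.frame(gene = as.character(sites[[gene]]),
                    tx = as.character(sites[[transcript]]),
                    utr = sites[[utr_length]],
                    mirna = as.character(sites[[mirna]]),
                    count = sites[[site_count]],
                    stringsAsFactors = FALSE)
  if (any(!is.finite(rec$utr)) || any(rec$utr < 0))
    stop("utr_length must be nonnegative and present for every record")
  if (any(!is.finite(rec$count)) || any(rec$count < 0) ||
      any(rec$count != round(rec$count)))
    stop("site_count must be a nonnegative integer")

  utr_by_tx <- tapply(rec$utr, rec$tx, function(u) length(unique(u)))
  bad <- names(utr_by_tx)[utr_by_tx > 1L]
  if (length(bad))
    stop("conflicting utr_length for transcript(s): ",
         paste(sort(bad), collapse = ", "))

  # longest 3'UTR per gene; ties -> lexicographically smallest transcript id
  tx_tab <- unique(rec[, c("gene", "tx", "utr")])
  tx_tab <- tx_tab[order(tx_tab$gene, -tx_tab$utr, tx_tab$tx,
                         method = "radix"), ]
  chosen <- tx_tab[!duplicated(tx_tab$gene), c("gene", "tx")]
  keep <- rec$tx == chosen$tx[match(rec$gene, chosen$gene)]
  rec <- rec[keep, , drop = FALSE]

  genes <- sort(unique(rec$gene), method = "radix")
  mirnas <- sort(unique(rec$mirna), method = "radix")
  counts <- matrix(0L, length(genes), length(mirnas),
                   dimnames = list(genes, mirnas))
  agg <- stats::aggregate(count ~ gene + mirna, data = rec, FUN = sum)
  counts[cbind(agg$gene, agg$mirna)] <- as.integer(agg$count)
  seed_matrix(counts)
}

#' Set every nonzero seed count to one
#'
#' @param C a [seed_matrix()].
#' @return A binary [seed_matrix()]; idempotent.
#' @export
binarize <- function(C) {
  stopifnot(is_seed_matrix(C))
  out <- as_plain_matrix(C)
  out[out > 0L] <- 1L
  seed_matrix(out, sort = FALSE)
}

#' Read and write seed-match matrices
#'
#' Two plain-text dialects are supported. `"dense"`: a TSV with the miRNA ids
#' as header, gene ids in the first column and integer cells. `"triplet"`:
#' three columns `gene<TAB>mirna<TAB>count`, no header; lines starting with
#' `#` are skipped. The two encodings of the same matrix read back as
#' identical objects, and `read_seed_matrix(write_seed_matrix(...))`
#' round-trips bit-exactly.
#'
#' Duplicate (gene, miRNA) triplet rows are rejected rather than summed:
#' duplicates in a serialised file usually indicate corruption, and site-level
#' aggregation belongs to [build_seed_matrix()].
#'
#' @param path file path.
#' @param format `"dense"` or `"triplet"`.
#' @return `read_seed_matrix`: a [seed_matrix()]. `write_seed_matrix`:
#'   `path`, invisibly.
#' @export
read_seed_matrix <- function(path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1L, check.names = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-integer or negative seed count at data line %d of %s",
                   bad[1L, 1L], path))
    return(seed_matrix(m))
  }
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  ln <- which(keep)
  if (!length(ln)) stop("no triplet records in ", path)
  parts <- strsplit(lines[ln], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop(sprintf("expected 3 tab-separated fields at line %d of %s",
                 ln[which(nf != 3L)[1L]], path))
  gene <- vapply(parts, `[[`, "", 1L)
  mirna <- vapply(parts, `[[`, "", 2L)
  count <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(!is.finite(count) | count < 0 | count != round(count))
  if (length(bad))
    stop(sprintf("non-integer or negative count at line %d of %s",
                 ln[bad[1L]], path))
  key <- paste(gene, mirna, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (gene, miRNA) pair '%s'/'%s' at line %d of %s",
                 gene[d], mirna[d], ln[d], path))
  }
  genes <- sort(unique(gene), method = "radix")
  mirnas <- sort(unique(mirna), method = "radix")
  m <- matrix(0L, length(genes), length(mirnas),
              dimnames = list(genes, mirnas))
  m[cbind(gene, mirna)] <- as.integer(count)
  seed_matrix(m)
}

#' @rdname read_seed_matrix
#' @param C a [seed_matrix()] to serialise.
#' @param zeros for the triplet dialect, write explicit zero pairs too
#'   (default FALSE: only nonzero counts are written, and absent pairs read
#'   back as zero provided their gene and miRNA appear elsewhere).
#' @export
write_seed_matrix <- function(C, path, format = c("dense", "triplet"),
                              zeros = FALSE) {
  stopifnot(is_seed_matrix(C))
  format <- match.arg(format)
  if (format == "dense") {
    tab <- data.frame(gene = rownames(C), as_plain_matrix(C),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = c("gene", colnames(C)))
  } else {
    idx <- if (zeros) which(C >= 0L) else which(C > 0L)
    tab <- data.frame(gene = rownames(C)[row(C)[idx]],
                      mirna = colnames(C)[col(C)[idx]],
                      count = as.integer(C[idx]))
    if (!zeros) {
      # keep all-zero genes/miRNAs representable so the round trip is exact
      zr <- rownames(C)[rowSums(C) == 0L]
      zc <- colnames(C)[colSums(C) == 0L]
      if (length(zr))
        tab <- rbind(tab, data.frame(gene = zr, mirna = colnames(C)[1L],
                                     count = 0L))
      if (length(zc)) {
        g1 <- setdiff(rownames(C), zr)[1L]
        if (is.na(g1)) g1 <- rownames(C)[1L]
        zc <- setdiff(zc, if (length(zr)) colnames(C)[1L] else character())
        if (length(zc))
          tab <- rbind(tab, data.frame(gene = g1, mirna = zc, count = 0L))
      }
      tab <- tab[!duplicated(paste(tab$gene, tab$mirna, sep = "\r")), ]
    }
    tab <- tab[order(tab$gene, tab$mirna, method = "radix"), ]
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
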