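#' Rank interactions by score
#'
#' Flattens a scored gene x miRNA matrix into a deterministic ranking:
#' descending score, ties broken by (gene, miRNA) lexicographic order. When a
#' seed matrix is supplied, only seed-matched pairs are ranked - pairs without
#' a site have no predicted interaction to rank.
#'
#' @param scores numeric matrix with gene row names and miRNA column names
#'   (e.g. one matrix of an `"mmi_signature"`), all finite.
#' @param seeds optional [seed_matrix()] restricting the ranking to pairs with
#'   a nonzero count.
#' @return data.frame with columns `gene`, `mirna`, `score`, ordered.
#' @export
rank_interactions <- function(scores, seeds = NULL) {
  stopifnot(is.matrix(scores))
  idx <- if (is.null(seeds)) seq_along(scores) else {
    stopifnot(is_seed_matrix(seeds), identical(dim(seeds), dim(scores)))
    which(as_plain_matrix(seeds) > 0L)
  }
  if (any(!is.finite(scores[idx]))) stop("scores must be finite")
  tab <- data.frame(gene = rownames(scores)[row(scores)[idx]],
                    mirna = colnames(scores)[col(scores)[idx]],
                    score = scores[idx], stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score, tab$gene, tab$mirna, method = "radix"), ]
  rownames(tab) <- NULL
  tab
}

check_binary_labels <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(!is.finite(scores))) stop("scores must be finite")
}

#' ROC curve and area under it
#'
#' `auroc()` is the Mann-Whitney probability that a random positive outscores
#' a random negative, with ties counting one half - identical to the area
#' under the threshold-sweep ROC curve. `roc_curve()` returns that sweep, one
#' point per distinct score (ties grouped), from (0, 0) to (1, 1).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 vector; needs at least one of each class.
#' @return `auroc()`: scalar in \[0, 1\]. `roc_curve()`: data.frame with
#'   `threshold`, `fpr`, `tpr`.
#' @export
auroc <- function(scores, labels) {
  check_binary_labels(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative label")
  r <- rank(scores)  # midranks: ties count 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @rdname auroc
#' @export
roc_curve <- function(scores, labels) {
  check_binary_labels(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative label")
  o <- order(-scores)
  s <- scores[o]
  l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(cumsum(l), grp, max)
  fp <- tapply(cumsum(1 - l), grp, max)
  data.frame(threshold = c(Inf, unique(s)),
             fpr = c(0, fp / n_neg),
             tpr = c(0, tp / n_pos))
}

#' Precision-recall curve and trapezoidal area
#'
#' Sweeps thresholds in descending score order with tied scores grouped at a
#' single threshold; the area is the trapezoid over recall, anchored at
#' recall 0 with the precision of the first threshold.
#'
#' @inheritParams auroc
#' @return `pr_curve()`: data.frame with `threshold`, `recall`, `precision`.
#'   `aupr()`: scalar.
#' @export
pr_curve <- function(scores, labels) {
  check_binary_labels(labels, scores)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("need at least one positive label")
  o <- order(-scores)
  s <- scores[o]
  l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- as.vector(tapply(cumsum(l), grp, max))
  n <- as.vector(tapply(seq_along(l), grp, max))
  data.frame(threshold = unique(s), recall = tp / n_pos, precision = tp / n)
}

#' @rdname pr_curve
#' @export
aupr <- function(scores, labels) {
  cv <- pr_curve(scores, labels)
  rec <- c(0, cv$recall)
  prec <- c(cv$precision[1L], cv$precision)
  sum(diff(rec) * (utils::head(prec, -1L) + utils::tail(prec, -1L)) / 2)
}

#' Count validated interactions among the top-ranked
#'
#' How many of the K best-ranked predictions are in an externally validated
#' set. The conventional grid is K = 500, 1000, 1500, 2000.
#'
#' @param ranked data.frame from [rank_interactions()].
#' @param validated data.frame (or 2-column matrix) of validated `gene`,
#'   `mirna` pairs.
#' @param k vector of positive cutoffs (default `c(500, 1000, 1500, 2000)`).
#' @return Named integer vector of counts, one per cutoff; monotone
#'   non-decreasing in K.
#' @export
count_validated_topk <- function(ranked, validated,
                                 k = c(500L, 1000L, 1500L, 2000L)) {
  stopifnot(all(k >= 1))
  vkey <- paste(validated[[1L]], validated[[2L]], sep = "\r")
  rkey <- paste(ranked$gene, ranked$mirna, sep = "\r")
  hit <- cumsum(rkey %in% vkey)
  kk <- pmin(as.integer(k), length(rkey))
  stats::setNames(as.integer(ifelse(kk >= 1L, hit[kk], 0L)), paste0("top", k))
}

#' Expression-correlation baseline ranking
#'
#' The classical multi-sample baseline: for every seed-matched pair, the
#' Pearson correlation of mRNA and miRNA expression across shared samples;
#' anti-correlated pairs rank first. Pairs whose correlation is undefined
#' (zero variance in either vector) are flagged and sorted after all defined
#' values.
#'
#' @param mrna,mirna expression matrices (features x samples) sharing >= 3
#'   sample columns.
#' @param C a [seed_matrix()] aligned to the two feature spaces.
#' @return data.frame `gene`, `mirna`, `r`, `score` (= -r, so descending
#'   score is ascending correlation), `undefined`; ordered.
#' @export
pearson_baseline <- function(mrna, mirna, C) {
  stopifnot(is_seed_matrix(C))
  samples <- intersect(colnames(mrna), colnames(mirna))
  if (length(samples) < 3L) stop("need >= 3 shared samples")
  if (!all(rownames(C) %in% rownames(mrna)) ||
      !all(colnames(C) %in% rownames(mirna)))
    stop("expression matrices do not cover the seed matrix identifiers")
  idx <- which(as_plain_matrix(C) > 0L)
  g <- rownames(C)[row(C)[idx]]
  m <- colnames(C)[col(C)[idx]]
  r <- suppressWarnings(vapply(seq_along(idx), function(j)
    stats::cor(mrna[g[j], samples], mirna[m[j], samples]), numeric(1L)))
  tab <- data.frame(gene = g, mirna = m, r = r, score = -r,
                    undefined = !is.finite(r), stringsAsFactors = FALSE)
  tab <- tab[order(tab$undefined, ifelse(is.finite(r), r, Inf),
                   tab$gene, tab$mirna, method = "radix"), ]
  rownames(tab) <- NULL
  tab
}

#' Mean cross-entropy classification loss
#'
#' The loss of predictive tumor probabilities against binary tumor/normal
#' labels, `mean(-t * log(p))` with the natural log: a tumor sample assigned
#' probability 1 contributes 0, probability 1/2 contributes ln 2. As defined,
#' normal samples (t = 0) contribute 0 regardless of p; set `full = TRUE` for
#' the complete binary cross-entropy `-t log p - (1-t) log(1-p)`, which also
#' penalises confident false positives.
#'
#' @param labels 0/1 vector (1 = tumor).
#' @param p predictive probabilities in (0, 1\]; a 0 under a positive label is
#'   an infinite loss and an error unless `clamp` is given.
#' @param full include the `(1-t) log(1-p)` term (default FALSE).
#' @param clamp optional lower bound; probabilities are clamped into
#'   `[clamp, 1 - clamp]` (upper clamp applied only when `full = TRUE`).
#' @return Nonnegative scalar.
#' @export
mean_cross_entropy <- function(labels, p, full = FALSE, clamp = NULL) {
  if (length(labels) != length(p)) stop("lengths differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(clamp)) {
    stopifnot(clamp > 0, clamp < 0.5)
    p <- pmin(pmax(p, clamp), if (full) 1 - clamp else 1)
  }
  if (any(p == 0 & labels == 1))
    stop("p = 0 under a positive label gives infinite loss; set `clamp`")
  if (full && any(p == 1 & labels == 0))
    stop("p = 1 under a negative label gives infinite loss; set `clamp`")
  loss <- ifelse(labels == 1, -log(p), 0)
  if (full) loss <- loss + ifelse(labels == 0, -log(1 - p), 0)
  mean(loss)
}

#' Read interaction labels or validated-pair lists
#'
#' Labels TSV: `gene<TAB>mirna<TAB>label` with label 0/1; validated TSV:
#' `gene<TAB>mirna`. No header; `#` comments allowed.
#'
#' @param path file path.
#' @return data.frame with 2 or 3 columns as present.
#' @export
read_pair_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- c("gene", "mirna", "label")[seq_len(ncol(tab))]
  tab
}
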