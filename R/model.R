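#' Model configuration
#'
#' Tuning parameters of the competition model.
#'
#' * `eta` — learning rate scaling the per-iteration expected mRNA reduction
#'   (default 0.001). Smaller values damp the hidden-total correction.
#' * `capacity_factor` — the transcriptional capacity multiplier: the hidden
#'   total mRNA pool is fixed at `T = capacity_factor * sum(x_obs)`
#'   (default 1.3, i.e. 30% more transcript than observed, standing for the
#'   amount degraded by miRNA before the equilibrium snapshot).
#' * `tol` — convergence threshold on the maximum absolute element-wise
#'   change of both probability matrices between iterations (default 1e-5).
#' * `max_iter` — iteration cap (default 200).
#' * `expression_rescale` — `"none"` feeds expression values into the
#'   exponents as given; `"mean_one"` divides each vector by its mean first.
#'   Large raw values (RPKM/RPM can be in the hundreds) sit in the exponents
#'   of the competition probabilities and can saturate them at 1;
#'   [infer_signature()] warns when that happens and the rescale is the
#'   provided remedy.
#'
#' @param eta positive learning rate.
#' @param capacity_factor capacity multiplier, >= 1.
#' @param tol positive convergence threshold.
#' @param max_iter positive integer iteration cap.
#' @param expression_rescale `"none"` or `"mean_one"`.
#' @return A list of class `"mmi_config"`.
#' @export
model_config <- function(eta = 0.001, capacity_factor = 1.3, tol = 1e-5,
                         max_iter = 200L,
                         expression_rescale = c("none", "mean_one")) {
  stopifnot(eta > 0, capacity_factor >= 1, tol > 0, max_iter >= 1)
  structure(list(eta = eta, capacity_factor = capacity_factor, tol = tol,
                 max_iter = as.integer(max_iter),
                 expression_rescale = match.arg(expression_rescale)),
            class = "mmi_config")
}

check_model_inputs <- function(x, z, C) {
  stopifnot(is_seed_matrix(C))
  if (length(x) != nrow(C) || length(z) != ncol(C))
    stop("expression vectors do not match the seed matrix dimensions")
  if (any(!is.finite(x)) || any(!is.finite(z)))
    stop("expression values must be finite")
  if (any(x < 0) || any(z < 0))
    stop("expression values must be nonnegative")
}

#' Competition probabilities
#'
#' `prob_mrna_competition()` scores the mRNA-competition event: the
#' probability that transcript i attracts miRNA k rather than losing it to
#' every other transcript carrying a compatible site,
#' \deqn{p^{(x)}_{ik} = 1 - \left[\frac{\sum_{j \ne i} c_{jk} x_j}
#'   {\sum_{j'} c_{j'k} x_{j'}}\right]^{z_k}.}
#' The bracket is the one-draw probability that miRNA k lands elsewhere; the
#' miRNA's abundance is the number of draws, so abundant miRNAs are more
#' likely to reach transcript i at least once.
#'
#' `prob_mirna_competition()` is the role-switched counterpart: miRNA k
#' competes against all other miRNAs with sites on transcript i, with the
#' transcript's (hidden total) abundance as the exponent.
#'
#' Conventions: the probability is exactly 0 whenever the pair has no seed
#' match, the exponent is 0 (non-expressed miRNA, or zero-total transcript),
#' or no expressed competitor carries any site (denominator 0 - no evidence of
#' targeting). The power is computed in log space for stability; a fraction of
#' 0 with a positive exponent gives probability 1 (sole expressed carrier).
#'
#' @param x_total hidden total mRNA abundance vector (length `nrow(C)`).
#' @param z miRNA expression vector (length `ncol(C)`).
#' @param C a [seed_matrix()].
#' @return An N x M matrix of probabilities in \[0, 1\] with `C`'s dimnames.
#' @examples
#' C <- seed_matrix(matrix(1L, 2, 1, dimnames = list(c("g1", "g2"), "m1")))
#' prob_mrna_competition(c(5, 5), 1, C)  # both genes: 1 - (5/10)^1 = 0.5
#' @export
prob_mrna_competition <- function(x_total, z, C) {
  check_model_inputs(x_total, z, C)
  Cn <- as_plain_matrix(C)
  denom <- as.vector(crossprod(Cn, x_total))        # sum_j c_jk x_j, per miRNA
  num <- sweep(-Cn * x_total, 2L, denom, "+")       # leave-one-out numerator
  frac <- sweep(num, 2L, pmax(denom, .Machine$double.xmin), "/")
  frac[frac < 0] <- 0
  frac[frac > 1] <- 1
  p <- 1 - exp(sweep(log(frac), 2L, z, "*"))
  p[, z == 0] <- 0
  p[, denom == 0] <- 0
  p[Cn == 0L] <- 0
  dimnames(p) <- dimnames(C)
  p
}

#' @rdname prob_mrna_competition
#' @export
prob_mirna_competition <- function(x_total, z, C) {
  check_model_inputs(x_total, z, C)
  Cn <- as_plain_matrix(C)
  denom <- as.vector(Cn %*% z)                      # sum_l c_il z_l, per gene
  num <- denom - sweep(Cn, 2L, z, "*")
  frac <- num / pmax(denom, .Machine$double.xmin)
  frac[frac < 0] <- 0
  frac[frac > 1] <- 1
  p <- 1 - exp(log(frac) * x_total)
  p[x_total == 0, ] <- 0
  p[denom == 0, ] <- 0
  p[Cn == 0L] <- 0
  dimnames(p) <- dimnames(C)
  p
}

#' Expected per-interaction mRNA reduction
#'
#' The amount of transcript i expected to be degraded through miRNA k,
#' `eta * p * x_total[i]`, where `p` is the mRNA-competition probability.
#'
#' @param p_mrna mRNA-competition probability matrix.
#' @param x_total hidden total mRNA vector.
#' @param eta positive learning rate.
#' @return N x M nonnegative matrix of reductions.
#' @export
expected_reduction <- function(p_mrna, x_total, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0)
    stop("`eta` must be a positive scalar")
  eta * p_mrna * x_total
}

#' Update the hidden total mRNA pool
#'
#' Adds the per-gene expected reductions to the base profile and rescales the
#' result so that it sums exactly to the transcriptional capacity `capacity`.
#'
#' @param x_base base mRNA vector (in the fitting loop, the observed profile).
#' @param delta N x M reduction matrix (or a precomputed vector of row sums).
#' @param capacity positive total `T` to rescale to.
#' @return A vector summing to `capacity` (relative error <= 1e-9).
#' @export
update_total_mrna <- function(x_base, delta, capacity) {
  stopifnot(capacity > 0, all(x_base >= 0))
  add <- if (is.matrix(delta)) rowSums(delta) else delta
  x_star <- x_base + add
  s <- sum(x_star)
  if (s <= 0) stop("degenerate profile: total mRNA is zero")
  x_star / s * capacity
}

#' Infer a probabilistic interaction signature from one paired profile
#'
#' Runs the alternating competition model on a single sample: initialise the
#' hidden total mRNA at the observed profile, then per iteration (i) compute
#' the mRNA-competition probabilities, (ii) convert them into expected
#' per-interaction reductions, (iii) refresh the hidden total as the observed
#' profile plus those reductions, rescaled to the fixed transcriptional
#' capacity `T`, and (iv) compute the miRNA-competition probabilities from the
#' refreshed total. Iteration stops when the maximum absolute element-wise
#' change of *both* probability matrices falls below `tol` (typically a
#' handful of iterations) or at `max_iter` (then a warning is raised and
#' `converged` is FALSE). The joint-competition matrix is the element-wise
#' product of the two and therefore conservative: both competitions must
#' favour the pair. Rows and columns are deliberately not normalized to sum
#' to 1 - one miRNA can target many transcripts with high probability and
#' vice versa.
#'
#' @param x observed mRNA expression vector (length `nrow(C)`), nonnegative.
#' @param z observed miRNA expression vector (length `ncol(C)`).
#' @param C a [seed_matrix()].
#' @param config a [model_config()].
#' @return An object of class `"mmi_signature"`: list with probability
#'   matrices `p_mrna`, `p_mirna`, `p_joint`, the final hidden total
#'   `x_total`, `capacity` (the value of `T`), `converged`, `n_iter`,
#'   `max_last_change` and the `config` used.
#' @examples
#' C <- seed_matrix(matrix(1L, 1, 1, dimnames = list("g1", "m1")))
#' sig <- infer_signature(3, 2, C)
#' sig$p_joint  # no competitor on either side: probability 1
#' @export
infer_signature <- function(x, z, C, config = model_config()) {
  check_model_inputs(x, z, C)
  stopifnot(inherits(config, "mmi_config"))
  if (nrow(C) == 0L || ncol(C) == 0L)
    stop("empty gene or miRNA set; nothing to infer")
  if (all(x == 0) || all(z == 0))
    stop("need at least one expressed gene and one expressed miRNA")
  if (config$expression_rescale == "mean_one") {
    x <- x / mean(x)
    z <- z / mean(z)
  }
  capacity <- config$capacity_factor * sum(x)
  x_total <- x
  p_x_old <- p_z_old <- matrix(0, nrow(C), ncol(C))
  n_iter <- 0L
  d <- Inf
  repeat {
    n_iter <- n_iter + 1L
    p_x <- prob_mrna_competition(x_total, z, C)
    delta <- expected_reduction(p_x, x_total, config$eta)
    x_total <- update_total_mrna(x, delta, capacity)
    p_z <- prob_mirna_competition(x_total, z, C)
    d <- max(max(abs(p_x - p_x_old)), max(abs(p_z - p_z_old)))
    p_x_old <- p_x
    p_z_old <- p_z
    if (d <= config$tol || n_iter >= config$max_iter) break
  }
  converged <- d <= config$tol
  if (!converged)
    warning(sprintf("not converged after %d iterations (last change %.3g)",
                    n_iter, d))
  nz <- as_plain_matrix(C) > 0L
  if (any(nz)) {
    sat <- max(mean(p_x[nz] > 1 - 1e-12), mean(p_z[nz] > 1 - 1e-12))
    if (sat > 0.5)
      warning(sprintf(paste0(
        "%.0f%% of seed-matched probabilities are saturated at 1; ",
        "consider model_config(expression_rescale = \"mean_one\")"), 100 * sat))
  }
  structure(list(p_mrna = p_x, p_mirna = p_z, p_joint = p_x * p_z,
                 x_total = stats::setNames(x_total, rownames(C)),
                 capacity = capacity, converged = converged, n_iter = n_iter,
                 max_last_change = d, config = config),
            class = "mmi_signature")
}

#' @export
print.mmi_signature <- function(x, ...) {
  cat(sprintf(paste0(
    "mmi_signature: %d genes x %d miRNAs\n",
    "  %s after %d iteration(s), last max change %.3g\n",
    "  capacity T = %.4g, joint probability range [%.3g, %.3g]\n"),
    nrow(x$p_mrna), ncol(x$p_mrna),
    if (x$converged) "converged" else "NOT converged", x$n_iter,
    x$max_last_change, x$capacity, min(x$p_joint), max(x$p_joint)))
  invisible(x)
}

#' Fuse a signature with sequence-based scores
#'
#' Multiplies one of the probability matrices element-wise with a
#' sequence-level score in \[0, 1\] (e.g. a probability of conserved
#' targeting), sharpening the ranking with conservation evidence. Pairs with
#' no sequence score are treated as score 0.
#'
#' @param sig an `"mmi_signature"`.
#' @param pct numeric matrix in \[0, 1\] with the same dimnames as the
#'   signature matrices; `NA` entries count as 0.
#' @param model which matrix to fuse: `"mrna"` (default, the representative
#'   model), `"mirna"` or `"joint"`.
#' @return The fused N x M score matrix.
#' @export
fuse_sequence_score <- function(sig, pct, model = c("mrna", "mirna", "joint")) {
  model <- match.arg(model)
  p <- signature_matrix(sig, model)
  if (!identical(dim(pct), dim(p)))
    stop("`pct` must match the signature dimensions")
  pct[is.na(pct)] <- 0
  if (any(pct < 0 | pct > 1)) stop("`pct` values must lie in [0, 1]")
  p * pct
}

#' Extract one probability matrix from a signature
#'
#' @param sig an `"mmi_signature"`.
#' @param model `"mrna"`, `"mirna"` or `"joint"`.
#' @return The corresponding N x M probability matrix.
#' @export
signature_matrix <- function(sig, model = c("mrna", "mirna", "joint")) {
  stopifnot(inherits(sig, "mmi_signature"))
  switch(match.arg(model), mrna = sig$p_mrna, mirna = sig$p_mirna,
         joint = sig$p_joint)
}

#' Serialise a fitted signature
#'
#' Writes a sparse triplet TSV (`gene`, `mirna`, `p_mrna`, `p_mirna`,
#' `p_joint`; seed-matched pairs only) plus a JSON sidecar recording the
#' configuration, capacity, iteration count and convergence flag. Optionally
#' also writes the three dense matrices.
#'
#' @param sig an `"mmi_signature"`.
#' @param prefix output path prefix; files are `<prefix>.triplets.tsv`,
#'   `<prefix>.json` and optionally `<prefix>.p_<model>.tsv`.
#' @param seeds the [seed_matrix()] the signature was fitted on (defines which
#'   pairs are written).
#' @param dense also write dense per-model TSVs (default FALSE).
#' @return The sidecar path, invisibly.
#' @export
write_signature <- function(sig, prefix, seeds, dense = FALSE) {
  stopifnot(inherits(sig, "mmi_signature"), is_seed_matrix(seeds))
  idx <- which(as_plain_matrix(seeds) > 0L)
  tab <- data.frame(gene = rownames(seeds)[row(seeds)[idx]],
                    mirna = colnames(seeds)[col(seeds)[idx]],
                    p_mrna = sig$p_mrna[idx], p_mirna = sig$p_mirna[idx],
                    p_joint = sig$p_joint[idx])
  tab <- tab[order(tab$gene, tab$mirna, method = "radix"), ]
  utils::write.table(tab, paste0(prefix, ".triplets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (dense)
    for (m in c("mrna", "mirna", "joint"))
      write_expression(signature_matrix(sig, m),
                       paste0(prefix, ".p_", m, ".tsv"), feature_col = "gene")
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(config = unclass(sig$config), capacity = sig$capacity,
         n_iter = sig$n_iter, converged = sig$converged,
         max_last_change = sig$max_last_change,
         n_genes = nrow(sig$p_mrna), n_mirnas = ncol(sig$p_mrna)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a serialised signature triplet table
#'
#' @param path a `*.triplets.tsv` written by [write_signature()].
#' @return data.frame with columns gene, mirna, p_mrna, p_mirna, p_joint.
#' @export
read_signature_triplets <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
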