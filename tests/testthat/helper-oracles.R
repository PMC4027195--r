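# Independent reference implementations used as oracles. These deliberately
# use naive loops / textbook definitions and never share code with R/.

oracle_prob_mrna <- function(x, z, C) {
  p <- matrix(0, nrow(C), ncol(C))
  for (i in seq_len(nrow(C))) for (k in seq_len(ncol(C))) {
    if (C[i, k] == 0 || z[k] == 0) next
    den <- sum(C[, k] * x)
    if (den == 0) next
    frac <- min(max((den - C[i, k] * x[i]) / den, 0), 1)
    p[i, k] <- 1 - frac^z[k]
  }
  p
}

oracle_prob_mirna <- function(x, z, C) {
  p <- matrix(0, nrow(C), ncol(C))
  for (i in seq_len(nrow(C))) for (k in seq_len(ncol(C))) {
    if (C[i, k] == 0 || x[i] == 0) next
    den <- sum(C[i, ] * z)
    if (den == 0) next
    frac <- min(max((den - C[i, k] * z[k]) / den, 0), 1)
    p[i, k] <- 1 - frac^x[i]
  }
  p
}

# AUROC by exhaustive enumeration of positive/negative pairs (ties = 1/2)
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Benjamini-Hochberg step-up from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# a small random valid model instance
random_instance <- function(n, m, density = 0.3, max_count = 3L,
                            zero_x = 0, zero_z = 0) {
  C <- matrix(rbinom(n * m, 1L, density) * sample.int(max_count, n * m,
                                                      replace = TRUE),
              n, m, dimnames = list(sprintf("g%03d", seq_len(n)),
                                    sprintf("m%03d", seq_len(m))))
  x <- rlnorm(n, 1, 1)
  z <- rlnorm(m, 1, 1)
  if (zero_x > 0) x[sample.int(n, zero_x)] <- 0
  if (zero_z > 0) z[sample.int(m, zero_z)] <- 0
  list(C = seed_matrix(C, sort = FALSE), x = x, z = z)
}
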