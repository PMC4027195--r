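#' Synthetic-data configuration
#'
#' Parameters of the generator that emulates the model's inputs: a sparse
#' integer seed-match matrix, long-tailed nonnegative expression (log-normal,
#' RPKM/RPM-like scales), a planted set of true interactions, and
#' multiplicative repression of true targets scaled by a saturating weight of
#' miRNA abundance.
#'
#' The `preset` names the law by which true interactions are planted among
#' seed-matched pairs:
#' * `"no_competition"` - uniform; expression carries no information about
#'   which pairs are true (negative control: expression-aware scoring has no
#'   advantage here by design).
#' * `"mrna_competition"` - mass-action on the mRNA side: the propensity of a
#'   pair is its expressed seed match, site count x latent mRNA abundance,
#'   gated by a saturating weight of miRNA abundance.
#' * `"mirna_competition"` - mass-action on the miRNA side: site count x
#'   miRNA abundance.
#' * `"mixed"` (default) - the product of both sides: abundant miRNAs engage
#'   abundant, site-rich transcripts, the regime the competition model is
#'   built for.
#'
#' @param n_genes,n_mirnas dimensions (default 300 x 20).
#' @param seed_density probability a pair carries at least one site
#'   (default 0.15).
#' @param site_count_mean mean site count of a seed-matched pair; counts are
#'   1 + geometric (default 1.5).
#' @param mrna_meanlog,mrna_sdlog log-normal parameters of latent mRNA
#'   expression (default 1.6, 1.2: median ~5, RPKM-like long tail).
#' @param mirna_meanlog,mirna_sdlog log-normal parameters of miRNA expression
#'   (default 2, 1). The miRNA scale is set so that the dimensionless
#'   exponent of the competition model, `z * c * x / S`, spans the same
#'   O(0.01-1) range on a few-hundred-gene panel as transcriptome-scale
#'   RPM data does over thousands of competing transcripts; a raw RPM scale
#'   on a small panel would saturate the probabilities at 1.
#' @param target_fraction fraction of seed-matched pairs that are true
#'   interactions (default 0.1).
#' @param repression_strength maximal multiplicative decrease of observed
#'   mRNA per true interaction, in \[0, 1) (default 0.6); the realised
#'   decrease is `repression_strength * w(z)` with `w(z) = z / (z +
#'   median(z))`.
#' @param preset truth-planting law, see above.
#' @param rng_seed integer seed making the dataset reproducible (default 1).
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 300L, n_mirnas = 20L, seed_density = 0.15,
                         site_count_mean = 1.5,
                         mrna_meanlog = 1.6, mrna_sdlog = 1.2,
                         mirna_meanlog = 2, mirna_sdlog = 1,
                         target_fraction = 0.1, repression_strength = 0.6,
                         preset = c("mixed", "no_competition",
                                    "mrna_competition", "mirna_competition"),
                         rng_seed = 1L) {
  stopifnot(n_genes >= 1, n_mirnas >= 1,
            seed_density > 0, seed_density <= 1, site_count_mean >= 1,
            target_fraction >= 0, target_fraction <= 1,
            repression_strength >= 0, repression_strength < 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 seed_density = seed_density,
                 site_count_mean = site_count_mean,
                 mrna_meanlog = mrna_meanlog, mrna_sdlog = mrna_sdlog,
                 mirna_meanlog = mirna_meanlog, mirna_sdlog = mirna_sdlog,
                 target_fraction = target_fraction,
                 repression_strength = repression_strength,
                 preset = match.arg(preset),
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

# saturating miRNA-abundance weight in [0, 1)
abundance_weight <- function(z) {
  half <- stats::median(z[z > 0])
  if (!is.finite(half) || half <= 0) half <- 1
  z / (z + half)
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))
mirna_ids <- function(n) sprintf("mir%03d", seq_len(n))

sample_seed_counts <- function(cfg) {
  p_extra <- 1 / cfg$site_count_mean  # 1 + Geom(p): mean = 1 + (1-p)/p
  n <- cfg$n_genes * cfg$n_mirnas
  counts <- stats::rbinom(n, 1L, cfg$seed_density) *
    (1L + stats::rgeom(n, p_extra))
  m <- matrix(as.integer(counts), cfg$n_genes, cfg$n_mirnas,
              dimnames = list(gene_ids(cfg$n_genes),
                              mirna_ids(cfg$n_mirnas)))
  if (all(m == 0L))
    stop("seed_density so low that no seed-matched pair was generated")
  seed_matrix(m, sort = FALSE)
}

plant_truth <- function(C, latent, z, cfg) {
  idx <- which(as_plain_matrix(C) > 0L)
  i <- row(C)[idx]
  k <- col(C)[idx]
  w <- abundance_weight(z)
  wt <- switch(cfg$preset,
               no_competition = rep(1, length(idx)),
               mrna_competition = C[idx] * latent[i] * w[k],
               mirna_competition = C[idx] * z[k],
               mixed = C[idx] * latent[i] * w[k] * z[k])
  n_true <- round(cfg$target_fraction * length(idx))
  truth_idx <- if (n_true == 0L) integer() else
    sample(idx, n_true, prob = wt / sum(wt))
  truth_idx
}

#' Generate a synthetic single-sample dataset
#'
#' Draws a seed matrix and one paired expression profile, plants true
#' interactions according to the configured preset, and represses the
#' observed expression of true targets multiplicatively (each true
#' interaction of gene i removes a `repression_strength * w(z_k)` share).
#' Reproducible: the same `rng_seed` yields the identical dataset.
#'
#' @param cfg a [synth_config()].
#' @return list of class `"mmi_simulation"`: `seeds`, `x_obs`, `x_latent`,
#'   `z` (named vectors), `truth` (data.frame `gene`, `mirna`), `config`.
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$rng_seed)
  C <- sample_seed_counts(cfg)
  latent <- stats::setNames(
    stats::rlnorm(cfg$n_genes, cfg$mrna_meanlog, cfg$mrna_sdlog), rownames(C))
  z <- stats::setNames(
    stats::rlnorm(cfg$n_mirnas, cfg$mirna_meanlog, cfg$mirna_sdlog),
    colnames(C))
  truth_idx <- plant_truth(C, latent, z, cfg)
  w <- abundance_weight(z)
  fac <- rep(1, cfg$n_genes)
  for (t in truth_idx) {
    i <- row(C)[t]
    fac[i] <- fac[i] * (1 - cfg$repression_strength * w[col(C)[t]])
  }
  truth <- data.frame(gene = rownames(C)[row(C)[truth_idx]],
                      mirna = colnames(C)[col(C)[truth_idx]],
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene, truth$mirna, method = "radix"), ]
  rownames(truth) <- NULL
  structure(list(seeds = C, x_obs = latent * fac, x_latent = latent, z = z,
                 truth = truth, config = cfg),
            class = "mmi_simulation")
}

#' Truth labels aligned to the seed-matched pairs
#'
#' @param sim an `"mmi_simulation"`.
#' @return list with `idx` (indices of seed-matched entries), `labels` (0/1
#'   per entry, 1 = planted true interaction) and `keys` (`gene|mirna`).
#' @export
truth_labels <- function(sim) {
  C <- sim$seeds
  idx <- which(as_plain_matrix(C) > 0L)
  keys <- paste(rownames(C)[row(C)[idx]], colnames(C)[col(C)[idx]], sep = "|")
  lab <- as.integer(keys %in% paste(sim$truth$gene, sim$truth$mirna,
                                    sep = "|"))
  list(idx = idx, labels = lab, keys = keys)
}

#' The fixed 10 x 4 toy system
#'
#' A versioned miniature dataset exercising the model's qualitative laws:
#' gene `g01` has no site for `mir2` (its probabilities must be 0); gene
#' `g02`'s only site is for `mir4` (its miRNA-competition probability must be
#' exactly 1); `mir4` has sites on seven of the ten genes (strong mRNA-side
#' competition). Expression values are small fixed integers, so the fit is
#' fast and unsaturated. Repeated calls return identical data.
#'
#' @return An `"mmi_simulation"` (with an empty truth set; the toy is for
#'   structural, not benchmark, tests).
#' @export
make_toy <- function() {
  counts <- matrix(c(
    # mir1 mir2 mir3 mir4
    1L, 0L, 1L, 2L,   # g01
    0L, 0L, 0L, 1L,   # g02: only mir4
    2L, 0L, 0L, 2L,   # g03
    0L, 1L, 1L, 0L,   # g04
    1L, 2L, 0L, 0L,   # g05
    0L, 0L, 1L, 1L,   # g06
    1L, 0L, 0L, 1L,   # g07
    0L, 1L, 0L, 1L,   # g08
    0L, 0L, 2L, 0L,   # g09
    0L, 1L, 1L, 1L),  # g10
    nrow = 10L, byrow = TRUE,
    dimnames = list(gene_ids(10L), mirna_ids(4L)))
  x <- stats::setNames(c(10, 2, 8, 5, 7, 3, 6, 4, 9, 5), rownames(counts))
  z <- stats::setNames(c(6, 3, 4, 8), colnames(counts))
  structure(list(seeds = seed_matrix(counts, sort = FALSE),
                 x_obs = x, x_latent = x, z = z,
                 truth = data.frame(gene = character(), mirna = character(),
                                    stringsAsFactors = FALSE),
                 config = NULL),
            class = "mmi_simulation")
}

#' Generate a matched tumor/normal cohort with planted differential
#' interactions
#'
#' Builds `n_pairs` matched sample pairs around one latent template. Each
#' pair has its own per-feature biological offset shared between its normal
#' and tumor sample (this is what the paired design cancels), plus
#' independent residual noise. In tumor samples, the planted interactions'
#' miRNAs are shifted up by `mirna_fold` and their target genes shifted by
#' `gene_fold` - down (`gene_fold < 1`) for coherent planting, up for
#' sign-incoherent planting used as a negative control.
#'
#' @param cfg a [synth_config()] describing the base system.
#' @param n_pairs number of matched pairs (default 20).
#' @param n_planted number of planted differential interactions (default 10);
#'   0 gives a null cohort.
#' @param mirna_fold tumor/normal fold-change of planted miRNAs (default 4,
#'   a cancer-scale expression shift).
#' @param gene_fold tumor/normal fold-change of planted target genes (default
#'   0.5: miRNA-mediated degradation is canonically modest, under twofold).
#' @param pair_sd log-scale SD of the per-pair shared offset (default 0.4).
#' @param noise_sd log-scale SD of residual within-pair noise (default 0.15).
#' @return list of class `"mmi_cohort"`: `seeds`, `mrna`/`mirna` (feature x
#'   sample matrices over `2 * n_pairs` samples), `manifest` (sample,
#'   condition, pair), `pairs` (wide form), `planted` (data.frame `gene`,
#'   `mirna`), `config`.
#' @export
simulate_cohort <- function(cfg = synth_config(), n_pairs = 20L,
                            n_planted = 10L, mirna_fold = 4,
                            gene_fold = 0.5, pair_sd = 0.4,
                            noise_sd = 0.15) {
  stopifnot(inherits(cfg, "synth_config"), n_pairs >= 2L, n_planted >= 0L,
            mirna_fold > 0, gene_fold > 0)
  set.seed(cfg$rng_seed)
  C <- sample_seed_counts(cfg)
  latent <- stats::setNames(
    stats::rlnorm(cfg$n_genes, cfg$mrna_meanlog, cfg$mrna_sdlog), rownames(C))
  z0 <- stats::setNames(
    stats::rlnorm(cfg$n_mirnas, cfg$mirna_meanlog, cfg$mirna_sdlog),
    colnames(C))
  idx <- which(as_plain_matrix(C) > 0L)
  if (n_planted > length(idx))
    stop("more planted interactions requested than seed-matched pairs")
  w <- abundance_weight(z0)
  planted_idx <- if (n_planted == 0L) integer() else
    sample(idx, n_planted, prob = w[col(C)[idx]])
  planted <- data.frame(gene = rownames(C)[row(C)[planted_idx]],
                        mirna = colnames(C)[col(C)[planted_idx]],
                        stringsAsFactors = FALSE)
  gene_fac <- rep(1, cfg$n_genes)
  mirna_fac <- rep(1, cfg$n_mirnas)
  gene_fac[unique(row(C)[planted_idx])] <- gene_fold
  mirna_fac[unique(col(C)[planted_idx])] <- mirna_fold

  ids_n <- sprintf("P%02d_N", seq_len(n_pairs))
  ids_t <- sprintf("P%02d_T", seq_len(n_pairs))
  mrna <- matrix(NA_real_, cfg$n_genes, 2L * n_pairs,
                 dimnames = list(rownames(C), c(rbind(ids_n, ids_t))))
  mirna <- matrix(NA_real_, cfg$n_mirnas, 2L * n_pairs,
                  dimnames = list(colnames(C), c(rbind(ids_n, ids_t))))
  for (j in seq_len(n_pairs)) {
    off_g <- stats::rnorm(cfg$n_genes, 0, pair_sd)
    off_m <- stats::rnorm(cfg$n_mirnas, 0, pair_sd)
    mrna[, ids_n[j]] <- latent * exp(off_g + stats::rnorm(cfg$n_genes, 0, noise_sd))
    mrna[, ids_t[j]] <- latent * gene_fac *
      exp(off_g + stats::rnorm(cfg$n_genes, 0, noise_sd))
    mirna[, ids_n[j]] <- z0 * exp(off_m + stats::rnorm(cfg$n_mirnas, 0, noise_sd))
    mirna[, ids_t[j]] <- z0 * mirna_fac *
      exp(off_m + stats::rnorm(cfg$n_mirnas, 0, noise_sd))
  }
  manifest <- data.frame(
    sample = c(rbind(ids_n, ids_t)),
    condition = rep(c("normal", "tumor"), n_pairs),
    pair = rep(sprintf("P%02d", seq_len(n_pairs)), each = 2L),
    stringsAsFactors = FALSE)
  structure(list(seeds = C, mrna = mrna, mirna = mirna, manifest = manifest,
                 pairs = data.frame(pair = sprintf("P%02d", seq_len(n_pairs)),
                                    sample_normal = ids_n,
                                    sample_tumor = ids_t,
                                    stringsAsFactors = FALSE),
                 planted = planted, config = cfg),
            class = "mmi_cohort")
}

#' Write a simulated dataset or cohort to a directory
#'
#' Expression TSVs, a triplet seed TSV, truth/planted pair TSVs and (for
#' cohorts) a manifest TSV, in the package's plain-text dialects.
#'
#' @param sim an `"mmi_simulation"` or `"mmi_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (inherits(sim, "mmi_cohort")) {
    write_expression(sim$mrna, p("mrna.tsv"), feature_col = "gene")
    write_expression(sim$mirna, p("mirna.tsv"), feature_col = "mirna")
    utils::write.table(sim$manifest, p("manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$planted, p("planted.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    write_expression(cbind(S1 = sim$x_obs), p("mrna.tsv"),
                     feature_col = "gene")
    write_expression(cbind(S1 = sim$z), p("mirna.tsv"),
                     feature_col = "mirna")
    utils::write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_seed_matrix(sim$seeds, p("seeds.tsv"), format = "triplet")
  invisible(dir)
}
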