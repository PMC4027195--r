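# mirsig

Per-sample probabilistic miRNA–mRNA interaction signatures from a single
paired expression profile.

## The problem

MicroRNAs repress mRNAs by base-pairing with seed-match sites in 3'UTRs, and
aberrant miRNA expression is a recurrent feature of cancer. Most
expression-based target predictors need many samples (they regress mRNA on
miRNA across a cohort), so they cannot say which interactions are active *in
one particular sample* — yet each tumor has its own regulatory wiring.
`mirsig` is for transcriptomics and systems-biology researchers who have one
matched mRNA/miRNA profile per sample (RPKM/RPM-like values) plus a
seed-match site annotation, and who want a per-sample *signature*: an N×M
matrix of interaction probabilities over N genes and M miRNAs.

## The model

Let **x** be the observed mRNA vector, **z** the miRNA vector and **C** the
N×M seed-match count matrix (c_ik = number of sites on gene i for miRNA k).
Targeting is treated as the outcome of two competitions:

- **mRNA competition** — transcripts carrying sites for miRNA k dilute its
  per-target effect. The probability that gene i attracts miRNA k is the
  reversed probability that all of the miRNA's `z_k` "draws" land on
  competing transcripts:

      p(x)_ik = 1 − [ Σ_{j≠i} c_jk x(t)_j / Σ_j c_jk x(t)_j ] ^ z_k

- **miRNA competition** — miRNAs with sites on gene i compete for it, with
  the gene's hidden total abundance x(t)_i as the exponent:

      p(z)_ik = 1 − [ Σ_{l≠k} c_il z_l / Σ_l c_il z_l ] ^ x(t)_i

- **joint competition** — the element-wise product p(j) = p(x) ⊙ p(z),
  a conservative score requiring both competitions to favour the pair.

The hidden total x(t) (transcription before miRNA-mediated degradation) is
estimated by a fast fixed-point alternation: probabilities imply expected
per-interaction reductions Δx_ik = η p(x)_ik x(t)_i; the total is refreshed
as the observed profile plus those reductions, rescaled to a fixed
transcriptional capacity T = 1.3 Σx; iteration stops when both probability
matrices change by less than `tol` (typically 3–5 iterations). Pairs with no
seed match have probability exactly 0; a gene whose only expressed site
belongs to one miRNA gets miRNA-competition probability exactly 1.

Around the core model the package provides seed-matrix construction from
site tables (longest-3'UTR rule), quantile normalisation and identifier
alignment, benchmarking (ROC/PR curves, validated-target counts, a Pearson
anti-correlation baseline, mean cross-entropy), a paired tumor/normal
differential pipeline with a sign-coherence filter and Cytoscape/GSEA
exports, and a synthetic-data generator with planted ground truth.

## Worked example

```r
library(mirsig)

toy <- make_toy()                       # fixed 10 x 4 demonstration system
sig <- infer_signature(toy$x_obs, toy$z, toy$seeds)
print(sig)
#> mmi_signature: 10 genes x 4 miRNAs
#>   converged after 4 iteration(s), last max change 5.02e-07
#>   capacity T = 76.7, joint probability range [0, 0.971]

round(sig$p_joint[1:4, ], 3)
#>       mir001 mir002 mir003 mir004
#> g0001  0.804  0.000  0.597  0.971
#> g0002  0.000  0.000  0.000  0.252
#> g0003  0.955  0.000  0.000  0.932
#> g0004  0.000  0.434  0.404  0.000
```

`g0001` has no site for `mir002`, so that probability is 0 whatever the
expression; `g0002`'s only site is for `mir004`, so its miRNA-competition
probability is 1 (`sig$p_mirna["g0002", "mir004"]`), while its joint score
(0.252) stays modest because seven other genes compete for `mir004`.

On simulated data with planted true targets, the expression-aware score
separates true from false seed-matched pairs far better than site counts
alone:

```r
sim <- simulate_dataset(synth_config(rng_seed = 1))   # 300 genes x 20 miRNAs
s2  <- infer_signature(sim$x_obs, sim$z, sim$seeds)
tl  <- truth_labels(sim)
auroc(s2$p_mrna[tl$idx], tl$labels)          # 0.823
auroc(unclass(sim$seeds)[tl$idx], tl$labels) # 0.576
```

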