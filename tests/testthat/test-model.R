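toy_C <- function(counts, genes, mirnas)
  seed_matrix(matrix(counts, length(genes), length(mirnas),
                     dimnames = list(genes, mirnas)), sort = FALSE)

test_that("mRNA-competition probability matches hand-computed cases", {
  C <- toy_C(c(1L, 1L), c("g1", "g2"), "m1")
  expect_equal(prob_mrna_competition(c(5, 5), 1, C)[, 1],
               c(g1 = 0.5, g2 = 0.5))
  expect_equal(prob_mrna_competition(c(5, 5), 2, C)[, 1],
               c(g1 = 0.75, g2 = 0.75))
  # sole expressed carrier of the site: probability 1
  C2 <- toy_C(c(1L, 0L), c("g1", "g2"), "m1")
  expect_equal(prob_mrna_competition(c(5, 5), 2, C2)["g1", "m1"], 1)
  # zero seed count, zero miRNA, zero denominator all give 0
  expect_equal(prob_mrna_competition(c(5, 5), 2, C2)["g2", "m1"], 0)
  expect_equal(prob_mrna_competition(c(5, 5), 0, C)["g1", "m1"], 0)
  expect_equal(prob_mrna_competition(c(0, 0), 2, C)["g1", "m1"], 0)
  expect_error(prob_mrna_competition(c(-1, 5), 1, C), "nonnegative")
})

test_that("miRNA-competition probability matches hand-computed cases", {
  # gene with sites for both miRNAs, equal expressed seeds
  C <- toy_C(c(1L, 1L), "g1", c("m1", "m2"))
  expect_equal(prob_mirna_competition(1, c(5, 5), C)[1, ],
               c(m1 = 0.5, m2 = 0.5))
  # gene whose only site is for one expressed miRNA: exactly 1
  C2 <- toy_C(c(1L, 0L), "g1", c("m1", "m2"))
  expect_identical(prob_mirna_competition(3, c(5, 5), C2)["g1", "m1"], 1)
  expect_identical(prob_mirna_competition(3, c(5, 5), C2)["g1", "m2"], 0)
  # zero gene expression gives 0 by the exponent convention
  expect_identical(prob_mirna_competition(0, c(5, 5), C2)["g1", "m1"], 0)
})

test_that("vectorized competition probabilities agree with the naive loops", {
  set.seed(42)
  for (rep in 1:40) {
    inst <- suppressWarnings(
      random_instance(sample(2:50, 1), sample(1:10, 1),
                      zero_x = sample(0:1, 1), zero_z = sample(0:1, 1)))
    expect_lt(max(abs(prob_mrna_competition(inst$x, inst$z, inst$C) -
                        oracle_prob_mrna(inst$x, inst$z, unclass(inst$C)))),
              1e-12)
    expect_lt(max(abs(prob_mirna_competition(inst$x, inst$z, inst$C) -
                        oracle_prob_mirna(inst$x, inst$z, unclass(inst$C)))),
              1e-12)
  }
})

test_that("probabilities stay in [0,1] and increase with abundance", {
  set.seed(7)
  for (rep in 1:20) {
    inst <- random_instance(20, 5)
    p <- prob_mrna_competition(inst$x, inst$z, inst$C)
    q <- prob_mirna_competition(inst$x, inst$z, inst$C)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(q >= 0 & q <= 1))
  }
  # monotonicity at a pair with fraction strictly inside (0,1)
  C <- toy_C(c(1L, 1L), c("g1", "g2"), "m1")
  p_z <- vapply(c(1, 2, 4, 8),
                function(zk) prob_mrna_competition(c(5, 5), zk, C)[1, 1],
                numeric(1))
  expect_true(all(diff(p_z) > 0))
  p_x <- vapply(c(1, 2, 4, 8),
                function(xi) prob_mrna_competition(c(xi, 5), 2, C)[1, 1],
                numeric(1))
  expect_true(all(diff(p_x) > 0))
  p_zx <- vapply(c(1, 2, 4, 8), function(xi)
    prob_mirna_competition(c(xi, 5), c(3, 4), toy_C(rep(1L, 4),
      c("g1", "g2"), c("m1", "m2")))[1, 1], numeric(1))
  expect_true(all(diff(p_zx) > 0))
})

test_that("expected reduction and total-mRNA update follow their definitions", {
  expect_equal(expected_reduction(0.5, 10, 0.001), 0.005)
  expect_equal(expected_reduction(0, 10, 0.001), 0)
  expect_error(expected_reduction(0.5, 10, 0), "positive")
  expect_equal(update_total_mrna(c(1, 1), c(0.5, 0.5), 4), c(2, 2))
  # zero delta: rescale only
  expect_equal(update_total_mrna(c(1, 3), c(0, 0), 8), c(2, 6))
  expect_equal(update_total_mrna(c(1, 3), c(0, 0), 4), c(1, 3))
  expect_error(update_total_mrna(c(0, 0), c(0, 0), 4), "degenerate")
  # capacity conservation at tight tolerance on random inputs
  set.seed(5)
  for (rep in 1:20) {
    x <- rlnorm(30, 2, 1)
    delta <- matrix(runif(30 * 4, 0, 0.1), 30, 4)
    capacity <- 1.3 * sum(x)
    expect_lt(abs(sum(update_total_mrna(x, delta, capacity)) - capacity) /
                capacity, 1e-9)
  }
})

test_that("fitting the toy system satisfies the structural laws", {
  toy <- make_toy()
  sig <- infer_signature(toy$x_obs, toy$z, toy$seeds)
  expect_true(sig$converged)
  expect_lt(sig$n_iter, 50)
  # no seed -> all three probabilities exactly 0
  expect_identical(sig$p_mrna["g0001", "mir002"], 0)
  expect_identical(sig$p_mirna["g0001", "mir002"], 0)
  expect_identical(sig$p_joint["g0001", "mir002"], 0)
  zero <- unclass(toy$seeds) == 0L
  expect_true(all(sig$p_joint[zero] == 0))
  # g02's only site is mir004: miRNA competition is certain
  expect_identical(sig$p_mirna["g0002", "mir004"], 1)
  # joint law and bounds
  expect_identical(sig$p_joint, sig$p_mrna * sig$p_mirna)
  expect_true(all(sig$p_joint >= 0 & sig$p_joint <= 1))
  # capacity: T = 1.3 * sum(x_obs), conserved by the final total
  expect_equal(sig$capacity, 1.3 * sum(toy$x_obs))
  expect_lt(abs(sum(sig$x_total) - sig$capacity) / sig$capacity, 1e-9)
})

test_that("fitting is deterministic and degenerate systems behave", {
  toy <- make_toy()
  s1 <- infer_signature(toy$x_obs, toy$z, toy$seeds)
  s2 <- infer_signature(toy$x_obs, toy$z, toy$seeds)
  expect_identical(s1$p_mrna, s2$p_mrna)
  expect_identical(s1$x_total, s2$x_total)
  # single gene, single miRNA: no competition on either side
  C1 <- toy_C(1L, "g1", "m1")
  s <- suppressWarnings(infer_signature(4, 7, C1))  # single pair saturates by design
  expect_identical(unname(s$p_mrna[1, 1]), 1)
  expect_identical(unname(s$p_mirna[1, 1]), 1)
  expect_identical(unname(s$p_joint[1, 1]), 1)
  # all-zero seed matrix: all probabilities zero, one iteration
  C0 <- suppressWarnings(toy_C(c(0L, 0L), c("g1", "g2"), "m1"))
  s0 <- infer_signature(c(1, 2), 3, C0)
  expect_true(all(s0$p_joint == 0))
  expect_identical(s0$n_iter, 1L)
  expect_true(s0$converged)
  expect_error(infer_signature(c(0, 0), 3, C0), "expressed")
})

test_that("non-convergence warns and mean-one rescale tames saturation", {
  toy <- make_toy()
  expect_warning(
    s <- infer_signature(toy$x_obs, toy$z, toy$seeds,
                         model_config(tol = 1e-30, max_iter = 3L)),
    "not converged")
  expect_false(s$converged)
  expect_identical(s$n_iter, 3L)
  # huge raw scales saturate; warning suggests the rescale, which resolves it
  expect_warning(
    infer_signature(toy$x_obs * 1e4, toy$z * 1e4, toy$seeds),
    "saturated")
  s2 <- infer_signature(toy$x_obs * 1e4, toy$z * 1e4, toy$seeds,
                        model_config(expression_rescale = "mean_one"))
  expect_true(s2$converged)
  expect_lt(max(s2$p_mrna), 1 - 1e-12)
})

test_that("sequence-score fusion multiplies element-wise with NA as 0", {
  toy <- make_toy()
  sig <- infer_signature(toy$x_obs, toy$z, toy$seeds)
  pct <- matrix(0.5, 10, 4, dimnames = dimnames(toy$seeds))
  expect_equal(fuse_sequence_score(sig, pct), 0.5 * sig$p_mrna)
  pct1 <- matrix(1, 10, 4, dimnames = dimnames(toy$seeds))
  expect_equal(fuse_sequence_score(sig, pct1, model = "joint"), sig$p_joint)
  pctNA <- pct1
  pctNA["g0001", "mir001"] <- NA
  expect_identical(fuse_sequence_score(sig, pctNA)["g0001", "mir001"], 0)
  expect_error(fuse_sequence_score(sig, pct1 * 2), "0, 1")
})

test_that("signatures serialise to triplets with a faithful JSON sidecar", {
  toy <- make_toy()
  sig <- infer_signature(toy$x_obs, toy$z, toy$seeds)
  prefix <- file.path(withr::local_tempdir(), "S1")
  write_signature(sig, prefix, toy$seeds)
  tab <- read_signature_triplets(paste0(prefix, ".triplets.tsv"))
  expect_identical(nrow(tab), sum(unclass(toy$seeds) > 0L))
  i <- tab$gene == "g0002" & tab$mirna == "mir004"
  expect_equal(tab$p_mirna[i], 1)
  expect_equal(tab$p_joint, tab$p_mrna * tab$p_mirna, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_true(side$converged)
  expect_equal(side$capacity, sig$capacity)
})
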