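test_that("ranking is descending with deterministic lexicographic tie-break", {
  m <- matrix(c(0.5, 0.9, 0.5, 0.1), 2, 2,
              dimnames = list(c("g2", "g1"), c("mB", "mA")))
  r <- rank_interactions(m)
  expect_identical(r$score, c(0.9, 0.5, 0.5, 0.1))
  # the two 0.5 ties are both g2: mA sorts before mB
  expect_identical(r$gene[2:3], c("g2", "g2"))
  expect_identical(r$mirna[2:3], c("mA", "mB"))
  # seed restriction drops zero-count pairs
  C <- seed_matrix(matrix(c(1L, 0L, 1L, 1L), 2, 2,
                          dimnames = list(c("g2", "g1"), c("mB", "mA"))),
                   sort = FALSE)
  expect_identical(nrow(rank_interactions(m, C)), 3L)
})

test_that("AUROC equals exhaustive pair counting, including ties", {
  expect_identical(auroc(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # many ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
    # reversing scores flips the area
    expect_equal(auroc(-scores, labels), 1 - auroc(scores, labels))
  }
})

test_that("AUROC and ROC curve agree with an independent library", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
  cv <- roc_curve(scores, labels)
  expect_identical(cv$fpr[1], 0)
  expect_identical(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
  # trapezoid under the sweep equals the rank statistic
  expect_equal(sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2),
               auroc(scores, labels))
})

test_that("precision-recall sweep handles the canonical hand cases", {
  # single positive ranked first among 10
  s <- c(10, 9:1)
  l <- c(1, rep(0, 9))
  cv <- pr_curve(s, l)
  expect_identical(cv$recall[1], 1)
  expect_identical(cv$precision[1], 1)
  expect_identical(aupr(s, l), 1)
  # single positive ranked last of 2: final sweep point (1, 0.5)
  cv2 <- pr_curve(c(2, 1), c(0, 1))
  expect_identical(cv2$recall, c(0, 1))
  expect_identical(cv2$precision, c(0, 0.5))
  # all positives: area 1
  expect_identical(aupr(c(3, 2, 1), c(1, 1, 1)), 1)
  # tied scores are grouped at one threshold
  cv3 <- pr_curve(rep(1, 4), c(1, 0, 1, 0))
  expect_identical(nrow(cv3), 1L)
  expect_identical(cv3$precision, 0.5)
})

test_that("top-K validated counts are correct and monotone in K", {
  ranked <- data.frame(gene = c("a", "b", "c"), mirna = "m",
                       score = c(3, 2, 1))
  validated <- data.frame(gene = c("a", "c"), mirna = c("m", "m"))
  expect_identical(unname(count_validated_topk(ranked, validated, 2)), 1L)
  expect_identical(unname(count_validated_topk(ranked, validated, 10)), 2L)
  empty <- data.frame(gene = character(), mirna = character())
  expect_identical(unname(count_validated_topk(ranked, empty, 2)), 0L)
  set.seed(4)
  big <- data.frame(gene = sample(letters, 200, TRUE),
                    mirna = sample(LETTERS[1:5], 200, TRUE), score = runif(200))
  big <- big[!duplicated(paste(big$gene, big$mirna)), ]
  big <- big[order(-big$score), ]
  val <- big[sample.int(nrow(big), 20), c("gene", "mirna")]
  ks <- count_validated_topk(big, val, k = c(5, 20, 50, nrow(big)))
  expect_true(all(diff(ks) >= 0))
  expect_identical(unname(ks[4]), 20L)
})

test_that("correlation baseline ranks anti-correlated pairs first", {
  C <- seed_matrix(matrix(c(1L, 1L, 1L), 3, 1,
                          dimnames = list(c("g1", "g2", "g3"), "m1")))
  mrna <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1), g3 = c(2, 2, 2))
  mirna <- rbind(m1 = c(1, 2, 3))
  colnames(mrna) <- colnames(mirna) <- c("s1", "s2", "s3")
  pb <- pearson_baseline(mrna, mirna, C)
  expect_identical(pb$gene, c("g2", "g1", "g3"))
  expect_equal(pb$r[1:2], c(-1, 1))
  # zero-variance pair is flagged and last
  expect_true(pb$undefined[3])
  expect_error(pearson_baseline(mrna[, 1:2], mirna[, 1:2], C), ">= 3")
})

test_that("mean cross-entropy follows the one-sided definition", {
  expect_identical(mean_cross_entropy(1, 1), 0)
  expect_equal(mean_cross_entropy(1, 0.5), log(2))
  # normal samples contribute nothing, however poor the probability
  expect_identical(mean_cross_entropy(0, 0.01), 0)
  expect_equal(mean_cross_entropy(c(1, 1, 0), c(1, 0.5, 0.9)), log(2) / 3)
  expect_error(mean_cross_entropy(c(1, 0), c(0, 0.5)), "infinite")
  expect_equal(mean_cross_entropy(c(1, 0), c(0, 0.5), clamp = 1e-6),
               -log(1e-6) / 2)
  # the full variant also charges confident false positives
  expect_gt(mean_cross_entropy(c(1, 0), c(0.9, 0.9), full = TRUE),
            mean_cross_entropy(c(1, 0), c(0.9, 0.9)))
})
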