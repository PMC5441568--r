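# Nested LOO ensemble: metric arithmetic (worked examples from printed
# per-class counts), forward selection on planted-truth features, ensemble
# shape/median invariants, leakage control and follow-up scoring.

test_that("evaluate reproduces the worked confusion-count examples", {
  # 26/34 patients and 31/34 controls correct
  labels <- rep(c(1L, -1L), each = 34)
  pred <- c(rep(1L, 26), rep(-1L, 8), rep(-1L, 31), rep(1L, 3))
  m <- evaluate(pred, labels)
  expect_equal(100 * m$accuracy, 83.82, tolerance = 0.005)
  expect_equal(100 * m$sensitivity, 76.47, tolerance = 0.005)
  expect_equal(100 * m$specificity, 91.18, tolerance = 0.005)
  expect_equal(unname(m$confusion), c(26L, 8L, 31L, 3L))
  # 26/33 patients and 14/20 controls correct
  labels2 <- rep(c(1L, -1L), c(33, 20))
  pred2 <- c(rep(1L, 26), rep(-1L, 7), rep(-1L, 14), rep(1L, 6))
  m2 <- evaluate(pred2, labels2)
  expect_equal(100 * m2$accuracy, 75.5, tolerance = 0.05)
  expect_equal(100 * m2$sensitivity, 78.79, tolerance = 0.005)
  expect_equal(100 * m2$specificity, 70.00, tolerance = 0.005)
  # perfectly separated scores give AUC 1
  s <- c(runif(10, 0.5, 1), runif(10, -1, -0.5))
  expect_equal(evaluate(sign(s), rep(c(1L, -1L), each = 10), s)$auc, 1)
  expect_error(evaluate(rep(1L, 4), rep(1L, 4)), "both classes")
})

test_that("balanced classes make accuracy the mean of sens/spec exactly", {
  set.seed(5)
  for (i in 1:20) {
    n <- 2 * sample(5:20, 1)
    labels <- rep(c(1L, -1L), each = n / 2)
    pred <- sample(c(1L, -1L), n, replace = TRUE)
    if (length(unique(pred)) < 1) next
    m <- evaluate(pred, labels)
    expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2, tolerance = 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney statistic (wilcox oracle)", {
  set.seed(8)
  labels <- rep(c(1L, -1L), c(12, 15))
  scores <- rnorm(27) + 0.8 * (labels > 0)
  m <- evaluate(ifelse(scores > 0, 1L, -1L), labels, scores)
  w <- wilcox.test(scores[labels > 0], scores[labels < 0])$statistic
  expect_equal(m$auc, unname(w) / (12 * 15), tolerance = 1e-12)
})

test_that("forward selection recovers planted components and honors anchors", {
  # Oracle-derived selection frequencies over 10 fixed seeds (signal on
  # components 3 and 7, noise anchors 1 and 2): each planted component is
  # selected in >= 90% of seeds, each null component in <= 20%.
  sel <- matrix(0, 10, 8)
  for (s in 1:10) {
    fs <- synthetic_features(n_per_class = 16, k = 8, v = 20,
                             signal = c(3, 7), shift = 3, seed = s)
    clf <- forward_select(fs)
    expect_true(all(c(1L, 2L) %in% clf$selected))
    sel[s, clf$selected] <- 1
  }
  freq <- colMeans(sel)
  expect_gte(freq[3], 0.9)
  expect_gte(freq[7], 0.9)
  expect_true(all(freq[c(4, 5, 6, 8)] <= 0.2))
})

test_that("selection stops at the anchors when they are already perfect", {
  fs <- synthetic_features(n_per_class = 8, k = 6, v = 20,
                           signal = c(1, 2), shift = 6, seed = 2)
  clf <- forward_select(fs)
  expect_identical(clf$selected, c(1L, 2L))
  expect_equal(clf$inner_accuracy, 1)
})

test_that("degenerate training sets are rejected", {
  fs <- synthetic_features(n_per_class = 5, k = 4, v = 10, seed = 3)
  fs$labels[] <- 1L
  expect_error(forward_select(fs), "single class")
  fs2 <- synthetic_features(n_per_class = 1, k = 4, v = 10, seed = 3)
  expect_error(forward_select(fs2), "at least 4")
})

test_that("classification scores are signed probabilities in [-1, 1]", {
  fs <- synthetic_features(n_per_class = 10, k = 4, v = 20,
                           signal = c(1, 2), shift = 2, seed = 4)
  clf <- forward_select(fs)
  s <- classification_score(clf, fs)
  expect_true(all(s >= -1 & s <= 1))
  p <- (s + 1) / 2
  # sign convention: s > 0 iff patient probability > 1/2
  expect_identical(s > 0, p > 0.5)
  # separable training data: patients score positive, controls negative
  expect_gt(mean(s[fs$labels == 1]), 0)
  expect_lt(mean(s[fs$labels == -1]), 0)
})

test_that("the ensemble has the stated shape and median invariants", {
  fs <- synthetic_features(n_per_class = 6, k = 4, v = 15,
                           signal = c(1, 2, 3), shift = 1.5, seed = 6)
  ens <- loo_ensemble(fs)
  n <- 12
  expect_equal(nrow(ens$scores), n)
  expect_equal(unique(ens$scores$n_base), n - 1L)   # one base classifier per training subject
  for (t in seq_len(n)) {
    bs <- ens$base_scores[[t]]
    agg <- ens$scores$aggregated_score[t]
    expect_gte(agg, min(bs)); expect_lte(agg, max(bs))
    expect_true(agg %in% bs)                        # odd count: median is a base score
    expect_equal(ens$scores$predicted_label[t], ifelse(agg > 0, 1L, -1L))
  }
  expect_true(all(vapply(ens$folds, function(f) all(c(1L, 2L) %in% f$selected), logical(1))))
  expect_error(loo_ensemble(synthetic_features(n_per_class = 2, k = 4, v = 10)),
               "at least 6")
})

test_that("no leakage: a subject's features never reach its own fold's training", {
  fs <- synthetic_features(n_per_class = 5, k = 4, v = 12,
                           signal = c(1, 2), shift = 2, seed = 7)
  ens1 <- loo_ensemble(fs)
  fs2 <- fs
  set.seed(99)
  for (cc in 1:4) fs2$blocks[[cc]][3, ] <- rnorm(12)   # corrupt subject 3
  ens2 <- loo_ensemble(fs2)
  # fold 3 excludes subject 3 at training: its selection, parameters and
  # base classifiers must be bit-identical after the corruption ...
  expect_identical(ens1$folds[[3]]$selected, ens2$folds[[3]]$selected)
  expect_identical(ens1$folds[[3]]$params, ens2$folds[[3]]$params)
  expect_identical(ens1$folds[[3]]$inner_accuracy, ens2$folds[[3]]$inner_accuracy)
  # ... while subject 3's own score does change (it is scored on new data)
  expect_false(isTRUE(all.equal(ens1$scores$aggregated_score[3],
                                ens2$scores$aggregated_score[3])))
})

test_that("follow-up scoring reuses each subject's own fold exactly", {
  fs <- synthetic_features(n_per_class = 6, k = 4, v = 15,
                           signal = c(1, 2), shift = 2, seed = 8)
  ens <- loo_ensemble(fs)
  # identical features: follow-up score equals the baseline aggregated score
  fu_same <- fs
  fu_same$sessions <- rep("followup", 12)
  res <- score_followup(ens, fu_same)
  expect_equal(res$followup_score, res$baseline_score, tolerance = 1e-12)
  # a shifted patient moves toward the control side
  fu_shift <- fs
  ctrl_mean <- lapply(fu_shift$blocks, function(B) colMeans(B[fs$labels == -1L, ]))
  for (cc in 1:4) fu_shift$blocks[[cc]][1, ] <- ctrl_mean[[cc]]
  res2 <- score_followup(ens, fu_shift)
  expect_lt(res2$followup_score[1], res2$baseline_score[1])
  unknown <- fs; unknown$subject_ids[1] <- "GHOST"
  expect_error(score_followup(ens, unknown), "GHOST")
})
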