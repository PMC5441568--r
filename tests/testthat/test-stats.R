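# Permutation and association statistics: worked arithmetic, sign-flip
# calibration, least-squares oracles, outlier screening.

test_that("treatment response is the normalized PANSS reduction", {
  expect_equal(treatment_response(82.43, 55.93), 0.3215, tolerance = 1e-4)
  expect_equal(treatment_response(80, 80), 0)
  expect_equal(treatment_response(100, 0), 1)
  expect_equal(treatment_response(c(80, 90), c(40, 90)), c(0.5, 0))
  expect_error(treatment_response(0, 10), "positive")
  expect_error(treatment_response(-5, 10), "positive")
})

test_that("paired permutation test handles flat and planted differences", {
  V <- 200
  pre <- lapply(1:6, function(i) rnorm(V))
  res0 <- paired_perm_test(pre, pre, n_perm = 200, seed = 1)
  expect_true(all(res0$p == 1))                    # all-zero differences
  expect_false(any(res0$mask))
  # sign symmetry: negating differences leaves two-sided p unchanged
  set.seed(2)
  post <- lapply(pre, function(x) x + rnorm(V, 0, 0.5))
  r1 <- paired_perm_test(pre, post, n_perm = 300, seed = 3)
  neg_post <- lapply(seq_along(pre), function(i) 2 * pre[[i]] - post[[i]])
  r2 <- paired_perm_test(pre, neg_post, n_perm = 300, seed = 3)
  expect_equal(r1$p, r2$p)
  expect_true(all(r1$p >= 1 / 301 & r1$p <= 1))
  # planted 1-SD mean shift in a 'blob' of voxels, 13 pairs -> high power
  blob <- 1:40
  set.seed(4)
  pre13 <- lapply(1:13, function(i) rnorm(V))
  post13 <- lapply(pre13, function(x) { x[blob] <- x[blob] + 1; x + rnorm(V, 0, 0.1) })
  rp <- paired_perm_test(pre13, post13, n_perm = 500, seed = 5)
  expect_gte(mean(rp$mask[blob]), 0.8)
  expect_lt(mean(rp$mask[-blob]), 0.2)
  expect_error(paired_perm_test(pre[1:2], post[1:2]), "3 pairs")
  expect_error(paired_perm_test(pre, post[1:3]), "differ")
})

test_that("one-tailed score-decrease permutation behaves at the extremes", {
  b <- seq(0.2, 1, length.out = 10)
  res <- perm_score_decrease(b, b - 0.3, n_perm = 1000, seed = 1)
  expect_equal(res$p, 1 / 1001, tolerance = 1e-12)  # minimum attainable
  res_same <- perm_score_decrease(b, b, n_perm = 1000, seed = 1)
  expect_equal(res_same$p, 1)
  # misclassified filter drops non-positive baselines
  b2 <- c(-0.5, -0.1, b)
  f2 <- c(0, 0, b - 0.3)
  res2 <- perm_score_decrease(b2, f2, n_perm = 500, exclude_misclassified = TRUE, seed = 2)
  expect_equal(res2$n_pairs, 10L)
  expect_error(perm_score_decrease(c(1, 2), c(0, 0)), "unpaired|3 pairs")
  expect_error(perm_score_decrease(c(-1, -1, -1, 1), c(0, 0, 0, 0), n_perm = 10,
                                   exclude_misclassified = TRUE), "3 pairs")
})

test_that("score-decrease p-values are uniform under the null", {
  set.seed(11)
  n_sim <- 200
  p <- vapply(seq_len(n_sim), function(i) {
    d <- rnorm(10)                                  # exchangeable null pairs
    perm_score_decrease(d, rep(0, 10), n_perm = 2000, seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))$statistic
  expect_lt(unname(ks), 0.15)
})

test_that("residualize is an exact least-squares projection", {
  set.seed(3)
  n <- 40
  cov <- data.frame(age = rnorm(n, 30, 8), sex = sample(c("M", "F"), n, TRUE),
                    edu = rnorm(n, 14, 3), ill = rexp(n, 1 / 5))
  y_lin <- 2 + 3 * cov$age
  expect_lt(max(abs(residualize(y_lin, cov))), 1e-8)
  y <- rnorm(n) + 0.5 * cov$age
  r <- residualize(y, cov)
  expect_lt(abs(cor(r, cov$age)), 1e-8)
  expect_lt(abs(cor(r, cov$edu)), 1e-8)
  expect_lt(abs(mean(r)), 1e-10)
  expect_error(residualize(y, data.frame(a = rep(1, n), b = rep(2, n))), "rank")
  expect_error(residualize(rnorm(3), data.frame(a = rnorm(4))), "mismatch")
})

test_that("outlier screen flags displaced points and stays calibrated", {
  x <- seq_len(20)
  expect_length(detect_outliers(x, 2 * x), 0)       # exact line
  y <- 2 * x; y[7] <- y[7] + 10 * 1                 # huge displacement, zero noise elsewhere
  set.seed(5); y <- y + rnorm(20, 0, 0.3)
  expect_identical(detect_outliers(x, y), 7L)
  # calibration: ~5% flagged in pure noise (mean over 100 seeds in [0.5, 2])
  set.seed(6)
  flags <- vapply(1:100, function(i) length(detect_outliers(rnorm(20), rnorm(20))),
                  numeric(1))
  expect_gte(mean(flags), 0.5); expect_lte(mean(flags), 2)
  expect_error(detect_outliers(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(detect_outliers(1:4, 1:4), "n >= 5")
})

test_that("association analysis adjusts covariates and corrects p-values", {
  set.seed(7)
  n <- 20
  cov <- data.frame(age = rnorm(n, 30, 5), sex = sample(c("M", "F"), n, TRUE),
                    edu = rnorm(n, 14, 2), ill = rexp(n, 1 / 6))
  scores <- rnorm(n)
  # response strictly decreasing in score, covariate-free world -> rho = -1
  resp <- data.frame(total = 1 - 0.3 * rank(scores) / n)
  noise_cov <- data.frame(z = rnorm(n))              # irrelevant covariate
  res <- score_response_association(scores, resp, noise_cov, family_size = 4)
  expect_s3_class(res, "icn_association")
  expect_lt(res$rho, -0.9)
  expect_equal(res$p_bonferroni, pmin(1, 4 * res$p_raw))
  # fully monotone, no covariates touched: Spearman is exactly -1
  expect_equal(cor(scores, resp$total, method = "spearman"), -1)
  # with real covariates and 4 measures the family size is recorded
  resp4 <- data.frame(total = rnorm(n), pos = rnorm(n), neg = rnorm(n), gen = rnorm(n))
  res4 <- score_response_association(scores, resp4, cov)
  expect_equal(nrow(res4), 4L)
  expect_equal(attr(res4, "family_size"), 4L)
  expect_true(all(abs(res4$rho) <= 1))
  expect_error(score_response_association(scores[1:3], resp4[1:3, ], cov[1:3, ]),
               "at least 5")
})

test_that("association calibration: null rejection rate near alpha", {
  set.seed(8)
  n_sim <- 200; n <- 20
  rej <- vapply(seq_len(n_sim), function(i) {
    cov <- data.frame(age = rnorm(n), sex = sample(c("M", "F"), n, TRUE))
    s <- rnorm(n); r <- rnorm(n)                    # independent
    res <- score_response_association(s, data.frame(total = r), cov, family_size = 1)
    res$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01); expect_lte(mean(rej), 0.10)
})

test_that("Spearman association is invariant to monotone transforms", {
  set.seed(9)
  n <- 24
  cov <- data.frame(age = rnorm(n))
  s <- rnorm(n)
  r <- -s + rnorm(n, 0, 0.4)
  a1 <- score_response_association(s, data.frame(total = r), cov, family_size = 1)
  # monotone transform of the response before residualization changes the
  # residuals, so invariance is asserted on the unadjusted statistic:
  rr1 <- cor(s, r, method = "spearman")
  rr2 <- cor(s, exp(r), method = "spearman")
  expect_equal(rr1, rr2, tolerance = 1e-12)
  expect_lt(a1$rho, 0)
})
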