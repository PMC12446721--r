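test_that("auc matches the exhaustive pairwise oracle, ties included", {
  # frozen derived example: wins {4>3, 4>2}, losses {1<3, 1<2} -> 0.5
  expect_identical(auc(c(3, 1, 2, 4), c(0, 1, 0, 1)), 0.5)

  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    # integer scores force ties
    scores <- sample.int(6, n, replace = TRUE)
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("auc agrees with an independent ROC implementation", {
  set.seed(7)
  for (i in 1:20) {
    labels <- c(1, 0, rbinom(48, 1, 0.3))
    scores <- sample.int(10, 50, replace = TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(scores, labels), ref)
  }
})

test_that("auc symmetry and monotone invariance", {
  set.seed(11)
  for (i in 1:50) {
    labels <- c(1, 0, rbinom(28, 1, 0.5))
    scores <- rnorm(30)
    a <- auc(scores, labels)
    expect_equal(auc(-scores, labels), 1 - a)
    expect_equal(auc(exp(2 * scores) + 5, labels), a)  # strictly increasing
    expect_equal(auc(rank(scores), labels), a)
  }
})

test_that("auc rejects degenerate input", {
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
  expect_error(auc(c(1, NA), c(1, 0)), "finite")
  expect_error(auc(1:3, c(1, 0)), "equal length")
})

test_that("roc_points endpoints, monotonicity, trapezoid equals auc", {
  set.seed(21)
  for (i in 1:30) {
    labels <- c(1, 0, rbinom(28, 1, 0.4))
    scores <- sample.int(8, 30, replace = TRUE)
    curve <- roc_points(scores, labels)
    expect_equal(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
    expect_equal(c(curve$fpr[nrow(curve)], curve$tpr[nrow(curve)]), c(1, 1))
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= 0))
    area <- sum(diff(curve$fpr) *
                  (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
    expect_equal(area, auc(scores, labels), tolerance = 1e-12)
  }
  # perfectly separated scores pass through (0, 1)
  sep <- roc_points(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  # constant scores: two points, area 0.5
  const <- roc_points(rep(2, 10), rep(c(1, 0), 5))
  expect_equal(nrow(const), 2L)
  expect_equal(auc(rep(2, 10), rep(c(1, 0), 5)), 0.5)
})

test_that("bootstrap_auc is seeded, stratified preserves class counts", {
  scores <- c(rnorm(15, 1), rnorm(45))
  labels <- rep(c(1, 0), c(15, 45))
  b1 <- bootstrap_auc(scores, labels, n_boot = 50, seed = 5)
  b2 <- bootstrap_auc(scores, labels, n_boot = 50, seed = 5)
  expect_identical(b1, b2)
  expect_length(b1, 50L)
  # n_boot = 1 returns the auc of one resample, a valid probability
  one <- bootstrap_auc(scores, labels, n_boot = 1, seed = 2)
  expect_length(one, 1L)
  expect_true(one >= 0 && one <= 1)
  # perfectly separated data: every bootstrap value is exactly 1
  sep_scores <- c(10, 11, 12, 1, 2, 3, 4, 5)
  sep_labels <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_true(all(bootstrap_auc(sep_scores, sep_labels, 100, seed = 1) == 1))
  # simple scheme reports its redraw count
  simple <- bootstrap_auc(scores, labels, 50, seed = 3, scheme = "simple")
  expect_true(is.integer(attr(simple, "n_redrawn")))
})

test_that("bootstrap distribution mean sits near the point estimate", {
  set.seed(31)
  scores <- c(rnorm(50, 1.19), rnorm(450))
  labels <- rep(c(1, 0), c(50, 450))
  boot <- bootstrap_auc(scores, labels, n_boot = 400, seed = 8)
  expect_lt(abs(mean(boot) - auc(scores, labels)), 0.02)
})

test_that("one-sided threshold p-value follows count/(n_boot + 1)", {
  # frozen arithmetic examples
  p <- p_threshold_one_sided(c(rep(0.9, 250), rep(0.7, 750)), 0.8, "below")
  expect_equal(p$p, 250 / 1001)
  expect_false(p$at_floor)
  p_all <- p_threshold_one_sided(rep(0.9, 1000), 0.8, "below")
  expect_equal(p_all$p, 1000 / 1001)
  # zero exceedances floor at 1/(n_boot+1), rendered "<0.001"
  p0 <- p_threshold_one_sided(rep(0.7, 1000), 0.8, "below")
  expect_true(p0$at_floor)
  expect_equal(p0$display, "<0.001")
  expect_equal(p0$p, 1 / 1001)
  # direction = above mirrors with values below threshold
  pa <- p_threshold_one_sided(c(rep(0.7, 300), rep(0.9, 700)), 0.8, "above")
  expect_equal(pa$p, 300 / 1001)
})

test_that("two-sided threshold p-value doubles the smaller tail share", {
  boot <- c(rep(0.75, 600), rep(0.85, 400))
  expect_equal(p_threshold_two_sided(boot, 0.8)$p, 2 * 400 / 1001)
  # all values above threshold: floored small p
  hi <- p_threshold_two_sided(rep(0.9, 1000), 0.8)
  expect_true(hi$at_floor)
  expect_equal(hi$display, "<0.001")
  # median at the threshold: p near 1 (both tail shares about one half)
  mid <- p_threshold_two_sided(c(rep(0.79, 500), rep(0.81, 500)), 0.8)
  expect_equal(mid$p, 1000 / 1001)
  # a value sitting exactly on the threshold counts in both tails: cap at 1
  cap <- p_threshold_two_sided(c(rep(0.79, 500), 0.8, rep(0.81, 500)), 0.8)
  expect_equal(cap$p, 1)
  # symmetric under reflection of the bootstrap values about the threshold
  set.seed(3)
  b <- runif(999, 0.6, 1)
  expect_equal(p_threshold_two_sided(b, 0.8)$p,
               p_threshold_two_sided(1.6 - b, 0.8)$p)
})

test_that("p-values stay inside (0, 1]", {
  set.seed(41)
  for (i in 1:50) {
    b <- runif(sample(1:30, 1))
    for (pv in list(p_threshold_one_sided(b, 0.5),
                    p_threshold_one_sided(b, 0.5, "above"),
                    p_threshold_two_sided(b, 0.5))) {
      expect_gt(pv$p, 0)
      expect_lte(pv$p, 1)
    }
  }
})

test_that("percentile CI uses the linear-interpolation quantile rule", {
  # frozen hand computation under quantile type 7
  ci <- bootstrap_ci(seq(0.1, 1.0, by = 0.1), level = 0.8)
  expect_equal(ci, c(0.19, 0.91))
  expect_equal(bootstrap_ci(rep(0.7, 50)), c(0.7, 0.7))  # zero width
  set.seed(51)
  for (i in 1:200) {
    b <- runif(sample(2:50, 1))
    ci <- bootstrap_ci(b, 0.95)
    expect_lte(ci[1], ci[2])
  }
})

test_that("binormal closed form is recovered, including at AUC 0.8", {
  # binormal model: positives ~ N(d, 1), negatives ~ N(0, 1)
  # => true AUC = pnorm(d / sqrt(2)); d = sqrt(2) qnorm(0.8) gives 0.8
  set.seed(61)
  for (d in c(0.5, sqrt(2) * qnorm(0.8), 2)) {
    n1 <- 600; n0 <- 600
    scores <- c(rnorm(n1, mean = d), rnorm(n0))
    labels <- rep(c(1, 0), c(n1, n0))
    A_true <- pnorm(d / sqrt(2))
    expect_lt(abs(auc(scores, labels) - A_true),
              3 * auc_se(A_true, n1, n0))
  }
})

test_that("roc_test assembles a coherent result record", {
  set.seed(71)
  scores <- c(rnorm(30, 2), rnorm(270))
  labels <- rep(c(1, 0), c(30, 270))
  res <- roc_test(scores, labels, threshold = 0.8, n_boot = 300, seed = 4)
  expect_s3_class(res, "roc_result")
  expect_equal(res$n_positives, 30)
  expect_equal(res$n_negatives, 270)
  expect_equal(res$auc, auc(scores, labels))
  expect_equal(res$ci, bootstrap_ci(res$boot, 0.95))
  expect_lte(res$ci[1], res$auc + 0.1)
  # reproducible under the same seed
  res2 <- roc_test(scores, labels, threshold = 0.8, n_boot = 300, seed = 4)
  expect_equal(res$boot, res2$boot)
  out <- capture.output(print(res))
  expect_match(out[2], "AUCROC \\d\\.\\d{3} \\(\\d\\.\\d{3}, \\d\\.\\d{3}\\)")
})
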