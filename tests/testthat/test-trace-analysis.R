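test_that("ROC frame reproduces hand-computed toy cases", {
  expect_equal(roc_frame(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_frame(rep(2, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  # brute-force over the four positive-negative pairs: 3 wins, 1 loss
  expect_equal(roc_frame(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_frame(1:4, c(1, 1, 1, 1)), "class")
  expect_error(roc_frame(1:3, c(0, 1)), "equal length")
})

test_that("AUC equals the pairwise Mann-Whitney statistic on random samples", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    vals <- sample(round(rnorm(n, 0, 2), 1))  # ties on purpose
    labs <- c(rep(1, 2), rep(0, 2), rbinom(n - 4, 1, 0.5))[seq_len(n)]
    expect_equal(roc_frame(vals, labs)$auc, auc_brute(vals, labs),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(5)
  vals <- rnorm(40); labs <- rbinom(40, 1, 0.4)
  labs[1:2] <- c(0, 1)
  a <- roc_frame(vals, labs)$auc
  expect_equal(roc_frame(exp(vals), labs)$auc, a)
  expect_equal(roc_frame(vals^3, labs)$auc, a)
  expect_equal(roc_frame(rank(vals, ties.method = "average"), labs)$auc, a)
})

test_that("optimal threshold maximizes Youden's J with the largest-cutoff tie rule", {
  ot <- optimal_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(ot$threshold, 2.5)
  expect_equal(ot$J, 1.0)
  # (1.5 -> J = 0.5) and (3.5 -> J = 0.5) tie; largest threshold wins
  ot2 <- optimal_threshold(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(ot2$threshold, 3.5)
  expect_equal(ot2$J, 0.5)
  # identical class distributions carry no information
  ot3 <- optimal_threshold(c(1, 2, 1, 2), c(0, 0, 1, 1))
  expect_equal(ot3$J, 0)
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    vals <- round(rnorm(n), 1)
    labs <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(optimal_threshold(vals, labs)$J, best_J_brute(vals, labs),
                 tolerance = 1e-12)
  }
})

test_that("shuffled labels give chance-level AUC across frames", {
  toy <- generate_labeled_toy(30, 30, separation = 3, seed = 4)
  m <- sapply(1:5, function(j) toy$values + 0.01 * j)
  set.seed(6)
  shuffled <- sample(toy$labels)
  rt <- roc_timecourse(m, shuffled, n_boot = 200, seed = 8)
  expect_lt(abs(mean(rt$auc) - 0.5), 2 * mean(rt$auc_sd))
})

test_that("bootstrap s.d. estimates are stable across seeds and shrink with n", {
  toy <- generate_labeled_toy(40, 40, separation = 1, seed = 12)
  m <- cbind(toy$values, toy$values * 1.1)
  r1 <- roc_timecourse(m, toy$labels, n_boot = 1000, seed = 1)
  r2 <- roc_timecourse(m, toy$labels, n_boot = 1000, seed = 2)
  expect_lt(max(abs(r1$auc_sd - r2$auc_sd) / r1$auc_sd), 0.10)
  # ~ 1/sqrt(n) scaling of the AUC bootstrap s.d.
  sds <- vapply(c(50, 200, 800), function(n) {
    toy <- generate_labeled_toy(n / 2, n / 2, separation = 1, seed = 3)
    rt <- roc_timecourse(matrix(toy$values, ncol = 1), toy$labels,
                         n_boot = 400, seed = 5)
    rt$auc_sd[1L]
  }, numeric(1L))
  expect_true(all(diff(sds) < 0))
  ratios <- sds[-3L] / sds[-1L]
  expect_true(all(ratios > 1.3 & ratios < 3.1))
})

test_that("prediction accuracy matches manual counting", {
  toy <- generate_labeled_toy(5, 5, separation = 50, seed = 2)
  m <- matrix(toy$values, ncol = 1)
  th <- optimal_threshold(toy$values, toy$labels)$threshold
  expect_equal(prediction_accuracy(m, toy$labels, th, frame = 1), 1.0)
  # all-positive predictions on a balanced sample are half right
  expect_equal(prediction_accuracy(m, toy$labels, -Inf, frame = 1), 0.5)
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  labs <- c(0, 0, 1, 0, 0, 1, 1, 0, 1, 1)
  m2 <- matrix(vals, ncol = 1)
  # threshold 5.5: predicted positives {6..10} -> 4 TP + 1 FP; predicted
  # negatives {1..5} -> 4 TN + 1 FN; 8 of 10 correct
  expect_equal(prediction_accuracy(m2, labs, 5.5, frame = 1), 0.8)
})

test_that("hierarchical clustering recovers well-separated trace classes", {
  set.seed(9)
  hi <- matrix(10 * exp(matrix(rnorm(60, 0, 0.1), 6, 10)), 6, 10)
  lo <- matrix(0.2 * exp(matrix(rnorm(40, 0, 0.1), 4, 10)), 4, 10)
  cl <- cluster_traces(rbind(hi, lo), k = 2)
  expect_equal(as.vector(cl), c(rep(1L, 6), rep(2L, 4)))  # 1 = high final level
  # identical traces merge at zero height
  same <- matrix(1, 5, 4)
  tree <- attr(cluster_traces(same, k = 3), "tree")
  expect_equal(max(tree$height), 0)
  expect_equal(as.vector(cluster_traces(same, k = 1)), rep(1L, 5))
  expect_error(cluster_traces(same, k = 6), "exceeds")
})

test_that("peak detection finds the modes of a bimodal mixture", {
  set.seed(14)
  x <- c(rnorm(5000, 0, 0.5), rnorm(5000, 5, 0.5))
  pk <- histogram_peaks(x)
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$position[1L] - 0), 0.2)
  expect_lt(abs(pk$position[2L] - 5), 0.2)
  # single normal: one peak near the mean
  y <- rnorm(2000, 3, 1)
  pk1 <- histogram_peaks(y)
  expect_equal(nrow(pk1), 1L)
  expect_lt(abs(pk1$position - 3), 0.3)
  # oversmoothing collapses structure to one peak
  expect_equal(nrow(histogram_peaks(x, bandwidth = 100)), 1L)
  expect_error(histogram_peaks(rnorm(5)), "at least 10")
})

test_that("peak positions are equivariant under shifts", {
  set.seed(15)
  x <- c(rnorm(2000, 0, 0.4), rnorm(2000, 4, 0.4))
  p0 <- histogram_peaks(x, bandwidth = 0.3)
  p1 <- histogram_peaks(x + 7.5, bandwidth = 0.3)
  expect_equal(p1$position, p0$position + 7.5, tolerance = 1e-8)
})

test_that("peak fold-change is the positive/negative peak position ratio", {
  set.seed(16)
  x <- c(rnorm(4000, 2, 0.2), rnorm(4000, 10, 0.5))
  expect_equal(peak_fold_change(x), 5, tolerance = 0.05)
  # scale invariance
  expect_equal(peak_fold_change(3 * x), peak_fold_change(x),
               tolerance = 1e-6)
  y <- c(rnorm(4000, 1, 0.15), rnorm(4000, 8, 0.5))
  expect_equal(peak_fold_change(y), 8, tolerance = 0.1 * 8)
  expect_error(peak_fold_change(rnorm(2000, 5)), "unimodal")
})

test_that("cumulative exposure integrates traces frame by frame", {
  m <- matrix(1, 2, 4)
  ce <- cumulative_exposure(m, times = c(0, 1, 2, 3))
  expect_equal(ce[1L, ], c(0, 1, 2, 3), ignore_attr = TRUE)
})
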