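test_that("t-test filter keeps strong effects and drops null features", {
  withr::with_seed(1, {
    x <- cbind(strong = c(rnorm(50, 0), rnorm(50, 5)),
               null = rnorm(100),
               const = rep(1, 100))
  })
  y <- rep(c("a", "b"), each = 50)
  res <- ttest_filter(x, y, alpha = 0.05)
  expect_true(1 %in% res$keep)
  expect_false(3 %in% res$keep)          # constant feature excluded
  expect_identical(res$p_value[3], 1)    # flagged degenerate with p = 1
  expect_true(res$degenerate[3])
  # cross-check one column against the reference implementation
  ref <- stats::t.test(x[y == "a", 1], x[y == "b", 1])
  expect_equal(res$p_value[1], ref$p.value, tolerance = 1e-12)
})

test_that("the p < alpha inequality is strict", {
  withr::with_seed(2, x <- matrix(rnorm(40), 20, 2))
  y <- rep(c("a", "b"), 10)
  p <- ttest_filter(x, y)$p_value
  # setting alpha exactly to a feature's p-value must exclude it
  res <- ttest_filter(x, y, alpha = p[1])
  expect_false(1 %in% res$keep)
})

test_that("shrinking alpha never enlarges the survivor set", {
  withr::with_seed(3, x <- matrix(rnorm(50 * 30), 50, 30))
  y <- rep(c("a", "b"), 25)
  alphas <- c(0.5, 0.2, 0.05, 0.01)
  keeps <- lapply(alphas, function(a) ttest_filter(x, y, alpha = a)$keep)
  for (i in seq_len(length(keeps) - 1)) {
    expect_true(all(keeps[[i + 1]] %in% keeps[[i]]))
  }
})

test_that("under the null the survivor fraction is near alpha", {
  # label permutations: survivor fraction ~ Binomial(p = alpha) / p_features
  n <- 60; p_feat <- 400; alpha <- 0.05
  withr::with_seed(4, {
    x <- matrix(rnorm(n * p_feat), n, p_feat)
    frac <- vapply(1:5, function(i) {
      y <- sample(rep(c("a", "b"), n / 2))
      length(ttest_filter(x, y, alpha = alpha)$keep) / p_feat
    }, numeric(1))
  })
  tol <- 3 * sqrt(alpha * (1 - alpha) / (p_feat * 5))
  expect_lt(abs(mean(frac) - alpha), tol + 0.01)
})

test_that("mutual information prefers a label-copy over noise", {
  withr::with_seed(5, {
    y <- rep(c("a", "b"), each = 25)
    x <- cbind(copy = as.numeric(y == "b") + rnorm(50, sd = 1e-3),
               noise = rnorm(50))
  })
  r <- mi_rank(x, y, k = 1)
  expect_identical(r$keep, 1L)
  expect_gt(r$mi[1], r$mi[2])
  # binned estimator agrees on the ranking
  r2 <- mi_rank(x, y, k = 1, estimator = "binned")
  expect_identical(r2$keep, 1L)
})

test_that("mi_rank is deterministic with index tie-breaking", {
  withr::with_seed(6, x <- matrix(rnorm(40), 20, 2))
  x <- cbind(x[, 1], x[, 1], x[, 2])  # identical first two columns
  y <- rep(c("a", "b"), 10)
  r <- mi_rank(x, y, k = 3)
  expect_identical(r$mi[1], r$mi[2])
  # tied identical columns rank by ascending original index
  expect_lt(which(r$keep == 1L), which(r$keep == 2L))
  expect_identical(mi_rank(x, y, k = 0)$keep, integer(0))
  expect_warning(r3 <- mi_rank(x, y, k = 10), "exceeds")
  expect_length(r3$keep, 3)
})

test_that("two-stage selection composes the filter and the ranking", {
  withr::with_seed(7, {
    n <- 80
    informative <- matrix(rnorm(n * 5), n, 5)
    informative[41:80, ] <- informative[41:80, ] + 2.5
    x <- cbind(informative, matrix(rnorm(n * 95), n, 95))
  })
  colnames(x) <- paste0("f", 1:100)
  y <- rep(c("lo", "hi"), each = 40)
  sel <- select_features(x, y, alpha = 0.05, k = 5)
  expect_true(all(sel$selected %in% 1:5))  # informative recovered
  expect_s3_class(sel, "selection_result")
  # MI of the selected, in rank order, is non-increasing
  expect_true(all(diff(sel$mi[sel$selected]) <= 1e-12))
  # alpha = 1 keeps everything (k caps at n subjects)
  sel_all <- select_features(x, y, alpha = 1, k = Inf)
  expect_length(sel_all$selected, 100)
  # tidy() exposes the ledger columns
  td <- tidy(sel)
  expect_identical(nrow(td), 100L)
  expect_identical(sum(td$selected), 5L)
})

test_that("selection is invariant to column permutation up to relabeling", {
  withr::with_seed(8, {
    x <- matrix(rnorm(60 * 10), 60, 10)
    x[31:60, 3] <- x[31:60, 3] + 3
  })
  colnames(x) <- paste0("f", 1:10)
  y <- rep(c("a", "b"), each = 30)
  perm <- sample(10)
  s1 <- select_features(x, y, k = 3)
  s2 <- select_features(x[, perm], y, k = 3,
                        feature_names = colnames(x)[perm])
  expect_setequal(s1$names, s2$names)
})

test_that("empty survivor sets warn and yield empty selections", {
  withr::with_seed(9, x <- matrix(rnorm(20 * 3), 20, 3))
  y <- rep(c("a", "b"), 10)
  expect_warning(sel <- select_features(x, y, alpha = 1e-12), "no feature")
  expect_length(sel$selected, 0)
})

test_that("selection frequencies tally appearances across folds", {
  mk <- function(names) structure(list(selected = seq_along(names),
                                       names = names),
                                  class = "selection_result")
  sels <- c(replicate(25, mk(c("always", "roiA")), simplify = FALSE),
            list(mk("roiB")))
  tf <- tally_frequency(sels)
  expect_identical(tf$count[tf$feature == "always"], 25L)
  expect_identical(tf$count[tf$feature == "roiB"], 1L)
  expect_identical(sum(tf$count), 51L)  # conservation
  expect_identical(nrow(tally_frequency(list())), 0L)
})
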