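test_that("the scalar KELM+ closed form matches hand arithmetic", {
  # n = m = 1: beta = (t - C w / eps) / (w / eps + 1 / C)
  w <- 0.8; t <- 2; C <- 3; eps <- 0.5
  m <- train_kelm_plus(matrix(1, 1, 1), y = matrix(t, 1, 1), C = C,
                       eps = eps, spec_main = kernel_spec("linear"),
                       omega_priv = matrix(w, 1, 1))
  expect_equal(m$beta[1, 1], (t - C * w / eps) / (w / eps + 1 / C))
})

test_that("a zero privileged Gram reduces the weights to C * T", {
  p <- make_problem(n = 8, seed = 20)
  T <- encode_labels(p$y)
  m <- train_kelm_plus(p$x, y = T, C = 2.5, eps = 1,
                       omega_priv = matrix(0, 8, 8))
  expect_equal(m$beta, 2.5 * T, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("ELM+ reduces to beta = H' C T when the privileged map is zero", {
  p <- make_problem(n = 10, d = 3, seed = 21)
  T <- encode_labels(p$y)
  H <- kelmplus:::random_hidden(p$x, 6, 99)
  beta <- crossprod(H, kelmplus:::plus_weights(matrix(0, 10, 10), T,
                                               C = 4, eps = 2))
  expect_equal(beta, crossprod(H, 4 * T), tolerance = 1e-10)
})

test_that("ELM+ training is deterministic under a fixed seed", {
  p <- make_problem(n = 14, d = 3, seed = 22)
  priv <- matrix(rnorm(14 * 2), 14, 2)
  m1 <- train_elm_plus(p$x, priv, p$y, C = 1, eps = 1, L = 10, L_priv = 8,
                       seed = 5)
  m2 <- train_elm_plus(p$x, priv, p$y, C = 1, eps = 1, L = 10, L_priv = 8,
                       seed = 5)
  expect_identical(m1$beta, m2$beta)
})

test_that("ELM+ weights agree with the KKT-system oracle", {
  p <- make_problem(n = 12, d = 3, seed = 23)
  priv <- matrix(rnorm(12 * 4), 12, 4)
  C <- 2; eps <- 0.7
  m <- train_elm_plus(p$x, priv, p$y, C = C, eps = eps, L = 9, L_priv = 7,
                      seed = 3)
  T <- encode_labels(p$y)
  H <- kelmplus:::random_hidden(p$x, 9, 3)
  Hp <- kelmplus:::random_hidden(priv, 7, 4L)
  # oracle: solve the multiplier system with a generic pseudo-inverse, then
  # map multipliers to output weights
  M <- tcrossprod(Hp) / eps + diag(1 / C, 12)
  rhs <- T - (C / eps) * tcrossprod(Hp) %*% matrix(1, 12, ncol(T))
  lambda <- MASS::ginv(M) %*% rhs
  expect_lt(max(abs(m$beta - crossprod(H, lambda))), 1e-6)
})

test_that("KELM+ weights agree with a generic solver over random problems", {
  worst <- 0
  specs <- list(kernel_spec("linear"), kernel_spec("rbf", 0.5))
  for (i in 1:25) {
    n <- 5 + (i %% 6) * 7
    p <- make_problem(n = n, d = 3, m_classes = 2 + i %% 2, seed = 200 + i)
    priv <- matrix(rnorm(n * 4), n, 4)
    spec <- specs[[1 + i %% 2]]
    C <- 10^runif(1, -2, 2); eps <- 10^runif(1, -1, 1)
    m <- train_kelm_plus(p$x, priv, p$y, C = C, eps = eps,
                         spec_main = spec, spec_priv = spec)
    T <- encode_labels(p$y)
    omega <- gram(priv, priv, spec)
    beta_oracle <- MASS::ginv(omega / eps + diag(1 / C, n)) %*%
      (T - (C / eps) * omega %*% matrix(1, n, ncol(T)))
    worst <- max(worst, max(abs(m$beta - beta_oracle)))
  }
  expect_lt(worst, 1e-8)
})

test_that("KELM+ reproduces ELM+ under the explicit-feature correspondence", {
  # linear kernels applied to the ELM+ hidden matrices make the two models
  # identical; this is the module's central correctness property
  p <- make_problem(n = 18, d = 4, seed = 24)
  priv <- matrix(rnorm(18 * 3), 18, 3)
  elm <- train_elm_plus(p$x, priv, p$y, C = 1.5, eps = 0.8, L = 12,
                        L_priv = 10, seed = 9)
  H <- kelmplus:::random_hidden(p$x, 12, 9)
  Hp <- kelmplus:::random_hidden(priv, 10, 10L)
  kel <- train_kelm_plus(H, Hp, p$y, C = 1.5, eps = 0.8,
                         spec_main = kernel_spec("linear"),
                         spec_priv = kernel_spec("linear"))
  xt <- matrix(rnorm(7 * 4), 7, 4)
  Ht <- kelmplus:::random_hidden(xt, 12, 9)
  s1 <- as.matrix(predict(elm, xt)[, elm$classes])
  s2 <- as.matrix(predict(kel, Ht)[, kel$classes])
  expect_lt(max(abs(s1 - s2)), 1e-6)
})

test_that("privileged data are never consulted at test time", {
  p <- make_problem(n = 16, d = 3, seed = 25)
  priv <- matrix(rnorm(16 * 5), 16, 5)
  m <- train_kelm_plus(p$x, priv, p$y, C = 1, eps = 1)
  xt <- matrix(rnorm(12), 4, 3)
  s1 <- predict(m, xt)
  rm(priv)                       # privileged table gone after training
  s2 <- predict(m, xt)
  expect_identical(s1, s2)
  expect_false(any(grepl("priv", names(m))))  # model retains no PI data
})

test_that("KELM+ prediction is deterministic and kernel-driven", {
  p <- make_problem(n = 10, seed = 26)
  priv <- matrix(rnorm(10 * 2), 10, 2)
  m <- train_kelm_plus(p$x, priv, p$y, C = 2, eps = 2)
  xt <- matrix(rnorm(9), 3, 3)
  expect_identical(predict(m, xt), predict(m, xt))
  expect_error(predict(m, matrix(0, 1, 7)), "dimensions differ")
  expect_error(train_kelm_plus(p$x, priv[1:5, ], p$y), "row-aligned")
})

test_that("KELM and KELM+ reach perfect training accuracy when separable", {
  d <- generate_separable(20, dim = 3, separation = 8, seed = 27)
  priv <- d$x + matrix(rnorm(120, sd = 0.1), 40, 3)
  mk <- train_kelm(d$x, d$y, C = 100)
  mp <- train_kelm_plus(d$x, priv, d$y, C = 100, eps = 1)
  expect_equal(mean(predict(mk, d$x)$.class == d$y), 1)
  expect_equal(mean(predict(mp, d$x)$.class == d$y), 1)
})
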