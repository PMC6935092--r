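# Small synthetic six-table cohort for ensemble tests, built once per file.
ens_fixture <- function(n_per = 12, d_eff = 2.5, seed = 31) {
  spec <- synthetic_spec(n_per_grade = n_per, grades = c(1, 2),
                         effect_size = d_eff, seed = seed)
  cohort <- generate_cohort(spec)
  list(feats = prepare_features(cohort), y = cohort$meta$grade)
}

test_that("the default configuration trains five members", {
  fx <- ens_fixture()
  cfg <- ensemble_config(alpha = 0.2)
  fit <- train_ensemble(fx$feats, fx$y, cfg)
  expect_length(fit$members, 5)
  expect_setequal(names(fit$members),
                  c("WMV", "CSFV", "Thickness", "Area", "Network"))
  pred <- predict(fit, fx$feats$GMV)
  expect_true(all(pred$.class %in% c("1", "2")))
  expect_identical(nrow(pred), length(fx$y))
  # per-member votes exposed
  expect_true(all(paste0("vote_", names(fit$members)) %in% names(pred)))
})

test_that("any feature type can serve as the main feature", {
  fx <- ens_fixture(n_per = 10)
  cfg <- ensemble_config(main = "Thickness", pi_types = c("GMV", "CSFV"),
                         alpha = 0.2)
  fit <- train_ensemble(fx$feats, fx$y, cfg)
  expect_length(fit$members, 2)
  pred <- predict(fit, fx$feats$Thickness)
  expect_identical(nrow(pred), 20L)
})

test_that("a single-PI ensemble is allowed and degenerate ties impossible", {
  fx <- ens_fixture(n_per = 10)
  cfg <- ensemble_config(pi_types = "WMV", alpha = 0.2)
  fit <- train_ensemble(fx$feats, fx$y, cfg)
  expect_length(fit$members, 1)
})

test_that("configuration invariants are enforced", {
  expect_error(ensemble_config(main = "GMV", pi_types = c("GMV", "WMV")),
               "cannot also be privileged")
  expect_error(ensemble_config(pi_types = character()), "at least one")
  fx <- ens_fixture(n_per = 8)
  expect_error(train_ensemble(fx$feats["GMV"], fx$y, ensemble_config()),
               "missing feature table")
  expect_error(train_ensemble(fx$feats, rep(1, length(fx$y)),
                              ensemble_config()), "two classes")
})

test_that("majority vote fuses member labels; ties break by summed score", {
  # direct enumeration oracle on synthetic vote patterns
  votes <- c("A", "A", "A", "B", "B")
  tab <- table(factor(votes, levels = c("A", "B")))
  expect_identical(names(tab)[which.max(tab)], "A")
  # 3-class tie (A, A, B, B, C): resolved among {A, B} by summed score
  classes <- c("A", "B", "C")
  votes <- c("A", "A", "B", "B", "C")
  scores <- c(A = 1.2, B = 2.0, C = 9)  # C ineligible despite top score
  tab <- table(factor(votes, levels = classes))
  top <- names(tab)[tab == max(tab)]
  expect_identical(top[which.max(scores[top])], "B")
})

test_that("ensemble prediction consumes only the main feature table", {
  fx <- ens_fixture(n_per = 10)
  fit <- train_ensemble(fx$feats, fx$y, ensemble_config(alpha = 0.2))
  p1 <- predict(fit, fx$feats$GMV)
  fx$feats[c("WMV", "CSFV", "Thickness", "Area", "Network")] <- NULL
  p2 <- predict(fit, fx$feats$GMV)
  expect_identical(p1, p2)
})

test_that("ensemble accuracy is no worse than the worst member", {
  fx <- ens_fixture(n_per = 12, d_eff = 1.2, seed = 33)
  fit <- train_ensemble(fx$feats, fx$y, ensemble_config(alpha = 0.2))
  pred <- predict(fit, fx$feats$GMV)
  acc_members <- vapply(names(fit$members), function(pt)
    mean(pred[[paste0("vote_", pt)]] == as.character(fx$y)), numeric(1))
  acc_ens <- mean(pred$.class == as.character(fx$y))
  expect_gte(acc_ens, min(acc_members))
})

test_that("tuning picks the grid point with the best inner-CV accuracy", {
  fx <- ens_fixture(n_per = 9, d_eff = 2, seed = 34)
  cfg <- ensemble_config(pi_types = "WMV", alpha = 0.2,
                         c_grid = c(0.01, 1), eps_grid = c(1),
                         tune_folds = 3, seed = 2)
  tuned <- tune_hyperparameters(fx$feats, fx$y, cfg)
  expect_named(tuned, "WMV")
  expect_true(tuned$WMV$C %in% cfg$c_grid)
  # exhaustive re-scan oracle: every grid point's accuracy <= chosen one
  rescan <- vapply(cfg$c_grid, function(C) {
    cfg2 <- cfg; cfg2$c_grid <- C; cfg2$C <- C
    tune_hyperparameters(fx$feats, fx$y, cfg2)$WMV$acc
  }, numeric(1))
  # singleton grids return unchanged without an accuracy estimate
  expect_true(all(is.na(rescan)))
  full <- vapply(cfg$c_grid, function(C) {
    cfg2 <- cfg; cfg2$c_grid <- c(C, C)  # force evaluation
    tune_hyperparameters(fx$feats, fx$y, cfg2)$WMV$acc
  }, numeric(1))
  expect_equal(tuned$WMV$acc, max(full))
})

test_that("stratified folds balance classes within one subject", {
  y <- rep(c("a", "b"), c(23, 17))
  folds <- kelmplus:::stratified_folds(y, n_folds = 5, seed = 4)
  for (f in 1:5) {
    na <- sum(y[folds == f] == "a")
    nb <- sum(y[folds == f] == "b")
    expect_lte(abs(na - 23 / 5), 1)
    expect_lte(abs(nb - 17 / 5), 1)
  }
  expect_error(kelmplus:::stratified_folds(rep(c("a", "b"), c(3, 20)), 5),
               "fewer members")
  # deterministic under a fixed seed
  expect_identical(folds, kelmplus:::stratified_folds(y, 5, seed = 4))
})
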