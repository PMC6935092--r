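test_that("the worked confusion table reproduces all seven metrics", {
  # TP = 3, FP = 1, TN = 4, FN = 2 (positive = "p")
  y_true <- c(rep("p", 5), rep("n", 5))
  y_pred <- c("p", "p", "p", "n", "n", "p", "n", "n", "n", "n")
  m <- confusion_metrics(y_true, y_pred, positive = "p")
  expect_equal(m$SEN, 0.6)
  expect_equal(m$SPC, 0.8)
  expect_equal(m$ACC, 0.7)
  expect_equal(m$PPV, 0.75)
  expect_equal(m$NPV, 2 / 3)
  expect_equal(m$YI, 0.4)
  expect_equal(m$F1, 2 / 3)
})

test_that("perfect prediction gives all-one metrics", {
  m <- confusion_metrics(c("p", "n", "p"), c("p", "n", "p"), "p")
  expect_equal(unlist(m), c(ACC = 1, SEN = 1, SPC = 1, YI = 1, PPV = 1,
                            NPV = 1, F1 = 1))
})

test_that("zero-denominator metrics are undefined, not zero", {
  m <- confusion_metrics(c("p", "p", "n"), c("n", "n", "n"), "p")
  expect_equal(m$SEN, 0)
  expect_true(is.na(m$PPV))
  expect_true(is.na(m$F1))
  expect_error(confusion_metrics(character(0), character(0), "p"),
               "non-empty")
  expect_error(confusion_metrics(c("p"), c("p", "n"), "p"), "equal-length")
})

test_that("metric identities hold on random confusion tables", {
  withr::with_seed(40, {
    for (i in 1:300) {
      counts <- rmultinom(1, size = sample(4:60, 1), prob = runif(4))
      y_true <- rep(c("p", "p", "n", "n"), counts)
      y_pred <- rep(c("p", "n", "p", "n"), counts)
      if (length(y_true) == 0) next
      m <- confusion_metrics(y_true, y_pred, "p")
      if (!is.na(m$YI)) expect_equal(m$YI, m$SEN + m$SPC - 1)
      if (!is.na(m$F1)) {
        expect_equal(m$F1, 2 * m$PPV * m$SEN / (m$PPV + m$SEN))
      }
      expect_true(all(unlist(m[c("ACC", "SEN", "SPC", "PPV", "NPV", "F1")]) >=
                        0, na.rm = TRUE))
    }
  })
})

# One small CV run shared by the protocol tests below.
cv_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      spec <- synthetic_spec(n_per_grade = 10, grades = c(1, 2),
                             effect_size = 2, seed = 50)
      cohort <- generate_cohort(spec)
      feats <- prepare_features(cohort)
      val <<- list(
        feats = feats, y = cohort$meta$grade,
        report = repeated_stratified_cv(
          feats, cohort$meta$grade, ensemble_config(alpha = 0.2),
          n_folds = 5, n_repeats = 2, seed = 7))
    }
    val
  }
})

test_that("the CV report has the expected shape and determinism", {
  fx <- cv_fixture()
  r <- fx$report
  expect_s3_class(r, "evaluation_report")
  # fold count = folds x repeats, two models, seven metrics
  expect_identical(nrow(r$metrics), 5L * 2L * 2L * 7L)
  expect_identical(r$positive, "2")  # higher grade is the positive class
  # identical seed reproduces the report exactly
  r2 <- repeated_stratified_cv(fx$feats, fx$y,
                               ensemble_config(alpha = 0.2),
                               n_folds = 5, n_repeats = 2, seed = 7)
  expect_identical(r$metrics, r2$metrics)
  expect_identical(r$frequency, r2$frequency)
})

test_that("mean Youden index equals mean SEN + mean SPC - 1", {
  s <- cv_fixture()$report$summary
  for (mod in unique(s$model)) {
    g <- function(met) s$mean[s$model == mod & s$metric == met]
    expect_equal(g("YI"), g("SEN") + g("SPC") - 1, tolerance = 1e-12)
  }
})

test_that("selection frequencies are capped by folds x repeats", {
  r <- cv_fixture()$report
  expect_true(all(r$frequency$count <= r$n_folds * r$n_repeats))
  expect_true(all(r$frequency$count >= 1))
  expect_setequal(unique(r$frequency$feature_type),
                  c("GMV", "WMV", "CSFV", "Thickness", "Area", "Network"))
})

test_that("the discriminative report ranks ROI and network lists", {
  r <- cv_fixture()$report
  d <- discriminative_report(r, top_n = 10)
  expect_setequal(unique(d$list), c("roi", "network"))
  for (l in unique(d$list)) {
    counts <- d$count[d$list == l]
    expect_lte(length(counts), 10)
    expect_true(all(diff(counts) <= 0))  # non-increasing frequencies
  }
  # top_n larger than the ledger returns the full ledger
  d_all <- discriminative_report(r, top_n = 1e6)
  expect_identical(nrow(d_all[d_all$list == "network", ]),
                   nrow(r$frequency[r$frequency$feature_type == "Network", ]))
})

test_that("tidy, glance and autoplot expose the report", {
  r <- cv_fixture()$report
  td <- tidy(r)
  expect_identical(names(td), c("repeat_", "fold", "model", "metric",
                                "value"))
  gl <- glance(r)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("ACC", "YI", "F1", "n_folds") %in% names(gl)))
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(plot_selection_frequency(r), "ggplot")
})

test_that("classes smaller than the fold count are rejected", {
  spec <- synthetic_spec(n_per_grade = 3, grades = c(1, 2), seed = 1)
  cohort <- generate_cohort(spec)
  feats <- prepare_features(cohort)
  expect_error(repeated_stratified_cv(feats, cohort$meta$grade,
                                      ensemble_config(), n_folds = 5,
                                      n_repeats = 1),
               "fewer members")
})
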