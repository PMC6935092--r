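# Evaluation protocol: repeated stratified five-fold cross-validation with
# seven confusion-matrix metrics (ACC, SEN, SPC, YI, PPV, NPV, F1), reported
# as mean +/- SD over all fold-level values, plus a ledger of how often each
# feature was selected across folds. Everything fitted (selection, EKM,
# tuning, classifiers) is fitted inside each training fold only.

METRIC_NAMES <- c("ACC", "SEN", "SPC", "YI", "PPV", "NPV", "F1")

#' Binary confusion-matrix metrics
#'
#' Computes accuracy, sensitivity, specificity, Youden index
#' (SEN + SPC - 1), positive/negative predictive value and F1
#' (2 * PPV * SEN / (PPV + SEN)). A metric with a zero denominator is
#' undefined and reported as `NA` (never coerced to 0); aggregation then
#' skips it.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive The positive class (by convention here, the higher
#'   blood-pressure grade).
#' @return One-row tibble with the seven metrics in `[0, 1]`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be equal-length and non-empty",
         call. = FALSE)
  }
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- frac(tp, tp + fn)
  spc <- frac(tn, tn + fp)
  ppv <- frac(tp, tp + fp)
  npv <- frac(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sen) || ppv + sen == 0) NA_real_ else
    2 * ppv * sen / (ppv + sen)
  tibble::tibble(ACC = (tp + tn) / length(y_true),
                 SEN = sen, SPC = spc, YI = sen + spc - 1,
                 PPV = ppv, NPV = npv, F1 = f1)
}

#' Repeated stratified cross-validation of the LUPI ensemble
#'
#' For each repeat, subjects are split into stratified folds; within each
#' fold the full pipeline — feature selection, empirical kernel mapping,
#' optional tuning, KELM+ ensemble training — is fitted on the training
#' split and scored on the held-out split. A single-feature KELM on the
#' main feature type (same selection + EKM) is evaluated alongside as the
#' baseline. Deterministic given `seed`.
#'
#' @param tables Named list of row-aligned feature tables/matrices covering
#'   the configured feature types.
#' @param y Class labels (two classes; the "positive" class defaults to the
#'   higher label, e.g. the higher blood-pressure grade).
#' @param config An [ensemble_config()].
#' @param n_folds,n_repeats Protocol shape (default 5 x 5 = 25 fold fits).
#' @param seed Integer seed; fold assignments derive from it.
#' @param positive Positive class for the metrics.
#' @return An `evaluation_report`: `metrics` (long tibble: repeat, fold,
#'   model, metric, value), `summary` (mean/sd per model x metric),
#'   `frequency` (per feature type, selection counts across the
#'   `n_folds * n_repeats` fits), plus the config, seed and positive class.
#' @export
repeated_stratified_cv <- function(tables, y, config = ensemble_config(),
                                   n_folds = 5, n_repeats = 5, seed = 1,
                                   positive = NULL) {
  mats <- as_feature_matrices(tables)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    stop("the evaluation protocol is defined for binary tasks", call. = FALSE)
  }
  positive <- positive %||% classes[length(classes)]
  rows <- list()
  selections <- stats::setNames(
    rep(list(list()), length(c(config$main, config$pi_types))),
    c(config$main, config$pi_types))
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(y, n_folds = n_folds,
                              seed = seed * 1000L + r)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- train_ensemble(lapply(mats, function(m) m[tr, , drop = FALSE]),
                            y[tr], config)
      x_test <- mats[[config$main]][!tr, , drop = FALSE]
      pred <- predict(fit, x_test)
      m_ens <- confusion_metrics(y[!tr], pred$.class, positive)
      # baseline: plain KELM on the selected main features, no empirical
      # kernel map — the usual single-feature reference
      kelm_fit <- train_kelm(
        mats[[config$main]][tr, fit$main_idx, drop = FALSE],
        y[tr], C = config$C, spec = config$spec_kelm, classes = classes)
      pred_k <- predict(kelm_fit, x_test[, fit$main_idx, drop = FALSE])
      m_kelm <- confusion_metrics(y[!tr], pred_k$.class, positive)
      rows[[length(rows) + 1]] <- dplyr::bind_rows(
        dplyr::mutate(m_ens, model = "ensemble"),
        dplyr::mutate(m_kelm, model = "kelm_main")) |>
        dplyr::mutate(repeat_ = r, fold = f)
      selections[[config$main]] <-
        c(selections[[config$main]], list(fit$main_selection))
      for (pt in names(fit$members)) {
        selections[[pt]] <-
          c(selections[[pt]], list(fit$members[[pt]]$pi_selection))
      }
    }
  }
  metrics <- dplyr::bind_rows(rows) |>
    tidyr::pivot_longer(dplyr::all_of(METRIC_NAMES),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("repeat_", "fold", "model", "metric", "value")
  summary <- metrics |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value[!is.na(.data$value)]),
                     n_defined = sum(!is.na(.data$value)),
                     .groups = "drop")
  frequency <- dplyr::bind_rows(lapply(names(selections), function(ft) {
    tf <- tally_frequency(selections[[ft]])
    if (nrow(tf) > 0) dplyr::mutate(tf, feature_type = ft, .before = 1)
  }))
  structure(list(metrics = metrics, summary = summary,
                 frequency = frequency, selections = selections,
                 config = config, n_folds = n_folds, n_repeats = n_repeats,
                 seed = seed, positive = positive, classes = classes),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "# evaluation_report: %d x %d stratified CV, positive class '%s'\n",
    x$n_repeats, x$n_folds, x$positive))
  s <- x$summary[x$summary$model == "ensemble", ]
  s <- s[match(METRIC_NAMES, s$metric), ]
  cat("# ensemble (mean +/- sd, %):\n")
  cat(paste(sprintf("  %-3s %5.2f +/- %5.2f", s$metric, 100 * s$mean,
                    100 * s$sd), collapse = "\n"), "\n")
  invisible(x)
}

#' Rank the most discriminative features by selection frequency
#'
#' Mirrors the usual "top-N most discriminative features" table: regional
#' (ROI) features from the five per-ROI tables and network ("correlative")
#' edge features are ranked separately by how often they were selected
#' across the cross-validation fits. Ties are broken by feature name.
#'
#' @param report An `evaluation_report`.
#' @param top_n Rows per list (default 10). Larger than the ledger returns
#'   the full ledger.
#' @return Tibble with `list` (`"roi"`/`"network"`), `rank`, `feature_type`,
#'   `feature` and `count` (non-increasing within each list).
#' @export
discriminative_report <- function(report, top_n = 10) {
  freq <- report$frequency
  take <- function(d, label) {
    d <- d[order(-d$count, d$feature), ]
    d <- utils::head(d, top_n)
    if (nrow(d) == 0) return(NULL)
    dplyr::mutate(d, list = label, rank = dplyr::row_number(), .before = 1)
  }
  dplyr::bind_rows(
    take(freq[freq$feature_type != "Network", , drop = FALSE], "roi"),
    take(freq[freq$feature_type == "Network", , drop = FALSE], "network"))
}
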