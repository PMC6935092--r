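# Two-stage filter feature selection: a two-sample t-test keeps features
# with p < alpha, then mutual information with the class label ranks the
# survivors and the top k are retained. Both stages are deterministic given
# the data; selection is always fitted on training folds only.

#' Two-sample t-test filter
#'
#' Welch's (default) or pooled-variance two-sample t-test for every feature
#' column, keeping features with p strictly below `alpha`. A feature constant
#' within both groups carries no evidence and is assigned p = 1 (flagged
#' degenerate).
#'
#' @param x Numeric matrix or data frame, subjects x features.
#' @param y Binary labels (two levels present, each with >= 2 subjects).
#' @param alpha Significance threshold; features with p < alpha survive
#'   (strict inequality).
#' @param var_equal Use the pooled-variance statistic instead of Welch's.
#' @return List with `keep` (integer indices of survivors, ascending),
#'   `p_value` (per feature) and `degenerate` (logical per feature).
#' @export
ttest_filter <- function(x, y, alpha = 0.05, var_equal = FALSE) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) {
    stop("ttest_filter requires exactly two classes present", call. = FALSE)
  }
  y <- droplevels(y)
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) {
    stop("each class needs at least two subjects", call. = FALSE)
  }
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- colSums((x[g1, , drop = FALSE] -
                   matrix(m1, n1, ncol(x), byrow = TRUE))^2) / (n1 - 1)
  v2 <- colSums((x[!g1, , drop = FALSE] -
                   matrix(m2, n2, ncol(x), byrow = TRUE))^2) / (n2 - 1)
  degenerate <- v1 == 0 & v2 == 0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, ncol(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- 1
  p[!degenerate & !is.finite(p)] <- 1  # zero spread in one group only
  list(keep = which(p < alpha), p_value = unname(p),
       degenerate = unname(degenerate))
}

# Nearest-neighbor mutual information between a continuous feature and a
# discrete label (Ross 2014): for each sample, the distance to its kth
# nearest neighbor within its own class sets a radius; counting how many
# samples of any class fall inside relates within-class to marginal density.
# I(x; y) = psi(N) - <psi(N_y)> + psi(k) - <psi(m_i)>, clamped at 0.
# Deterministic: no tie-breaking noise is added, so identical columns get
# identical scores (ties are then broken by column index in mi_rank()).
mi_knn_discrete <- function(x, y, k = 3L) {
  n <- length(x)
  classes <- split(seq_len(n), y)
  xs <- sort(x)
  m_i <- numeric(n)
  psi_ny <- numeric(n)
  ok <- rep(TRUE, n)
  for (idx in classes) {
    nc <- length(idx)
    if (nc < 2) { ok[idx] <- FALSE; next }
    kk <- min(k, nc - 1L)
    xc <- sort(x[idx])
    # kth-NN distance within class for each member, via the sorted values
    for (ii in idx) {
      d <- abs(xc - x[ii])
      r <- sort.int(d, partial = kk + 1L)[kk + 1L]  # exclude self (d = 0)
      # count of all samples strictly inside the radius (excluding self)
      cnt <- sum(abs(xs - x[ii]) < r) - 1L
      m_i[ii] <- max(cnt, 1L)
      psi_ny[ii] <- digamma(nc)
    }
  }
  if (!any(ok)) return(0)
  val <- digamma(n) - mean(psi_ny[ok]) + digamma(min(k, max(1L, n - 1L))) -
    mean(digamma(m_i[ok]))
  max(val, 0)
}

mi_binned <- function(x, y, bins = 8L) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE)
  qs <- unique(qs)
  if (length(qs) < 2) return(0)
  xb <- cut(x, breaks = qs, include.lowest = TRUE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Mutual information of each feature with the class label
#'
#' @param x Numeric matrix, subjects x features.
#' @param y Class labels.
#' @param estimator `"knn"` (nearest-neighbor estimator for continuous
#'   features, default) or `"binned"` (equal-frequency 8-bin plug-in).
#' @param k Neighbor count for the knn estimator.
#' @return Numeric vector of non-negative MI estimates (nats).
#' @export
mi_scores <- function(x, y, estimator = c("knn", "binned"), k = 3L) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x)
  y <- as.factor(y)
  f <- if (estimator == "knn") {
    function(col) mi_knn_discrete(col, y, k = k)
  } else {
    function(col) mi_binned(col, y)
  }
  apply(x, 2, f)
}

#' Rank features by mutual information and keep the top k
#'
#' Ties are broken by ascending original column index, so the ranking is
#' fully deterministic.
#'
#' @inheritParams mi_scores
#' @param k Number of features to keep; if it exceeds the number available,
#'   all are returned with a warning.
#' @param estimator Passed to [mi_scores()].
#' @return List with `keep` (indices ordered by decreasing MI) and `mi`
#'   (score per input column).
#' @export
mi_rank <- function(x, y, k, estimator = "knn") {
  x <- as.matrix(x)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (ncol(x) == 0 || k == 0) {
    return(list(keep = integer(0), mi = numeric(ncol(x))))
  }
  if (k > ncol(x)) {
    warning("k exceeds available features; returning all ", ncol(x))
    k <- ncol(x)
  }
  mi <- mi_scores(x, y, estimator = estimator)
  ord <- order(-mi, seq_along(mi))
  list(keep = ord[seq_len(k)], mi = unname(mi))
}

#' Two-stage feature selection
#'
#' Composition of [ttest_filter()] (p < alpha) and [mi_rank()] (top k among
#' survivors). If no feature survives the t-test, an empty selection is
#' returned with a warning and downstream callers fall back to all features.
#'
#' @inheritParams ttest_filter
#' @param k Post-ranking dimensionality; default `NULL` means
#'   `min(#survivors, #subjects)`.
#' @param estimator MI estimator, see [mi_scores()].
#' @param feature_names Optional names recorded in the result.
#' @return A `selection_result`: list with `selected` (original column
#'   indices, MI-ranked), `names`, `p_value`, `mi` (NA for features that
#'   failed the t-test), `alpha`, `k`.
#' @export
select_features <- function(x, y, alpha = 0.05, k = NULL, estimator = "knn",
                            var_equal = FALSE, feature_names = colnames(x)) {
  x <- as.matrix(x)
  tt <- ttest_filter(x, y, alpha = alpha, var_equal = var_equal)
  mi_full <- rep(NA_real_, ncol(x))
  if (length(tt$keep) == 0) {
    warning("no feature survived the t-test filter at alpha = ", alpha)
    sel <- integer(0)
    k_used <- 0L
  } else {
    k_used <- if (is.null(k)) min(length(tt$keep), nrow(x)) else
      min(k, length(tt$keep))
    mr <- mi_rank(x[, tt$keep, drop = FALSE], y, k = k_used,
                  estimator = estimator)
    mi_full[tt$keep] <- mr$mi
    sel <- tt$keep[mr$keep]
  }
  structure(list(selected = sel,
                 names = if (!is.null(feature_names)) feature_names[sel],
                 p_value = tt$p_value, mi = mi_full,
                 alpha = alpha, k = k_used),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("# selection_result: %d of %d features (alpha = %g, k = %d)\n",
              length(x$selected), length(x$p_value), x$alpha, x$k))
  invisible(x)
}

#' Tally how often each feature was selected across folds
#'
#' @param selections List of `selection_result` objects (e.g., one per
#'   fold x repeat of a cross-validation run).
#' @param feature_names Names used when a selection lacks them.
#' @return Tibble with `feature` and `count`, sorted by decreasing count
#'   then name. The maximum attainable count is `length(selections)`.
#' @export
tally_frequency <- function(selections, feature_names = NULL) {
  picked <- unlist(lapply(selections, function(s) {
    s$names %||% as.character(s$selected)
  }))
  if (length(picked) == 0) {
    return(tibble::tibble(feature = character(0), count = integer(0)))
  }
  tab <- table(picked)
  out <- tibble::tibble(feature = names(tab), count = as.integer(tab))
  out[order(-out$count, out$feature), ]
}
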