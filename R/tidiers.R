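# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Long tibble: `repeat_`, `fold`, `model`, `metric`, `value`.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$metrics

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param model Which model to summarize (`"ensemble"` or `"kelm_main"`).
#' @param ... Unused.
#' @return One-row tibble of mean metrics (proportions in `[0, 1]`) plus
#'   protocol shape.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, model = "ensemble", ...) {
  s <- x$summary[x$summary$model == model, ]
  out <- tibble::as_tibble(as.list(stats::setNames(s$mean, s$metric)))
  out <- out[, intersect(METRIC_NAMES, names(out))]
  out$n_folds <- x$n_folds
  out$n_repeats <- x$n_repeats
  out$positive <- x$positive
  out
}

#' Tidy a feature-selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return Tibble with per-feature `index`, `name`, `p_value`, `mi`,
#'   `selected` flag and MI `rank` (NA if unselected).
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  p <- length(x$p_value)
  rank <- rep(NA_integer_, p)
  rank[x$selected] <- seq_along(x$selected)
  tibble::tibble(index = seq_len(p),
                 name = x$names[match(seq_len(p), x$selected)],
                 p_value = x$p_value, mi = x$mi,
                 selected = seq_len(p) %in% x$selected,
                 rank = rank)
}

#' Per-fold metric distributions of an evaluation report
#'
#' Boxplots of the fold-level values of the seven metrics, by model.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- object$metrics
  d$metric <- factor(d$metric, levels = METRIC_NAMES)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value,
                                  fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_continuous(labels = function(v) 100 * v) +
    ggplot2::labs(x = NULL, y = "fold-level value (%)",
                  title = sprintf("%d x %d stratified CV",
                                  object$n_repeats, object$n_folds)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a morphometric network
#'
#' @param object A `morph_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot morph_network
#' @export
autoplot.morph_network <- function(object, ...) {
  m <- object$matrix
  d <- tibble::tibble(
    from = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    to = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    weight = as.vector(m))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Selection-frequency bar chart
#'
#' Plots the top-ranked discriminative features of an evaluation report.
#'
#' @param report An `evaluation_report`.
#' @param top_n Features per list.
#' @return A ggplot object.
#' @export
plot_selection_frequency <- function(report, top_n = 10) {
  d <- discriminative_report(report, top_n = top_n)
  d$feature <- stats::reorder(paste0(d$feature, " (", d$feature_type, ")"),
                              d$count)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~list, scales = "free_y") +
    ggplot2::labs(x = sprintf("selection frequency (max %d)",
                              report$n_folds * report$n_repeats),
                  y = NULL) +
    ggplot2::theme_minimal()
}
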