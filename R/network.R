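# Single-subject morphometric brain networks. Each ROI's cortical thickness
# is summarized as a Gaussian N(mean, variance) over the ROI's vertices; the
# association between two ROIs is exp(-KLsym), where KLsym is the symmetrized
# closed-form Kullback-Leibler divergence between their Gaussians. The
# resulting 78 x 78 similarity matrix is symmetric with unit diagonal and
# entries in (0, 1]; its strict upper triangle (row-major) is the subject's
# 3003-dimensional network feature vector.

#' Build a per-subject inter-ROI thickness network
#'
#' @param stats One subject's thickness summaries: a data frame with columns
#'   `roi`, `thick_mean` (mm) and `thick_var` (mm^2), one row per included
#'   ROI. For `method = "pearson_vertex"` pass instead a named list of
#'   equal-length vertex-level thickness vectors, one per ROI.
#' @param method `"gaussian_kl"` (default; consumes mean + variance) or
#'   `"pearson_vertex"` (Pearson correlation of vertex-level vectors).
#' @param rois ROI names to include, in order; defaults to the 78 cortical
#'   regions.
#' @return A `morph_network`: list with `roi_names`, symmetric `matrix`
#'   (unit diagonal) and `method`.
#' @examples
#' s <- tibble::tibble(roi = select_cortical_rois(),
#'                     thick_mean = rnorm(78, 2.5, 0.2),
#'                     thick_var = runif(78, 0.05, 0.2))
#' net <- build_network(s)
#' dim(net$matrix)  # 78 78
#' @export
build_network <- function(stats, method = c("gaussian_kl", "pearson_vertex"),
                          rois = select_cortical_rois()) {
  method <- match.arg(method)
  if (method == "gaussian_kl") {
    if (!all(c("roi", "thick_mean", "thick_var") %in% names(stats))) {
      stop("`stats` needs columns roi, thick_mean, thick_var", call. = FALSE)
    }
    missing <- setdiff(rois, stats$roi)
    if (length(missing) > 0) {
      stop("thickness stats missing for ROI(s): ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
    idx <- match(rois, stats$roi)
    mu <- stats$thick_mean[idx]
    s2 <- stats$thick_var[idx]
    if (any(!is.finite(mu)) || any(!is.finite(s2)) || any(s2 < 0)) {
      stop("thickness means/variances must be finite with variance >= 0",
           call. = FALSE)
    }
    if (any(s2 == 0)) {
      stop("degenerate input: zero thickness variance for ROI '",
           rois[which(s2 == 0)[1]], "'", call. = FALSE)
    }
    m <- exp(-gaussian_kl_sym(mu, s2))
    diag(m) <- 1
  } else {
    vecs <- stats[rois]
    if (any(vapply(vecs, is.null, logical(1)))) {
      stop("vertex vectors missing for some requested ROI", call. = FALSE)
    }
    lens <- vapply(vecs, length, integer(1))
    if (length(unique(lens)) != 1) {
      stop("vertex vectors must have equal length for pearson_vertex",
           call. = FALSE)
    }
    m <- stats::cor(do.call(cbind, vecs))
    diag(m) <- 1
  }
  dimnames(m) <- list(rois, rois)
  structure(list(roi_names = rois, matrix = m, method = method),
            class = "morph_network")
}

# Symmetrized KL divergence between all pairs of 1-D Gaussians, closed form:
# KL(N1||N2) = log(s2/s1)/2 + (s1^2 + (m1-m2)^2) / (2 s2^2) - 1/2,
# with s^2 the variances; KLsym = (KL(i||j) + KL(j||i)) / 2.
gaussian_kl_sym <- function(mu, var) {
  dm2 <- outer(mu, mu, "-")^2
  vi <- matrix(var, length(var), length(var))
  vj <- t(vi)
  kl_ij <- 0.5 * log(vj / vi) + (vi + dm2) / (2 * vj) - 0.5
  (kl_ij + t(kl_ij)) / 2
}

#' @export
print.morph_network <- function(x, ...) {
  cat(sprintf("# morph_network (%s): %d ROIs, %d edge features\n",
              x$method, length(x$roi_names),
              length(x$roi_names) * (length(x$roi_names) - 1) / 2))
  invisible(x)
}

#' Vectorize the strict upper triangle of a network
#'
#' Flattens a symmetric association matrix into its strict upper-triangle
#' entries in row-major order — (1,2), (1,3), ..., (1,n), (2,3), ... — of
#' length n(n-1)/2 (3003 for the default 78-ROI network). Names follow the
#' `"ROIa-ROIb"` convention.
#'
#' @param net A `morph_network`, or a square symmetric matrix.
#' @return Named numeric vector of length n(n-1)/2.
#' @export
vectorize_upper_triangle <- function(net) {
  m <- if (inherits(net, "morph_network")) net$matrix else as.matrix(net)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  v <- t(m)[lower.tri(m)]  # row-major strict upper triangle
  rn <- rownames(m) %||% paste0("V", seq_len(nrow(m)))
  names(v) <- edge_names(rn)
  v
}

edge_names <- function(rois) {
  n <- length(rois)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) seq(a + 1, n)))
  paste0(rois[i], "-", rois[j])
}

#' Build the cohort's network feature table
#'
#' Applies [build_network()] + [vectorize_upper_triangle()] to every subject
#' in a thickness-summary table, producing a `Network` feature table (one row
#' per subject, one column per ROI pair).
#'
#' @param stats Tibble with columns `subject_id`, `roi`, `thick_mean`,
#'   `thick_var` (long format, one row per subject x ROI).
#' @param rois ROI names to include (default: 78 cortical regions).
#' @param method Passed to [build_network()].
#' @return An `roi_feature_table` of type `Network` (flagged normalized:
#'   similarity values are already scale-free).
#' @export
network_feature_table <- function(stats, rois = select_cortical_rois(),
                                  method = "gaussian_kl") {
  ids <- unique(stats$subject_id)
  rows <- lapply(ids, function(id) {
    s <- stats[stats$subject_id == id, , drop = FALSE]
    vectorize_upper_triangle(build_network(s, method = method, rois = rois))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  roi_feature_table(m, "Network", normalized = TRUE)
}
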