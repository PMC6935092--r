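# Kernels and the empirical kernel map (EKM). The EKM turns an implicit
# kernel feature space into an explicit r-dimensional one: eigendecompose the
# training Gram matrix K = P Lambda P', keep the positive spectrum, and map
# any sample x to Lambda^(-1/2) P' (k(x, x_1), ..., k(x, x_m))'. Inner
# products of mapped points reproduce kernel values, so downstream kernel
# machines see an equivalent but explicit representation.

#' Kernel specification
#'
#' @param kind `"rbf"` or `"linear"`.
#' @param gamma RBF width parameter (> 0); `NULL` means "set by the median
#'   heuristic when first fitted" (1 / (2 * median squared pairwise
#'   distance)).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("rbf", "linear"), gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "rbf" && !is.null(gamma) &&
      (!is.finite(gamma) || gamma <= 0)) {
    stop("gamma must be a positive finite number", call. = FALSE)
  }
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("# kernel_spec: %s%s\n", x$kind,
              if (x$kind == "rbf")
                paste0(" (gamma = ", x$gamma %||% "median heuristic", ")")
              else ""))
  invisible(x)
}

#' Median-heuristic RBF width
#'
#' gamma = 1 / (2 * median of squared pairwise Euclidean distances), a
#' standard scale-free default for the RBF kernel.
#'
#' @param x Numeric matrix, samples x features.
#' @return Positive scalar.
#' @export
median_gamma <- function(x) {
  x <- as.matrix(x)
  d2 <- as.numeric(stats::dist(x))^2
  d2 <- d2[d2 > 0]
  if (length(d2) == 0) return(1)
  1 / (2 * stats::median(d2))
}

resolve_spec <- function(spec, x) {
  if (spec$kind == "rbf" && is.null(spec$gamma)) {
    spec$gamma <- median_gamma(x)
  }
  spec
}

#' Gram matrix between two sample sets
#'
#' Entry (i, j) is ker(x_i, z_j): the inner product for the linear kernel, or
#' exp(-gamma * ||x_i - z_j||^2) for the RBF kernel.
#'
#' @param x,z Numeric matrices with matching column counts (rows are
#'   samples); vectors are treated as single rows.
#' @param spec A [kernel_spec()]. An RBF spec without `gamma` gets the median
#'   heuristic computed from `x`.
#' @return `nrow(x)` x `nrow(z)` matrix.
#' @export
gram <- function(x, z = x, spec = kernel_spec("rbf")) {
  x <- rbind(x); z <- rbind(z)
  if (ncol(x) != ncol(z)) {
    stop("feature dimensions differ: ", ncol(x), " vs ", ncol(z),
         call. = FALSE)
  }
  if (spec$kind == "linear") {
    return(tcrossprod(x, z))
  }
  spec <- resolve_spec(spec, x)
  d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
  d2[d2 < 0] <- 0
  exp(-spec$gamma * d2)
}

#' Fit an empirical kernel map
#'
#' Eigendecomposes the m x m training Gram matrix and retains eigenpairs
#' whose eigenvalue exceeds `tol` times the largest one; the retained count r
#' is the dimension of the empirical feature space. Eigenvector signs are
#' fixed (largest-magnitude component non-negative) so the map is
#' reproducible across linear-algebra backends.
#'
#' @param x_train Training samples, m x d.
#' @param spec A [kernel_spec()]; RBF width defaults to the median heuristic
#'   of the training set.
#' @param tol Relative eigenvalue tolerance (default 1e-10).
#' @return An `ekm` object: `x_train`, resolved `spec`, eigenvalues
#'   `lambda` (length r, decreasing), eigenvectors `P` (m x r), `rank`, and
#'   `tol`.
#' @export
fit_ekm <- function(x_train, spec = kernel_spec("rbf"), tol = 1e-10) {
  x_train <- rbind(x_train)
  spec <- resolve_spec(spec, x_train)
  K <- gram(x_train, x_train, spec)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  thr <- tol * max(e$values)
  keep <- which(e$values > pmax(thr, 0))
  if (length(keep) == 0 || max(e$values) <= 0) {
    stop("degenerate kernel: no eigenvalue above tolerance", call. = FALSE)
  }
  P <- e$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-|component| of each eigenvector >= 0
  sgn <- vapply(seq_len(ncol(P)), function(j) {
    v <- P[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  P <- sweep(P, 2, sgn, "*")
  structure(list(x_train = x_train, spec = spec,
                 lambda = e$values[keep], P = P,
                 rank = length(keep), tol = tol),
            class = "ekm")
}

#' @export
print.ekm <- function(x, ...) {
  cat(sprintf("# empirical kernel map: %s kernel, m = %d, rank r = %d\n",
              x$spec$kind, nrow(x$x_train), x$rank))
  invisible(x)
}

#' Map samples into the empirical feature space
#'
#' Row for sample x is Lambda^(-1/2) P' (k(x, x_1), ..., k(x, x_m))'. Applied
#' to the training set of a full-rank map, pairwise inner products of the
#' output reproduce the training Gram matrix.
#'
#' @param map A fitted `ekm`.
#' @param x Samples to map, p x d.
#' @return p x r matrix.
#' @export
transform_ekm <- function(map, x) {
  kx <- gram(rbind(x), map$x_train, map$spec)  # p x m
  kx %*% map$P %*% diag(1 / sqrt(map$lambda), map$rank)
}

#' @export
predict.ekm <- function(object, newdata, ...) transform_ekm(object, newdata)
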