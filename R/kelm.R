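# Kernel extreme learning machine (KELM): a single-hidden-layer network
# whose hidden features are replaced by a kernel, trained in closed form by
# ridge regression. With training Gram Omega and +/-1 one-vs-all label
# matrix T, the output weights are beta = (I/C + Omega)^{-1} T and test
# scores are K(test, train) beta; the predicted class is the argmax column.

#' Encode class labels as a +/-1 one-vs-all matrix
#'
#' @param y Class labels.
#' @param classes Class order (columns of the matrix); defaults to the
#'   sorted unique labels. A single-class `y` against a longer class order
#'   is valid but warns.
#' @return n x m matrix with +1 in the true-class column, -1 elsewhere;
#'   class order stored as colnames.
#' @export
encode_labels <- function(y, classes = NULL) {
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  classes <- as.character(classes)
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  bad <- setdiff(y, classes)
  if (length(bad) > 0) {
    stop("label(s) outside the class order: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    warning("only one class present in y")
  }
  T <- matrix(-1, length(y), length(classes),
              dimnames = list(NULL, classes))
  T[cbind(seq_along(y), match(y, classes))] <- 1
  T
}

#' Decode a score matrix to labels (argmax rule)
#'
#' The predicted class of each row is the column with the highest score;
#' invariant under any strictly increasing transform applied uniformly to a
#' row. The first of tied columns wins.
#'
#' @param scores n x m score matrix with class colnames.
#' @return Character vector of labels.
#' @export
decode_scores <- function(scores) {
  colnames(scores)[max.col(scores, ties.method = "first")]
}

#' Train a kernel extreme learning machine
#'
#' @param x Training samples, n x d.
#' @param y Class labels (or a pre-encoded +/-1 label matrix).
#' @param C Ridge regularization parameter (> 0); larger C fits the training
#'   targets more tightly.
#' @param spec Kernel specification ([kernel_spec()]).
#' @param classes Class order for label encoding.
#' @return A `kelm` model: `x_train`, resolved `spec`, `C`, output weights
#'   `beta` (n x m) and `classes`.
#' @export
train_kelm <- function(x, y, C = 1, spec = kernel_spec("rbf"),
                       classes = NULL) {
  if (!is.finite(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  x <- rbind(x)
  T <- if (is.matrix(y)) y else encode_labels(y, classes)
  spec <- resolve_spec(spec, x)
  omega <- gram(x, x, spec)
  beta <- solve(diag(1 / C, nrow(x)) + omega, T)
  structure(list(x_train = x, spec = spec, C = C, beta = beta,
                 classes = colnames(T)),
            class = "kelm")
}

#' @export
print.kelm <- function(x, ...) {
  cat(sprintf("# KELM: %s kernel, n = %d, C = %g, classes: %s\n",
              x$spec$kind, nrow(x$x_train), x$C,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict from a KELM model
#'
#' @param object A `kelm` model.
#' @param newdata Samples to score, p x d.
#' @param ... Unused.
#' @return Tibble with one row per sample: predicted `.class` and one score
#'   column per class.
#' @export
predict.kelm <- function(object, newdata, ...) {
  scores <- gram(rbind(newdata), object$x_train, object$spec) %*% object$beta
  score_tibble(scores, object$classes)
}

score_tibble <- function(scores, classes) {
  colnames(scores) <- classes
  out <- tibble::as_tibble(as.data.frame(scores, check.names = FALSE))
  tibble::add_column(out, .class = decode_scores(scores), .before = 1)
}
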