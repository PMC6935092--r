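# Learning using privileged information (LUPI) for extreme learning
# machines. Privileged features are available for training subjects only;
# they enter the closed-form output weights through their Gram matrix and
# are never consulted at test time.
#
# ELM+ (explicit random hidden layers H for main features, H~ for privileged
# ones):   beta = H' (H~H~'/eps + I/C)^{-1} (T - (C/eps) H~H~' J),
# KELM+ (kernelized, privileged Gram Omega~):
#          beta_kernel = (Omega~/eps + I/C)^{-1} (T - (C/eps) Omega~ J),
# with J the n x m all-ones matrix; test scores are K(test, train) beta.
# Note the subtracted (C/eps) term is identical in every label column, so it
# shifts all class scores of a test point equally and the argmax decision is
# driven by (Omega~/eps + I/C)^{-1} T — the privileged information acts as a
# data-dependent regularizer of the solve.

plus_weights <- function(omega_priv, T, C, eps) {
  n <- nrow(T)
  M <- omega_priv / eps + diag(1 / C, n)
  rhs <- T - (C / eps) * (omega_priv %*% matrix(1, n, ncol(T)))
  solve(M, rhs)
}

random_hidden <- function(x, L, seed) {
  d <- ncol(x)
  withr::with_seed(seed, {
    W <- matrix(stats::runif(d * L, -1, 1), d, L)
    b <- stats::runif(L, -1, 1)
  })
  1 / (1 + exp(-(x %*% W + matrix(b, nrow(x), L, byrow = TRUE))))
}

#' Train an ELM+ (random-hidden-layer LUPI classifier)
#'
#' Explicit-feature counterpart of [train_kelm_plus()], retained as a
#' baseline and as the correctness oracle for the kernel version: with a
#' linear kernel applied to the hidden matrices the two give identical
#' scores. Hidden layers are sigmoid units with seeded uniform [-1, 1]
#' weights and biases.
#'
#' @param x Main-feature training samples, n x d1.
#' @param p_priv Privileged-feature training samples, n x d2 (row-aligned
#'   with `x`).
#' @param y Class labels or +/-1 label matrix.
#' @param C,eps Positive regularization parameters: `C` weighs the training
#'   fit, `eps` the privileged-space weight norm.
#' @param L,L_priv Hidden-layer sizes for main and privileged maps.
#' @param seed Integer seed for the random hidden weights.
#' @param classes Class order for label encoding.
#' @return An `elm_plus` model with hidden-map parameters and output weights
#'   `beta` (L x m).
#' @export
train_elm_plus <- function(x, p_priv, y, C = 1, eps = 1, L = 50,
                           L_priv = 50, seed = 1, classes = NULL) {
  stopifnot(C > 0, eps > 0, L >= 1, L_priv >= 1)
  x <- rbind(x); p_priv <- rbind(p_priv)
  if (nrow(x) != nrow(p_priv)) {
    stop("main and privileged training sets must be row-aligned",
         call. = FALSE)
  }
  T <- if (is.matrix(y)) y else encode_labels(y, classes)
  H <- random_hidden(x, L, seed)
  H_priv <- random_hidden(p_priv, L_priv, seed + 1L)
  beta <- crossprod(H, plus_weights(tcrossprod(H_priv), T, C, eps))
  structure(list(d = ncol(x), L = L, L_priv = L_priv, seed = seed,
                 C = C, eps = eps, beta = beta, classes = colnames(T)),
            class = "elm_plus")
}

#' @export
predict.elm_plus <- function(object, newdata, ...) {
  H <- random_hidden(rbind(newdata), object$L, object$seed)
  score_tibble(H %*% object$beta, object$classes)
}

#' Train a KELM+ (kernel LUPI classifier)
#'
#' Kernelized ELM+: the privileged features enter only through their Gram
#' matrix, computed once at training time; prediction needs the main-feature
#' training samples only, honoring the LUPI contract that privileged
#' information is unavailable at test time.
#'
#' @param x_main Main-feature training samples, n x d1.
#' @param x_priv Privileged-feature training samples, n x d2, row-aligned
#'   with `x_main`. Alternatively pass a precomputed n x n privileged Gram
#'   matrix via `omega_priv`.
#' @param y Class labels or +/-1 label matrix.
#' @param C,eps Positive regularization parameters (see [train_elm_plus()]).
#' @param spec_main,spec_priv Kernel specifications for the main and
#'   privileged features.
#' @param omega_priv Optional precomputed privileged Gram matrix.
#' @param classes Class order for label encoding.
#' @return A `kelm_plus` model: `x_train` (main features), `spec_main`, `C`,
#'   `eps`, output weights `beta` (n x m), `classes`.
#' @export
train_kelm_plus <- function(x_main, x_priv = NULL, y, C = 1, eps = 1,
                            spec_main = kernel_spec("rbf"),
                            spec_priv = kernel_spec("rbf"),
                            omega_priv = NULL, classes = NULL) {
  stopifnot(C > 0, eps > 0)
  x_main <- rbind(x_main)
  if (is.null(omega_priv)) {
    if (is.null(x_priv)) {
      stop("supply privileged samples `x_priv` or a Gram matrix `omega_priv`",
           call. = FALSE)
    }
    x_priv <- rbind(x_priv)
    if (nrow(x_priv) != nrow(x_main)) {
      stop("main and privileged training sets must be row-aligned",
           call. = FALSE)
    }
    spec_priv <- resolve_spec(spec_priv, x_priv)
    omega_priv <- gram(x_priv, x_priv, spec_priv)
  }
  T <- if (is.matrix(y)) y else encode_labels(y, classes)
  if (nrow(T) != nrow(x_main)) {
    stop("labels must align with training rows", call. = FALSE)
  }
  spec_main <- resolve_spec(spec_main, x_main)
  beta <- plus_weights(omega_priv, T, C, eps)
  structure(list(x_train = x_main, spec_main = spec_main, C = C, eps = eps,
                 beta = beta, classes = colnames(T)),
            class = "kelm_plus")
}

#' @export
print.kelm_plus <- function(x, ...) {
  cat(sprintf("# KELM+: %s main kernel, n = %d, C = %g, eps = %g\n",
              x$spec_main$kind, nrow(x$x_train), x$C, x$eps))
  invisible(x)
}

#' Predict from a KELM+ model
#'
#' Scores are `K_main(newdata, x_train) %*% beta`; only main features are
#' consumed — the model retains nothing of the privileged table beyond its
#' influence on `beta`.
#'
#' @param object A `kelm_plus` model.
#' @param newdata Main-feature samples, p x d1.
#' @param ... Unused.
#' @return Tibble with predicted `.class` and per-class score columns.
#' @export
predict.kelm_plus <- function(object, newdata, ...) {
  scores <- gram(rbind(newdata), object$x_train, object$spec_main) %*%
    object$beta
  score_tibble(scores, object$classes)
}
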