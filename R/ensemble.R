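# The five-member LUPI ensemble: one feature type is the "main" feature
# (available at train and test time); each of the remaining five types
# serves as privileged information for one KELM+ member. Per member, main
# and privileged features are feature-selected, lifted through an empirical
# kernel map fitted on the training fold, and fed to KELM+. Test-time
# prediction consumes the main feature table only; labels are fused by
# majority vote (ties broken by the largest summed member score).

#' Ensemble configuration
#'
#' @param main Main feature type (default `"GMV"`).
#' @param pi_types Privileged feature types, default the other five of
#'   GMV/WMV/CSFV/Thickness/Area/Network; must not contain `main`.
#' @param spec_ekm,spec_kelm Kernel specifications for the empirical kernel
#'   map and the KELM+ core (RBF with median-heuristic width by default).
#' @param C,eps Fallback regularization parameters, used directly when the
#'   grids are singletons and as the untuned baseline's C.
#' @param c_grid,eps_grid,gamma_mult Hyperparameter grids for the inner-CV
#'   search of [tune_hyperparameters()]: candidate C and eps values
#'   (default: a coarse log-2 grid 2^(-5), 2^(-3), ..., 2^5) and
#'   multipliers applied to the median-heuristic RBF width (default 1, i.e.
#'   the width is data-driven, not tuned). Singleton grids switch tuning
#'   off and use the values as-is.
#' @param alpha,k Feature-selection parameters (t-test threshold and post-MI
#'   dimensionality; `k = NULL` caps at the training-set size).
#' @param mi_estimator Mutual-information estimator, see [mi_scores()].
#' @param tune_folds Inner stratified folds used during tuning.
#' @param seed Integer seed governing tuning folds.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(main = "GMV", pi_types = NULL,
                            spec_ekm = kernel_spec("rbf"),
                            spec_kelm = kernel_spec("rbf"),
                            C = 1, eps = 1,
                            c_grid = NULL, eps_grid = NULL,
                            gamma_mult = 1,
                            alpha = 0.05, k = NULL,
                            mi_estimator = "knn",
                            tune_folds = 3, seed = 1) {
  main <- match.arg(main, FEATURE_TYPES)
  if (is.null(pi_types)) pi_types <- setdiff(FEATURE_TYPES, main)
  if (main %in% pi_types) {
    stop("main feature type cannot also be privileged", call. = FALSE)
  }
  if (length(pi_types) < 1) stop("need at least one PI type", call. = FALSE)
  structure(list(main = main, pi_types = pi_types,
                 spec_ekm = spec_ekm, spec_kelm = spec_kelm,
                 C = C, eps = eps,
                 c_grid = c_grid %||% 2^seq(-5, 5, by = 2),
                 eps_grid = eps_grid %||% 2^seq(-5, 5, by = 2),
                 gamma_mult = gamma_mult,
                 alpha = alpha, k = k, mi_estimator = mi_estimator,
                 tune_folds = tune_folds, seed = seed),
            class = "ensemble_config")
}

# Feature-select and EKM-lift one feature table on training rows; returns
# the selection, the fitted map and the lifted training matrix.
prepare_branch <- function(x, y, config) {
  sel <- select_features(x, y, alpha = config$alpha, k = config$k,
                         estimator = config$mi_estimator,
                         feature_names = colnames(x))
  idx <- if (length(sel$selected) > 0) sel$selected else seq_len(ncol(x))
  map <- fit_ekm(x[, idx, drop = FALSE], spec = config$spec_ekm)
  list(selection = sel, idx = idx, map = map,
       z = transform_ekm(map, x[, idx, drop = FALSE]))
}

#' Train a KELM+ voting ensemble
#'
#' @param tables Named list of row-aligned feature matrices or
#'   `roi_feature_table`s, covering the main type and every configured
#'   privileged type.
#' @param y Class labels, aligned with the table rows.
#' @param config An [ensemble_config()]. When its grids are non-singleton,
#'   hyperparameters are tuned per member by inner cross-validation first.
#' @return An `ensemble_model` with the fitted main branch (selection + EKM)
#'   and one `kelm_plus` member per privileged type.
#' @export
train_ensemble <- function(tables, y, config = ensemble_config()) {
  mats <- as_feature_matrices(tables)
  need <- c(config$main, config$pi_types)
  missing <- setdiff(need, names(mats))
  if (length(missing) > 0) {
    stop("missing feature table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  if (!is.null(config$tuned)) {
    # per-member hyperparameters chosen by tune_hyperparameters()
  } else if (length(config$c_grid) > 1 || length(config$eps_grid) > 1 ||
             length(config$gamma_mult) > 1) {
    config$tuned <- tune_hyperparameters(mats, y, config)
  }
  main_branch <- prepare_branch(mats[[config$main]], y, config)
  T <- encode_labels(y, classes)
  members <- lapply(config$pi_types, function(pt) {
    hp <- member_hp(config, pt)
    pb <- prepare_branch(mats[[pt]], y, config)
    spec_main <- config$spec_kelm
    if (spec_main$kind == "rbf") {
      base_gamma <- spec_main$gamma %||% median_gamma(main_branch$z)
      spec_main$gamma <- base_gamma * (hp$gamma_mult %||% 1)
    }
    model <- train_kelm_plus(main_branch$z, pb$z, T,
                             C = hp$C, eps = hp$eps,
                             spec_main = spec_main,
                             spec_priv = config$spec_kelm)
    list(pi_type = pt, model = model, pi_selection = pb$selection)
  })
  names(members) <- config$pi_types
  structure(list(config = config, classes = classes,
                 main_selection = main_branch$selection,
                 main_idx = main_branch$idx, main_map = main_branch$map,
                 members = members),
            class = "ensemble_model")
}

member_hp <- function(config, pi_type) {
  if (!is.null(config$tuned) && pi_type %in% names(config$tuned)) {
    config$tuned[[pi_type]]
  } else {
    list(C = config$C, eps = config$eps, gamma_mult = config$gamma_mult[1])
  }
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("# KELM+ ensemble: main = %s, %d member(s) [PI: %s]\n",
              x$config$main, length(x$members),
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}

#' Predict from a KELM+ ensemble
#'
#' Only the main feature table is consumed — the LUPI contract. Each member
#' scores the EKM-lifted main features; the final label is the majority vote
#' across members, ties broken by the highest summed member score over the
#' tied classes.
#'
#' @param object An `ensemble_model`.
#' @param newdata Main-feature matrix or `roi_feature_table` with the same
#'   columns the model was trained on.
#' @param ... Unused.
#' @return Tibble with `.class` (final label), one vote column per member
#'   (`vote_<PI>`), and summed per-class scores.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  x <- as_feature_matrices(list(main = newdata))[["main"]]
  z <- transform_ekm(object$main_map, x[, object$main_idx, drop = FALSE])
  preds <- lapply(object$members, function(m) predict(m$model, z))
  votes <- do.call(cbind, lapply(preds, function(p) p$.class))
  scores <- Reduce(`+`, lapply(preds, function(p)
    as.matrix(p[, object$classes, drop = FALSE])))
  final <- vapply(seq_len(nrow(votes)), function(i) {
    tab <- table(factor(votes[i, ], levels = object$classes))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) return(top)
    top[which.max(scores[i, top])]  # tie: highest summed score
  }, character(1))
  out <- tibble::tibble(.class = final)
  for (pt in names(object$members)) out[[paste0("vote_", pt)]] <-
    preds[[pt]]$.class
  for (cl in object$classes) out[[cl]] <- scores[, cl]
  out
}

#' Tune C, eps and RBF width per ensemble member
#'
#' Exhaustive grid search by inner stratified cross-validation on the
#' training data, maximizing mean accuracy; deterministic given
#' `config$seed` (ties go to the earliest grid point, C varying fastest).
#' Feature selection and the empirical kernel maps are fitted once per
#' inner fold and shared across grid points, so the grid sweep costs one
#' linear solve per point. Singleton grids are returned unchanged without
#' fitting.
#'
#' @inheritParams train_ensemble
#' @return Named list (per PI type) of `list(C, eps, gamma_mult, acc)`.
#' @export
tune_hyperparameters <- function(tables, y, config = ensemble_config()) {
  mats <- as_feature_matrices(tables)
  y <- as.character(y)
  classes <- sort(unique(y))
  grid <- expand.grid(C = config$c_grid, eps = config$eps_grid,
                      gamma_mult = config$gamma_mult,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 1) {
    out <- lapply(config$pi_types, function(pt)
      list(C = grid$C[1], eps = grid$eps[1], gamma_mult = grid$gamma_mult[1],
           acc = NA_real_))
    names(out) <- config$pi_types
    return(out)
  }
  folds <- stratified_folds(y, n_folds = config$tune_folds,
                            seed = config$seed)
  rbf <- config$spec_kelm$kind == "rbf"
  cache <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    ytr <- y[tr]
    mb <- prepare_branch(mats[[config$main]][tr, , drop = FALSE], ytr,
                         config)
    z_te <- transform_ekm(mb$map,
                          mats[[config$main]][!tr, mb$idx, drop = FALSE])
    d2 <- lin <- NULL
    base_gamma <- NA_real_
    if (rbf) {
      base_gamma <- config$spec_kelm$gamma %||% median_gamma(mb$z)
      d2 <- outer(rowSums(z_te^2), rowSums(mb$z^2), "+") -
        2 * tcrossprod(z_te, mb$z)
      d2[d2 < 0] <- 0
    } else {
      lin <- tcrossprod(z_te, mb$z)
    }
    omegas <- lapply(config$pi_types, function(pt) {
      pb <- prepare_branch(mats[[pt]][tr, , drop = FALSE], ytr, config)
      gram(pb$z, pb$z, config$spec_kelm)
    })
    names(omegas) <- config$pi_types
    list(T = encode_labels(ytr, classes), y_te = y[!tr],
         base_gamma = base_gamma, d2 = d2, lin = lin, omegas = omegas)
  })
  out <- lapply(config$pi_types, function(pt) {
    accs <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(cache, function(cc) {
        beta <- plus_weights(cc$omegas[[pt]], cc$T, grid$C[g], grid$eps[g])
        k_te <- if (rbf) {
          exp(-(cc$base_gamma * grid$gamma_mult[g]) * cc$d2)
        } else {
          cc$lin
        }
        mean(decode_scores(k_te %*% beta) == cc$y_te)
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(accs)  # first grid point among ties
    list(C = grid$C[best], eps = grid$eps[best],
         gamma_mult = grid$gamma_mult[best], acc = accs[best])
  })
  names(out) <- config$pi_types
  out
}

as_feature_matrices <- function(tables) {
  if (is.matrix(tables) || inherits(tables, "roi_feature_table")) {
    tables <- list(tables)
  }
  named <- lapply(tables, function(t) {
    if (inherits(t, "roi_feature_table")) feature_matrix(t) else as.matrix(t)
  })
  tabs <- tables[vapply(tables, inherits, logical(1), "roi_feature_table")]
  if (length(tabs) > 1) check_aligned(tabs)
  named
}

# Seeded stratified fold assignment: within each class, subjects are
# shuffled and dealt round-robin, so fold class proportions match the
# cohort's within one subject.
stratified_folds <- function(y, n_folds = 5, seed = 1) {
  y <- as.character(y)
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < n_folds) {
        stop("class '", cl, "' has fewer members (", length(idx),
             ") than folds (", n_folds, ")", call. = FALSE)
      }
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}
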