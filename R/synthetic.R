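# Synthetic cohorts with the statistical structure the pipeline assumes:
# grade-dependent mean shifts in designated ROIs (tissue volumes, thickness
# and surface area decrease with grade; cerebrospinal fluid increases),
# exchangeable inter-ROI correlation, blood pressures sampled inside each
# grade's band so the grade assignment round-trips exactly.

#' Synthetic cohort specification
#'
#' @param n_per_grade Subjects per grade (default 73).
#' @param grades Grades to generate, subset of 1:4.
#' @param effect_size Standardized mean shift `d` per grade step applied to
#'   affected ROIs (in units of the feature's between-subject SD).
#' @param affected_rois ROIs carrying the grade effect (default: 15 cortical
#'   regions in the frontal/temporal/parietal territories where
#'   hypertension-related atrophy is typically reported).
#' @param rho Exchangeable inter-ROI correlation in `[0, 1)`.
#' @param baselines Named list per feature type of `c(mean, sd)` in the
#'   feature's native units (cm^3 for volumes, mm for thickness, cm^2 for
#'   area).
#' @param vertex_var Mean within-ROI thickness variance (mm^2) used for the
#'   per-ROI thickness summaries feeding the network.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_grade = 73, grades = 1:4,
                           effect_size = 1.5,
                           affected_rois = default_affected_rois(),
                           rho = 0.2,
                           baselines = default_baselines(),
                           vertex_var = 0.12,
                           seed = 1) {
  stopifnot(n_per_grade >= 2, effect_size >= 0, rho >= 0, rho < 1,
            all(grades %in% 1:4))
  bad <- setdiff(affected_rois, aal_registry()$roi)
  if (length(bad) > 0) {
    stop("affected ROI(s) not in the registry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_per_grade = as.integer(n_per_grade),
                 grades = sort(unique(as.integer(grades))),
                 effect_size = effect_size, affected_rois = affected_rois,
                 rho = rho, baselines = baselines, vertex_var = vertex_var,
                 seed = seed),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_affected_rois <- function() {
  c("Frontal_Sup_Orb_R", "Frontal_Inf_Oper_R", "Olfactory_L",
    "Supp_Motor_Area_L", "Supp_Motor_Area_R", "Rectus_R",
    "Frontal_Mid_L", "Rolandic_Oper_R", "Insula_R",
    "Temporal_Sup_L", "Temporal_Sup_R", "Temporal_Mid_L",
    "Angular_L", "Precuneus_R", "SupraMarginal_L")
}

#' @rdname synthetic_spec
#' @export
default_baselines <- function() {
  list(GMV = c(mean = 8, sd = 0.8),
       WMV = c(mean = 6, sd = 0.6),
       CSFV = c(mean = 2, sd = 0.25),
       Thickness = c(mean = 2.5, sd = 0.18),
       Area = c(mean = 25, sd = 2.5))
}

# Per-subject multiplicative size factors (log-normal) model anatomical
# common variance: bigger heads have proportionally bigger ROIs. The log-sd
# nu is calibrated so the raw inter-ROI correlation is approximately the
# exchangeable rho: for raw = s * (mu + sigma * e) with s = exp(nu * g),
# cor(roi_i, roi_j) ~= (nu * mu / sigma)^2 / ((nu * mu / sigma)^2 + 1),
# hence nu = (sigma / mu) * sqrt(rho / (1 - rho)). Being multiplicative,
# the factor is removed exactly by the per-subject normalizations (total
# brain volume, total area, within-subject SD), as it is in real data.
size_log_sd <- function(rho, mean, sd) {
  if (rho <= 0) return(0)
  (sd / mean) * sqrt(rho / (1 - rho))
}

bp_bands <- list(
  `1` = list(sbp = c(95, 119.5), dbp = c(55, 79.5)),
  `2` = list(sbp = c(120, 129.5), dbp = c(55, 79.5)),
  `3` = list(sbp = c(130, 139.5), dbp = c(70, 89.5)),
  `4` = list(sbp = c(140, 175), dbp = c(90, 115)))

#' Generate a synthetic morphometry cohort
#'
#' Produces the five regional feature tables (unnormalized, strictly
#' positive), per-ROI thickness summaries for network construction, and a
#' cohort table whose blood pressures fall inside each generating grade's
#' band (so [grade_from_bp()] round-trips). Affected ROIs are shifted by
#' `-d * (grade - 1) * SD` for GMV/WMV/Thickness/Area and `+d * (grade - 1)
#' * SD` for CSFV; the thickness variance of affected ROIs also grows with
#' grade so network features carry signal too.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `tables` (named list of `roi_feature_table`s),
#'   `thickness_stats` (long tibble: subject_id, roi, thick_mean,
#'   thick_var), and `meta` (subject_id, grade, sbp, dbp).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  reg <- aal_registry()
  rois <- reg$roi
  p <- length(rois)
  grades <- rep(spec$grades, each = spec$n_per_grade)
  n <- length(grades)
  ids <- sprintf("S%03d", seq_len(n))
  aff <- match(spec$affected_rois, rois)
  withr::with_seed(spec$seed, {
    # one head-size factor shared by the volumetric/area features, an
    # independent one for thickness (cortical thickness scales with head
    # size only weakly, and through its own allometry)
    g_head <- stats::rnorm(n)
    g_thick <- stats::rnorm(n)
    tables <- list()
    for (ft in names(spec$baselines)) {
      b <- spec$baselines[[ft]]
      nu <- size_log_sd(spec$rho, b[["mean"]], b[["sd"]])
      s <- exp(nu * (if (ft == "Thickness") g_thick else g_head))
      shift_sign <- if (ft == "CSFV") 1 else -1
      mu <- matrix(b[["mean"]], n, p)
      mu[, aff] <- mu[, aff] +
        shift_sign * spec$effect_size * (grades - 1) * b[["sd"]]
      m <- s * (mu + b[["sd"]] * matrix(stats::rnorm(n * p), n, p))
      m[m < b[["mean"]] * 0.05] <- b[["mean"]] * 0.05  # keep positive
      rownames(m) <- ids
      colnames(m) <- rois
      tables[[ft]] <- roi_feature_table(m, ft)
    }
    thick <- feature_matrix(tables$Thickness)
    s_th <- exp(size_log_sd(spec$rho, spec$baselines$Thickness[["mean"]],
                            spec$baselines$Thickness[["sd"]]) * g_thick)
    lv <- matrix(log(spec$vertex_var), n, p) +
      0.2 * matrix(stats::rnorm(n * p), n, p)
    lv[, aff] <- lv[, aff] + 0.3 * spec$effect_size * (grades - 1)
    vvar <- exp(lv) * s_th^2  # vertex variance scales with thickness
    stats_tbl <- tibble::tibble(
      subject_id = rep(ids, each = p),
      roi = rep(rois, n),
      thick_mean = as.vector(t(thick)),
      thick_var = as.vector(t(vvar)))
    sbp <- numeric(n); dbp <- numeric(n)
    for (g in spec$grades) {
      band <- bp_bands[[as.character(g)]]
      sel <- grades == g
      sbp[sel] <- stats::runif(sum(sel), band$sbp[1], band$sbp[2])
      dbp[sel] <- stats::runif(sum(sel), band$dbp[1], band$dbp[2])
    }
  })
  meta <- tibble::tibble(subject_id = ids, sbp = sbp, dbp = dbp,
                         grade = grades)
  stopifnot(all(grade_from_bp(meta$sbp, meta$dbp) == meta$grade))
  list(tables = tables, thickness_stats = stats_tbl, meta = meta)
}

#' Two-class isotropic Gaussian test data
#'
#' Unit-variance Gaussian classes centered `separation` apart along the
#' first axis — fodder for classifier unit tests.
#'
#' @param n_per_class Samples per class.
#' @param dim Feature dimension.
#' @param separation Distance between class means (>= 0).
#' @param seed Integer seed.
#' @return List with `x` (2n x dim matrix) and `y` (labels "A"/"B").
#' @export
generate_separable <- function(n_per_class = 20, dim = 2, separation = 4,
                               seed = 1) {
  stopifnot(separation >= 0, n_per_class >= 1, dim >= 1)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(2 * n_per_class * dim), ncol = dim)
  })
  x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + separation
  list(x = x, y = rep(c("A", "B"), each = n_per_class))
}

#' Normalize a synthetic (or real) cohort and attach network features
#'
#' Convenience wrapper running the full preprocessing stage: volume tables
#' normalized by total brain volume, thickness by within-subject SD, area by
#' total area, and the network feature table built from the thickness
#' summaries over the cortical ROIs.
#'
#' @param cohort List as returned by [generate_cohort()] (fields `tables`,
#'   `thickness_stats`).
#' @param rois ROIs for the network (default: 78 cortical).
#' @return Named list of six normalized feature tables (GMV, WMV, CSFV,
#'   Thickness, Area, Network), row-aligned.
#' @export
prepare_features <- function(cohort, rois = select_cortical_rois()) {
  t <- cohort$tables
  tbv <- total_brain_volume(t$GMV, t$WMV, t$CSFV)
  out <- list(
    GMV = normalize_volumes(t$GMV, tbv),
    WMV = normalize_volumes(t$WMV, tbv),
    CSFV = normalize_volumes(t$CSFV, tbv),
    Thickness = normalize_thickness(t$Thickness),
    Area = normalize_area(t$Area),
    Network = network_feature_table(cohort$thickness_stats, rois = rois))
  check_aligned(out)
  out
}
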