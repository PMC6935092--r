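# Per-subject normalization of regional features. Each rule is strictly
# within-subject, so normalization commutes with row permutation and can
# safely be applied before cross-validation without leaking between subjects.

stop_if_normalized <- function(x, what) {
  if (is_normalized(x)) {
    stop(what, ": table is already normalized; refusing to double-normalize",
         call. = FALSE)
  }
}

#' Normalize tissue volumes by total brain volume
#'
#' Divides each subject's regional GMV/WMV/CSFV values by that subject's
#' total brain volume (TBV), removing head-size differences. When `tbv` is
#' not supplied it must be computed externally as the subject's summed
#' GMV + WMV + CSFV over all ROIs (see [total_brain_volume()]).
#'
#' @param table Unnormalized `roi_feature_table` of type GMV, WMV or CSFV.
#' @param tbv Named numeric vector of total brain volumes, one strictly
#'   positive entry per subject (names = subject ids), or an unnamed vector
#'   in table row order.
#' @return The normalized table (`normalized` flag set).
#' @export
normalize_volumes <- function(table, tbv) {
  if (!feature_type(table) %in% c("GMV", "WMV", "CSFV")) {
    stop("normalize_volumes applies to GMV/WMV/CSFV tables", call. = FALSE)
  }
  stop_if_normalized(table, "normalize_volumes")
  tbv <- resolve_per_subject(tbv, table$subject_id, "tbv")
  if (any(!is.finite(tbv)) || any(tbv <= 0)) {
    stop("total brain volume must be strictly positive for every subject",
         call. = FALSE)
  }
  scale_rows(table, 1 / tbv)
}

#' Per-subject total brain volume from the three tissue tables
#'
#' @param gmv,wmv,csfv Unnormalized volume tables, row-aligned.
#' @return Named numeric vector of per-subject GMV + WMV + CSFV sums.
#' @export
total_brain_volume <- function(gmv, wmv, csfv) {
  check_aligned(list(GMV = gmv, WMV = wmv, CSFV = csfv))
  tbv <- rowSums(feature_matrix(gmv)) + rowSums(feature_matrix(wmv)) +
    rowSums(feature_matrix(csfv))
  stats::setNames(tbv, gmv$subject_id)
}

#' Normalize cortical thickness by its within-subject spread
#'
#' Divides each subject's regional thickness values by the standard deviation
#' (population form, divisor n) of that subject's values across the 90 ROIs,
#' so every normalized row has unit spread.
#'
#' @param table Unnormalized `Thickness` table.
#' @return The normalized table.
#' @export
normalize_thickness <- function(table) {
  if (feature_type(table) != "Thickness") {
    stop("normalize_thickness applies to Thickness tables", call. = FALSE)
  }
  stop_if_normalized(table, "normalize_thickness")
  m <- feature_matrix(table)
  n <- ncol(m)
  sds <- sqrt(rowSums((m - rowMeans(m))^2) / n)
  if (any(sds <= 0)) {
    stop("degenerate input: subject '",
         table$subject_id[which(sds <= 0)[1]],
         "' has zero thickness variation across ROIs", call. = FALSE)
  }
  scale_rows(table, 1 / sds)
}

#' Normalize cortical surface area by each subject's total area
#'
#' Divides each subject's regional areas by that subject's summed area over
#' all ROIs, so every normalized row sums to one.
#'
#' @param table Unnormalized `Area` table.
#' @return The normalized table.
#' @export
normalize_area <- function(table) {
  if (feature_type(table) != "Area") {
    stop("normalize_area applies to Area tables", call. = FALSE)
  }
  stop_if_normalized(table, "normalize_area")
  tot <- rowSums(feature_matrix(table))
  scale_rows(table, 1 / tot)
}

resolve_per_subject <- function(v, subject_ids, what) {
  if (!is.null(names(v))) {
    missing <- setdiff(subject_ids, names(v))
    if (length(missing) > 0) {
      stop(what, " missing for subject(s): ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
    v <- v[subject_ids]
  } else if (length(v) != length(subject_ids)) {
    stop(what, " must have one value per subject", call. = FALSE)
  }
  as.numeric(v)
}

scale_rows <- function(table, factor) {
  m <- feature_matrix(table) * factor
  out <- tibble::as_tibble(as.data.frame(m))
  out <- tibble::add_column(out, subject_id = table$subject_id, .before = 1)
  roi_feature_table(out, feature_type(table), normalized = TRUE)
}
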