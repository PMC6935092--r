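#' Assign 2017 ACC/AHA blood-pressure grades
#'
#' Maps systolic/diastolic pressure (mmHg) to the four-grade categorization:
#' Grade 1 (normal, SBP < 120 and DBP < 80), Grade 2 (elevated, SBP 120-129
#' and DBP < 80), Grade 3 (hypertension stage 1, SBP 130-139 and/or DBP
#' 80-89), Grade 4 (hypertension stage 2, SBP >= 140 and/or DBP >= 90;
#' hypertensive crisis is folded in). When several conditions hold the
#' highest applicable grade wins, so the map is total, exclusive and monotone
#' in both pressures.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg; positive finite
#'   numerics, recycled to a common length.
#' @return Integer vector of grades in `1:4`.
#' @examples
#' grade_from_bp(109.1, 69.64)  # 1
#' grade_from_bp(125, 85)       # 3 (diastolic triggers stage 1)
#' grade_from_bp(153.8, 88.4)   # 4
#' @export
grade_from_bp <- function(sbp, dbp) {
  n <- max(length(sbp), length(dbp))
  sbp <- rep_len(as.numeric(sbp), n)
  dbp <- rep_len(as.numeric(dbp), n)
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) ||
      any(sbp <= 0) || any(dbp <= 0)) {
    stop("sbp and dbp must be positive finite pressures in mmHg",
         call. = FALSE)
  }
  grade <- rep.int(1L, n)
  grade[sbp >= 120] <- 2L
  grade[sbp >= 130 | dbp >= 80] <- 3L
  grade[sbp >= 140 | dbp >= 90] <- 4L
  grade
}

#' Add a grade column to a cohort table
#'
#' Tibble-first wrapper around [grade_from_bp()]: takes a cohort data frame
#' with `sbp` and `dbp` columns (mmHg) and appends an integer `grade` column.
#'
#' @param data Data frame with numeric `sbp` and `dbp` columns.
#' @return The input as a tibble with a `grade` column appended.
#' @export
add_bp_grade <- function(data) {
  if (!all(c("sbp", "dbp") %in% names(data))) {
    stop("`data` must have columns `sbp` and `dbp`", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data$grade <- grade_from_bp(data$sbp, data$dbp)
  data
}
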