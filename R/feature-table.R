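#' @importFrom rlang %||% .data
NULL

FEATURE_TYPES <- c("GMV", "WMV", "CSFV", "Thickness", "Area", "Network")

#' Construct an ROI feature table
#'
#' An ROI feature table is a tibble with a `subject_id` character column
#' followed by one numeric column per feature (ROI names for the five
#' regional feature types; `"ROIa-ROIb"` pair names for `Network` tables).
#' Two attributes track provenance: `feature_type` and `normalized`.
#'
#' @param data Data frame with a `subject_id` column and numeric feature
#'   columns, or a numeric matrix with rownames as subject ids.
#' @param feature_type One of `"GMV"`, `"WMV"`, `"CSFV"`, `"Thickness"`,
#'   `"Area"`, `"Network"`.
#' @param normalized Logical; whether per-subject normalization has been
#'   applied.
#' @param validate Check invariants (finite values; strictly positive values
#'   for unnormalized regional tables; unique subject ids; for regional
#'   tables, feature columns matching the AAL registry).
#' @return A tibble of class `roi_feature_table`.
#' @export
roi_feature_table <- function(data, feature_type, normalized = FALSE,
                              validate = TRUE) {
  feature_type <- match.arg(feature_type, FEATURE_TYPES)
  if (is.matrix(data)) {
    data <- tibble::as_tibble(data, .name_repair = "minimal") |>
      tibble::add_column(subject_id = rownames(data) %||%
                           paste0("S", seq_len(nrow(data))), .before = 1)
  }
  data <- tibble::as_tibble(data)
  if (names(data)[1] != "subject_id") {
    stop("first column must be `subject_id`", call. = FALSE)
  }
  data$subject_id <- as.character(data$subject_id)
  out <- structure(data,
                   class = c("roi_feature_table", class(tibble::tibble())),
                   feature_type = feature_type,
                   normalized = isTRUE(normalized))
  if (validate) validate_feature_table(out)
  out
}

#' @rdname roi_feature_table
#' @param x An `roi_feature_table`.
#' @export
feature_type <- function(x) attr(x, "feature_type")

#' @rdname roi_feature_table
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Extract the numeric feature matrix from a feature table
#'
#' @param x An `roi_feature_table` (or any tibble whose first column is
#'   `subject_id`).
#' @return Numeric matrix, subjects x features, with subject ids as rownames.
#' @export
feature_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$subject_id
  m
}

validate_feature_table <- function(x) {
  ft <- feature_type(x)
  vals <- feature_matrix(x)
  if (anyDuplicated(x$subject_id)) {
    stop("duplicate subject_id: ",
         x$subject_id[duplicated(x$subject_id)][1], call. = FALSE)
  }
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at subject '%s', column '%s'",
                 x$subject_id[bad[1]], colnames(vals)[bad[2]]),
         call. = FALSE)
  }
  if (ft != "Network") {
    reg <- aal_registry()
    extra <- setdiff(colnames(vals), reg$roi)
    if (length(extra) > 0) {
      stop("unknown ROI column(s): ", paste(utils::head(extra, 3),
                                            collapse = ", "), call. = FALSE)
    }
    if (!is_normalized(x) && any(vals <= 0)) {
      bad <- which(vals <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "unnormalized %s values must be strictly positive (subject '%s', ROI '%s')",
        ft, x$subject_id[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.roi_feature_table <- function(x, ...) {
  cat(sprintf("# ROI feature table: %s (%s), %d subjects x %d features\n",
              feature_type(x),
              if (is_normalized(x)) "normalized" else "raw",
              nrow(x), ncol(x) - 1L))
  NextMethod()
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an ROI feature table from delimited text
#'
#' Reads a comma- or tab-delimited (auto-detected) UTF-8 file whose header
#' names the features, whose first column holds subject ids, and whose
#' remaining cells are numeric. Malformed cells, duplicate subjects, and ROI
#' names absent from the AAL registry are errors naming the offending cell.
#'
#' @param path File path.
#' @param feature_type Feature type of the stored table (see
#'   [roi_feature_table()]).
#' @param normalized Whether the stored values are already normalized.
#' @return An `roi_feature_table`.
#' @export
read_feature_table <- function(path, feature_type, normalized = FALSE) {
  delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()))
  if (nrow(raw) == 0) stop("empty feature table: ", path, call. = FALSE)
  names(raw)[1] <- "subject_id"
  for (j in seq(2, ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | raw[[j]] %in% c("NA", ""))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell in '%s': row %d (subject '%s'), column '%s'",
                   path, bad[1], raw$subject_id[bad[1]], names(raw)[j]),
           call. = FALSE)
    }
    raw[[j]] <- v
  }
  roi_feature_table(raw, feature_type, normalized = normalized)
}

#' Write an ROI feature table as delimited text
#'
#' @param x An `roi_feature_table`.
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(as.data.frame(x)), path, delim = delim)
  invisible(path)
}

#' Read a cohort table (subject id + blood pressures)
#'
#' Reads a delimited file with columns `subject_id`, `sbp`, `dbp` (mmHg) and
#' derives the blood-pressure `grade`; the grade is always derived, never
#' read, so stored tables cannot disagree with the thresholds.
#'
#' @param path File path.
#' @return Tibble with `subject_id`, `sbp`, `dbp`, `grade`.
#' @export
read_cohort_table <- function(path) {
  delim <- detect_delim(path)
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols())
  need <- c("subject_id", "sbp", "dbp")
  if (!all(need %in% names(x))) {
    stop("cohort table must have columns subject_id, sbp, dbp", call. = FALSE)
  }
  x$subject_id <- as.character(x$subject_id)
  add_bp_grade(x[, c(need, setdiff(names(x), need))])
}

check_aligned <- function(tables) {
  ids <- lapply(tables, function(t) t$subject_id)
  ref <- ids[[1]]
  for (i in seq_along(ids)) {
    if (!identical(ids[[i]], ref)) {
      if (length(ids[[i]]) != length(ref)) {
        mism <- sprintf("row counts %d vs %d", length(ref), length(ids[[i]]))
      } else {
        mism <- sprintf("row %d", which(ids[[i]] != ref)[1])
      }
      stop(sprintf(
        "subject rows misaligned between tables '%s' and '%s' (first mismatch: %s)",
        names(tables)[1] %||% "1", names(tables)[i] %||% as.character(i),
        mism), call. = FALSE)
    }
  }
  invisible(TRUE)
}
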