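# Shared fixtures, built in code at test time.

# A small unnormalized regional feature table on real registry ROI names.
make_table <- function(n = 4, feature_type = "GMV", seed = 42,
                       rois = head(aal_registry()$roi, 6)) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * length(rois), 1, 10), n,
                dimnames = list(sprintf("S%02d", seq_len(n)), rois))
  })
  roi_feature_table(m, feature_type)
}

# Thickness summaries for one subject over given ROIs.
make_stats <- function(rois = select_cortical_rois(), seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    roi = rois,
    thick_mean = rnorm(length(rois), 2.5, 0.2),
    thick_var = runif(length(rois), 0.05, 0.2)))
}

# Random binary-labelled problem for the classifier core.
make_problem <- function(n = 16, d = 3, m_classes = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(LETTERS[seq_len(m_classes)], n, replace = TRUE)
    while (length(unique(y)) < m_classes) {
      y <- sample(LETTERS[seq_len(m_classes)], n, replace = TRUE)
    }
  })
  list(x = x, y = y)
}
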