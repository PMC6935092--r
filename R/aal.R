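# AAL-90 parcellation registry: 45 base regions x 2 hemispheres, interleaved
# L/R in the conventional atlas order. Six bilateral deep gray-matter nuclei
# are flagged non-cortical and form the default network exclusion list.

.aal_base <- function() {
  tibble::tribble(
    ~base,                  ~lobe,         ~cortical,
    "Precentral",           "Central",     TRUE,
    "Frontal_Sup",          "Frontal",     TRUE,
    "Frontal_Sup_Orb",      "Frontal",     TRUE,
    "Frontal_Mid",          "Frontal",     TRUE,
    "Frontal_Mid_Orb",      "Frontal",     TRUE,
    "Frontal_Inf_Oper",     "Frontal",     TRUE,
    "Frontal_Inf_Tri",      "Frontal",     TRUE,
    "Frontal_Inf_Orb",      "Frontal",     TRUE,
    "Rolandic_Oper",        "Central",     TRUE,
    "Supp_Motor_Area",      "Frontal",     TRUE,
    "Olfactory",            "Frontal",     TRUE,
    "Frontal_Sup_Medial",   "Frontal",     TRUE,
    "Frontal_Med_Orb",      "Frontal",     TRUE,
    "Rectus",               "Frontal",     TRUE,
    "Insula",               "Insula",      TRUE,
    "Cingulum_Ant",         "Limbic",      TRUE,
    "Cingulum_Mid",         "Limbic",      TRUE,
    "Cingulum_Post",        "Limbic",      TRUE,
    "Hippocampus",          "Limbic",      FALSE,
    "ParaHippocampal",      "Limbic",      TRUE,
    "Amygdala",             "Limbic",      FALSE,
    "Calcarine",            "Occipital",   TRUE,
    "Cuneus",               "Occipital",   TRUE,
    "Lingual",              "Occipital",   TRUE,
    "Occipital_Sup",        "Occipital",   TRUE,
    "Occipital_Mid",        "Occipital",   TRUE,
    "Occipital_Inf",        "Occipital",   TRUE,
    "Fusiform",             "Occipital",   TRUE,
    "Postcentral",          "Central",     TRUE,
    "Parietal_Sup",         "Parietal",    TRUE,
    "Parietal_Inf",         "Parietal",    TRUE,
    "SupraMarginal",        "Parietal",    TRUE,
    "Angular",              "Parietal",    TRUE,
    "Precuneus",            "Parietal",    TRUE,
    "Paracentral_Lobule",   "Central",     TRUE,
    "Caudate",              "Subcortical", FALSE,
    "Putamen",              "Subcortical", FALSE,
    "Pallidum",             "Subcortical", FALSE,
    "Thalamus",             "Subcortical", FALSE,
    "Heschl",               "Temporal",    TRUE,
    "Temporal_Sup",         "Temporal",    TRUE,
    "Temporal_Pole_Sup",    "Limbic",      TRUE,
    "Temporal_Mid",         "Temporal",    TRUE,
    "Temporal_Pole_Mid",    "Limbic",      TRUE,
    "Temporal_Inf",         "Temporal",    TRUE
  )
}

#' AAL region-of-interest registry
#'
#' Returns the 90-region Automated Anatomical Labeling (AAL) parcellation used
#' throughout the package: 45 regions per hemisphere, interleaved left/right,
#' each annotated with its lobe and whether it is cortical. The twelve deep
#' gray-matter regions (bilateral hippocampus, amygdala, caudate, putamen,
#' pallidum, thalamus) carry `cortical = FALSE` and are the default exclusion
#' set when building cortical-thickness networks.
#'
#' @return A tibble with 90 rows and columns `roi` (name with `_L`/`_R`
#'   suffix), `hemisphere` (`"L"`/`"R"`), `lobe`, and `cortical` (logical).
#' @examples
#' reg <- aal_registry()
#' nrow(reg)                    # 90
#' sum(reg$hemisphere == "L")   # 45
#' sum(!reg$cortical)           # 12
#' @export
aal_registry <- function() {
  base <- .aal_base()
  idx <- rep(seq_len(nrow(base)), each = 2)
  hemi <- rep(c("L", "R"), nrow(base))
  tibble::tibble(
    roi = paste0(base$base[idx], "_", hemi),
    hemisphere = hemi,
    lobe = base$lobe[idx],
    cortical = base$cortical[idx]
  )
}

#' Default sub-cortical exclusion list
#'
#' The twelve deep gray-matter ROIs dropped before building the inter-regional
#' cortical-thickness network. The set is configurable in
#' [select_cortical_rois()] because the literature is not unanimous about
#' which regions count as sub-cortical.
#'
#' @return Character vector of 12 ROI names.
#' @export
subcortical_rois <- function() {
  reg <- aal_registry()
  reg$roi[!reg$cortical]
}

#' Select the cortical ROIs used for network construction
#'
#' Drops an exclusion list (default: the 12 sub-cortical ROIs) from the
#' registry, preserving atlas order. With the default exclusion this yields
#' the 78 cortical regions whose pairwise associations form the
#' 78 x 78 network.
#'
#' @param registry ROI registry tibble, as from [aal_registry()].
#' @param exclude Character vector of ROI names to drop; every entry must be
#'   present in the registry.
#' @return Character vector of retained ROI names, in registry order.
#' @examples
#' length(select_cortical_rois())      # 78
#' length(select_cortical_rois(exclude = character()))  # 90
#' @export
select_cortical_rois <- function(registry = aal_registry(),
                                 exclude = subcortical_rois()) {
  bad <- setdiff(exclude, registry$roi)
  if (length(bad) > 0) {
    stop("exclusion list contains ROI(s) not in the registry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  setdiff(registry$roi, exclude)
}
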