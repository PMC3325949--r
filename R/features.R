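# Derived layer features: nasal/temporal means per layer, the central ONL
# convention, and the between-layer thickness ratios used for diagnosis.

#' Mean of the nasal and temporal thickest points of a layer
#'
#' Layers other than the ONL are measured at their thickest point nasally
#' and temporally of the fovea; the per-layer summary is the arithmetic
#' mean of the two. Vectorized; if either side is missing the result is
#' missing (that subject is excluded from analyses needing the field).
#'
#' @param nasal,temporal Thickness values in micrometres.
#' @return Mean thickness in micrometres, `NA` where either input is `NA`.
#' @examples
#' layer_mean_nasal_temporal(44.63, 40.96) # 42.795
#' @export
layer_mean_nasal_temporal <- function(nasal, temporal) {
  (nasal + temporal) / 2
}

#' Central outer-nuclear-layer thickness
#'
#' The ONL usually shows a single central thickest point, measured
#' directly. In the few eyes with distinct nasal and temporal maxima the
#' higher of the two is used.
#'
#' @param central Central maximum thickness (micrometres), or `NA` when the
#'   eye instead shows two maxima.
#' @param nasal_max,temporal_max The two maxima when present.
#' @return The ONL thickness in micrometres; `NA` only if no input is
#'   available.
#' @examples
#' onl_value(104)                                # 104
#' onl_value(NA, nasal_max = 100, temporal_max = 110) # 110
#' @export
onl_value <- function(central, nasal_max = NA_real_, temporal_max = NA_real_) {
  two_max <- pmax(nasal_max, temporal_max, na.rm = TRUE)
  ifelse(is.na(central), two_max, central)
}

#' Thickness ratio between two layers
#'
#' Dimensionless ratio of two thickness summaries. A missing or
#' non-positive denominator yields a missing result with a warning, never
#' an infinity.
#'
#' @param numerator,denominator Thickness values in micrometres.
#' @return `numerator / denominator`; `NA` where the denominator is missing
#'   or not > 0.
#' @examples
#' layer_ratio(93.92, 38.21) # ~2.458
#' @export
layer_ratio <- function(numerator, denominator) {
  bad <- !is.na(denominator) & denominator <= 0
  if (any(bad)) {
    warning("non-positive denominator in layer_ratio; result set to NA")
    denominator[bad] <- NA_real_
  }
  numerator / denominator
}

#' Per-subject diagnostic feature table
#'
#' Builds one row per subject from the eye-averaged panels: the
#' nasal/temporal means of RGC+IPL, INL and OPL, the central ONL, the
#' ONL/OPL and INL/OPL ratios, and a pass-through of every eye-averaged
#' panel field. Ratios use the mean OPL (mean of its nasal and temporal
#' thickest points). Missingness propagates per feature only: a subject
#' lacking OPL has missing ratios but keeps its other features.
#'
#' @param cohort A validated `oct_cohort`, typically after [qc_filter()].
#' @return A data frame with columns `subject_id`, `group`, `n_eyes`,
#'   `mean_rgc_ipl`, `mean_inl`, `mean_opl`, `onl`, `ratio_onl_opl`,
#'   `ratio_inl_opl`, then all eye-averaged panel fields.
#' @export
build_feature_table <- function(cohort) {
  em <- subject_eye_means(cohort)
  p <- em$panels
  feat <- data.frame(
    subject_id = p$subject_id,
    group = p$group,
    n_eyes = p$n_eyes,
    mean_rgc_ipl = layer_mean_nasal_temporal(p$rgc_ipl_nasal,
                                             p$rgc_ipl_temporal),
    mean_inl = layer_mean_nasal_temporal(p$inl_nasal, p$inl_temporal),
    mean_opl = layer_mean_nasal_temporal(p$opl_nasal, p$opl_temporal),
    onl = onl_value(p$onl_central),
    stringsAsFactors = FALSE
  )
  feat$ratio_onl_opl <- layer_ratio(feat$onl, feat$mean_opl)
  feat$ratio_inl_opl <- layer_ratio(feat$mean_inl, feat$mean_opl)
  cbind(feat, p[, panel_fields(), drop = FALSE])
}
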