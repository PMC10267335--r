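#' One Western blot lane's integrated band densities
#'
#' The module consumes already-integrated densities (e.g. ImageJ lane
#' profiles); band detection and background subtraction are upstream
#' concerns. `protein_ug` is carried as metadata only: the loading-control
#' normalisation is the sole correction, and dividing out loaded protein as
#' well would double-correct, since the control signal already scales with
#' loading.
#'
#' @param lane_id Lane label.
#' @param band_c_intensity Integrated density of mature CFTR (band C,
#'   ~180 kDa), >= 0, arbitrary units.
#' @param loading_control_intensity Integrated density of the loading
#'   control (e.g. calnexin), > 0.
#' @param condition Genotype/treatment label.
#' @param protein_ug Protein loaded (µg), metadata only.
#' @return An object of class `"lane_density"`.
#' @export
lane_density <- function(lane_id, band_c_intensity,
                         loading_control_intensity,
                         condition = NA_character_, protein_ug = NA_real_) {
  check_number(band_c_intensity, "band_c_intensity", lower = 0)
  check_number(loading_control_intensity, "loading_control_intensity",
               lower = 0, strict_lower = TRUE)
  structure(
    list(lane_id = lane_id, condition = condition,
         band_c_intensity = band_c_intensity,
         loading_control_intensity = loading_control_intensity,
         protein_ug = protein_ug),
    class = "lane_density"
  )
}

#' Mature CFTR (band C) as percent of the wild-type lane
#'
#' Each lane's band C density is first normalised to its own loading
#' control; the sample's normalised signal is then expressed as a percentage
#' of the wild-type lane's normalised signal. The ratio-of-ratios cancels
#' per-lane exposure factors and (provided the control scales with loading)
#' unequal protein loading.
#'
#' @param sample,wt [lane_density()] objects; the WT lane must have a
#'   non-zero band C density.
#' @return Percent of wild type (>= 0).
#' @export
#' @examples
#' wt <- lane_density("WT1", 2, 1)
#' s <- lane_density("Q1", 1, 2)
#' band_c_percent_of_wt(s, wt) # 25
band_c_percent_of_wt <- function(sample, wt) {
  stopifnot(inherits(sample, "lane_density"), inherits(wt, "lane_density"))
  if (wt$band_c_intensity <= 0) {
    stop_("wild-type lane '%s' has zero band C density", wt$lane_id)
  }
  100 * (sample$band_c_intensity / sample$loading_control_intensity) /
    (wt$band_c_intensity / wt$loading_control_intensity)
}

#' Normalise a table of lanes against a wild-type lane
#'
#' @param lanes Data frame with columns `lane_id`, `band_c_intensity`,
#'   `calnexin_intensity` (optionally `condition`, `protein_ug`).
#' @param wt_lane `lane_id` of the wild-type reference lane.
#' @return The input data frame with a `percent_of_wt` column appended.
#' @export
blot_percent_of_wt <- function(lanes, wt_lane) {
  need <- c("lane_id", "band_c_intensity", "calnexin_intensity")
  missing <- setdiff(need, names(lanes))
  if (length(missing)) {
    stop_("lane table lacks columns: %s", paste(missing, collapse = ", "))
  }
  wi <- which(lanes$lane_id == wt_lane)
  if (length(wi) != 1L) {
    stop_("wild-type lane '%s' matches %d rows (needs exactly 1)",
          wt_lane, length(wi))
  }
  as_lane <- function(i) {
    lane_density(
      lanes$lane_id[i], lanes$band_c_intensity[i],
      lanes$calnexin_intensity[i],
      condition = if ("condition" %in% names(lanes)) lanes$condition[i]
                  else NA_character_,
      protein_ug = if ("protein_ug" %in% names(lanes)) lanes$protein_ug[i]
                   else NA_real_
    )
  }
  wt <- as_lane(wi)
  lanes$percent_of_wt <- vapply(
    seq_len(nrow(lanes)),
    function(i) band_c_percent_of_wt(as_lane(i), wt),
    numeric(1)
  )
  lanes
}
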