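#' Quantification settings for conventional PET/MRI parameters
#'
#' @param suv_threshold SUV threshold for MTV/TLG segmentation; voxels with
#'   SUV >= threshold (inclusive) qualify. Default 2.5.
#' @param b_low,b_high b-values (s/mm^2) of the DWI pair used for ADC mapping.
#' @param signal_floor minimum DWI signal treated as valid; voxels with either
#'   signal below the floor get an invalid (`NA`) ADC.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(suv_threshold = 2.5, b_low = 0, b_high = 800,
                         signal_floor = 1e-6) {
  if (suv_threshold <= 0) stop("suv_threshold must be positive")
  if (!(b_high > b_low) || b_low < 0) stop("need b_high > b_low >= 0")
  structure(list(suv_threshold = suv_threshold, b_low = b_low, b_high = b_high,
                 signal_floor = signal_floor), class = "quant_config")
}

#' Ellipsoid volume of interest
#'
#' A VOI drawn around the entire primary tumour. A voxel belongs to the VOI
#' iff its center satisfies the ellipsoid inequality.
#'
#' @param center voxel indices (length 3).
#' @param radii semi-axes in mm (all > 0).
#' @return an object of class `ellipsoid_voi`.
#' @export
ellipsoid_voi <- function(center, radii) {
  if (length(center) != 3L || length(radii) != 3L) stop("center and radii must have length 3")
  if (any(!is.finite(radii)) || any(radii <= 0)) stop("radii must be positive")
  structure(list(center = as.numeric(center), radii = as.numeric(radii)),
            class = "ellipsoid_voi")
}

#' Circular region of interest on one axial slice
#'
#' @param slice_index axial (third-axis) index.
#' @param center in-plane voxel coordinates (length 2).
#' @param radius radius in mm (> 0).
#' @return an object of class `circle_roi`.
#' @export
circle_roi <- function(slice_index, center, radius) {
  if (length(center) != 2L) stop("center must have length 2")
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  structure(list(slice_index = as.integer(slice_index),
                 center = as.numeric(center), radius = as.numeric(radius)),
            class = "circle_roi")
}

# logical mask of in-VOI voxels; errors when the VOI misses the grid entirely
voi_mask <- function(volume, voi) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(voi, "ellipsoid_voi"))
  u2 <- ellipsoid_u2(dim(volume$values), volume$spacing, voi$center, voi$radii)
  mask <- u2 <= 1
  if (!any(mask)) stop("VOI does not intersect the grid")
  mask
}

#' Maximum SUV inside an ellipsoid VOI
#'
#' @param volume a `voxel_volume` of modality `"SUV"`.
#' @param voi an [ellipsoid_voi()].
#' @return the maximum voxel value among in-VOI voxels.
#' @export
suv_max <- function(volume, voi) {
  max(volume$values[voi_mask(volume, voi)])
}

#' Metabolic tumour volume (MTV)
#'
#' Volume (mL) of in-VOI voxels with SUV at or above the segmentation
#' threshold; 0 when no voxel qualifies.
#'
#' @inheritParams suv_max
#' @param config a [quant_config()].
#' @return MTV in mL.
#' @export
metabolic_tumor_volume <- function(volume, voi, config = quant_config()) {
  mask <- voi_mask(volume, voi)
  n_qual <- sum(volume$values[mask] >= config$suv_threshold)
  n_qual * voxel_mm3(volume) / 1000
}

#' Total lesion glycolysis (TLG)
#'
#' MTV multiplied by the mean SUV over the qualifying (threshold-passing)
#' voxels; 0 when MTV is 0.
#'
#' @inheritParams metabolic_tumor_volume
#' @return TLG in mL * SUV.
#' @export
total_lesion_glycolysis <- function(volume, voi, config = quant_config()) {
  mask <- voi_mask(volume, voi)
  v <- volume$values[mask]
  qual <- v >= config$suv_threshold
  if (!any(qual)) return(0)
  sum(qual) * voxel_mm3(volume) / 1000 * mean(v[qual])
}

#' Compute an ADC map from a two-b-value DWI pair
#'
#' Per voxel, `ADC = log(S_b_low / S_b_high) / (b_high - b_low)` in mm^2/s.
#' Voxels where either signal falls below `config$signal_floor` are marked
#' invalid (`NA`) and excluded from downstream ROI means; noise-induced
#' negative ADC values are clamped to 0.
#'
#' @param b0 `voxel_volume` at the low b-value.
#' @param bhigh `voxel_volume` at the high b-value (same grid and spacing).
#' @param config a [quant_config()].
#' @return a `voxel_volume` of modality `"ADC"` (mm^2/s).
#' @export
adc_map <- function(b0, bhigh, config = quant_config()) {
  stopifnot(inherits(b0, "voxel_volume"), inherits(bhigh, "voxel_volume"))
  if (!identical(dim(b0$values), dim(bhigh$values)) ||
      !isTRUE(all.equal(b0$spacing, bhigh$spacing)))
    stop("b0 and bhigh grids do not match")
  invalid <- b0$values < config$signal_floor | bhigh$values < config$signal_floor
  adc <- array(NA_real_, dim = dim(b0$values))
  ok <- !invalid
  adc[ok] <- log(b0$values[ok] / bhigh$values[ok]) / (config$b_high - config$b_low)
  adc[ok & adc < 0] <- 0
  voxel_volume(adc, b0$spacing, "ADC")
}

# logical in-plane mask of the circle on its slice (mm metric)
roi_mask_slice <- function(volume, roi) {
  d <- dim(volume$values); sp <- volume$spacing
  if (roi$slice_index < 1L || roi$slice_index > d[3]) stop("ROI slice outside the volume")
  ext_lo <- (roi$center - c(0.5, 0.5)) * sp[1:2]
  ext_hi <- (roi$center + c(0.5, 0.5)) * sp[1:2]
  if (any(ext_lo - roi$radius < 0) || any(ext_hi + roi$radius > d[1:2] * sp[1:2]))
    stop("ROI circle does not lie fully inside the slice")
  dx <- (seq_len(d[1]) - roi$center[1]) * sp[1]
  dy <- (seq_len(d[2]) - roi$center[2]) * sp[2]
  outer(dx^2, dy^2, "+") <= roi$radius^2
}

#' Mean ADC inside a circular ROI
#'
#' Arithmetic mean of the valid (non-`NA`) ADC voxels whose in-plane centers
#' lie within the circle on the given axial slice.
#'
#' @param adc a `voxel_volume` of modality `"ADC"` (mm^2/s).
#' @param roi a [circle_roi()].
#' @return mean ADC in mm^2/s.
#' @export
roi_mean_adc <- function(adc, roi) {
  stopifnot(inherits(adc, "voxel_volume"), adc$modality == "ADC",
            inherits(roi, "circle_roi"))
  mask <- roi_mask_slice(adc, roi)
  vals <- adc$values[, , roi$slice_index][mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no valid ADC voxel inside the ROI")
  mean(vals)
}

#' Percent change between baseline and interim values
#'
#' `(interim - baseline) * 100 / baseline`; `NA` when the baseline is 0 (the
#' ratio is undefined), an error when either value is negative.
#'
#' @param baseline,interim non-negative scalars.
#' @return percent change, or `NA_real_` when `baseline == 0`.
#' @export
percent_change <- function(baseline, interim) {
  if (any(c(baseline, interim) < 0, na.rm = TRUE)) stop("inputs must be non-negative")
  ifelse(baseline == 0, NA_real_, (interim - baseline) * 100 / baseline)
}

# Axial slice with the largest lesion cross-section: the slice maximizing the
# count of in-VOI voxels (optionally also >= threshold); ties -> lowest index.
largest_cross_section_slice <- function(volume, voi, threshold = NULL) {
  mask <- voi_mask(volume, voi)
  if (!is.null(threshold)) mask <- mask & volume$values >= threshold
  counts <- apply(mask, 3L, sum)
  if (all(counts == 0L)) counts <- apply(voi_mask(volume, voi), 3L, sum)
  which.max(counts)
}

# Default ground-truth-guided placements for a phantom patient: VOI = tumour
# ellipsoid with a 30% margin (shared between timepoints so it covers both),
# ROI = circle at the tumour center slice with 60% of the in-plane semi-axis,
# floored at one voxel.
default_voi <- function(study) {
  ellipsoid_voi(study$tumor_center, pmax(study$tumor_radii, study$tumor_radii_interim) * 1.3)
}

default_roi <- function(study, interim = FALSE) {
  radii <- if (interim) study$tumor_radii_interim else study$tumor_radii
  sp <- study$pet_baseline$spacing
  r <- max(0.6 * min(radii[1:2]), 1.01 * max(sp[1:2]))
  circle_roi(study$tumor_center[3], study$tumor_center[1:2], r)
}

#' Extract the twelve conventional parameters for one patient
#'
#' Computes SUVmax, MTV and TLG on the baseline and interim PET volumes inside
#' the VOIs, mean ADC inside the circular ROIs on ADC maps derived from the
#' DWI pairs, and the four percent changes. When VOIs/ROIs are omitted they
#' are placed from the phantom's ground-truth tumour geometry. A percent
#' change whose baseline value is 0 is reported as `NA`.
#'
#' @param study a `patient_study`.
#' @param voi0,voi1 [ellipsoid_voi()]s for baseline and interim PET.
#' @param roi0,roi1 [circle_roi()]s for baseline and interim ADC maps.
#' @param config a [quant_config()].
#' @return a one-row `data.frame`: `patient_id`, `suv0`, `suv1`, `mtv0`,
#'   `mtv1` (mL), `tlg0`, `tlg1` (mL*SUV), `adc0`, `adc1` (10^-3 mm^2/s),
#'   `dsuv`, `dmtv`, `dtlg`, `dadc` (percent).
#' @export
extract_parameters <- function(study, voi0 = NULL, voi1 = NULL,
                               roi0 = NULL, roi1 = NULL, config = quant_config()) {
  stopifnot(inherits(study, "patient_study"))
  if (is.null(voi0)) voi0 <- default_voi(study)
  if (is.null(voi1)) voi1 <- voi0
  if (is.null(roi0)) roi0 <- default_roi(study, interim = FALSE)
  if (is.null(roi1)) roi1 <- default_roi(study, interim = TRUE)

  suv0 <- suv_max(study$pet_baseline, voi0)
  suv1 <- suv_max(study$pet_interim, voi1)
  mtv0 <- metabolic_tumor_volume(study$pet_baseline, voi0, config)
  mtv1 <- metabolic_tumor_volume(study$pet_interim, voi1, config)
  tlg0 <- total_lesion_glycolysis(study$pet_baseline, voi0, config)
  tlg1 <- total_lesion_glycolysis(study$pet_interim, voi1, config)
  adc0 <- roi_mean_adc(adc_map(study$dwi_baseline$b0, study$dwi_baseline$bhigh, config), roi0) * 1e3
  adc1 <- roi_mean_adc(adc_map(study$dwi_interim$b0, study$dwi_interim$bhigh, config), roi1) * 1e3

  data.frame(patient_id = study$patient_id,
             suv0 = suv0, suv1 = suv1, mtv0 = mtv0, mtv1 = mtv1,
             tlg0 = tlg0, tlg1 = tlg1, adc0 = adc0, adc1 = adc1,
             dsuv = percent_change(suv0, suv1),
             dmtv = percent_change(mtv0, mtv1),
             dtlg = percent_change(tlg0, tlg1),
             dadc = percent_change(adc0, adc1),
             stringsAsFactors = FALSE)
}

#' Extract conventional parameters for a whole cohort
#'
#' @param cohort list of `patient_study` objects.
#' @param config a [quant_config()].
#' @return a `data.frame` with one [extract_parameters()] row per patient.
#' @export
extract_cohort_parameters <- function(cohort, config = quant_config()) {
  do.call(rbind, lapply(cohort, extract_parameters, config = config))
}
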