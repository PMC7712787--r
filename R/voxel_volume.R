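#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D scalar image with a physical voxel spacing and a
#' modality tag saying what the values mean: `"SUV"` for PET standardized
#' uptake values, `"DWI_b0"` / `"DWI_b800"` for diffusion-weighted MR signal at
#' the two b-values, or `"ADC"` for an apparent diffusion coefficient map in
#' mm^2/s (ADC maps may contain `NA` where the source signal was too low to
#' be trusted).
#'
#' @param values numeric 3D array; SUV and DWI values must be non-negative.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param modality one of `"SUV"`, `"DWI_b0"`, `"DWI_b800"`, `"ADC"`.
#' @return an object of class `voxel_volume` with elements `values`,
#'   `spacing`, `modality`.
#' @export
voxel_volume <- function(values, spacing, modality = c("SUV", "DWI_b0", "DWI_b800", "ADC")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  if (modality != "ADC" && anyNA(values))
    stop(modality, " volumes must not contain NA")
  if (modality != "ADC" && any(values < 0))
    stop(modality, " values must be >= 0")
  structure(list(values = values, spacing = as.numeric(spacing), modality = modality),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume %s> %s voxels @ %s mm; range [%g, %g]\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

# voxel volume in mm^3
voxel_mm3 <- function(volume) prod(volume$spacing)
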