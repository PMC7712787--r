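#' Construct a lesion crop
#'
#' A `lesion_crop` is a 64x64 image patch of one lesion at one
#' modality/timepoint, carrying its patient id, response label and provenance
#' (`"original"` or `"rotation_<k>x45"` for augmented copies).
#'
#' @param pixels 64x64 numeric matrix with finite values.
#' @param patient_id patient identifier.
#' @param modality_timepoint one of `"PET0"`, `"PET1"`, `"MRI0"`, `"MRI1"`.
#' @param responder logical response label.
#' @param provenance `"original"` or `"rotation_<k>x45"`, k in 1..7.
#' @return an object of class `lesion_crop`.
#' @export
lesion_crop <- function(pixels, patient_id, modality_timepoint, responder,
                        provenance = "original") {
  modality_timepoint <- match.arg(modality_timepoint, c("PET0", "PET1", "MRI0", "MRI1"))
  if (!is.matrix(pixels) || !identical(dim(pixels), c(64L, 64L)))
    stop("pixels must be a 64x64 matrix")
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  if (provenance != "original" &&
      !grepl("^rotation_[1-7]x45$", provenance))
    stop("provenance must be 'original' or 'rotation_<k>x45' with k in 1..7")
  structure(list(pixels = pixels, patient_id = patient_id,
                 modality_timepoint = modality_timepoint,
                 responder = isTRUE(responder), provenance = provenance),
            class = "lesion_crop")
}

#' @export
print.lesion_crop <- function(x, ...) {
  cat(sprintf("<lesion_crop %s %s %s, %s> range [%g, %g]\n",
              x$patient_id, x$modality_timepoint,
              if (x$responder) "responder" else "non-responder", x$provenance,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Bilinear sampling of a 2D image at arbitrary (row, col) coordinates;
# points outside the pixel-center support evaluate to `fill`.
bilinear_sample <- function(img, xs, ys, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  gather <- function(xi, yi) {
    ok <- xi >= 1 & xi <= H & yi >= 1 & yi <= W
    out <- rep(fill, length(xi))
    out[ok] <- img[cbind(xi[ok], yi[ok])]
    out
  }
  v00 <- gather(x0, y0);     v10 <- gather(x0 + 1, y0)
  v01 <- gather(x0, y0 + 1); v11 <- gather(x0 + 1, y0 + 1)
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

# Resample a square window (center, side in pixels) of a slice to size x size
# by bilinear interpolation; zero outside the slice.
resample_square <- function(slice, center, side, size = 64L) {
  step <- side / size
  xs <- center[1] - side / 2 + (seq_len(size) - 0.5) * step
  ys <- center[2] - side / 2 + (seq_len(size) - 0.5) * step
  grid_x <- rep(xs, times = size)
  grid_y <- rep(ys, each = size)
  matrix(bilinear_sample(slice, grid_x, grid_y), size, size)
}

# min-max normalization to [0, 1]; a constant patch maps to all zeros
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

#' Crop a 64x64 lesion patch at the largest cross-section
#'
#' Selects the axial slice with the largest lesion cross-section (most in-VOI
#' voxels; ties broken by the lowest slice index), takes a square window
#' centered on the lesion whose side is the tight in-plane bounding box side
#' plus a 20 percent margin, resamples it bilinearly to 64x64 and min-max
#' normalizes the patch to [0, 1]. `NA` voxels (invalid ADC) are treated as 0.
#'
#' @param volume a `voxel_volume` (SUV or ADC).
#' @param voi an [ellipsoid_voi()] delineating the lesion.
#' @param modality_timepoint crop tag, one of `"PET0"`, `"PET1"`, `"MRI0"`, `"MRI1"`.
#' @param patient_id patient identifier.
#' @param responder logical response label.
#' @param margin bounding-box margin fraction (default 0.2).
#' @return a [lesion_crop()].
#' @export
crop_lesion <- function(volume, voi, modality_timepoint, patient_id, responder,
                        margin = 0.2) {
  mask <- voi_mask(volume, voi)                  # errors when lesion is empty
  k <- largest_cross_section_slice(volume, voi)
  m2 <- mask[, , k]
  if (!any(m2)) stop("lesion is empty on every slice")
  ri <- range(which(rowSums(m2) > 0)); ci <- range(which(colSums(m2) > 0))
  side <- max(ri[2] - ri[1] + 1, ci[2] - ci[1] + 1) * (1 + margin)
  slice <- volume$values[, , k]
  slice[is.na(slice)] <- 0
  patch <- resample_square(slice, voi$center[1:2], side, 64L)
  lesion_crop(minmax01(patch), patient_id, modality_timepoint, responder)
}

# Rotate a 64x64 matrix by k * 45 degrees about the image center.
# Multiples of 90 degrees are exact index permutations (so the 180-degree
# rotation equals the double axis flip with no interpolation); odd multiples
# use bilinear interpolation with zero fill outside the support.
rotate_crop_pixels <- function(m, k) {
  k <- as.integer(k) %% 8L
  if (k == 0L) return(m)
  if (k %% 2L == 0L) {
    q <- k %/% 2L                        # quarter turns
    out <- m
    for (i in seq_len(q)) out <- t(out)[rev(seq_len(ncol(out))), , drop = FALSE]
    return(out)
  }
  theta <- k * pi / 4
  cc <- (nrow(m) + 1) / 2
  idx <- seq_len(nrow(m)) - cc
  u <- rep(idx, times = ncol(m))
  v <- rep(idx, each = nrow(m))
  sx <- cos(theta) * u + sin(theta) * v + cc
  sy <- -sin(theta) * u + cos(theta) * v + cc
  matrix(bilinear_sample(m, sx, sy), nrow(m), ncol(m))
}

#' Rotation augmentation of responder crops
#'
#' Each input crop is rotated seven times in 45-degree increments (45, 90,
#' ..., 315 degrees) about the image center, producing seven augmented copies
#' per input; the originals are not included in the output. Augmentation is
#' applied to responder images only (it exists to balance the minority class),
#' so non-responder input is an error.
#'
#' @param crops list of responder [lesion_crop()]s.
#' @return list of `7 * length(crops)` augmented crops.
#' @export
augment_rotations <- function(crops) {
  if (length(crops) == 0L) return(list())
  if (any(!vapply(crops, function(cr) cr$responder, logical(1))))
    stop("augmentation is applied to responder crops only")
  out <- vector("list", 7L * length(crops))
  pos <- 0L
  for (cr in crops) {
    for (k in 1:7) {
      pos <- pos + 1L
      out[[pos]] <- lesion_crop(rotate_crop_pixels(cr$pixels, k),
                                cr$patient_id, cr$modality_timepoint,
                                cr$responder, sprintf("rotation_%dx45", k))
    }
  }
  out
}

#' Build the crop dataset for one modality/timepoint
#'
#' Crops one original 64x64 patch per patient from the requested volume
#' (`PET0`/`PET1`: baseline/interim PET; `MRI0`/`MRI1`: ADC map computed from
#' the baseline/interim DWI pair). With `augment = TRUE` the responder
#' originals are additionally rotated seven times, so a cohort of 6 responders
#' and 50 non-responders yields 98 crops of which 48 are responder-labelled.
#'
#' @param cohort list of `patient_study` objects.
#' @param modality_timepoint one of `"PET0"`, `"PET1"`, `"MRI0"`, `"MRI1"`.
#' @param augment include 7 rotated copies of each responder crop.
#' @param config a [quant_config()] (used for ADC mapping).
#' @return list of [lesion_crop()]s.
#' @export
build_dataset <- function(cohort, modality_timepoint = c("PET0", "PET1", "MRI0", "MRI1"),
                          augment = FALSE, config = quant_config()) {
  modality_timepoint <- match.arg(modality_timepoint)
  if (length(cohort) == 0L) stop("cohort is empty")
  originals <- lapply(cohort, function(study) {
    interim <- modality_timepoint %in% c("PET1", "MRI1")
    volume <- switch(modality_timepoint,
                     PET0 = study$pet_baseline,
                     PET1 = study$pet_interim,
                     MRI0 = adc_map(study$dwi_baseline$b0, study$dwi_baseline$bhigh, config),
                     MRI1 = adc_map(study$dwi_interim$b0, study$dwi_interim$bhigh, config))
    radii <- if (interim) study$tumor_radii_interim else study$tumor_radii
    voi <- ellipsoid_voi(study$tumor_center, radii)
    crop_lesion(volume, voi, modality_timepoint, study$patient_id, study$true_response)
  })
  if (!augment) return(originals)
  responders <- Filter(function(cr) cr$responder, originals)
  c(originals, augment_rotations(responders))
}

crop_labels <- function(crops) vapply(crops, function(cr) cr$responder, logical(1))
crop_patients <- function(crops) vapply(crops, function(cr) cr$patient_id, character(1))

#' Split a crop dataset into training and test sets by patient
#'
#' The split is stratified by response label and performed at the patient
#' level: all crops sharing a `patient_id` (originals and rotated copies) land
#' on the same side, so augmentation can never leak a patient across the
#' split. Within each class the training share is as close to
#' `train_fraction` as the integer patient count allows, with at least one
#' patient on each side.
#'
#' @param dataset list of [lesion_crop()]s.
#' @param train_fraction fraction of patients assigned to training (default 0.8).
#' @param seed integer seed for the patient shuffle.
#' @return list with elements `train` and `test` (lists of crops).
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, seed = 1L) {
  pid <- crop_patients(dataset)
  lab <- crop_labels(dataset)
  patients <- !duplicated(pid)
  tab <- split(pid[patients], lab[patients])
  if (length(tab) < 2L || any(lengths(tab) < 2L))
    stop("need at least two patients per class to split")
  train_ids <- with_seed(derive_seed(seed, 0L, 2L), {
    unlist(lapply(tab, function(ids) {
      ids <- sample(ids)
      n_train <- min(max(round(train_fraction * length(ids)), 1L), length(ids) - 1L)
      ids[seq_len(n_train)]
    }), use.names = FALSE)
  })
  list(train = dataset[pid %in% train_ids],
       test = dataset[!(pid %in% train_ids)])
}

# Assign training patients to k cross-validation folds, stratified by class
# (round-robin over a seeded shuffle within each class). Returns the fold id
# of every crop. Errors when any fold would miss a class.
assign_folds <- function(crops, k = 3L, seed = 1L) {
  pid <- crop_patients(crops)
  lab <- crop_labels(crops)
  patients <- !duplicated(pid)
  fold_of <- with_seed(derive_seed(seed, 0L, 3L), {
    out <- list()
    for (cls in unique(lab[patients])) {
      ids <- sample(pid[patients][lab[patients] == cls])
      out[ids] <- rep_len(seq_len(k), length(ids))
    }
    unlist(out)
  })
  folds <- fold_of[pid]
  for (f in seq_len(k)) {
    in_fold <- folds == f
    if (!any(in_fold) || length(unique(lab[in_fold])) < 2L ||
        length(unique(lab[!in_fold])) < 2L)
      stop("degenerate fold: every fold (and its complement) needs both classes")
  }
  unname(folds)
}
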