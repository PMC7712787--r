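#' Write a phantom cohort to NIfTI volumes plus a manifest CSV
#'
#' Each patient's six volumes (baseline/interim PET, baseline/interim DWI
#' b0/high-b pairs) are written as NIfTI-1 `.nii.gz` files with the voxel
#' spacing in the header. The manifest records per patient: id, grade, true
#' response, ER/PR/HER2 flags, tumour geometry, applied ground-truth effect
#' sizes, and the six file paths (relative to the manifest location).
#'
#' @param cohort list of `patient_study` objects.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vol <- function(vol, path) {
    img <- RNifti::asNifti(vol$values)
    img <- RNifti::`pixdim<-`(img, vol$spacing)
    RNifti::writeNifti(img, path, datatype = "double")
  }
  rows <- lapply(cohort, function(st) {
    files <- c(pet0 = sprintf("%s_pet0.nii.gz", st$patient_id),
               pet1 = sprintf("%s_pet1.nii.gz", st$patient_id),
               dwi0_b0 = sprintf("%s_dwi0_b0.nii.gz", st$patient_id),
               dwi0_bhigh = sprintf("%s_dwi0_bhigh.nii.gz", st$patient_id),
               dwi1_b0 = sprintf("%s_dwi1_b0.nii.gz", st$patient_id),
               dwi1_bhigh = sprintf("%s_dwi1_bhigh.nii.gz", st$patient_id))
    write_vol(st$pet_baseline, file.path(dir, files["pet0"]))
    write_vol(st$pet_interim, file.path(dir, files["pet1"]))
    write_vol(st$dwi_baseline$b0, file.path(dir, files["dwi0_b0"]))
    write_vol(st$dwi_baseline$bhigh, file.path(dir, files["dwi0_bhigh"]))
    write_vol(st$dwi_interim$b0, file.path(dir, files["dwi1_b0"]))
    write_vol(st$dwi_interim$bhigh, file.path(dir, files["dwi1_bhigh"]))
    data.frame(patient_id = st$patient_id, grade = st$grade,
               true_response = st$true_response,
               ER = unname(st$subtype["ER"]), PR = unname(st$subtype["PR"]),
               HER2 = unname(st$subtype["HER2"]),
               center_x = st$tumor_center[1], center_y = st$tumor_center[2],
               center_z = st$tumor_center[3],
               radius_x = st$tumor_radii[1], radius_y = st$tumor_radii[2],
               radius_z = st$tumor_radii[3],
               radius1_x = st$tumor_radii_interim[1],
               radius1_y = st$tumor_radii_interim[2],
               radius1_z = st$tumor_radii_interim[3],
               truth_dsuv = st$truth$dsuv, truth_dmtv = st$truth$dmtv,
               truth_dadc = st$truth$dadc,
               file_pet0 = files[["pet0"]], file_pet1 = files[["pet1"]],
               file_dwi0_b0 = files[["dwi0_b0"]], file_dwi0_bhigh = files[["dwi0_bhigh"]],
               file_dwi1_b0 = files[["dwi1_b0"]], file_dwi1_bhigh = files[["dwi1_bhigh"]],
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom cohort back from a manifest CSV
#'
#' Reconstructs the `patient_study` list written by [write_cohort()]; volume
#' paths in the manifest are resolved relative to the manifest location.
#'
#' @param manifest path to a manifest CSV.
#' @return list of `patient_study` objects.
#' @export
read_cohort <- function(manifest) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  read_vol <- function(fname, modality) {
    img <- RNifti::readNifti(file.path(dir, fname))
    voxel_volume(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img), modality)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    structure(list(patient_id = r$patient_id,
                   pet_baseline = read_vol(r$file_pet0, "SUV"),
                   pet_interim = read_vol(r$file_pet1, "SUV"),
                   dwi_baseline = list(b0 = read_vol(r$file_dwi0_b0, "DWI_b0"),
                                       bhigh = read_vol(r$file_dwi0_bhigh, "DWI_b800")),
                   dwi_interim = list(b0 = read_vol(r$file_dwi1_b0, "DWI_b0"),
                                      bhigh = read_vol(r$file_dwi1_bhigh, "DWI_b800")),
                   tumor_center = c(r$center_x, r$center_y, r$center_z),
                   tumor_radii = c(r$radius_x, r$radius_y, r$radius_z),
                   tumor_radii_interim = c(r$radius1_x, r$radius1_y, r$radius1_z),
                   true_response = r$true_response,
                   grade = r$grade,
                   subtype = c(ER = r$ER, PR = r$PR, HER2 = r$HER2),
                   truth = list(dsuv = r$truth_dsuv, dmtv = r$truth_dmtv,
                                dadc = r$truth_dadc)),
              class = "patient_study")
  })
}
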