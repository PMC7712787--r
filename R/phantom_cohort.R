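#' Configuration for a synthetic longitudinal PET/DWI phantom cohort
#'
#' Defines the study conditions for [generate_cohort()]. Each patient carries
#' an ellipsoidal tumour rendered into baseline and interim PET (SUV) volumes
#' and baseline and interim DWI pairs (b = 0 and b = 800 s/mm^2). Responders
#' are given a large metabolic decline and ADC rise between baseline and
#' interim imaging; non-responders small changes. Defaults emulate a cohort of
#' 6 responders and 50 non-responders with class effect sizes that straddle
#' typical early-response cutoffs (around -56 percent for delta-SUVmax and +25
#' percent for delta-ADC).
#'
#' All `*_dist` arguments are `c(mean, sd)` pairs. SUV distributions are on
#' the natural SUV scale (baseline SUVmax is lognormal with that mean/sd);
#' percent-change distributions are Gaussian in percent; ADC distributions are
#' in 10^-3 mm^2/s. Draws are truncated at small positive floors so rendered
#' intensities stay positive: baseline SUVmax >= 3, interim peak SUV >=
#' background + 0.1, baseline ADC >= 0.3e-3 mm^2/s, percent changes >= -99.9
#' (volume) / -90 (ADC). The truncated value is what the generator applies and
#' records as ground truth.
#'
#' @param n_responders,n_nonresponders patient counts (>= 0).
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm per voxel.
#' @param tumor_radius_range min/max ellipsoid semi-axis, mm.
#' @param baseline_suvmax_dist lognormal mean/sd of the baseline peak SUV.
#' @param responder_dsuv_dist,nonresponder_dsuv_dist percent change of peak
#'   SUV between baseline and interim.
#' @param responder_dmtv_dist,nonresponder_dmtv_dist percent change of tumour
#'   volume; interim semi-axes scale by its cube root.
#' @param baseline_adc_dist tumour ADC at baseline, 10^-3 mm^2/s.
#' @param responder_dadc_dist,nonresponder_dadc_dist percent change of tumour ADC.
#' @param background_suv,background_adc background tissue SUV and ADC
#'   (10^-3 mm^2/s).
#' @param noise_sigma relative noise level: sd of the multiplicative Gaussian
#'   PET noise and the Rician scale as a fraction of the DWI b0 signal.
#' @param texture_flag if `TRUE`, responder tumours receive multiplicative
#'   intratumoral speckle of amplitude `texture_amp` (both PET and ADC), giving
#'   the lesion crops a class-specific texture signal that the conventional
#'   scalar parameters cannot see.
#' @param texture_amp speckle amplitude (sd of the multiplicative factor).
#' @param subtype_prevalence named probabilities for ER/PR/HER2 positivity
#'   (defaults follow the observed marginal proportions of a 56-patient
#'   advanced breast cancer cohort).
#' @param s0_level DWI b0 signal level (a.u.).
#' @param b_high high b-value, s/mm^2.
#' @param seed integer; single top-level seed. Per-patient substreams are
#'   derived by counter so cohort-size changes never reshuffle earlier patients.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_responders = 6, n_nonresponders = 50,
                          grid_shape = c(64L, 64L, 64L),
                          voxel_spacing = c(2, 2, 2),
                          tumor_radius_range = c(10, 25),
                          baseline_suvmax_dist = c(mean = 8, sd = 3),
                          responder_dsuv_dist = c(mean = -70, sd = 15),
                          nonresponder_dsuv_dist = c(mean = -20, sd = 15),
                          responder_dmtv_dist = c(mean = -90, sd = 8),
                          nonresponder_dmtv_dist = c(mean = -30, sd = 20),
                          baseline_adc_dist = c(mean = 1.0, sd = 0.15),
                          responder_dadc_dist = c(mean = 40, sd = 15),
                          nonresponder_dadc_dist = c(mean = 5, sd = 10),
                          background_suv = 0.3,
                          background_adc = 1.8,
                          noise_sigma = 0.05,
                          texture_flag = FALSE,
                          texture_amp = 0.4,
                          subtype_prevalence = c(ER = 0.45, PR = 0.58, HER2 = 0.38),
                          s0_level = 1000,
                          b_high = 800,
                          seed = 1L) {
  cfg <- list(n_responders = as.integer(n_responders),
              n_nonresponders = as.integer(n_nonresponders),
              grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              tumor_radius_range = as.numeric(tumor_radius_range),
              baseline_suvmax_dist = unname(as.numeric(baseline_suvmax_dist)),
              responder_dsuv_dist = unname(as.numeric(responder_dsuv_dist)),
              nonresponder_dsuv_dist = unname(as.numeric(nonresponder_dsuv_dist)),
              responder_dmtv_dist = unname(as.numeric(responder_dmtv_dist)),
              nonresponder_dmtv_dist = unname(as.numeric(nonresponder_dmtv_dist)),
              baseline_adc_dist = unname(as.numeric(baseline_adc_dist)),
              responder_dadc_dist = unname(as.numeric(responder_dadc_dist)),
              nonresponder_dadc_dist = unname(as.numeric(nonresponder_dadc_dist)),
              background_suv = as.numeric(background_suv),
              background_adc = as.numeric(background_adc),
              noise_sigma = as.numeric(noise_sigma),
              texture_flag = isTRUE(texture_flag),
              texture_amp = as.numeric(texture_amp),
              subtype_prevalence = subtype_prevalence,
              s0_level = as.numeric(s0_level),
              b_high = as.numeric(b_high),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_responders < 0L || cfg$n_nonresponders < 0L)
    stop("configuration error: patient counts must be >= 0")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape <= 0L))
    stop("configuration error: grid_shape must be 3 positive integers")
  if (length(cfg$voxel_spacing) != 3L || any(cfg$voxel_spacing <= 0))
    stop("configuration error: voxel_spacing must be positive")
  if (length(cfg$tumor_radius_range) != 2L || any(cfg$tumor_radius_range <= 0) ||
      diff(cfg$tumor_radius_range) < 0)
    stop("configuration error: tumor_radius_range must be positive and ordered")
  for (nm in grep("_dist$", names(cfg), value = TRUE)) {
    d <- cfg[[nm]]
    if (length(d) != 2L || !all(is.finite(d)) || d[2] < 0)
      stop("configuration error: ", nm, " must be c(mean, sd) with sd >= 0")
  }
  if (cfg$background_suv < 0 || cfg$background_adc <= 0)
    stop("configuration error: backgrounds must be non-negative (SUV) / positive (ADC)")
  if (cfg$noise_sigma < 0) stop("configuration error: noise_sigma must be >= 0")
  if (cfg$s0_level <= 0 || cfg$b_high <= 0)
    stop("configuration error: s0_level and b_high must be positive")
  if (!all(c("ER", "PR", "HER2") %in% names(cfg$subtype_prevalence)))
    stop("configuration error: subtype_prevalence needs ER, PR, HER2")
  invisible(cfg)
}

# Squared normalized ellipsoid coordinate at every voxel center:
# u2 <= 1 inside the ellipsoid. center in voxel indices, radii in mm.
ellipsoid_u2 <- function(grid_shape, spacing, center, radii) {
  a1 <- ((seq_len(grid_shape[1]) - center[1]) * spacing[1] / radii[1])^2
  a2 <- ((seq_len(grid_shape[2]) - center[2]) * spacing[2] / radii[2])^2
  a3 <- ((seq_len(grid_shape[3]) - center[3]) * spacing[3] / radii[3])^2
  outer(outer(a1, a2, "+"), a3, "+")
}

#' Render an ellipsoidal tumour into a PET (SUV) volume
#'
#' Voxels whose centers lie inside the ellipsoid carry a smooth quadratic
#' profile that peaks at `suv_peak` at the center and falls to 40 percent of
#' the peak at the rim; all other voxels carry `background`. Optional
#' intratumoral speckle multiplies in-tumour values by `1 + texture_amp * Z`
#' (clipped at 0.1). Multiplicative Gaussian noise of relative sd
#' `noise_sigma` is then applied to the whole volume and the result floored at
#' zero. Uses the current RNG state.
#'
#' @param center tumour center, voxel indices (length 3).
#' @param radii ellipsoid semi-axes in mm (all > 0).
#' @param suv_peak peak SUV (> `background`).
#' @param background background SUV (>= 0).
#' @param noise_sigma relative sd of the multiplicative Gaussian noise.
#' @param grid_shape,spacing grid geometry.
#' @param texture_amp intratumoral speckle amplitude (0 = none).
#' @return a `voxel_volume` of modality `"SUV"`.
#' @export
render_tumor_pet <- function(center, radii, suv_peak, background, noise_sigma,
                             grid_shape, spacing, texture_amp = 0) {
  if (any(radii <= 0)) stop("radii must be positive")
  if (background < 0 || suv_peak <= background)
    stop("suv_peak must exceed background and background must be >= 0")
  u2 <- ellipsoid_u2(grid_shape, spacing, center, radii)
  inside <- u2 <= 1
  vals <- array(background, dim = grid_shape)
  vals[inside] <- suv_peak * (1 - 0.6 * u2[inside])
  if (texture_amp > 0 && any(inside))
    vals[inside] <- vals[inside] * pmax(1 + texture_amp * rnorm(sum(inside)), 0.1)
  if (noise_sigma > 0)
    vals <- vals * (1 + noise_sigma * rnorm(length(vals)))
  vals[vals < 0] <- 0
  voxel_volume(vals, spacing, "SUV")
}

# Piecewise-constant ADC field (mm^2/s): adc_tumor inside the ellipsoid,
# adc_background outside, optional multiplicative speckle inside.
make_adc_field <- function(center, radii, adc_tumor, adc_background,
                           grid_shape, spacing, texture_amp = 0) {
  u2 <- ellipsoid_u2(grid_shape, spacing, center, radii)
  inside <- u2 <= 1
  vals <- array(adc_background, dim = grid_shape)
  vals[inside] <- adc_tumor
  if (texture_amp > 0 && any(inside))
    vals[inside] <- vals[inside] * pmax(1 + texture_amp * rnorm(sum(inside)), 0.1)
  voxel_volume(vals, spacing, "ADC")
}

#' Render a DWI b0 / high-b signal pair from an ADC field
#'
#' The b0 volume is `s0_level` everywhere; the high-b volume follows the
#' monoexponential diffusion decay `s0_level * exp(-b_high * ADC)`. Noise is
#' Rician with scale `noise_sigma * s0_level` (the standard magnitude-MR
#' model); with `noise_sigma = 0` the signals are exact, so
#' [adc_map()] recovers the input field to floating-point accuracy.
#' Uses the current RNG state.
#'
#' @param adc_field a `voxel_volume` of modality `"ADC"` (mm^2/s, all > 0).
#' @param s0_level b0 signal level (> 0).
#' @param b_high high b-value in s/mm^2 (> 0).
#' @param noise_sigma Rician scale as a fraction of `s0_level`.
#' @return list with elements `b0` and `bhigh` (`voxel_volume`s of modality
#'   `"DWI_b0"` and `"DWI_b800"`).
#' @export
render_dwi_pair <- function(adc_field, s0_level, b_high, noise_sigma = 0) {
  stopifnot(inherits(adc_field, "voxel_volume"), adc_field$modality == "ADC")
  if (anyNA(adc_field$values) || any(adc_field$values <= 0))
    stop("adc_field must be strictly positive")
  if (s0_level <= 0) stop("s0_level must be positive")
  if (b_high <= 0) stop("b_high must be positive")
  d <- dim(adc_field$values)
  s_b0 <- array(s0_level, dim = d)
  s_hi <- s0_level * exp(-b_high * adc_field$values)
  if (noise_sigma > 0) {
    sg <- noise_sigma * s0_level
    n <- length(s_b0)
    s_b0 <- sqrt((s_b0 + sg * rnorm(n))^2 + (sg * rnorm(n))^2)
    s_hi <- sqrt((s_hi + sg * rnorm(n))^2 + (sg * rnorm(n))^2)
    dim(s_b0) <- d; dim(s_hi) <- d
  }
  list(b0 = voxel_volume(s_b0, adc_field$spacing, "DWI_b0"),
       bhigh = voxel_volume(s_hi, adc_field$spacing, "DWI_b800"))
}

#' Draw a Miller-Payne grade consistent with the latent response
#'
#' Responders receive grade 4 or 5, non-responders grade 1, 2 or 3, uniformly
#' within the set. Uses the current RNG state.
#'
#' @param true_response logical scalar.
#' @return integer grade in 1..5.
#' @export
assign_grade <- function(true_response) {
  stopifnot(is.logical(true_response), length(true_response) == 1L, !is.na(true_response))
  if (true_response) sample(4:5, 1L) else sample(1:3, 1L)
}

rnorm2 <- function(dist) rnorm(1L, dist[1], dist[2])

#' Generate a synthetic longitudinal PET/DWI cohort
#'
#' Draws `n_responders + n_nonresponders` patients (responders first) from the
#' study conditions in `config`. Each patient gets an ellipsoidal tumour at a
#' random interior location, a baseline peak SUV, class-specific percent
#' changes of peak SUV, tumour volume and tumour ADC, rendered baseline and
#' interim PET volumes and DWI pairs, a Miller-Payne grade consistent with the
#' latent response (grades 4-5 iff responder), and independent ER/PR/HER2
#' flags. The applied (truncated) effect sizes are stored in `$truth` as
#' per-patient ground truth. Identical configs (including seed) give
#' bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return list of `patient_study` objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  n <- config$n_responders + config$n_nonresponders
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    responder <- i <= config$n_responders
    with_seed(derive_seed(config$seed, i, 1L),
              simulate_patient(config, sprintf("P%03d", i), responder))
  })
}

simulate_patient <- function(cfg, patient_id, responder) {
  gs <- cfg$grid_shape; sp <- cfg$voxel_spacing
  radii <- runif(3L, cfg$tumor_radius_range[1], cfg$tumor_radius_range[2])

  # keep the tumour plus a 35% margin inside the grid
  margin <- ceiling(1.35 * radii / sp) + 1L
  lo <- margin + 1L; hi <- gs - margin
  if (any(lo > hi))
    stop("configuration error: grid too small for the configured tumor radii")
  center <- vapply(1:3, function(a) if (lo[a] == hi[a]) lo[a] else sample(lo[a]:hi[a], 1L),
                   integer(1))

  # baseline peak SUV: lognormal parameterized by natural-scale mean/sd
  m <- cfg$baseline_suvmax_dist[1]; s <- cfg$baseline_suvmax_dist[2]
  sdlog <- sqrt(log(1 + (s / m)^2))
  peak0 <- max(rlnorm(1L, log(m) - sdlog^2 / 2, sdlog), 3.0)

  dsuv <- rnorm2(if (responder) cfg$responder_dsuv_dist else cfg$nonresponder_dsuv_dist)
  peak1 <- max(peak0 * (1 + dsuv / 100), cfg$background_suv + 0.1)
  dsuv <- (peak1 / peak0 - 1) * 100            # applied value is the ground truth

  dmtv <- max(rnorm2(if (responder) cfg$responder_dmtv_dist else cfg$nonresponder_dmtv_dist),
              -99.9)
  radii1 <- radii * (1 + dmtv / 100)^(1 / 3)

  adc0 <- max(rnorm2(cfg$baseline_adc_dist), 0.3)          # 1e-3 mm^2/s
  dadc <- max(rnorm2(if (responder) cfg$responder_dadc_dist else cfg$nonresponder_dadc_dist),
              -90)
  adc1 <- adc0 * (1 + dadc / 100)

  tex <- if (cfg$texture_flag && responder) cfg$texture_amp else 0

  pet0 <- render_tumor_pet(center, radii, peak0, cfg$background_suv,
                           cfg$noise_sigma, gs, sp, texture_amp = tex)
  pet1 <- render_tumor_pet(center, radii1, peak1, cfg$background_suv,
                           cfg$noise_sigma, gs, sp, texture_amp = tex)
  field0 <- make_adc_field(center, radii, adc0 * 1e-3, cfg$background_adc * 1e-3,
                           gs, sp, texture_amp = tex)
  field1 <- make_adc_field(center, radii1, adc1 * 1e-3, cfg$background_adc * 1e-3,
                           gs, sp, texture_amp = tex)
  dwi0 <- render_dwi_pair(field0, cfg$s0_level, cfg$b_high, cfg$noise_sigma)
  dwi1 <- render_dwi_pair(field1, cfg$s0_level, cfg$b_high, cfg$noise_sigma)

  grade <- assign_grade(responder)
  prev <- cfg$subtype_prevalence
  subtype <- c(ER = runif(1L) < prev[["ER"]],
               PR = runif(1L) < prev[["PR"]],
               HER2 = runif(1L) < prev[["HER2"]])

  structure(list(patient_id = patient_id,
                 pet_baseline = pet0, pet_interim = pet1,
                 dwi_baseline = dwi0, dwi_interim = dwi1,
                 tumor_center = center,
                 tumor_radii = radii,
                 tumor_radii_interim = radii1,
                 true_response = responder,
                 grade = grade,
                 subtype = subtype,
                 truth = list(dsuv = dsuv, dmtv = dmtv, dadc = dadc,
                              suv_peak0 = peak0, suv_peak1 = peak1,
                              adc0 = adc0, adc1 = adc1)),
            class = "patient_study")
}

#' @export
print.patient_study <- function(x, ...) {
  cat(sprintf("<patient_study %s> %s, grade %d; dSUV %.1f%%, dADC %.1f%%\n",
              x$patient_id, if (x$true_response) "responder" else "non-responder",
              x$grade, x$truth$dsuv, x$truth$dadc))
  invisible(x)
}
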