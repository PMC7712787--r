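test_that("SUVmax, MTV and TLG match exhaustive-enumeration oracles", {
  set.seed(11)
  for (rep in 1:25) {
    dims <- sample(8:12, 3L, replace = TRUE)
    vol <- random_suv_volume(dims)
    voi <- random_voi(dims)
    expect_identical(suv_max(vol, voi), brute_suv_max(vol, voi))
    expect_identical(metabolic_tumor_volume(vol, voi), brute_mtv(vol, voi))
    expect_equal(total_lesion_glycolysis(vol, voi), brute_tlg(vol, voi))
  }
})

test_that("PET quantification handles constants, thresholds and units", {
  sp <- c(2, 2, 2)
  voi <- ellipsoid_voi(c(5, 5, 5), c(6, 6, 6))

  flat <- voxel_volume(array(3, c(10, 10, 10)), sp, "SUV")
  expect_equal(suv_max(flat, voi), 3)

  # sub-threshold lesion: MTV and TLG are zero
  dim_vol <- voxel_volume(array(2.4, c(10, 10, 10)), sp, "SUV")
  expect_equal(metabolic_tumor_volume(dim_vol, voi), 0)
  expect_equal(total_lesion_glycolysis(dim_vol, voi), 0)

  # threshold is inclusive: voxels exactly at 2.5 qualify
  at_thr <- voxel_volume(array(2.5, c(10, 10, 10)), sp, "SUV")
  expect_gt(metabolic_tumor_volume(at_thr, voi), 0)

  # exactly 100 qualifying voxels at 2x2x2 mm -> 0.8 mL; all at 4.0 -> TLG 3.2
  vals <- array(0, c(10, 10, 10))
  mask <- nacresp:::voi_mask(flat, voi)
  inside <- which(mask)[1:100]
  vals[inside] <- 4.0
  vol100 <- voxel_volume(vals, sp, "SUV")
  expect_equal(metabolic_tumor_volume(vol100, voi), 0.8)
  expect_equal(total_lesion_glycolysis(vol100, voi), 0.8 * 4.0)

  # VOI outside the grid errors
  expect_error(suv_max(flat, ellipsoid_voi(c(50, 50, 50), c(1, 1, 1))), "intersect")
})

test_that("MTV/TLG are monotone in the threshold and scale-consistent", {
  set.seed(12)
  vol <- random_suv_volume(c(12, 12, 12))
  voi <- ellipsoid_voi(c(6, 6, 6), c(8, 8, 8))
  thr <- sort(runif(6, 0.5, 6))
  mtv <- vapply(thr, function(t) metabolic_tumor_volume(vol, voi, quant_config(suv_threshold = t)), numeric(1))
  tlg <- vapply(thr, function(t) total_lesion_glycolysis(vol, voi, quant_config(suv_threshold = t)), numeric(1))
  expect_true(all(diff(mtv) <= 0))
  expect_true(all(diff(tlg) <= 0))

  # TLG / MTV lies between threshold and SUVmax whenever MTV > 0
  q <- quant_config()
  m <- metabolic_tumor_volume(vol, voi, q)
  if (m > 0) {
    ratio <- total_lesion_glycolysis(vol, voi, q) / m
    expect_gte(ratio, q$suv_threshold)
    expect_lte(ratio, suv_max(vol, voi))
  }

  # multiplying the volume by c scales SUVmax by c
  vol2 <- voxel_volume(vol$values * 3, vol$spacing, "SUV")
  expect_equal(suv_max(vol2, voi), 3 * suv_max(vol, voi))
})

test_that("ADC mapping applies the two-point log formula with guards", {
  sp <- c(2, 2, 2); d <- c(6, 6, 4)
  b0 <- voxel_volume(array(1000, d), sp, "DWI_b0")
  bh <- voxel_volume(array(449.3290, d), sp, "DWI_b800")
  adc <- adc_map(b0, bh, quant_config())
  expect_equal(adc$values[1, 1, 1], 1.0e-3, tolerance = 1e-6)

  # equal signals -> ADC 0
  same <- adc_map(b0, b0, quant_config())
  expect_true(all(same$values == 0))

  # noise pushing the high-b signal above b0 clamps the ADC at 0
  hot <- voxel_volume(array(1100, d), sp, "DWI_b800")
  expect_true(all(adc_map(b0, hot, quant_config())$values == 0))

  # sub-floor signal is marked invalid
  weak <- voxel_volume(array(c(0, rep(500, prod(d) - 1)), d), sp, "DWI_b800")
  flagged <- adc_map(b0, weak, quant_config(signal_floor = 1))
  expect_true(is.na(flagged$values[1, 1, 1]))
  expect_false(anyNA(flagged$values[-1]))

  mismatch <- voxel_volume(array(1, c(5, 6, 4)), sp, "DWI_b800")
  expect_error(adc_map(b0, mismatch), "match")
})

test_that("circular ROI means agree with the pixel-scan oracle", {
  sp <- c(2, 2, 2)
  set.seed(13)
  vals <- array(runif(10 * 10 * 5, 0.5e-3, 2e-3), c(10, 10, 5))
  adc <- voxel_volume(vals, sp, "ADC")

  unif <- voxel_volume(array(1.1e-3, c(10, 10, 5)), sp, "ADC")
  roi <- circle_roi(3, c(5, 5), 4)
  expect_equal(roi_mean_adc(unif, roi), 1.1e-3)

  # sub-voxel radius: the single enclosed voxel
  expect_equal(roi_mean_adc(adc, circle_roi(2, c(5, 5), 0.9)), vals[5, 5, 2])

  for (rep in 1:20) {
    r <- circle_roi(sample(1:5, 1), c(runif(1, 4, 7), runif(1, 4, 7)), runif(1, 1, 5))
    expect_equal(roi_mean_adc(adc, r), brute_roi_mean(adc, r))
  }

  # circle leaving the slice, or no valid voxel, errors
  expect_error(roi_mean_adc(adc, circle_roi(1, c(2, 5), 6)), "inside the slice")
  all_na <- voxel_volume(array(NA_real_, c(10, 10, 5)), sp, "ADC")
  expect_error(roi_mean_adc(all_na, roi), "no valid ADC voxel")
})

test_that("percent change follows the baseline-relative formula", {
  expect_equal(percent_change(10, 5), -50)
  expect_equal(percent_change(7, 7), 0)
  expect_true(is.na(percent_change(0, 3)))
  expect_error(percent_change(-1, 3), "non-negative")
  # scale invariance: percent_change(cx, cy) == percent_change(x, y)
  expect_equal(percent_change(3 * 4.2, 3 * 2.1), percent_change(4.2, 2.1))
})

test_that("parameter records cover all twelve fields with missing-value rules", {
  co <- tiny_cohort(n_resp = 1, n_non = 1, seed = 21)
  st <- co[[1]]

  # identical baseline and interim volumes: all deltas are zero
  st0 <- st
  st0$pet_interim <- st0$pet_baseline
  st0$dwi_interim <- st0$dwi_baseline
  st0$tumor_radii_interim <- st0$tumor_radii
  rec <- extract_parameters(st0)
  expect_equal(rec$dsuv, 0)
  expect_equal(rec$dmtv, 0)
  expect_equal(rec$dtlg, 0)
  expect_equal(rec$dadc, 0)

  # sub-threshold baseline: mtv0 = tlg0 = 0 and the volume deltas are missing
  st1 <- st
  st1$pet_baseline <- voxel_volume(st$pet_baseline$values * 0.1,
                                   st$pet_baseline$spacing, "SUV")
  rec1 <- extract_parameters(st1)
  expect_equal(rec1$mtv0, 0)
  expect_equal(rec1$tlg0, 0)
  expect_true(is.na(rec1$dmtv))
  expect_true(is.na(rec1$dtlg))
  expect_false(is.na(rec1$dsuv))
})
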