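test_that("lesion crops are 64x64, normalized, and centered on the lesion", {
  co <- tiny_cohort(n_resp = 1, n_non = 1, seed = 51)
  st <- co[[1]]
  voi <- ellipsoid_voi(st$tumor_center, st$tumor_radii)
  cr <- crop_lesion(st$pet_baseline, voi, "PET0", st$patient_id, st$true_response)
  expect_identical(dim(cr$pixels), c(64L, 64L))
  expect_gte(min(cr$pixels), 0)
  expect_lte(max(cr$pixels), 1)

  # the peak pixel lies within 1 pixel of the crop center
  peak <- which(cr$pixels == max(cr$pixels), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - 32.5)), 1.5)

  # a uniform-intensity lesion maps all in-lesion pixels to the same value
  flat <- st$pet_baseline
  flat$values <- array(0, dim(flat$values))
  flat$values[nacresp:::voi_mask(st$pet_baseline, voi)] <- 5
  crf <- crop_lesion(flat, voi, "PET0", "X", TRUE)
  # interior lesion pixels share one constant value (edge pixels blend to 0)
  expect_gt(mean(abs(crf$pixels - 1) < 1e-9), 0.25)
})

test_that("a 64-pixel window resamples to itself", {
  set.seed(52)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- nacresp:::resample_square(img, center = c(32.5, 32.5), side = 64, size = 64L)
  expect_equal(out, img)
})

test_that("rotation augmentation produces 7 copies with exact right-angle turns", {
  set.seed(53)
  crops <- separable_crops(6)[1:6]          # 6 responder originals
  aug <- augment_rotations(crops)
  expect_length(aug, 42L)
  expect_true(all(vapply(aug, function(a) a$responder, logical(1))))
  expect_identical(sort(unique(vapply(aug, function(a) a$provenance, character(1)))),
                   sort(sprintf("rotation_%dx45", 1:7)))

  expect_identical(augment_rotations(list()), list())

  # 180 degrees equals the double axis flip exactly (no interpolation)
  m <- matrix(runif(64 * 64), 64, 64)
  expect_identical(nacresp:::rotate_crop_pixels(m, 4L), m[64:1, 64:1])
  # four quarter turns restore the image exactly
  m90 <- nacresp:::rotate_crop_pixels(m, 2L)
  expect_identical(nacresp:::rotate_crop_pixels(m90, 6L), m)
  # a 45-degree rotation keeps the center pixel mass near the center
  m45 <- nacresp:::rotate_crop_pixels(m, 1L)
  expect_identical(dim(m45), c(64L, 64L))

  bad <- separable_crops(2)[3:4]            # non-responders
  expect_error(augment_rotations(bad), "responder")
})

test_that("dataset assembly reproduces the augmentation bookkeeping", {
  co <- tiny_cohort(n_resp = 3, n_non = 5, seed = 54)
  for (mod in c("PET0", "PET1", "MRI0", "MRI1")) {
    plain <- build_dataset(co, mod, augment = FALSE)
    expect_length(plain, 8L)
    expect_identical(sum(crop_labels(plain)), 3L)
    aug <- build_dataset(co, mod, augment = TRUE)
    # n_nonresp + 8 * n_resp crops, 8 * n_resp responder-labelled
    expect_length(aug, 5L + 8L * 3L)
    expect_identical(sum(crop_labels(aug)), 8L * 3L)
  }
  # a cohort with no responders is unchanged by augmentation
  non <- tiny_cohort(n_resp = 0, n_non = 3, seed = 55)
  expect_length(build_dataset(non, "PET0", augment = TRUE), 3L)
})

test_that("train/test split is patient-level, stratified and deterministic", {
  co <- tiny_cohort(n_resp = 5, n_non = 5, seed = 56)
  ds <- build_dataset(co, "PET0", augment = TRUE)
  sp <- split_train_test(ds, 0.8, seed = 3)
  train_pat <- unique(crop_patients(sp$train))
  test_pat <- unique(crop_patients(sp$test))
  # 10 patients, 5/5: 8 train and 2 test patients, one per class in test
  expect_length(train_pat, 8L)
  expect_length(test_pat, 2L)
  test_lab <- crop_labels(sp$test)[!duplicated(crop_patients(sp$test))]
  expect_identical(sort(test_lab), c(FALSE, TRUE))
  # no patient appears on both sides, including augmented copies
  expect_length(intersect(train_pat, test_pat), 0L)
  # all 8 crops (1 + 7 rotations) of each responder stay together
  for (p in unique(crop_patients(ds))) {
    sides <- c(p %in% train_pat, p %in% test_pat)
    expect_identical(sum(sides), 1L)
  }
  # determinism
  sp2 <- split_train_test(ds, 0.8, seed = 3)
  expect_identical(crop_patients(sp2$train), crop_patients(sp$train))

  expect_error(split_train_test(build_dataset(tiny_cohort(1, 5, seed = 57), "PET0")),
               "two patients per class")
})

test_that("cross-validation folds partition training patients with both classes", {
  co <- tiny_cohort(n_resp = 4, n_non = 6, seed = 58)
  ds <- build_dataset(co, "PET0", augment = TRUE)
  folds <- nacresp:::assign_folds(ds, k = 3L, seed = 2)
  expect_identical(sort(unique(folds)), 1:3)
  pid <- crop_patients(ds)
  # each patient sits in exactly one fold
  expect_true(all(vapply(unique(pid), function(p) length(unique(folds[pid == p])), integer(1)) == 1L))
  # every fold holds both classes
  lab <- crop_labels(ds)
  for (f in 1:3) expect_identical(sort(unique(lab[folds == f])), c(FALSE, TRUE))

  # too few responders for 3 folds -> degenerate fold error
  small <- build_dataset(tiny_cohort(2, 6, seed = 59), "PET0")
  expect_error(nacresp:::assign_folds(small, k = 3L, seed = 2), "degenerate fold")
})

test_that("analytic CNN gradients match numerical differentiation", {
  arch <- arch_config(conv_filters = 3L, conv_kernel = 3L, fc_hidden = 5L,
                      dropout_rate = 0, epochs = 1L, batch_size = 4L)
  set.seed(60)
  net <- nacresp:::cnn_init(arch, input_size = 8L)
  N <- 3L
  x <- array(rnorm(8 * 8 * N), c(8, 8, N))
  y <- c(0L, 1L, 1L)
  loss_of <- function(net) {
    p <- nacresp:::cnn_forward(net, x, N, dropout = FALSE)$probs
    -mean(log(p[cbind(seq_len(N), y + 1L)]))
  }
  cache <- nacresp:::cnn_forward(net, x, N, dropout = FALSE)
  grads <- nacresp:::cnn_backward(net, cache, y, N)
  eps <- 1e-6
  for (nm in names(net$params)) {
    idx <- sample(length(net$params[[nm]]), min(6L, length(net$params[[nm]])))
    for (i in idx) {
      up <- net; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- net; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("max-pooling keeps window maxima and routes gradients to them", {
  x <- array(0, c(4, 4, 1))
  x[, , 1] <- matrix(c(1, 5, 2, 0,
                       3, 4, 8, 7,
                       0, 1, 2, 3,
                       9, 6, 4, 5), 4, 4, byrow = TRUE)
  p <- nacresp:::maxpool_fwd(x)
  expect_equal(p$out[, , 1], matrix(c(5, 8, 9, 5), 2, 2, byrow = TRUE))
  d <- array(1, c(2, 2, 1))
  g <- nacresp:::maxpool_bwd(d, p)
  expect_equal(sum(g), 4)
  expect_equal(g[1, 2, 1], 1)  # the 5 at (1,2)
  expect_equal(g[4, 1, 1], 1)  # the 9 at (4,1)
})

test_that("training is deterministic and learns a separable toy problem", {
  crops <- separable_crops(8)
  arch <- arch_config(conv_filters = 8L, fc_hidden = 16L, dropout_rate = 0.2,
                      learning_rate = 1e-3, epochs = 5L, batch_size = 8L)
  net1 <- train_cnn(crops, arch, seed = 4)
  net2 <- train_cnn(crops, arch, seed = 4)
  expect_identical(predict_cnn(net1, crops), predict_cnn(net2, crops))

  probs <- predict_cnn(net1, crops)
  expect_identical(probs >= 0.5, crop_labels(crops))
})

test_that("evaluation metrics equal hand-computed confusion-matrix counts", {
  probs <- c(0.9, 0.8, 0.6, 0.4, 0.2, 0.7, 0.3, 0.1, 0.55, 0.45)
  labels <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  m <- nacresp:::metrics_from_probs(probs, labels, threshold = 0.5)
  # TP=3 FN=2 TN=3 FP=2 by hand
  expect_equal(unname(m["sensitivity"]), 60)
  expect_equal(unname(m["specificity"]), 60)
  expect_equal(unname(m["accuracy"]), 60)
  expect_equal(unname(m["auc"]), brute_auc(probs, labels))

  # a constant 0.5 classifier has AUC 0.5 by the tie convention
  flat <- nacresp:::metrics_from_probs(rep(0.5, 10), labels)
  expect_equal(unname(flat["auc"]), 0.5)
})
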