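# Random-forest pixel classifier: feature bank, training, segmentation,
# label refinement.

test_that("feature bank has the advertised shape and degenerate behavior", {
  s <- intensity_stack(array(0.5, c(24, 24, 2)))
  spec <- feature_spec(sigmas = c(1, 2, 4, 8),
                       features = c("gaussian", "gradient_magnitude",
                                    "laplacian"))
  fs <- extract_features(s, spec)
  expect_equal(length(fs$feature_names), 4 * 3 + 1)   # + raw
  expect_equal(dim(fs$frames[["1"]]), c(24, 24, 13))
  # constant frame: gradient magnitude identically 0
  expect_true(all(fs$frames[["1"]][, , "gradient_magnitude_s2"] == 0))
  expect_error(feature_spec(sigmas = numeric(0)), "at least one")
})

test_that("gaussian feature of an impulse matches the closed-form kernel peak", {
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  s <- intensity_stack(array(img, c(33, 33, 1)))
  fs <- extract_features(s, feature_spec(sigmas = 2, features = "gaussian"))
  peak <- unname(fs$frames[["1"]][17, 17, "gaussian_s2"])
  expect_equal(peak, 1 / (2 * pi * 2^2), tolerance = 0.05)
})

test_that("training is deterministic and separable labels are fit exactly", {
  ph <- small_phantom(seed = 43, speckle_sigma = 0.05)
  st <- ph$stack
  set.seed(5)
  lab <- sample_phantom_labels(ph, n_per_class = 150, frames = c(3, 8, 12))
  fs <- extract_features(st, feature_spec(sigmas = c(1, 2)),
                         frames = sort(unique(lab$frame)))
  cls <- train_rf(fs, lab, n_trees = 60, seed = 9)
  # training accuracy on the labeled pixels (dark lumens vs bright tissue
  # are separable in this feature space)
  x <- octlumen:::features_at(fs, lab)
  p <- stats::predict(cls$model, data.frame(x, check.names = FALSE),
                      num.threads = 1)$predictions[, "lumen"]
  acc <- mean((p >= 0.5) == (lab$class == "lumen"))
  expect_gte(acc, 0.99)
  # same seed -> identical held-out predictions
  cls2 <- train_rf(fs, lab, n_trees = 60, seed = 9)
  seg1 <- rf_segment(subset_frames(st, 5), cls, closing_radius_px = 0)
  seg2 <- rf_segment(subset_frames(st, 5), cls2, closing_radius_px = 0)
  expect_identical(seg1$data, seg2$data)
  # single-class labels error
  one <- sparse_labels(1, 5, 5, "lumen")
  expect_error(train_rf(fs, one, seed = 1), "both classes")
})

test_that("rf segmentation beats the kappa floor on the phantom benchmark", {
  # a well-separated scene: minimal optical blur, low speckle, low floor
  ph <- small_phantom(seed = 47, speckle_sigma = 0.05,
                      blur_sigma0_px = 0.3, blur_gain_per_frame = 0.01,
                      noise_floor = 0.01)
  st <- ph$stack
  set.seed(6)
  lab <- sample_phantom_labels(ph, n_per_class = 200,
                               frames = c(2, 5, 8, 11, 14), near_frac = 0.5)
  fs <- extract_features(st, feature_spec(sigmas = c(1, 2, 4)),
                         frames = sort(unique(lab$frame)))
  cls <- train_rf(fs, lab, n_trees = 100, seed = 2)
  seg <- rf_segment(st, cls, closing_radius_px = 1)
  prof <- kappa_profile(seg, ph$truth$mask)
  mid <- prof$kappa[prof$depth_um >= 50 & prof$depth_um <= 200]
  expect_gte(mean(mid), 0.7)
  # sanity floor vs the calibrated morphological detector: on a crisp scene
  # the chain needs no erosion (there is no blur halo to trim)
  p <- phantom_mip_params(); p$erosion_radius_px <- 0L
  cal <- calibrate_threshold(st, ph$truth$mask, c(0.02, 0.05, 0.1),
                             params = p)
  mip_prof <- kappa_profile(segment_mip(st, cal$params), ph$truth$mask)
  mip_mid <- mip_prof$kappa[mip_prof$depth_um >= 50 & mip_prof$depth_um <= 200]
  expect_gte(mean(mid), mean(mip_mid) - 0.1)
})

test_that("polarity mismatch is the documented failure mode", {
  ph <- small_phantom(seed = 53, speckle_sigma = 0.05)
  st <- ph$stack
  inverted <- intensity_stack(1 - st$data, st$axis_order,
                              st$pixel_pitch_um, st$frame_spacing_um)
  set.seed(7)
  lab <- sample_phantom_labels(ph, n_per_class = 150, frames = c(4, 9))
  fs_inv <- extract_features(inverted, feature_spec(sigmas = c(1, 2)),
                             frames = c(4, 9))
  cls <- train_rf(fs_inv, lab, n_trees = 60, seed = 3)
  seg <- rf_segment(st, cls, closing_radius_px = 0)
  prof <- kappa_profile(seg, ph$truth$mask)
  mid <- prof$kappa[prof$depth_um >= 50 & prof$depth_um <= 200]
  expect_lte(mean(mid), 0.1)   # near or below zero: classifier transfers badly
})

test_that("closing radius 0 is the identity on thresholded probabilities", {
  ph <- small_phantom(seed = 59, speckle_sigma = 0.05, n_frames = 6)
  st <- ph$stack
  set.seed(8)
  lab <- sample_phantom_labels(ph, n_per_class = 100, frames = c(2, 4))
  fs <- extract_features(st, feature_spec(sigmas = 1), frames = c(2, 4))
  cls <- train_rf(fs, lab, n_trees = 40, seed = 4)
  seg0 <- rf_segment(st, cls, closing_radius_px = 0)
  seg2 <- rf_segment(st, cls, closing_radius_px = 2)
  # closing is extensive: output contains the pre-closing foreground
  expect_true(all(seg2$data >= seg0$data))
})

test_that("label refinement merges corrections and needs non-empty input", {
  ph <- small_phantom(seed = 61, speckle_sigma = 0.05, n_frames = 6)
  st <- ph$stack
  set.seed(9)
  lab <- sample_phantom_labels(ph, n_per_class = 120, frames = c(2, 4))
  fs <- extract_features(st, feature_spec(sigmas = c(1, 2)), frames = c(2, 4))
  cls <- train_rf(fs, lab, n_trees = 40, seed = 11)
  # duplicating existing labels leaves predictions unchanged (same seed)
  dup <- sparse_labels(lab$frame[1:10], lab$x[1:10], lab$y[1:10],
                       lab$class[1:10])
  cls_dup <- refine_labels(fs, cls, dup)
  test_frame <- subset_frames(st, 3)
  expect_identical(rf_segment(test_frame, cls_dup, 0)$data,
                   rf_segment(test_frame, cls, 0)$data)
  # new corrections are absorbed into the training set
  extra <- sample_phantom_labels(ph, n_per_class = 40, frames = 3)
  cls_ref <- refine_labels(fs3 <- extract_features(
    st, feature_spec(sigmas = c(1, 2)), frames = c(2, 3, 4)), cls, extra)
  expect_equal(nrow(cls_ref$labels), nrow(lab) + nrow(extra))
  expect_error(refine_labels(fs, cls, sparse_labels(integer(0), integer(0),
                                                    integer(0), character(0))),
               "non-empty")
  bad <- sparse_labels(2, 9999, 5, "lumen")
  expect_error(refine_labels(fs, cls, bad), "out-of-range")
})
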