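test_that("KNN votes, breaks ties toward the nearest neighbour and validates k", {
  tr <- data.frame(x = c(0, 10), label = c("A", "B"))
  q <- data.frame(x = 1)
  expect_equal(knn_classify(q, tr, knn_params(1, "x")), "A")
  # k = 1: training rows classify to their own labels
  expect_equal(knn_classify(tr, tr, knn_params(1, "x")), c("A", "B"))
  # k = 3 with neighbours {A, A, B} -> A
  tr3 <- data.frame(x = c(0, 2, 10), label = c("A", "A", "B"))
  expect_equal(knn_classify(data.frame(x = 3), tr3, knn_params(3, "x")), "A")
  # vote tie at k = 2 resolves to the nearest neighbour's class
  tr2 <- data.frame(x = c(1, 4), label = c("A", "B"))
  expect_equal(knn_classify(data.frame(x = 2), tr2, knn_params(2, "x")), "A")
  expect_error(knn_classify(q, tr, knn_params(5, "x")), "k exceeds")
  expect_error(knn_classify(data.frame(y = 1), tr, knn_params(1, "x")),
               "feature_names")
})

test_that("depth training selection bins reliable segments by DSM mean", {
  sc <- small_scene()
  aoi <- !is.na(rg_band(sc$truth$depth))
  m <- rg_band(sc$ortho0, "G") * 255
  sm <- multiresolution_segment(list(m), mask = aoi,
                                params = segmentation_params(scale = 30),
                                template = sc$ortho0)
  # noise-free DSM: every segment eligible at quantile 1, labels = true bins
  tr <- select_training_segments_depth(sm, sc$dsm0, quality_quantile = 1,
                                       dsm_smooth_px = 0)
  expect_equal(nrow(tr), nrow(sm$features))
  f <- compute_segment_features(sm, list(dep = rg_band(sc$truth$depth)))
  expected <- bin_depth(depth_binning(),
                        pmin(pmax(f$dep_mean[tr$segment], 0), 14))
  expect_equal(as.integer(tr$label), expected)

  # quantile 0.25 keeps about a quarter of the segments
  tr25 <- select_training_segments_depth(sm, sc$dsm0, quality_quantile = 0.25,
                                         dsm_smooth_px = 0)
  expect_lte(abs(nrow(tr25) - 0.25 * nrow(sm$features)), 0.05 * nrow(sm$features) + 1)
})

test_that("depth binning uses half-open intervals with 11 default classes", {
  b <- depth_binning()
  expect_equal(b$n_classes, 11)
  expect_length(b$labels, 11)
  # value exactly on an edge joins the upper interval
  expect_equal(bin_depth(b, c(0, 1, 8.999, 9, 11, 13.999)),
               c(1L, 2L, 9L, 10L, 11L, 11L))
  expect_true(is.na(bin_depth(b, 14.5)))
  expect_error(depth_binning(c(1, 2)), "start at 0")
})

test_that("noise-free single-substrate scene recovers depth classes almost exactly", {
  catalog <- default_catalog()
  truth <- generate_scene_truth(shape = c(120, 120), seed = 21,
                                substrate_weights = c(platform = 1,
                                                      boulders = 0,
                                                      blocks = 0, sand = 0))
  ortho <- render_orthomosaic(truth, optics_params(texture_sd = 0,
                                                   sensor_noise_sd = 0),
                              seed = 1)
  dsm <- generate_dsm(truth, 0, seed = 1)
  dcm <- estimate_depth_class_map(ortho, dsm,
                                  seg_params = segmentation_params(scale = 5),
                                  presmooth_px = 0, dsm_smooth_px = 0,
                                  quality_quantile = 1, smooth_factor = 0)
  dc <- rg_band(dcm, 1)
  tdc <- matrix(bin_depth(depth_binning(), rg_band(truth$depth)), 120)
  w <- !is.na(dc) & !is.na(tdc)
  expect_gte(mean(dc[w] == tdc[w]), 0.99)
  expect_length(attr(dcm, "legend"), 11)
})

test_that("substrate classification is per-depth-class with full coverage", {
  sc <- small_scene()
  dcm <- estimate_depth_class_map(sc$ortho, sc$dsm0)
  training <- sample_substrate_training(sc$truth, dcm, n_per_class = 10,
                                        seed = 3)
  physio <- classify_substrate_map(sc$ortho, sc$dsm0, dcm, training)
  sub <- rg_band(physio$substrate, 1)
  dc <- rg_band(dcm, 1)
  # coverage contract: every classified depth pixel gets a substrate label
  expect_true(all(!is.na(sub[!is.na(dc)])))
  expect_true(all(is.na(sub[is.na(dc)])))
  expect_s3_class(physio, "physiographic_map")

  # training from one class only -> that depth class is labelled that class
  one <- training[training$substrate == "sand", ][1, ]
  rc <- rg_rowcol(sc$ortho, one$x, one$y)
  cl <- dc[rc]
  tr1 <- data.frame(x = one$x, y = one$y, substrate = "sand")
  physio1 <- suppressWarnings(classify_substrate_map(sc$ortho, sc$dsm0, dcm,
                                                     tr1))
  sub1 <- rg_band(physio1$substrate, 1)
  expect_true(all(sub1[!is.na(dc) & dc == cl] == 4))
})

test_that("depth recovery degrades monotonically with sensor noise", {
  truth <- generate_scene_truth(shape = c(96, 96), seed = 7, n_patches = 10)
  dsm <- generate_dsm(truth, 0.5, seed = 8)
  tdc <- matrix(bin_depth(depth_binning(), rg_band(truth$depth)), 96)
  agree <- vapply(c(0.002, 0.03), function(ns) {
    ortho <- render_orthomosaic(truth, optics_params(sensor_noise_sd = ns),
                                seed = 9)
    dc <- rg_band(estimate_depth_class_map(ortho, dsm), 1)
    w <- !is.na(dc) & !is.na(tdc)
    mean(abs(dc[w] - tdc[w]) <= 1)
  }, 0)
  expect_lte(agree[2], agree[1] + 0.02)
})
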