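test_that("region merging honours the scale threshold at its extremes", {
  # constant image: zero colour cost, everything merges per component
  m <- matrix(5, 24, 24)
  mask <- matrix(TRUE, 24, 24)
  mask[, 12] <- FALSE          # two disconnected components
  sm <- multiresolution_segment(list(m), mask = mask,
                                params = segmentation_params(scale = 65),
                                template = raster_grid(m, origin = c(0, 24),
                                                       pixel_size = 1))
  expect_equal(nrow(sm$features), 2)

  # scale 0: no merges at all
  sm0 <- multiresolution_segment(list(m), mask = mask,
                                 params = segmentation_params(scale = 0),
                                 template = raster_grid(m, origin = c(0, 24),
                                                        pixel_size = 1))
  expect_equal(nrow(sm0$features), sum(mask))
  expect_error(multiresolution_segment(list(m), mask = mask & FALSE,
                                       template = raster_grid(m,
                                                              origin = c(0, 24),
                                                              pixel_size = 1)),
               "empty mask")
})

test_that("a two-valued image splits into exactly its two halves", {
  m <- cbind(matrix(0, 20, 10), matrix(255, 20, 10))
  tpl <- raster_grid(m, origin = c(0, 20), pixel_size = 1)
  sm <- multiresolution_segment(list(m),
                                params = segmentation_params(
                                  scale = 65, shape_weight = 0),
                                template = tpl)
  lab <- rg_band(sm$labels, 1)
  expect_equal(nrow(sm$features), 2)
  expect_equal(length(unique(as.vector(lab[, 1:10]))), 1)
  expect_equal(length(unique(as.vector(lab[, 11:20]))), 1)
  expect_false(lab[1, 1] == lab[1, 20])
  # brute-force check: crossing the boundary costs more than the threshold
  n <- 200
  sd_mix <- stats::sd(rep(c(0, 255), each = n)) * sqrt((2 * n - 1) / (2 * n))
  expect_gt(2 * n * sd_mix, 65^2)
})

test_that("segment features match hand computation and conserve sums", {
  m <- matrix(c(1, 1, 5, 7), 2, 2)
  tpl <- raster_grid(m, origin = c(0, 2), pixel_size = 0.5)
  sm <- multiresolution_segment(list(m),
                                params = segmentation_params(scale = 1,
                                                             shape_weight = 0),
                                template = tpl)
  f <- compute_segment_features(sm, list(v = m))
  # the equal pixels merge at zero cost; merging 5 and 7 would raise
  # n * sd by 2 > scale^2 = 1, so they stay single
  expect_equal(sort(f$n_pixels), c(1, 1, 2))
  expect_equal(sort(f$v_mean), c(1, 5, 7))
  expect_equal(f$area_m2, f$n_pixels * 0.25)
  expect_equal(sum(f$v_mean * f$n_pixels), sum(m))
  single <- f[f$n_pixels == 1, ]
  expect_true(all(single$v_sd == 0))
  expect_true(all(single$perimeter == 4))
})

test_that("class merging dissolves only within-class boundaries", {
  m <- matrix(rep(c(0, 100, 200, 300), each = 25), 10, 10)
  tpl <- raster_grid(m, origin = c(0, 10), pixel_size = 1)
  sm <- multiresolution_segment(list(m),
                                params = segmentation_params(scale = 5,
                                                             shape_weight = 0),
                                template = tpl)
  nseg <- nrow(sm$features)
  cls <- rep(1L, nseg)              # all segments same class
  merged <- merge_segments_by_class(sm, cls)
  expect_equal(unique(as.vector(rg_band(merged, 1))), 1L)

  cls2 <- seq_len(nseg)             # identity classes: pixels keep class
  merged2 <- merge_segments_by_class(sm, cls2)
  expect_equal(rg_band(merged2, 1), rg_band(sm$labels, 1))
  expect_equal(unname(table(rg_band(merged2, 1))),
               unname(table(rg_band(sm$labels, 1))))
  expect_error(merge_segments_by_class(sm, cls[-1]), "every segment")
})

test_that("majority smoothing removes salt-and-pepper noise but not edges", {
  m <- matrix(1L, 21, 21)
  m[11, 11] <- 2L
  g <- raster_grid(m, origin = c(0, 21), pixel_size = 1)
  expect_identical(rg_band(smooth_class_boundaries(g, 0), 1), rg_band(g, 1))
  sm <- rg_band(smooth_class_boundaries(g, 0.25), 1)
  expect_equal(sm[11, 11], 1L)

  halves <- cbind(matrix(1L, 20, 10), matrix(2L, 20, 10))
  gh <- raster_grid(halves, origin = c(0, 20), pixel_size = 1)
  smh <- rg_band(smooth_class_boundaries(gh, 0.25), 1)
  moved <- which(smh != halves, arr.ind = TRUE)
  expect_true(nrow(moved) == 0 || all(abs(moved[, 2] - 10.5) <= 1.5))
  expect_error(smooth_class_boundaries(gh, 1.5), "factor")
})

test_that("partitions are exact, deterministic and coarsen with scale", {
  set.seed(42)
  m <- matrix(runif(40 * 40, 0, 255), 40, 40)
  tpl <- raster_grid(m, origin = c(0, 40), pixel_size = 1)
  counts <- integer(0)
  for (sc in c(10, 30, 65, 120)) {
    sm <- multiresolution_segment(list(m),
                                  params = segmentation_params(scale = sc),
                                  template = tpl)
    lab <- rg_band(sm$labels, 1)
    expect_false(anyNA(lab))                      # partition covers the mask
    expect_equal(sum(sm$features$n_pixels), 1600)
    # 4-connectivity of every segment
    comp <- benthomap:::cpp_connected_components(lab == lab)
    for (s in sample(unique(as.vector(lab)), min(5, nrow(sm$features)))) {
      cc <- benthomap:::cpp_connected_components(lab == s)
      expect_equal(max(cc), 1)
    }
    counts <- c(counts, nrow(sm$features))
  }
  expect_true(all(diff(counts) <= 0))             # non-increasing in scale
  sm1 <- multiresolution_segment(list(m),
                                 params = segmentation_params(scale = 65),
                                 template = tpl)
  sm2 <- multiresolution_segment(list(m),
                                 params = segmentation_params(scale = 65),
                                 template = tpl)
  expect_identical(sm1$labels$values, sm2$labels$values)
  expect_true(all(sm1$adjacency[, "a"] < sm1$adjacency[, "b"]))
})
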