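test_that("catalog derivation recovers conditions and flags conflicts", {
  md <- data.frame(sample_id = paste0("S", 1:6),
                   depth_class = c(5, 6, 10, 10, 5, 10),
                   substrate = c("platform", "platform", "boulders",
                                 "boulders", "blocks", "blocks"))
  g <- setNames(c("a", "a", "b", "b", "d", "d"), md$sample_id)
  cat1 <- derive_biotope_catalog(g, md)
  expect_s3_class(cat1, "biotope_catalog")
  d_rows <- cat1$conditions[cat1$conditions$assemblage == "d", ]
  expect_equal(nrow(d_rows), 2)      # one assemblage spanning two windows

  # two groups claiming the same pair is an error...
  g2 <- g
  g2["S2"] <- "b"
  md2 <- md
  md2$depth_class[2] <- 10
  md2$substrate[2] <- "boulders"
  expect_error(derive_biotope_catalog(c(g, x = "a"), md), "without metadata")
  g3 <- setNames(c("a", "b"), c("S1", "S2"))
  md3 <- data.frame(sample_id = c("S1", "S2"), depth_class = c(5, 5),
                    substrate = c("boulders", "boulders"))
  expect_error(derive_biotope_catalog(g3, md3), "conflict")
  # ...unless majority fallback is requested
  g4 <- setNames(c("a", "a", "b"), c("S1", "S2", "S3"))
  md4 <- data.frame(sample_id = c("S1", "S2", "S3"),
                    depth_class = c(5, 5, 5),
                    substrate = rep("boulders", 3))
  cat4 <- derive_biotope_catalog(g4, md4, force_majority = TRUE)
  expect_equal(cat4$conditions$assemblage, "a")
})

test_that("planted design round-trips through grouping to the same catalog", {
  qp <- generate_quadrat_points(seed = 30)
  g <- setNames(qp$metadata$assemblage, qp$metadata$sample_id)
  rec <- derive_biotope_catalog(g, qp$metadata)
  cmp <- compare_catalogs(rec, default_catalog())
  expect_true(cmp$identical)
  expect_equal(unname(cmp$mapping), names(cmp$mapping))  # same letters here
})

test_that("extrapolation is a pure (depth class, substrate) lookup", {
  truth <- small_scene()$truth
  dc_r <- rg_like(truth$depth,
                  matrix(bin_depth(truth$binning, rg_band(truth$depth)),
                         nrow(truth$depth$values)))
  physio <- structure(list(
    depth_class = dc_r, substrate = truth$substrate,
    substrate_legend = truth$substrate_legend,
    depth_legend = setNames(truth$binning$labels, 1:11)),
    class = "physiographic_map")
  bm <- extrapolate_biotope_map(physio, truth$catalog)
  # with true inputs the map equals the truth biotope raster (over water)
  bio <- rg_band(bm$raster, 1)
  tbio <- rg_band(truth$biotope, 1)
  w <- !is.na(tbio)
  expect_equal(bio[w], tbio[w])
  # pixels outside the windows are unassigned
  dc <- rg_band(dc_r, 1)
  outside <- w & !(dc %in% c(5, 6, 10))
  expect_true(all(bio[outside] == 0))
  # empty catalog: everything unassigned
  empty <- biotope_catalog(data.frame(assemblage = character(0),
                                      depth_class = integer(0),
                                      substrate = character(0)))
  bm0 <- extrapolate_biotope_map(physio, empty)
  expect_true(all(rg_band(bm0$raster, 1)[w] == 0))
  bad <- biotope_catalog(data.frame(assemblage = "a", depth_class = 5,
                                    substrate = "lava"))
  expect_error(extrapolate_biotope_map(physio, bad), "unknown")
})

test_that("area summaries are consistent and match the planted truth", {
  truth <- small_scene()$truth
  dc_r <- rg_like(truth$depth,
                  matrix(bin_depth(truth$binning, rg_band(truth$depth)),
                         nrow(truth$depth$values)))
  physio <- structure(list(
    depth_class = dc_r, substrate = truth$substrate,
    substrate_legend = truth$substrate_legend,
    depth_legend = setNames(truth$binning$labels, 1:11)),
    class = "physiographic_map")
  bm <- extrapolate_biotope_map(physio, truth$catalog)
  areas <- summarize_areas(bm)
  expect_equal(sum(areas$fraction_assigned), 1, tolerance = 1e-9)
  expect_equal(areas$area_ha, areas$area_m2 / 1e4)
  tb <- rg_band(truth$biotope, 1)
  px <- rg_pixel_area(truth$biotope)
  for (i in seq_len(nrow(areas))) {
    code <- as.integer(names(bm$legend)[bm$legend == areas$biotope[i]])
    expect_equal(areas$area_m2[i], sum(tb == code, na.rm = TRUE) * px)
  }
  # area accounting conserves the total assessed area
  expect_equal(attr(areas, "assigned_m2") + attr(areas, "unassigned_m2"),
               sum(!is.na(tb)) * px)
})

test_that("transect validation detects true structure and rejects degenerate input", {
  truth <- generate_scene_truth(shape = c(220, 220), seed = 4)
  dc_r <- rg_like(truth$depth,
                  matrix(bin_depth(truth$binning, rg_band(truth$depth)),
                         220))
  physio <- structure(list(
    depth_class = dc_r, substrate = truth$substrate,
    substrate_legend = truth$substrate_legend,
    depth_legend = setNames(truth$binning$labels, 1:11)),
    class = "physiographic_map")
  bm <- extrapolate_biotope_map(physio, truth$catalog)
  tr <- generate_transect_records(truth, n_transects = 8, seed = 5)
  val <- validate_with_transects(tr, bm, n_perm = 499, seed = 1)
  expect_equal(nrow(val$matrix$cover), 8)
  expect_gte(val$test$statistic, 0.8)
  expect_lte(val$test$p_value, 0.05)
  expect_equal(unname(val$predicted), unname(attr(tr, "true_biotope")))

  # profiles ignoring the biotope -> R near zero
  pooled <- default_profiles()
  for (nm in names(pooled)) pooled[[nm]]$mean_cover <-
    c(Turf = 40, CCA = 30, `Biofilm w/ silt` = 30)
  tr0 <- generate_transect_records(truth, pooled, n_transects = 8, seed = 6)
  val0 <- validate_with_transects(tr0, bm, n_perm = 499, seed = 2)
  expect_lte(abs(val0$test$statistic), 0.35)

  one <- tr[tr$transect_id %in% c("T1", "T5"), ]   # both in biotope a
  expect_error(validate_with_transects(one, bm, n_perm = 99, seed = 1),
               "one group")
})
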