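#' KNN classifier parameters
#' @param k number of neighbours (>= 1)
#' @param feature_names columns of the feature table to use
#' @param standardize z-standardize features (training statistics) before
#'   computing Euclidean distances
#' @export
knn_params <- function(k = 1L, feature_names = NULL, standardize = TRUE) {
  if (k < 1) stop("k must be >= 1")
  structure(list(k = as.integer(k), feature_names = feature_names,
                 standardize = standardize), class = "knn_params")
}

#' Euclidean KNN classification of segments
#'
#' Majority vote over the k nearest training rows; vote ties are broken
#' toward the class of the nearest neighbour among the tied classes.
#' Distance ties prefer the lower training row index (deterministic).
#'
#' @param features data.frame of query rows
#' @param training data.frame of training rows with a \code{label} column
#' @param params a \code{knn_params}; \code{feature_names} defaults to all
#'   shared numeric columns except \code{label}
#' @return character vector of predicted labels
#' @export
knn_classify <- function(features, training, params = knn_params()) {
  if (params$k > nrow(training)) stop("k exceeds training size")
  fn <- params$feature_names
  if (is.null(fn))
    fn <- setdiff(intersect(names(features), names(training)), "label")
  if (!all(fn %in% names(features)) || !all(fn %in% names(training)))
    stop("feature_names missing from features or training")
  X <- as.matrix(features[, fn, drop = FALSE])
  Tr <- as.matrix(training[, fn, drop = FALSE])
  if (anyNA(X) || anyNA(Tr)) stop("missing values in features")
  if (params$standardize) {
    mu <- colMeans(Tr)
    sdv <- apply(Tr, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    Tr <- sweep(sweep(Tr, 2, mu), 2, sdv, "/")
  }
  lab <- as.character(training$label)
  k <- params$k
  apply(X, 1L, function(q) {
    d <- sqrt(colSums((t(Tr) - q)^2))
    ord <- order(d, seq_along(d))
    nn <- ord[seq_len(k)]
    tab <- table(lab[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    # tie: class of the nearest neighbour among tied classes
    for (i in nn) if (lab[i] %in% top) return(lab[i])
    top[1L]
  })
}

#' Select depth-training segments from the DSM
#'
#' Computes per-segment DSM mean and SD, keeps the segments in the lowest
#' \code{quality_quantile} of within-segment DSM SD (the most reliable
#' surface estimates, standing in for manually edited depth contours) and
#' labels them by binning their mean DSM depth.
#'
#' @param segmap a \code{segment_map}
#' @param dsm single-band \code{raster_grid} (elevation; depth = -DSM)
#' @param binning a \code{depth_binning}
#' @param quality_quantile fraction of segments retained
#' @param dsm_smooth_px Gaussian pre-smoothing of the DSM (pixels) before
#'   computing segment statistics (0 disables)
#' @return data.frame of training segments with columns \code{segment},
#'   \code{label} (depth class index as character) and the DSM stats
#' @export
select_training_segments_depth <- function(segmap, dsm,
                                           binning = depth_binning(),
                                           quality_quantile = 0.25,
                                           dsm_smooth_px = 8) {
  # smoothing the DSM before labelling mirrors the contour-smoothing step
  # of photogrammetric workflows: SfM error over water is spatially
  # correlated and largely averages out at the ~2 m scale
  if (dsm_smooth_px > 0) {
    v <- rg_band(dsm, 1L)
    dsm <- rg_like(dsm, blur_masked(v, !is.na(v), dsm_smooth_px),
                   band_names = dsm$band_names[1])
  }
  f <- compute_segment_features(segmap, list(dsm = dsm))
  depth <- -f$dsm_mean
  cls <- bin_depth(binning, pmin(pmax(depth, 0),
                                 max(binning$edges)))
  thr <- stats::quantile(f$dsm_sd, quality_quantile, names = FALSE)
  keep <- f$dsm_sd <= thr & !is.na(cls)
  tr <- data.frame(segment = f$segment[keep],
                   label = as.character(cls[keep]),
                   dsm_mean = f$dsm_mean[keep], dsm_sd = f$dsm_sd[keep])
  if (nrow(tr) == 0) stop("empty depth training set")
  tr
}

#' Estimate the discrete depth-class map
#'
#' End-to-end optical depth classification: compute the normalized ln-Red
#' and ln-Green/ln-Blue ratio indices, segment them with multiresolution
#' region merging, train a KNN on the segments with the most reliable DSM
#' statistics, classify all segments, dissolve by class and smooth.
#'
#' @param ortho 3-band RGB \code{raster_grid}
#' @param dsm single-band DSM \code{raster_grid}
#' @param aoi_mask logical matrix delimiting the submerged area of interest
#'   (default: non-nodata pixels)
#' @param seg_params \code{segmentation_params}
#' @param binning \code{depth_binning}
#' @param kparams \code{knn_params} (default k = 1)
#' @param quality_quantile DSM-SD quantile for training selection
#' @param smooth_factor boundary smoothing factor
#' @param presmooth_px Gaussian pre-smoothing (pixels) of the index layers
#'   before segmentation
#' @param index_scaling value range the index layers are scaled to before
#'   segmentation (the merge scale parameter is calibrated against it)
#' @param dsm_smooth_px DSM smoothing before training-label extraction
#' @return single-band \code{raster_grid} of depth-class indices with the
#'   binning legend attached as attribute \code{"legend"} and the segment
#'   map as attribute \code{"segmap"}
#' @export
estimate_depth_class_map <- function(ortho, dsm, aoi_mask = NULL,
                                     seg_params = segmentation_params(),
                                     binning = depth_binning(),
                                     kparams = knn_params(),
                                     quality_quantile = 0.9,
                                     smooth_factor = 0.25,
                                     presmooth_px = 3,
                                     index_scaling = 24000,
                                     dsm_smooth_px = 8) {
  if (is.null(aoi_mask)) aoi_mask <- !is.na(rg_band(ortho, 1L)) &
      !is.na(rg_band(dsm, 1L))
  idx <- index_stack(ortho, aoi_mask)
  # pre-smoothing suppresses pixel noise that region merging would
  # otherwise chase in optically flat (deep) areas; index_scaling sets the
  # value range the scale parameter is calibrated against
  l1 <- blur_masked(rg_band(idx$ln_red_norm, 1L), aoi_mask, presmooth_px) *
    index_scaling
  l2 <- blur_masked(rg_band(normalize_index(idx$ln_gb_ratio, aoi_mask), 1L),
                    aoi_mask, presmooth_px) * index_scaling
  segmap <- multiresolution_segment(list(ln_red = l1, ln_gb = l2),
                                    mask = aoi_mask, params = seg_params,
                                    template = ortho)
  feats <- compute_segment_features(segmap, list(ln_red = l1, ln_gb = l2))
  training <- select_training_segments_depth(segmap, dsm, binning,
                                             quality_quantile,
                                             dsm_smooth_px = dsm_smooth_px)
  fn <- c("ln_red_mean", "ln_gb_mean")
  tr <- cbind(training, feats[match(training$segment, feats$segment), fn])
  kp <- knn_params(min(kparams$k, nrow(tr)), feature_names = fn,
                   standardize = kparams$standardize)
  pred <- knn_classify(feats, tr, kp)
  merged <- merge_segments_by_class(segmap, as.integer(pred))
  out <- smooth_class_boundaries(merged, smooth_factor)
  attr(out, "legend") <- setNames(binning$labels,
                                  seq_len(binning$n_classes))
  attr(out, "segmap") <- segmap
  attr(out, "binning") <- binning
  out
}

#' Classify substrate within each depth class
#'
#' For each depth class independently: segment the class footprint on the
#' R and G bands, DSM and depth indices; compute per-segment means of the
#' modified normalized-difference indices, RGB bands and DSM; 1-NN
#' classify into substrate categories using supplied ground-truth points;
#' dissolve and smooth. Per-class results are compiled into one raster, so
#' labels outside a class footprint are never touched.
#'
#' @param ortho 3-band RGB \code{raster_grid}
#' @param dsm DSM \code{raster_grid}
#' @param depth_class_raster output of \code{estimate_depth_class_map}
#' @param substrate_training data.frame with columns x, y, substrate
#'   (ground-truth point annotations)
#' @param seg_params \code{segmentation_params}
#' @param kparams \code{knn_params}; the substrate step uses k = 1
#' @param smooth_factor boundary smoothing factor
#' @return a \code{physiographic_map}: depth-class raster, substrate
#'   raster (codes with legend; 0 = na) and combined legend
#' @export
classify_substrate_map <- function(ortho, dsm, depth_class_raster,
                                   substrate_training,
                                   seg_params = segmentation_params(),
                                   kparams = knn_params(k = 1),
                                   smooth_factor = 0.25,
                                   presmooth_px = 3,
                                   index_scaling = 24000) {
  stopifnot(all(c("x", "y", "substrate") %in% names(substrate_training)))
  dc <- rg_band(depth_class_raster, 1L)
  water <- !is.na(dc)
  # global normalized layers
  norm_band <- function(nm) {
    b <- rg_like(ortho, rg_band(ortho, nm), band_names = nm)
    normalize_index(apply_mask(b, water), water)
  }
  Rn <- norm_band("R"); Gn <- norm_band("G"); Bn <- norm_band("B")
  idx <- index_stack(ortho, water)
  nd <- normalized_difference_indices(
    rg_like(ortho, array(c(rg_band(Rn), rg_band(Gn), rg_band(Bn)),
                         dim = c(dim(dc), 3L)), band_names = c("R", "G", "B")),
    idx$ln_red_norm)
  feat_layers <- list(ndvi_mod = nd$ndvi_mod, ndwi_mod = nd$ndwi_mod,
                      ndsi_mod = nd$ndsi_mod, R = Rn, G = Gn, B = Bn,
                      dsm = dsm)
  # training point -> pixel
  rc <- rg_rowcol(ortho, substrate_training$x, substrate_training$y)
  ok <- rc[, 1] >= 1 & rc[, 1] <= nrow(dc) & rc[, 2] >= 1 & rc[, 2] <= ncol(dc)
  rc <- rc[ok, , drop = FALSE]
  tr_sub <- as.character(substrate_training$substrate)[ok]
  tr_class <- dc[rc]
  out <- matrix(NA_integer_, nrow(dc), ncol(dc))
  sub_codes <- SUBSTRATE_LEVELS[setdiff(names(SUBSTRATE_LEVELS), "land")]
  # segmentation runs on pre-smoothed layers (noise suppression); the
  # classification features are raw per-pixel values averaged per segment
  dsm_n <- rg_band(normalize_index(apply_mask(dsm, water), water), 1L)
  seg_layers_all <- list(
    R = blur_masked(rg_band(Rn), water, presmooth_px) * index_scaling,
    G = blur_masked(rg_band(Gn), water, presmooth_px) * index_scaling,
    dsm = blur_masked(dsm_n, water, presmooth_px) * index_scaling,
    ln_red = blur_masked(rg_band(idx$ln_red_norm), water, presmooth_px) *
      index_scaling,
    ln_gb = blur_masked(rg_band(normalize_index(idx$ln_gb_ratio, water)),
                        water, presmooth_px) * index_scaling)
  for (cl in sort(unique(dc[water]))) {
    m <- water & dc == cl
    seg_layers <- lapply(seg_layers_all, function(l) { l[!m] <- NA; l })
    segmap <- multiresolution_segment(seg_layers, mask = m,
                                      params = seg_params, template = ortho)
    feats <- compute_segment_features(segmap, feat_layers)
    fn <- paste0(names(feat_layers), "_mean")
    in_cl <- tr_class == cl & !is.na(tr_class)
    if (!any(in_cl)) {
      warning("depth class ", cl, " has no substrate training; left na")
      out[m] <- 0L
      next
    }
    lab_m <- rg_band(segmap$labels, 1L)
    tr_seg <- lab_m[rc[in_cl, , drop = FALSE]]
    keep <- !is.na(tr_seg)
    # majority substrate per training segment
    tr_tab <- stats::aggregate(list(label = tr_sub[in_cl][keep]),
                               by = list(segment = tr_seg[keep]),
                               FUN = function(v) names(sort(table(v),
                                                            decreasing = TRUE))[1])
    training <- cbind(tr_tab,
                      feats[match(tr_tab$segment, feats$segment), fn])
    kp <- knn_params(1L, feature_names = fn,
                     standardize = kparams$standardize)
    pred <- knn_classify(feats, training, kp)
    merged <- merge_segments_by_class(segmap, unname(sub_codes[pred]))
    sm <- smooth_class_boundaries(merged, smooth_factor)
    out[m] <- rg_band(sm, 1L)[m]
  }
  sub_raster <- rg_like(depth_class_raster, out, band_names = "substrate")
  legend <- c("0" = "na", setNames(names(sub_codes), sub_codes))
  structure(list(depth_class = depth_class_raster, substrate = sub_raster,
                 substrate_legend = legend,
                 depth_legend = attr(depth_class_raster, "legend")),
            class = "physiographic_map")
}

#' @export
print.physiographic_map <- function(x, ...) {
  cat("physiographic_map\n")
  cat("  depth classes:\n")
  print(area_by_class(x$depth_class, x$depth_legend)[, c("class", "area_m2",
                                                         "fraction")])
  cat("  substrate:\n")
  print(area_by_class(x$substrate, x$substrate_legend)[, c("class", "area_m2",
                                                           "fraction")])
  invisible(x)
}

#' Sample substrate ground-truth points from scene truth
#'
#' Emulates diver annotations: draws up to \code{n_per_class} random truth-
#' labelled points per (depth class, substrate) combination over water.
#'
#' @param truth a \code{scene_truth}
#' @param depth_class_raster estimated (or true) depth-class raster used to
#'   stratify the sampling
#' @param n_per_class points per (depth class, substrate) stratum
#' @param seed RNG seed
#' @return data.frame (x, y, substrate)
#' @export
sample_substrate_training <- function(truth, depth_class_raster,
                                      n_per_class = 60, seed = 1) {
  set.seed(seed)
  sub <- rg_band(truth$substrate)
  dc <- rg_band(depth_class_raster, 1L)
  water <- !is.na(dc) & sub != SUBSTRATE_LEVELS[["land"]]
  idx <- which(water)
  strata <- paste(dc[idx], sub[idx])
  picks <- unlist(lapply(split(idx, strata), function(v)
    v[sample.int(length(v), min(n_per_class, length(v)))]))
  rows <- ((picks - 1L) %% nrow(sub)) + 1L
  cols <- ((picks - 1L) %/% nrow(sub)) + 1L
  xy <- rg_xy(truth$substrate, rows, cols)
  data.frame(x = xy[, 1], y = xy[, 2],
             substrate = names(SUBSTRATE_LEVELS)[sub[picks]])
}
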