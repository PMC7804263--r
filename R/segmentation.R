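#' Multiresolution segmentation parameters
#'
#' Controls for bottom-up region merging: \code{scale} stops merging once
#' the cheapest fusion cost reaches scale^2 (larger scale = larger
#' objects); \code{shape_weight} trades shape against color homogeneity;
#' \code{compactness_weight} trades compactness against smoothness within
#' the shape term. Defaults mirror common OBIA practice (scale 65, both
#' ratios 0.5) and presume roughly 8-bit-scaled layer values.
#'
#' @param scale non-negative merge threshold parameter
#' @param shape_weight shape vs color weight in [0, 1]
#' @param compactness_weight compactness vs smoothness weight in [0, 1]
#' @param band_weights per-layer non-negative weights (default equal)
#' @export
segmentation_params <- function(scale = 65, shape_weight = 0.5,
                                compactness_weight = 0.5,
                                band_weights = NULL) {
  if (scale < 0) stop("scale must be >= 0")
  if (shape_weight < 0 || shape_weight > 1) stop("shape_weight in [0,1]")
  if (compactness_weight < 0 || compactness_weight > 1)
    stop("compactness_weight in [0,1]")
  if (!is.null(band_weights) && (any(band_weights < 0) ||
                                 all(band_weights == 0)))
    stop("band_weights must be non-negative with at least one positive")
  structure(list(scale = scale, shape_weight = shape_weight,
                 compactness_weight = compactness_weight,
                 band_weights = band_weights), class = "segmentation_params")
}

as_layer_matrix <- function(x) {
  if (inherits(x, "raster_grid")) rg_band(x, 1L) else x
}

#' Bottom-up multiresolution region-merging segmentation
#'
#' Starts from single-pixel objects and greedily merges adjacent segments
#' while the Baatz-Schape fusion cost (weighted color heterogeneity
#' increase plus compactness/smoothness terms) stays below scale^2,
#' scheduled by local mutual best fitting with lowest-id tie-breaking, so
#' results are deterministic.
#'
#' @param layers list of single-band \code{raster_grid}s or matrices on one
#'   grid
#' @param mask logical matrix of pixels to segment (default: non-NA in the
#'   first layer)
#' @param params a \code{segmentation_params}
#' @param template optional \code{raster_grid} supplying georeferencing
#'   when \code{layers} are bare matrices
#' @return a \code{segment_map}: label raster (\code{$labels}), per-segment
#'   feature table (\code{$features}) and segment adjacency pairs
#'   (\code{$adjacency})
#' @export
multiresolution_segment <- function(layers, mask = NULL,
                                    params = segmentation_params(),
                                    template = NULL) {
  if (inherits(layers, "raster_grid")) layers <- list(layers)
  if (is.null(template))
    template <- Filter(function(x) inherits(x, "raster_grid"), layers)[[1]]
  mats <- lapply(layers, as_layer_matrix)
  if (is.null(mask)) mask <- !is.na(mats[[1]])
  if (!any(mask)) stop("empty mask")
  for (m in mats) {
    if (!identical(dim(m), dim(mask))) stop("layers must share the grid")
    if (all(is.na(m[mask]))) stop("all-nodata layer")
  }
  mats <- lapply(mats, function(m) { m[is.na(m)] <- 0; m })
  bw <- params$band_weights
  if (is.null(bw)) bw <- rep(1, length(mats))
  lab <- cpp_multiresolution_segment(mats, mask, params$scale,
                                     params$shape_weight,
                                     params$compactness_weight,
                                     as.numeric(bw))
  segmap <- structure(list(
    labels = rg_like(template, lab, band_names = "segment"),
    mask = mask, params = params), class = "segment_map")
  segmap$features <- compute_segment_features(segmap, layers)
  segmap$adjacency <- segment_adjacency(lab)
  segmap
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("segment_map: %d segments over %d masked px (scale %g)\n",
              nrow(x$features), sum(x$mask), x$params$scale))
  invisible(x)
}

segment_adjacency <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  h <- cbind(as.vector(lab[, -nc]), as.vector(lab[, -1]))
  v <- cbind(as.vector(lab[-nr, ]), as.vector(lab[-1, ]))
  e <- rbind(h, v)
  e <- e[!is.na(e[, 1]) & !is.na(e[, 2]) & e[, 1] != e[, 2], , drop = FALSE]
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  colnames(e) <- c("a", "b")
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Per-segment feature table
#'
#' Means and SDs of each supplied layer over segment member pixels, pixel
#' count, area, perimeter (exposed pixel-edge count) and bounding-box
#' dimensions.
#'
#' @param segmap a \code{segment_map}
#' @param layers named list of single-band \code{raster_grid}s or matrices
#' @return data.frame, one row per segment id
#' @export
compute_segment_features <- function(segmap, layers) {
  lab <- rg_band(segmap$labels, 1L)
  idx <- which(!is.na(lab))
  s <- lab[idx]
  n <- tabulate(s)
  ids <- seq_along(n)
  feat <- data.frame(segment = ids, n_pixels = n,
                     area_m2 = n * rg_pixel_area(segmap$labels))
  if (length(layers) > 0) {
    nms <- names(layers)
    if (is.null(nms)) nms <- paste0("layer", seq_along(layers))
    nms[nms == ""] <- paste0("layer", which(nms == ""))
    for (k in seq_along(layers)) {
      v <- as_layer_matrix(layers[[k]])[idx]
      sm <- rowsum(v, s, reorder = TRUE)
      sq <- rowsum(v^2, s, reorder = TRUE)
      mu <- sm / n
      va <- pmax(sq / n - mu^2, 0)
      feat[[paste0(nms[k], "_mean")]] <- as.vector(mu)
      feat[[paste0(nms[k], "_sd")]] <- sqrt(as.vector(va))
    }
  }
  # perimeter: edges to a different segment, to nodata, or off the image
  nr <- nrow(lab); nc <- ncol(lab)
  perim <- integer(length(ids))
  add_exposed <- function(a, b) {
    # edges where a is a segment and b differs (or is NA)
    sel <- !is.na(a)
    expos <- sel & (is.na(b) | (a != b))
    tab <- tabulate(a[expos], nbins = length(ids))
    perim <<- perim + tab
  }
  pad <- function(m, side) {
    switch(side,
           up = rbind(NA, m[-nr, , drop = FALSE]),
           down = rbind(m[-1, , drop = FALSE], NA),
           left = cbind(NA, m[, -nc, drop = FALSE]),
           right = cbind(m[, -1, drop = FALSE], NA))
  }
  for (sd_ in c("up", "down", "left", "right")) add_exposed(lab, pad(lab, sd_))
  feat$perimeter <- perim
  rows <- row(lab)[idx]; cols <- col(lab)[idx]
  rmin <- tapply(rows, s, min); rmax <- tapply(rows, s, max)
  cmin <- tapply(cols, s, min); cmax <- tapply(cols, s, max)
  feat$bbox_h <- as.integer(rmax - rmin + 1L)
  feat$bbox_w <- as.integer(cmax - cmin + 1L)
  feat
}

#' Dissolve segment boundaries within classes
#'
#' Maps each pixel to its segment's class; pixels keep their class, only
#' the within-class segment boundaries disappear.
#'
#' @param segmap a \code{segment_map}
#' @param class_assignment vector of class codes (or labels) indexed by
#'   segment id; every segment must have a class
#' @return single-band \code{raster_grid} of class codes
#' @export
merge_segments_by_class <- function(segmap, class_assignment) {
  lab <- rg_band(segmap$labels, 1L)
  nseg <- max(lab, na.rm = TRUE)
  if (length(class_assignment) < nseg || anyNA(class_assignment[seq_len(nseg)]))
    stop("every segment needs a class")
  out <- matrix(NA_integer_, nrow(lab), ncol(lab))
  sel <- !is.na(lab)
  cls <- class_assignment[lab[sel]]
  if (!is.numeric(cls)) cls <- as.integer(factor(cls))
  out[sel] <- as.integer(cls)
  rg_like(segmap$labels, out, band_names = "class")
}

#' Majority-filter smoothing of a categorical raster
#'
#' One pass of a square majority filter whose half-width is
#' \code{round(factor * 8)} pixels (factor 0.25 gives a 5x5 window, the
#' package's reading of the usual GUI smoothing setting). NA cells are
#' preserved and do not vote; ties keep the current class.
#'
#' @param label_raster single-band categorical \code{raster_grid}
#' @param factor smoothing factor in [0, 1]; 0 is the identity
#' @export
smooth_class_boundaries <- function(label_raster, factor = 0.25) {
  stopifnot(inherits(label_raster, "raster_grid"))
  if (factor < 0 || factor > 1) stop("factor must lie in [0, 1]")
  hw <- as.integer(round(factor * 8))
  if (hw == 0L) return(label_raster)
  lab <- rg_band(label_raster, 1L)
  sm <- cpp_majority_filter(matrix(as.integer(lab), nrow(lab), ncol(lab)), hw)
  rg_like(label_raster, sm, band_names = label_raster$band_names[1])
}
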