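#' Natural-log reflectance index
#'
#' ln-transforms a reflectance band, clamping values below \code{epsilon}.
#' The ln transform approximately linearizes bottom reflectance with
#' respect to depth under exponential water-column attenuation, which is
#' what makes reflectance-based depth classification possible.
#'
#' @param band single-band \code{raster_grid} (values >= 0)
#' @param epsilon positive clamp applied before the log
#' @return single-band \code{raster_grid}; nodata propagated
#' @export
ln_index <- function(band, epsilon = 1e-4) {
  stopifnot(inherits(band, "raster_grid"))
  if (epsilon <= 0) stop("epsilon must be > 0")
  v <- rg_band(band, 1L)
  if (any(v < 0, na.rm = TRUE)) stop("band values must be >= 0")
  rg_like(band, log(pmax(v, epsilon)), band_names = "ln")
}

#' Ratio of ln-Green to ln-Blue indices
#'
#' The per-band attenuation difference between green and blue makes this
#' ratio depth-sensitive yet comparatively albedo-robust. The denominator
#' is clamped away from zero at magnitude \code{epsilon}.
#'
#' @param green,blue single-band \code{raster_grid}s on the same grid
#' @param epsilon clamp for both the ln transform and the denominator
#' @export
ln_ratio_index <- function(green, blue, epsilon = 1e-4) {
  check_same_grid(green, blue)
  num <- rg_band(ln_index(green, epsilon), 1L)
  den <- rg_band(ln_index(blue, epsilon), 1L)
  den <- sign(den) * pmax(abs(den), epsilon)
  den[den == 0] <- epsilon
  rg_like(green, num / den, band_names = "lnG_lnB")
}

#' Min-max normalize a raster over a mask
#'
#' Linear rescale so the masked minimum maps to 0 and the maximum to 1;
#' values outside the mask do not influence the scaling.
#'
#' @param raster single-band \code{raster_grid}
#' @param mask logical matrix (default: all non-nodata cells)
#' @export
normalize_index <- function(raster, mask = NULL) {
  stopifnot(inherits(raster, "raster_grid"))
  v <- rg_band(raster, 1L)
  if (is.null(mask)) mask <- !is.na(v)
  vals <- v[mask & !is.na(v)]
  if (length(unique(vals)) < 2L) stop("degenerate normalization: constant raster")
  r <- range(vals)
  out <- (v - r[1]) / (r[2] - r[1])
  out[!mask] <- NA
  rg_like(raster, out, band_names = raster$band_names[1])
}

#' Generic normalized difference of two layers
#' @param a,b single-band \code{raster_grid}s on one grid
#' @return (a - b) / (a + b), with zero-sum pixels set to 0
#' @export
nd_index <- function(a, b) {
  check_same_grid(a, b)
  av <- rg_band(a, 1L); bv <- rg_band(b, 1L)
  s <- av + bv
  out <- (av - bv) / s
  out[!is.na(s) & s == 0] <- 0
  rg_like(a, out, band_names = "nd")
}

#' Modified normalized-difference soil/water/vegetation indices
#'
#' The classic NDVI/NDWI/NDSI use a near-infrared band that an RGB sensor
#' lacks; here the normalized ln-Red index substitutes for it (red being
#' the most water-attenuated visible band). Band assignments are
#' configurable; defaults: ndvi_mod = nd(red_index, R),
#' ndwi_mod = nd(G, red_index), ndsi_mod = nd(B, red_index).
#'
#' @param rgb 3-band \code{raster_grid} with bands normalized to [0, 1]
#' @param red_index single-band \code{raster_grid}, the normalized ln-Red
#' @param assignments named list of c(a, b) band specs, each "R","G","B" or
#'   "red_index"
#' @return list of single-band \code{raster_grid}s in [-1, 1]
#' @export
normalized_difference_indices <- function(rgb, red_index,
    assignments = list(ndvi_mod = c("red_index", "R"),
                       ndwi_mod = c("G", "red_index"),
                       ndsi_mod = c("B", "red_index"))) {
  stopifnot(inherits(rgb, "raster_grid"), dim(rgb$values)[3] == 3L)
  check_same_grid(rgb, red_index)
  pick <- function(nm) {
    if (nm == "red_index") red_index
    else rg_like(rgb, rg_band(rgb, nm), band_names = nm)
  }
  lapply(assignments, function(ab) nd_index(pick(ab[1]), pick(ab[2])))
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values)[1:2], dim(b$values)[1:2]) ||
      !isTRUE(all.equal(a$origin, b$origin)) ||
      !isTRUE(all.equal(a$pixel_size, b$pixel_size)))
    stop("rasters are not on the same grid")
  invisible(TRUE)
}

#' Build the depth-index stack used by the OBIA depth classifier
#'
#' Computes the normalized ln-Red index and the ln-Green/ln-Blue ratio
#' index over the area of interest.
#'
#' @param ortho 3-band RGB \code{raster_grid}
#' @param mask logical AOI matrix (default: all non-nodata water pixels)
#' @param epsilon ln clamp
#' @return list(ln_red_norm, ln_gb_ratio) of single-band grids masked to
#'   the AOI
#' @export
index_stack <- function(ortho, mask = NULL, epsilon = 1e-4) {
  stopifnot(dim(ortho$values)[3] == 3L)
  if (is.null(mask)) mask <- !is.na(rg_band(ortho, 1L))
  band <- function(nm) rg_like(ortho, rg_band(ortho, nm), band_names = nm)
  lnr <- ln_index(band("R"), epsilon)
  lnr_n <- normalize_index(apply_mask(lnr, mask), mask)
  ratio <- apply_mask(ln_ratio_index(band("G"), band("B"), epsilon), mask)
  list(ln_red_norm = lnr_n, ln_gb_ratio = ratio)
}

#' Mask-aware Gaussian smoothing of a layer
#'
#' Normalized convolution: values are blurred with a separable Gaussian
#' kernel while NA/off-mask cells carry zero weight, so the result is
#' defined everywhere on the mask and off-mask values never leak in.
#' Used to suppress pixel noise before segmentation.
#'
#' @param m numeric matrix
#' @param mask logical matrix; cells outside stay NA
#' @param sigma kernel SD in pixels (0 = identity)
#' @export
blur_masked <- function(m, mask, sigma = 2) {
  if (sigma <= 0) return(m)
  v <- m
  v[!mask | is.na(v)] <- 0
  w <- matrix(0, nrow(m), ncol(m))
  w[mask & !is.na(m)] <- 1
  num <- smooth_field(v, sigma)
  den <- smooth_field(w, sigma)
  out <- num / pmax(den, 1e-12)
  out[!mask] <- NA
  out
}

#' Restrict a raster to a mask
#' @param raster single-band \code{raster_grid}
#' @param mask logical matrix; cells outside become NA
#' @export
apply_mask <- function(raster, mask) {
  v <- rg_band(raster, 1L)
  v[!mask] <- NA
  rg_like(raster, v, band_names = raster$band_names[1])
}
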