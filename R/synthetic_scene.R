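#' @useDynLib benthomap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rgamma rmultinom quantile sd var hclust as.dist cor lm coef setNames aggregate
#' @importFrom utils head write.csv read.csv
NULL

SUBSTRATE_LEVELS <- c(platform = 1L, boulders = 2L, blocks = 3L, sand = 4L,
                      land = 5L)
NONLIVING_CATS <- c("sand", "rock", "shadow", "frame")
NONVALID_CATS <- c("shadow", "frame")
NONLIVING_SUBSTRATE <- c("sand", "rock", "rubble")

# separable Gaussian blur with edge replication; sigma in pixels
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  pad <- function(v, h) c(rep(v[1], h), v, rep(v[length(v)], h))
  conv1 <- function(v) {
    out <- stats::filter(pad(v, half), k, sides = 2)
    out[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

#' Water-column optics parameters
#'
#' Two-flux (Lyzenga-form) radiative model parameters: per-band diffuse
#' attenuation, asymptotic deep-water signal, per-substrate bottom albedo
#' and noise levels. The physical premise is wavelength-dependent
#' attenuation: red light is absorbed fastest, so \code{K_R > K_G >= K_B}.
#'
#' @param attenuation per-band diffuse attenuation coefficient (1/m),
#'   named R, G, B
#' @param water_signal asymptotic deep-water radiance per band (reflectance
#'   units)
#' @param substrate_albedo matrix (substrate x band) of bottom reflectance
#'   in (0, 1]
#' @param texture_sd multiplicative within-patch noise SD
#' @param sensor_noise_sd additive sensor noise SD
#' @export
optics_params <- function(attenuation = c(R = 0.55, G = 0.12, B = 0.07),
                          water_signal = c(R = 0.02, G = 0.04, B = 0.06),
                          substrate_albedo = default_albedo(),
                          texture_sd = 0.08, sensor_noise_sd = 0.005) {
  if (!(attenuation["R"] > attenuation["G"] &&
        attenuation["G"] >= attenuation["B"] && attenuation["B"] > 0))
    stop("attenuation must satisfy K_R > K_G >= K_B > 0")
  if (any(substrate_albedo <= 0) || any(substrate_albedo > 1))
    stop("albedos must lie in (0, 1]")
  structure(list(attenuation = attenuation, water_signal = water_signal,
                 substrate_albedo = substrate_albedo,
                 texture_sd = texture_sd, sensor_noise_sd = sensor_noise_sd),
            class = "optics_params")
}

#' Default per-substrate bottom albedo table
#'
#' Volcanic-rock reflectances: biofilm-covered platforms slightly brighter
#' than boulder fields, large blocks darkest (self-shading), sand markedly
#' brighter. Rock classes are kept spectrally close (as on a basalt coast)
#' so depth, not substrate albedo, dominates the water-leaving signal.
#' @export
default_albedo <- function() {
  rbind(platform = c(R = 0.20, G = 0.190, B = 0.150),
        boulders = c(R = 0.16, G = 0.155, B = 0.125),
        blocks   = c(R = 0.12, G = 0.115, B = 0.095),
        sand     = c(R = 0.35, G = 0.320, B = 0.260),
        land     = c(R = 0.45, G = 0.400, B = 0.330))
}

#' Depth-class binning
#'
#' Half-open intervals [lo, hi) delimiting discrete depth classes. The
#' default spans 0-14 m in 11 classes of 1-3 m width.
#' @param edges strictly ascending numeric vector starting at 0
#' @export
depth_binning <- function(edges = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 11, 14)) {
  if (edges[1] != 0 || any(diff(edges) <= 0))
    stop("edges must start at 0 and ascend strictly")
  labels <- sprintf("%g-%gm", edges[-length(edges)], edges[-1])
  structure(list(edges = edges, labels = labels,
                 n_classes = length(edges) - 1L), class = "depth_binning")
}

#' Assign depths to classes
#' @param binning a \code{depth_binning}
#' @param depth numeric depths (m)
#' @return integer class index (NA outside [first, last) edge range)
#' @export
bin_depth <- function(binning, depth) {
  idx <- findInterval(depth, binning$edges, rightmost.closed = FALSE)
  idx[idx < 1L | idx > binning$n_classes] <- NA_integer_
  # depth exactly on the last edge joins the last class (14 m ceiling)
  idx[!is.na(depth) & depth == binning$edges[length(binning$edges)]] <-
    binning$n_classes
  as.integer(idx)
}

#' Biotope catalog: assemblage -> (depth class, substrate) conditions
#'
#' @param conditions data.frame with columns \code{assemblage},
#'   \code{depth_class} (integer class index) and \code{substrate}
#' @param composition optional per-assemblage top-taxa summary
#' @export
biotope_catalog <- function(conditions, composition = NULL) {
  stopifnot(all(c("assemblage", "depth_class", "substrate") %in%
                  names(conditions)))
  key <- paste(conditions$depth_class, conditions$substrate)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("catalog conditions overlap across assemblages: ",
         paste(unique(dup), collapse = "; "))
  }
  structure(list(conditions = conditions, composition = composition),
            class = "biotope_catalog")
}

#' @export
print.biotope_catalog <- function(x, ...) {
  cat("biotope_catalog:\n")
  for (a in unique(x$conditions$assemblage)) {
    sub <- x$conditions[x$conditions$assemblage == a, ]
    cat(sprintf("  %s: %s\n", a,
                paste(sprintf("(%s, class %d)", sub$substrate,
                              sub$depth_class), collapse = ", ")))
  }
  invisible(x)
}

#' Default planted catalog
#'
#' Four assemblages on rocky substrates in two depth windows (4-6 m and
#' 9-11 m): a = platforms at 4-6 m, b = boulders at 9-11 m, c = boulders at
#' 4-6 m, d = blocks in both windows.
#' @param binning a \code{depth_binning}
#' @export
default_catalog <- function(binning = depth_binning()) {
  cls <- function(lo, hi) {
    which(binning$edges[-length(binning$edges)] >= lo - 1e-9 &
            binning$edges[-1] <= hi + 1e-9)
  }
  w1 <- cls(4, 6); w2 <- cls(9, 11)
  conditions <- rbind(
    data.frame(assemblage = "a", depth_class = w1, substrate = "platform"),
    data.frame(assemblage = "b", depth_class = w2, substrate = "boulders"),
    data.frame(assemblage = "c", depth_class = w1, substrate = "boulders"),
    data.frame(assemblage = "d", depth_class = c(w1, w2), substrate = "blocks"))
  biotope_catalog(conditions)
}

#' Mean sessile community compositions of the four default assemblages
#'
#' Percent-cover means of the benthic categories characterising each
#' assemblage: a = turf/Asparagopsis-dominated platforms, b = biofilm/
#' Macrorhynchia boulders, c = biofilm/turf boulders, d = CCA-dominated
#' blocks (CCA = crustose coralline algae).
#'
#' @param concentration Dirichlet concentration controlling quadrat-to-
#'   quadrat variability (larger = tighter around the mean)
#' @param nonliving_range interval for the injected nonliving/non-valid
#'   point fraction (sand, rock, shadow, frame)
#' @return list of assemblage profiles
#' @export
default_profiles <- function(concentration = 60,
                             nonliving_range = c(0.05, 0.20)) {
  mk <- function(label, ...) {
    mc <- c(...)
    list(label = label, mean_cover = mc, concentration = concentration,
         nonliving_range = nonliving_range)
  }
  list(
    a = mk("a", Turf = 41.11, `Asparagopsis sp.` = 33.14,
           `Biofilm w/ silt` = 11.88, `Dictyota sp.` = 7.63, CCA = 5.13,
           `Spongionella sp.` = 0.20, `Reptadeonella sp.` = 0.16,
           `Crambe sp.` = 0.11, `Macrorhynchia sp.` = 0.33),
    b = mk("b", `Biofilm w/ silt` = 48.68, Turf = 19.01,
           `Macrorhynchia sp.` = 13.04, CCA = 9.00, `Lobophora sp.` = 3.40,
           `Asparagopsis sp.` = 4.14, `Dictyota sp.` = 1.86,
           Rodolith = 0.44, `Crambe sp.` = 0.11),
    c = mk("c", `Biofilm w/ silt` = 38.23, Turf = 38.37, CCA = 7.94,
           `Dictyota sp.` = 2.99, `Asparagopsis sp.` = 4.41,
           `Halopteris sp.` = 5.13, `Ircinia sp.` = 2.67,
           `Crambe sp.` = 0.11),
    d = mk("d", CCA = 45.60, `Biofilm w/ silt` = 23.68, Turf = 0.47))
}

#' Generate ground-truth rasters for a synthetic coastal scene
#'
#' Builds a smooth monotone-offshore bathymetry (shore-parallel gradient
#' plus a low-frequency Gaussian random field) spanning 0-14 m, contiguous
#' substrate patches by seeded region growth (nearest-seed tessellation)
#' covering all four substrate classes, and the biotope raster implied by
#' the planted catalog.
#'
#' @param shape c(nrow, ncol) grid dimensions, both >= 64
#' @param pixel_size ground sampling distance in m/pixel
#' @param catalog planted \code{biotope_catalog}
#' @param binning \code{depth_binning} used to derive the biotope raster
#' @param seed integer RNG seed
#' @param n_patches number of substrate patch seeds
#' @param land_fraction fraction of rows (at the shore edge) above water
#' @param substrate_weights relative area weights of the substrate patch
#'   classes (classes with zero weight are omitted)
#' @param min_patch_run_m site-suitability criterion: minimum straight
#'   (horizontal or vertical) run, in metres, that every assemblage's
#'   biotope region must contain; 0 disables the check
#' @return a \code{scene_truth}: depth, substrate and biotope
#'   \code{raster_grid}s sharing shape and geotransform, plus legends
#' @export
generate_scene_truth <- function(shape = c(400, 400), pixel_size = 0.25,
                                 catalog = default_catalog(),
                                 binning = depth_binning(), seed = 1,
                                 n_patches = 24, land_fraction = 0.05,
                                 substrate_weights = c(platform = 0.30,
                                                       boulders = 0.35,
                                                       blocks = 0.25,
                                                       sand = 0.10),
                                 min_patch_run_m = 0) {
  if (any(shape < 64)) stop("degenerate shape: need at least 64 x 64")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  stopifnot(inherits(catalog, "biotope_catalog"))
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  # bathymetry: shore at top (row 1), deepening southwards
  land_rows <- max(2L, round(land_fraction * nr))
  base <- seq(-1.0, 14.4, length.out = nr)
  depth <- matrix(rep(base, nc), nr, nc)
  pert <- matrix(rnorm(nr * nc), nr, nc)
  pert <- smooth_field(pert, sigma = nr / 16)
  pert <- 0.9 * pert / stats::sd(as.vector(pert))
  depth <- depth + pert
  depth[seq_len(land_rows), ] <- -abs(depth[seq_len(land_rows), ]) - 0.01
  land <- depth <= 0
  depth_w <- depth
  depth_w[land] <- NA
  depth_w[!land] <- pmin(depth_w[!land], max(binning$edges))
  # substrate: nearest-seed patches over water; land class on land.
  # When min_patch_run_m > 0 the tessellation is re-drawn (deterministically)
  # until every assemblage's biotope region contains a straight run of that
  # length -- a site-suitability criterion: survey sites are chosen so that
  # every target biotope is present with workable extent.
  substrate_weights <- substrate_weights[substrate_weights > 0]
  subs <- names(substrate_weights)
  ns <- n_patches
  counts <- pmax(1L, round(substrate_weights / sum(substrate_weights) * ns))
  while (sum(counts) > ns) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < ns) counts[which.max(substrate_weights)] <-
    counts[which.max(substrate_weights)] + 1L
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dc <- matrix(bin_depth(binning, depth_w), nr, nc)
  bio_levels <- sort(unique(catalog$conditions$assemblage))
  lut <- setNames(catalog$conditions$assemblage,
                  paste(catalog$conditions$depth_class,
                        catalog$conditions$substrate))
  run_px <- ceiling(min_patch_run_m / pixel_size)
  max_run <- function(mask) {
    best <- 0L
    for (mm in list(mask, t(mask))) {
      r <- apply(mm, 1L, function(v) {
        rl <- rle(v)
        m <- rl$lengths[rl$values]
        if (length(m)) max(m) else 0L
      })
      best <- max(best, max(r))
    }
    best
  }
  for (attempt in seq_len(50L)) {
    sr <- runif(ns, land_rows + 1, nr)
    sc <- runif(ns, 1, nc)
    cls <- rep(subs, counts)
    cls <- cls[sample.int(ns)]
    best_d <- matrix(Inf, nr, nc)
    best_k <- matrix(1L, nr, nc)
    for (k in seq_len(ns)) {
      d2 <- (rows - sr[k])^2 + (cols - sc[k])^2
      sel <- d2 < best_d
      best_d[sel] <- d2[sel]
      best_k[sel] <- k
    }
    substrate <- matrix(SUBSTRATE_LEVELS[cls[best_k]], nr, nc)
    substrate[land] <- SUBSTRATE_LEVELS[["land"]]
    sub_name <- names(SUBSTRATE_LEVELS)[substrate]
    bio_lab <- unname(lut[paste(as.vector(dc), sub_name)])
    bio <- matrix(match(bio_lab, bio_levels), nr, nc)
    bio[is.na(bio) & !land] <- 0L   # unassigned water
    bio[land] <- NA_integer_
    if (run_px <= 0) break
    ok <- all(vapply(seq_along(bio_levels), function(code)
      max_run(!is.na(bio) & bio == code) >= run_px, TRUE))
    if (ok) break
    if (attempt == 50L)
      stop("no tessellation with ", min_patch_run_m,
           " m runs of every biotope found in 50 attempts; ",
           "reduce min_patch_run_m or enlarge the scene")
  }
  org <- c(0, nr * pixel_size)
  g <- function(v) raster_grid(v, origin = org, pixel_size = pixel_size)
  structure(list(
    depth = g(depth_w),
    substrate = g(substrate),
    biotope = g(bio),
    substrate_legend = setNames(names(SUBSTRATE_LEVELS), SUBSTRATE_LEVELS),
    biotope_legend = setNames(c("unassigned", bio_levels),
                              c(0, seq_along(bio_levels))),
    binning = binning, catalog = catalog,
    pixel_size = pixel_size, seed = seed), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  d <- dim(x$depth$values)
  dep <- rg_band(x$depth)
  cat(sprintf("scene_truth: %d x %d px at %g m/px (seed %d)\n",
              d[1], d[2], x$pixel_size, x$seed))
  cat(sprintf("  water depth range: %.2f - %.2f m; land: %d px\n",
              min(dep, na.rm = TRUE), max(dep, na.rm = TRUE),
              sum(is.na(dep))))
  invisible(x)
}

#' Render a 3-band orthomosaic from scene truth
#'
#' Two-flux water-column model: for band c,
#' \code{L_c = Linf_c + (A_c - Linf_c) * exp(-2 K_c z) * (1 + texture)
#'  + noise}, where A_c is the substrate albedo and Linf_c the deep-water
#' signal. Land pixels carry unattenuated albedo. Values clamped to (0, 1].
#'
#' @param truth a \code{scene_truth}
#' @param optics an \code{optics_params}
#' @param seed integer RNG seed
#' @return 3-band \code{raster_grid} (R, G, B reflectance)
#' @export
render_orthomosaic <- function(truth, optics, seed = 1) {
  stopifnot(inherits(truth, "scene_truth"), inherits(optics, "optics_params"))
  set.seed(seed)
  dep <- rg_band(truth$depth)
  sub <- rg_band(truth$substrate)
  nr <- nrow(dep); nc <- ncol(dep)
  land <- is.na(dep)
  z <- dep
  z[land] <- 0
  texture <- matrix(rnorm(nr * nc, 0, optics$texture_sd), nr, nc)
  bands <- c("R", "G", "B")
  arr <- array(NA_real_, dim = c(nr, nc, 3L))
  alb <- optics$substrate_albedo
  for (b in seq_along(bands)) {
    K <- optics$attenuation[[bands[b]]]
    Li <- optics$water_signal[[bands[b]]]
    A <- matrix(alb[match(names(SUBSTRATE_LEVELS)[sub], rownames(alb)),
                    bands[b]], nr, nc)
    L <- Li + (A - Li) * exp(-2 * K * z) * (1 + texture)
    L[land] <- A[land] * (1 + texture[land])
    if (optics$sensor_noise_sd > 0)
      L <- L + rnorm(nr * nc, 0, optics$sensor_noise_sd)
    arr[, , b] <- pmin(pmax(L, 1e-6), 1)
  }
  rg_like(truth$depth, arr, band_names = bands)
}

#' Generate a noisy digital surface model
#'
#' DSM = -depth plus a smooth, spatially correlated error field (Gaussian-
#' filtered white noise rescaled to pointwise SD \code{vertical_noise_sd}),
#' mimicking structure-from-motion noise over water.
#'
#' @param truth a \code{scene_truth}
#' @param vertical_noise_sd pointwise error SD in metres
#' @param seed integer RNG seed
#' @param correlation_px correlation length of the error field in pixels
#' @return single-band \code{raster_grid} (elevation, m; negative in water)
#' @export
generate_dsm <- function(truth, vertical_noise_sd = 0.5, seed = 1,
                         correlation_px = 8) {
  stopifnot(inherits(truth, "scene_truth"))
  if (vertical_noise_sd < 0) stop("vertical_noise_sd must be >= 0")
  set.seed(seed)
  dep <- rg_band(truth$depth)
  dsm <- -dep
  if (vertical_noise_sd > 0) {
    err <- smooth_field(matrix(rnorm(length(dep)), nrow(dep), ncol(dep)),
                        sigma = correlation_px)
    err <- vertical_noise_sd * err / stats::sd(as.vector(err))
    dsm <- dsm + err
    dsm[is.na(dep)] <- NA
  }
  rg_like(truth$depth, dsm, band_names = "dsm")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) <= 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate photoquadrat point-intercept records
#'
#' For each quadrat a living-cover composition is drawn from
#' Dirichlet(concentration x normalized mean cover), a nonliving/non-valid
#' fraction from the profile's range, and \code{points_per_quadrat} labels
#' multinomially, assigned 25 per cell in the stratified 4-cell design.
#'
#' @param profiles list of assemblage profiles (see
#'   \code{\link{default_profiles}})
#' @param design named integer vector: samples per assemblage (default
#'   c(a=4, b=4, c=3, d=3) giving the 14-sample survey; each assemblage's
#'   samples cycle through its catalog condition pairs, so every pair is
#'   represented)
#' @param quadrats_per_sample quadrats per sampling station
#' @param points_per_quadrat points per quadrat; must be divisible by 4
#' @param catalog planted \code{biotope_catalog} supplying each sample's
#'   (depth class, substrate) metadata
#' @param seed integer RNG seed
#' @return list with \code{$points} (sample_id, quadrat_id, cell, point_idx,
#'   label) and \code{$metadata} (sample_id, assemblage, depth_class,
#'   substrate)
#' @export
generate_quadrat_points <- function(profiles = default_profiles(),
                                    design = c(a = 4, b = 4, c = 3, d = 3),
                                    quadrats_per_sample = 6,
                                    points_per_quadrat = 100,
                                    catalog = default_catalog(), seed = 1) {
  if (length(profiles) == 0) stop("empty profile list")
  if (any(design < 0)) stop("negative design counts")
  if (quadrats_per_sample < 1) stop("quadrats_per_sample must be >= 1")
  if (points_per_quadrat %% 4 != 0)
    stop("points_per_quadrat must be divisible by 4 (stratified design)")
  set.seed(seed)
  pts <- list(); meta <- list(); sid <- 0L
  for (a in names(design)) {
    prof <- profiles[[a]]
    if (is.null(prof)) stop("no profile for assemblage ", a)
    conds <- catalog$conditions[catalog$conditions$assemblage == a, ,
                                drop = FALSE]
    for (s in seq_len(design[[a]])) {
      sid <- sid + 1L
      cond <- conds[((s - 1L) %% nrow(conds)) + 1L, ]
      sample_id <- sprintf("S%02d", sid)
      meta[[sid]] <- data.frame(sample_id = sample_id, assemblage = a,
                                depth_class = cond$depth_class,
                                substrate = cond$substrate)
      for (q in seq_len(quadrats_per_sample)) {
        labels <- draw_quadrat_labels(prof, points_per_quadrat)
        pts[[length(pts) + 1L]] <- data.frame(
          sample_id = sample_id,
          quadrat_id = sprintf("%s_Q%d", sample_id, q),
          cell = rep(1:4, each = points_per_quadrat / 4),
          point_idx = seq_len(points_per_quadrat),
          label = labels)
      }
    }
  }
  list(points = do.call(rbind, pts), metadata = do.call(rbind, meta))
}

draw_quadrat_labels <- function(prof, n_points) {
  w <- prof$mean_cover / sum(prof$mean_cover)
  p_live <- rdirichlet1(prof$concentration * w)
  u <- runif(1, prof$nonliving_range[1], prof$nonliving_range[2])
  probs <- c(p_live * (1 - u), rep(u / length(NONLIVING_CATS),
                                   length(NONLIVING_CATS)))
  cats <- c(names(prof$mean_cover), NONLIVING_CATS)
  counts <- as.vector(rmultinom(1, n_points, probs))
  sample(rep(cats, counts))
}

#' Simulate validation transect point-intercept records
#'
#' Places each 10 m transect fully inside one connected region of a single
#' true biotope and draws its point labels from that biotope's assemblage
#' profile; point coordinates are spaced every 10 cm along the line.
#'
#' @param truth a \code{scene_truth}
#' @param profiles assemblage profiles
#' @param n_transects number of transects
#' @param points_per_transect intersection points per transect
#' @param spacing_m along-transect point spacing (m)
#' @param seed integer RNG seed
#' @return data.frame (transect_id, point_idx, x, y, label) with attribute
#'   \code{"true_biotope"} (named vector per transect)
#' @export
generate_transect_records <- function(truth, profiles = default_profiles(),
                                      n_transects = 8,
                                      points_per_transect = 100,
                                      spacing_m = 0.1, seed = 1,
                                      interior_margin_px = 4) {
  stopifnot(inherits(truth, "scene_truth"))
  set.seed(seed)
  bio <- rg_band(truth$biotope)
  ps <- truth$pixel_size
  len_px <- ceiling((points_per_transect - 1) * spacing_m / ps) + 1L
  labels <- truth$biotope_legend
  assemblages <- setdiff(unname(labels), "unassigned")
  erode <- function(m, it) {
    for (i in seq_len(it)) {
      nr <- nrow(m); nc <- ncol(m)
      m <- m &
        rbind(FALSE, m[-nr, ]) & rbind(m[-1, ], FALSE) &
        cbind(FALSE, m[, -nc]) & cbind(m[, -1], FALSE)
    }
    m
  }
  out <- list(); truth_lab <- character(n_transects)
  for (t in seq_len(n_transects)) {
    a <- assemblages[((t - 1L) %% length(assemblages)) + 1L]
    code <- as.integer(names(labels)[labels == a])
    full_mask <- !is.na(bio) & bio == code
    # prefer patch interiors (field transects avoid habitat edges)
    masks <- list(full_mask)
    if (interior_margin_px > 0) {
      interior <- erode(full_mask, interior_margin_px)
      if (any(interior)) masks <- list(interior, full_mask)
    }
    placed <- FALSE
    for (mask in masks) {
    # try horizontal runs, then vertical, long enough to host the transect
    cand <- which(mask, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      for (orient in c("h", "v")) {
        along <- if (orient == "h") 1L else 2L
        across <- 3L - along
        lines_avail <- sample(unique(cand[, along]))
        for (ln in lines_avail) {
          cs <- sort(cand[cand[, along] == ln, across])
          runs <- split(cs, cumsum(c(1, diff(cs) != 1)))
          runs <- runs[vapply(runs, length, 0L) >= len_px]
          if (length(runs) == 0) next
          run <- runs[[sample.int(length(runs), 1)]]
          c0 <- run[sample.int(length(run) - len_px + 1L, 1)]
          step <- (seq_len(points_per_transect) - 1) * spacing_m
          if (orient == "h") {
            start <- rg_xy(truth$biotope, ln, c0)
            xs <- start[1] + step
            ys <- rep(start[2], points_per_transect)
          } else {
            start <- rg_xy(truth$biotope, c0, ln)
            xs <- rep(start[1], points_per_transect)
            ys <- start[2] - step   # southwards, within the run
          }
          prof <- profiles[[a]]
          labs <- draw_quadrat_labels(prof, points_per_transect)
          out[[t]] <- data.frame(transect_id = sprintf("T%d", t),
                                 point_idx = seq_len(points_per_transect),
                                 x = xs, y = ys, label = labs)
          truth_lab[t] <- a
          placed <- TRUE
          break
        }
        if (placed) break
      }
    }
    if (placed) break
    }
    if (!placed)
      stop("no biotope region large enough to host a ", len_px,
           "-pixel transect for assemblage ", a)
  }
  rec <- do.call(rbind, out)
  attr(rec, "true_biotope") <- setNames(truth_lab,
                                        sprintf("T%d", seq_len(n_transects)))
  rec
}
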