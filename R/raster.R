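#' Gridded raster values with a geotransform
#'
#' A minimal in-memory raster container: one or more bands of equal shape,
#' a north-up affine geotransform (pixel-center convention, 0-based rows and
#' columns internally 1-based in R), an NA nodata mask and an opaque CRS tag.
#' Values are stored as a numeric \code{nrow x ncol x nband} array; nodata
#' cells are \code{NA} in every band.
#'
#' @param values numeric matrix (single band) or \code{nrow x ncol x nband}
#'   array. \code{NA} marks nodata.
#' @param origin numeric length-2: x and y of the top-left raster corner.
#' @param pixel_size numeric length-2 \code{c(dx, dy)} with \code{dx > 0} and
#'   \code{dy < 0} (north-up), in projected units (metres); a single positive
#'   number is shorthand for \code{c(s, -s)}.
#' @param crs opaque CRS tag; geographic (degree) CRS are not supported.
#' @param band_names optional character vector naming the bands.
#' @return an object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, origin = c(0, 0), pixel_size = 1,
                        crs = "local-projected", band_names = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (length(dim(values)) != 3L) stop("values must be a matrix or 3-d array")
  if (length(pixel_size) == 1L) pixel_size <- c(pixel_size, -pixel_size)
  if (pixel_size[1] <= 0 || pixel_size[2] >= 0)
    stop("pixel_size must be c(dx > 0, dy < 0) (north-up)")
  if (grepl("^EPSG:4326$|geographic", crs, ignore.case = TRUE))
    stop("geographic CRS not supported; supply a projected CRS")
  nb <- dim(values)[3]
  if (is.null(band_names)) band_names <- paste0("band", seq_len(nb))
  if (length(band_names) != nb) stop("band_names length must match band count")
  # nodata must agree across bands
  if (nb > 1L) {
    m <- is.na(values[, , 1L])
    for (b in 2L:nb) {
      if (!identical(m, is.na(values[, , b])))
        stop("nodata mask differs between bands")
    }
  }
  structure(list(values = values, origin = as.numeric(origin),
                 pixel_size = as.numeric(pixel_size), crs = crs,
                 band_names = band_names),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_grid: %d x %d px, %d band(s) [%s]\n", d[1], d[2], d[3],
              paste(x$band_names, collapse = ", ")))
  cat(sprintf("  origin (%g, %g), pixel %g x %g m, crs: %s\n",
              x$origin[1], x$origin[2], x$pixel_size[1], x$pixel_size[2], x$crs))
  cat(sprintf("  nodata: %d / %d px\n", sum(is.na(x$values[, , 1])), d[1] * d[2]))
  invisible(x)
}

#' Extract one band as a matrix
#' @param grid a \code{raster_grid}
#' @param band band index or name
#' @export
rg_band <- function(grid, band = 1L) {
  if (is.character(band)) band <- match(band, grid$band_names)
  grid$values[, , band]
}

#' Replace bands of a grid keeping its georeferencing
#' @param grid template \code{raster_grid}
#' @param values new matrix or array
#' @param band_names optional new band names
#' @export
rg_like <- function(grid, values, band_names = NULL) {
  raster_grid(values, origin = grid$origin, pixel_size = grid$pixel_size,
              crs = grid$crs, band_names = band_names)
}

#' Pixel area in square metres
#' @param grid a \code{raster_grid}
#' @export
rg_pixel_area <- function(grid) grid$pixel_size[1] * abs(grid$pixel_size[2])

#' Centre coordinates of a pixel
#' @param grid a \code{raster_grid}
#' @param row,col 1-based indices (vectors allowed)
#' @return two-column matrix of x, y
#' @export
rg_xy <- function(grid, row, col) {
  cbind(x = grid$origin[1] + (col - 0.5) * grid$pixel_size[1],
        y = grid$origin[2] + (row - 0.5) * grid$pixel_size[2])
}

#' Row/col of points given coordinates (pixel-center convention)
#' @param grid a \code{raster_grid}
#' @param x,y coordinates
#' @export
rg_rowcol <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$pixel_size[1]) + 1L
  row <- floor((y - grid$origin[2]) / grid$pixel_size[2]) + 1L
  cbind(row = as.integer(row), col = as.integer(col))
}

# ---------------------------------------------------------------------------
# I/O: ESRI ASCII grid per band + JSON sidecar (band names, nodata, crs,
# optional legend). Values printed with 17 significant digits so numeric
# round-trips are bit-exact.

#' Save a raster to disk
#'
#' Writes one ESRI ASCII grid (.asc) per band plus a JSON sidecar
#' \code{<path>.json} recording band files, geotransform, CRS tag and an
#' optional legend for categorical rasters.
#'
#' @param grid a \code{raster_grid}
#' @param path output path without extension (or ending in .asc for single
#'   band)
#' @param legend optional named vector mapping integer codes to class names
#' @param nodata numeric sentinel written to file for NA cells
#' @return the sidecar path, invisibly
#' @export
save_raster <- function(grid, path, legend = NULL, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  if (abs(grid$pixel_size[1]) != abs(grid$pixel_size[2]))
    stop("ASCII grid requires square pixels")
  path <- sub("\\.asc$", "", path)
  d <- dim(grid$values)
  files <- character(d[3])
  for (b in seq_len(d[3])) {
    f <- if (d[3] == 1L) paste0(path, ".asc") else
      sprintf("%s_%s.asc", path, grid$band_names[b])
    m <- grid$values[, , b]
    m[is.na(m)] <- nodata
    hdr <- c(sprintf("ncols %d", d[2]),
             sprintf("nrows %d", d[1]),
             sprintf("xllcorner %.17g", grid$origin[1]),
             sprintf("yllcorner %.17g", grid$origin[2] + d[1] * grid$pixel_size[2]),
             sprintf("cellsize %.17g", grid$pixel_size[1]),
             sprintf("NODATA_value %.17g", nodata))
    rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(c(hdr, rows), f)
    files[b] <- basename(f)
  }
  side <- list(format = "esri-ascii-grid", bands = as.list(files),
               band_names = as.list(grid$band_names),
               origin = grid$origin, pixel_size = grid$pixel_size,
               crs = grid$crs, nodata = nodata)
  if (!is.null(legend)) side$legend <- as.list(legend)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, ".json"))
}

read_asc <- function(f) {
  hdr <- readLines(f, n = 6L)
  kv <- strsplit(tolower(hdr), "\\s+")
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                          vapply(kv, `[[`, "", 1L))
  m <- matrix(scan(f, skip = 6L, quiet = TRUE), nrow = vals[["nrows"]],
              ncol = vals[["ncols"]], byrow = TRUE)
  nod <- vals[["nodata_value"]]
  m[m == nod] <- NA
  list(m = m, hdr = vals)
}

#' Load a raster saved by \code{save_raster}
#'
#' @param path sidecar path (\code{.json}) or base path / single \code{.asc}
#'   file. A bare \code{.asc} without sidecar loads with a unit CRS and a
#'   warning.
#' @return a \code{raster_grid}; a legend, when present, is attached as
#'   attribute \code{"legend"}.
#' @export
load_raster <- function(path) {
  side_path <- if (grepl("\\.json$", path)) path else paste0(sub("\\.asc$", "", path), ".json")
  if (!file.exists(side_path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    warning("no sidecar JSON; assuming unit transform and unknown CRS")
    a <- read_asc(path)
    ps <- a$hdr[["cellsize"]]
    org <- c(a$hdr[["xllcorner"]], a$hdr[["yllcorner"]] + nrow(a$m) * ps)
    return(raster_grid(a$m, origin = org, pixel_size = c(ps, -ps),
                       crs = "unknown"))
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  dir <- dirname(side_path)
  mats <- lapply(file.path(dir, side$bands), function(f) read_asc(f)$m)
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  g <- raster_grid(arr, origin = side$origin, pixel_size = side$pixel_size,
                   crs = side$crs, band_names = unlist(side$band_names))
  if (!is.null(side$legend)) attr(g, "legend") <- unlist(side$legend)
  g
}

# ---------------------------------------------------------------------------
# Polygonization of categorical rasters

# Trace boundary rings of a binary mask component. Returns list of rings,
# each a matrix of corner (i = row-line 0..nr, j = col-line 0..nc) indices.
# Directed so exterior rings are counter-clockwise in world (north-up) space.
trace_rings <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inm <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # directed edges keyed by start corner; corner key = i * (nc + 1) + j
  key <- function(i, j) i * (nc + 1L) + j
  starts <- integer(0); ends <- integer(0)
  for (c in seq_len(nc)) {
    for (r in seq_len(nr)) {
      if (!mask[r, c]) next
      if (!inm(r, c - 1L)) { starts <- c(starts, key(r - 1L, c - 1L)); ends <- c(ends, key(r, c - 1L)) }      # west: TL->BL
      if (!inm(r + 1L, c)) { starts <- c(starts, key(r, c - 1L)); ends <- c(ends, key(r, c)) }                # south: BL->BR
      if (!inm(r, c + 1L)) { starts <- c(starts, key(r, c)); ends <- c(ends, key(r - 1L, c)) }                # east: BR->TR
      if (!inm(r - 1L, c)) { starts <- c(starts, key(r - 1L, c)); ends <- c(ends, key(r - 1L, c - 1L)) }      # north: TR->TL
    }
  }
  used <- rep(FALSE, length(starts))
  ord <- order(starts)
  sorted_starts <- starts[ord]
  rings <- list()
  for (e0 in seq_along(starts)) {
    if (used[e0]) next
    ring <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring <- c(ring, starts[e])
      target <- ends[e]
      # candidate outgoing edges from target
      lo <- findInterval(target - 1L, sorted_starts) + 1L
      cand <- integer(0)
      while (lo <= length(ord) && sorted_starts[lo] == target) {
        if (!used[ord[lo]]) cand <- c(cand, ord[lo])
        lo <- lo + 1L
      }
      if (length(cand) == 0L) break
      if (length(cand) == 1L) e <- cand[1L] else {
        # saddle: prefer the sharpest right turn (keeps rings simple)
        din <- c(ends[e] %/% (nc + 1L) - starts[e] %/% (nc + 1L),
                 ends[e] %% (nc + 1L) - starts[e] %% (nc + 1L))
        turn <- vapply(cand, function(k) {
          dk <- c(ends[k] %/% (nc + 1L) - starts[k] %/% (nc + 1L),
                  ends[k] %% (nc + 1L) - starts[k] %% (nc + 1L))
          din[1] * dk[2] - din[2] * dk[1]  # cross product (row, col frame)
        }, 0)
        e <- cand[order(turn)][1L]
      }
    }
    ij <- cbind(i = ring %/% (nc + 1L), j = ring %% (nc + 1L))
    rings[[length(rings) + 1L]] <- rbind(ij, ij[1L, , drop = FALSE])
  }
  rings
}

ring_to_world <- function(ring_ij, grid) {
  cbind(x = grid$origin[1] + ring_ij[, "j"] * grid$pixel_size[1],
        y = grid$origin[2] + ring_ij[, "i"] * grid$pixel_size[2])
}

shoelace <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  0.5 * sum(x[-n] * y[-1] - x[-1] * y[-n])
}

#' Vectorize a categorical raster into class polygons
#'
#' Traces pixel-edge boundaries of each class into polygons with holes
#' (one polygon per 4-connected component), in world coordinates. Area is
#' conserved exactly: the signed areas of a component's rings sum to its
#' pixel count times the pixel area.
#'
#' @param label_raster single-band \code{raster_grid} of integer class codes
#' @param legend named vector mapping codes (as names or values) to class
#'   names; defaults to the codes themselves
#' @return a \code{class_polygon_layer}: list with per-class multipolygons
#'   (\code{$polygons}), class names and areas (m^2)
#' @export
labels_to_polygons <- function(label_raster, legend = NULL) {
  stopifnot(inherits(label_raster, "raster_grid"))
  if (dim(label_raster$values)[3] != 1L) stop("expected single-band categorical raster")
  lab <- rg_band(label_raster, 1L)
  codes <- sort(unique(as.vector(lab[!is.na(lab)])))
  out <- list()
  for (cd in codes) {
    nm <- if (!is.null(legend)) {
      v <- legend[as.character(cd)]
      if (is.na(v)) as.character(cd) else unname(v)
    } else as.character(cd)
    mask <- !is.na(lab) & lab == cd
    comp <- cpp_connected_components(mask)
    polys <- list()
    for (k in seq_len(max(comp))) {
      rings_ij <- trace_rings(comp == k)
      rings_w <- lapply(rings_ij, ring_to_world, grid = label_raster)
      areas <- vapply(rings_w, shoelace, 0)
      ext <- which(areas > 0)
      holes <- which(areas < 0)
      # one exterior expected per component; extra positives can arise from
      # saddle splitting -- treat each positive ring as its own shell
      for (ei in ext) {
        polys[[length(polys) + 1L]] <- c(list(rings_w[[ei]]),
                                         if (ei == ext[1]) rings_w[holes] else list())
      }
    }
    area <- sum(mask) * rg_pixel_area(label_raster)
    out[[nm]] <- list(class = nm, code = cd, polygons = polys, area_m2 = area)
  }
  structure(list(classes = out, crs = label_raster$crs),
            class = "class_polygon_layer")
}

#' @export
print.class_polygon_layer <- function(x, ...) {
  cat("class_polygon_layer:\n")
  for (cl in x$classes)
    cat(sprintf("  %s: %d polygon(s), %.2f m2\n", cl$class,
                length(cl$polygons), cl$area_m2))
  invisible(x)
}

#' Write a polygon layer as GeoJSON
#' @param layer a \code{class_polygon_layer}
#' @param path output path
#' @export
write_polygons_geojson <- function(layer, path) {
  feats <- lapply(layer$classes, function(cl) {
    coords <- lapply(cl$polygons, function(poly)
      lapply(poly, function(ring) lapply(seq_len(nrow(ring)), function(i)
        c(ring[i, 1], ring[i, 2]))))
    list(type = "Feature",
         properties = list(class = cl$class, code = cl$code,
                           area_m2 = cl$area_m2),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Area accounting of a categorical raster
#'
#' @param label_raster single-band \code{raster_grid} of class codes (or
#'   factor-coded categories)
#' @param legend optional named vector code -> class name
#' @return data.frame with class, pixel count, area in m^2 and fraction of
#'   the non-nodata area
#' @export
area_by_class <- function(label_raster, legend = NULL) {
  stopifnot(inherits(label_raster, "raster_grid"))
  lab <- rg_band(label_raster, 1L)
  px <- rg_pixel_area(label_raster)
  tab <- table(lab[!is.na(lab)])
  codes <- as.numeric(names(tab))
  nm <- if (!is.null(legend)) {
    v <- legend[as.character(codes)]
    ifelse(is.na(v), as.character(codes), unname(v))
  } else as.character(codes)
  n <- as.integer(tab)
  data.frame(class = nm, code = codes, n_pixels = n, area_m2 = n * px,
             fraction = n / sum(n), row.names = NULL)
}
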