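#' Derive a biotope catalog from an assemblage grouping
#'
#' Maps each statistically identified assemblage to the set of
#' (depth class, substrate) condition pairs observed among its samples.
#' Conditions must be diagnostic: a pair observed under two assemblages is
#' an error (use \code{force_majority} to fall back to majority voting).
#'
#' @param grouping \code{assemblage_grouping} or named group vector keyed
#'   by sample id
#' @param metadata data.frame with sample_id, depth_class, substrate
#' @param force_majority resolve conflicting pairs by assigning them to
#'   the assemblage with most samples on that pair
#' @return a \code{biotope_catalog}
#' @export
derive_biotope_catalog <- function(grouping, metadata,
                                   force_majority = FALSE) {
  g <- if (inherits(grouping, "assemblage_grouping")) grouping$groups else grouping
  stopifnot(all(c("sample_id", "depth_class", "substrate") %in%
                  names(metadata)))
  if (!all(names(g) %in% metadata$sample_id))
    stop("sample(s) without metadata: ",
         paste(setdiff(names(g), metadata$sample_id), collapse = ", "))
  md <- metadata[match(names(g), metadata$sample_id), ]
  tab <- data.frame(assemblage = unname(g), depth_class = md$depth_class,
                    substrate = md$substrate,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n = rep(1L, nrow(tab))),
                          by = tab[c("assemblage", "depth_class",
                                     "substrate")], FUN = sum)
  key <- paste(agg$depth_class, agg$substrate)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    if (!force_majority) {
      msg <- vapply(dup, function(k) {
        rows <- agg[key == k, ]
        sprintf("(%s) claimed by %s", k,
                paste(rows$assemblage, collapse = ", "))
      }, "")
      stop("conflicting catalog conditions: ", paste(msg, collapse = "; "))
    }
    keep <- unlist(lapply(unique(key), function(k) {
      rows <- which(key == k)
      rows[which.max(agg$n[rows])]
    }))
    agg <- agg[sort(keep), ]
  }
  biotope_catalog(agg[c("assemblage", "depth_class", "substrate")])
}

#' Compare two biotope catalogs up to assemblage relabelling
#'
#' Statistically derived assemblage letters need not match the planted
#' ones, so catalogs are compared by their condition sets: each assemblage
#' of \code{recovered} is matched to the \code{reference} assemblage with
#' the identical set of (depth class, substrate) pairs.
#'
#' @param recovered,reference \code{biotope_catalog}s
#' @return list(identical = logical, mapping = named vector recovered ->
#'   reference label, NA where unmatched)
#' @export
compare_catalogs <- function(recovered, reference) {
  pair_sets <- function(cat) {
    lapply(split(cat$conditions, cat$conditions$assemblage), function(df)
      sort(paste(df$depth_class, df$substrate)))
  }
  rs <- pair_sets(recovered)
  fs <- pair_sets(reference)
  mapping <- vapply(rs, function(s) {
    hit <- names(fs)[vapply(fs, identical, TRUE, y = s)]
    if (length(hit) == 1) hit else NA_character_
  }, "")
  identical_cat <- !anyNA(mapping) && length(rs) == length(fs) &&
    !anyDuplicated(mapping)
  list(identical = identical_cat, mapping = mapping)
}

#' Per-biotope intersection-over-union against scene truth
#'
#' Aligns the map's (statistically labelled) assemblages with the planted
#' ones through their catalog condition sets, then computes IoU of each
#' biotope's predicted and true footprints. A recovered assemblage whose
#' condition set is a strict subset of one planted assemblage's set (as
#' happens when a group is statistically over-split) contributes its
#' footprint to that planted assemblage; a planted assemblage with no
#' recovered counterpart scores 0.
#'
#' @param biomap a \code{biotope_map} produced from a recovered catalog
#' @param truth a \code{scene_truth}
#' @return named numeric vector of IoU per planted assemblage
#' @export
biotope_iou <- function(biomap, truth) {
  pair_set <- function(cat, lab) {
    df <- cat$conditions[cat$conditions$assemblage == lab, ]
    sort(paste(df$depth_class, df$substrate))
  }
  rec_labs <- unique(biomap$catalog$conditions$assemblage)
  planted_labs <- sort(unique(truth$catalog$conditions$assemblage))
  bio <- rg_band(biomap$raster, 1L)
  tbio <- rg_band(truth$biotope, 1L)
  tl <- truth$biotope_legend
  out <- setNames(numeric(length(planted_labs)), planted_labs)
  for (planted in planted_labs) {
    pset <- pair_set(truth$catalog, planted)
    members <- rec_labs[vapply(rec_labs, function(rl)
      all(pair_set(biomap$catalog, rl) %in% pset), TRUE)]
    code_tru <- as.integer(names(tl)[tl == planted])
    b <- !is.na(tbio) & tbio == code_tru
    if (length(members) == 0) { out[planted] <- 0; next }
    codes_rec <- as.integer(names(biomap$legend)[biomap$legend %in% members])
    a <- !is.na(bio) & bio %in% codes_rec
    out[planted] <- sum(a & b) / sum(a | b)
  }
  out
}

#' Extrapolate biotope distribution over the physiographic map
#'
#' Pure lookup: each pixel's (depth class, substrate) pair is matched
#' against the catalog; non-matching pixels are unassigned (code 0).
#'
#' @param physio a \code{physiographic_map}
#' @param catalog a \code{biotope_catalog}
#' @return a \code{biotope_map}: categorical raster (codes with legend:
#'   0 = unassigned, 1.. = assemblages) and area table
#' @export
extrapolate_biotope_map <- function(physio, catalog) {
  stopifnot(inherits(physio, "physiographic_map"),
            inherits(catalog, "biotope_catalog"))
  known_sub <- unname(physio$substrate_legend)
  bad <- setdiff(unique(catalog$conditions$substrate), known_sub)
  if (length(bad) > 0)
    stop("catalog substrate(s) unknown to the map: ",
         paste(bad, collapse = ", "))
  dc <- rg_band(physio$depth_class, 1L)
  sub <- rg_band(physio$substrate, 1L)
  sub_name <- matrix(physio$substrate_legend[as.character(sub)],
                     nrow(sub), ncol(sub))
  levels_b <- sort(unique(catalog$conditions$assemblage))
  lut <- setNames(match(catalog$conditions$assemblage, levels_b),
                  paste(catalog$conditions$depth_class,
                        catalog$conditions$substrate))
  code <- unname(lut[paste(as.vector(dc), as.vector(sub_name))])
  out <- matrix(as.integer(code), nrow(dc), ncol(dc))
  out[is.na(out) & !is.na(dc)] <- 0L
  raster <- rg_like(physio$depth_class, out, band_names = "biotope")
  legend <- setNames(c("unassigned", levels_b), c(0, seq_along(levels_b)))
  bm <- structure(list(raster = raster, legend = legend,
                       catalog = catalog), class = "biotope_map")
  bm$areas <- summarize_areas(bm)
  bm
}

#' @export
print.biotope_map <- function(x, ...) {
  cat("biotope_map\n")
  print(x$areas)
  invisible(x)
}

#' Area accounting of a biotope map
#'
#' @param biomap a \code{biotope_map}
#' @return data.frame with per-biotope m^2, ha and fraction of the
#'   assigned area, plus assigned/unassigned totals
#' @export
summarize_areas <- function(biomap) {
  stopifnot(inherits(biomap, "biotope_map"))
  ab <- area_by_class(biomap$raster, biomap$legend)
  assigned <- ab[ab$class != "unassigned", , drop = FALSE]
  tot_assigned <- sum(assigned$area_m2)
  out <- data.frame(biotope = assigned$class,
                    area_m2 = assigned$area_m2,
                    area_ha = assigned$area_m2 / 1e4,
                    fraction_assigned = if (tot_assigned > 0)
                      assigned$area_m2 / tot_assigned
                    else rep(NA_real_, nrow(assigned)))
  attr(out, "assigned_m2") <- tot_assigned
  attr(out, "unassigned_m2") <- sum(ab$area_m2) - tot_assigned
  out
}

#' Validate the biotope map with independent transects
#'
#' Labels each transect with the biotope predicted at its point locations
#' (majority rule; a warning is emitted when points fall on unassigned
#' pixels), builds transect-level percent covers, prunes/standardizes/
#' sqrt-transforms them, and tests the predicted grouping with one-way
#' ANOSIM on Bray-Curtis similarities.
#'
#' @param records transect point data.frame (transect_id, point_idx, x, y,
#'   label)
#' @param biomap a \code{biotope_map}
#' @param n_perm ANOSIM permutations
#' @param seed RNG seed
#' @param search_radius_px search radius (pixels) for the nearest-assigned
#'   fallback
#' @return list(test = \code{permutation_test_result}, predicted = named
#'   label vector, matrix = transect \code{community_matrix})
#' @export
validate_with_transects <- function(records, biomap, n_perm = 999,
                                    seed = 1, search_radius_px = 8) {
  stopifnot(inherits(biomap, "biotope_map"),
            all(c("transect_id", "x", "y", "label") %in% names(records)))
  bio <- rg_band(biomap$raster, 1L)
  rc <- rg_rowcol(biomap$raster, records$x, records$y)
  inb <- rc[, 1] >= 1 & rc[, 1] <= nrow(bio) & rc[, 2] >= 1 &
    rc[, 2] <= ncol(bio)
  px <- rep(NA_integer_, nrow(records))
  px[inb] <- bio[rc[inb, , drop = FALSE]]
  # a point on an unassigned pixel takes the nearest assigned biotope
  # within search_radius_px (transects can graze predicted-patch edges)
  nearest_assigned <- function(r0, c0) {
    r1 <- max(1L, r0 - search_radius_px); r2 <- min(nrow(bio), r0 + search_radius_px)
    c1 <- max(1L, c0 - search_radius_px); c2 <- min(ncol(bio), c0 + search_radius_px)
    win <- bio[r1:r2, c1:c2, drop = FALSE]
    cand <- which(!is.na(win) & win != 0L, arr.ind = TRUE)
    if (nrow(cand) == 0) return(NA_integer_)
    d2 <- (cand[, 1] + r1 - 1L - r0)^2 + (cand[, 2] + c1 - 1L - c0)^2
    win[cand[which.min(d2), , drop = FALSE]]
  }
  fill <- which(inb & (is.na(px) | px == 0L))
  for (i in fill) px[i] <- nearest_assigned(rc[i, 1], rc[i, 2])
  predicted <- vapply(split(px, records$transect_id), function(v) {
    v <- v[!is.na(v) & v != 0L]
    if (length(v) == 0) return(NA_character_)
    unname(biomap$legend[as.character(as.integer(names(sort(table(v),
      decreasing = TRUE))[1]))])
  }, "")
  if (length(fill) > 0)
    warning("some transect points fall on unassigned pixels; ",
            "majority/nearest rule applied")
  if (anyNA(predicted))
    stop("transect(s) entirely outside the assigned biotope area: ",
         paste(names(predicted)[is.na(predicted)], collapse = ", "))
  if (length(unique(predicted)) < 2)
    stop("all transects predicted in one group; test undefined")
  cm <- percent_cover_from_points(records, unit_key = "transect_id")
  cm <- transform_sqrt(prepare_community_matrix(cm))
  sim <- bray_curtis(cm)
  test <- anosim(sim, predicted[sim$labels], n_perm = n_perm, seed = seed)
  list(test = test, predicted = predicted, matrix = cm)
}
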