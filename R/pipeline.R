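#' Default pipeline configuration
#'
#' All tunables of the pipeline stages with their defaults; see the
#' methods vignette for the rationale behind each value. Override by
#' passing a nested list (or YAML file via \code{load_config}) with a
#' subset of these keys; unknown keys are rejected.
#'
#' @export
default_config <- function() {
  list(
    seed = 1L,
    scene = list(shape = c(400L, 400L), pixel_size = 0.25, n_patches = 24L,
                 land_fraction = 0.05,
                 substrate_weights = c(platform = 0.30, boulders = 0.35,
                                       blocks = 0.25, sand = 0.10),
                 min_patch_run_m = 12,
                 attenuation = c(R = 0.55, G = 0.12, B = 0.07),
                 water_signal = c(R = 0.02, G = 0.04, B = 0.06),
                 texture_sd = 0.08, sensor_noise_sd = 0.005,
                 dsm_noise_sd = 0.5),
    radiometry = list(epsilon = 1e-4),
    segmentation = list(scale = 65, shape_weight = 0.5,
                        compactness_weight = 0.5),
    obia = list(edges = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 11, 14),
                k = 1L, quality_quantile = 0.9, smooth_factor = 0.25,
                presmooth_px = 3, index_scaling = 24000,
                training_points_per_class = 60L),
    community = list(design = c(a = 4L, b = 4L, c = 3L, d = 3L),
                     quadrats_per_sample = 6L, points_per_quadrat = 100L,
                     concentration = 60, nonliving_range = c(0.05, 0.20),
                     n_perm = 999L, alpha = 0.05),
    biotope = list(n_transects = 8L, points_per_transect = 100L,
                   force_majority = FALSE))
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0)
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_config_keys(as.list(cfg[[nm]]), ref[[nm]],
                        paste0(path, nm, "."))
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#' @param path YAML file (NULL for defaults) or a nested list of overrides
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (is.character(path)) yaml::read_yaml(path) else path
    check_config_keys(user, cfg)
    cfg <- merge_config(cfg, user)
  }
  cfg
}

# deterministic per-stage seed from the global seed and the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

log_info <- function(...) message(sprintf("[benthomap] %s", sprintf(...)))

#' Run the biotope-mapping pipeline
#'
#' Orchestrates the stages: \code{simulate} (synthetic scene + surveys),
#' \code{map-physiography} (depth classes + substrate via OBIA),
#' \code{analyze-community} (SIMPROF grouping, SIMPER, ANOSIM, nMDS,
#' DistLM, CAP), \code{map-biotopes} (catalog + extrapolation + areas) and
#' \code{validate} (transect ANOSIM). Each stage writes its artifacts under
#' \code{out_dir} plus a JSON manifest recording inputs, the config hash,
#' the stage seed and output paths. Per-stage seeds derive
#' deterministically from the global seed, so stages can be re-run
#' individually.
#'
#' @param config nested configuration list (see \code{default_config})
#' @param stages character subset of the stage names above (in pipeline
#'   order); defaults to all
#' @param out_dir output directory
#' @param state optional in-memory state from a previous call (avoids
#'   re-reading artifacts)
#' @return the pipeline state (invisibly): all intermediate objects plus
#'   \code{$manifest}
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "map-physiography",
                                    "analyze-community", "map-biotopes",
                                    "validate"),
                         out_dir = tempfile("benthomap_"), state = NULL) {
  check_config_keys(config, default_config())
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- if (is.null(state)) list() else state
  st$config <- config
  hash <- config_hash(config)
  manifest <- if (is.null(st$manifest)) list() else st$manifest
  record <- function(stage, seed, outputs, inputs = character(0)) {
    manifest[[stage]] <<- list(stage = stage, seed = seed,
                               config_hash = hash, inputs = inputs,
                               outputs = outputs)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("simulate" %in% stages) {
    sd <- stage_seed(config$seed, "simulate")
    sc <- config$scene
    binning <- depth_binning(config$obia$edges)
    catalog <- default_catalog(binning)
    truth <- generate_scene_truth(shape = sc$shape,
                                  pixel_size = sc$pixel_size,
                                  catalog = catalog, binning = binning,
                                  seed = sd, n_patches = sc$n_patches,
                                  land_fraction = sc$land_fraction,
                                  substrate_weights =
                                    unlist(sc$substrate_weights),
                                  min_patch_run_m = sc$min_patch_run_m)
    optics <- optics_params(attenuation = sc$attenuation,
                            water_signal = sc$water_signal,
                            texture_sd = sc$texture_sd,
                            sensor_noise_sd = sc$sensor_noise_sd)
    ortho <- render_orthomosaic(truth, optics, seed = sd + 1L)
    dsm <- generate_dsm(truth, sc$dsm_noise_sd, seed = sd + 2L)
    profiles <- default_profiles(config$community$concentration,
                                 config$community$nonliving_range)
    quad <- generate_quadrat_points(profiles,
                                    design = unlist(config$community$design),
                                    quadrats_per_sample =
                                      config$community$quadrats_per_sample,
                                    points_per_quadrat =
                                      config$community$points_per_quadrat,
                                    catalog = catalog, seed = sd + 3L)
    trans <- generate_transect_records(truth, profiles,
                                       n_transects = config$biotope$n_transects,
                                       points_per_transect =
                                         config$biotope$points_per_transect,
                                       seed = sd + 4L)
    outs <- c(ortho = "ortho.json", dsm = "dsm.json",
              depth_truth = "truth_depth.json",
              substrate_truth = "truth_substrate.json",
              biotope_truth = "truth_biotope.json",
              quadrat_points = "quadrat_points.csv",
              sample_metadata = "sample_metadata.csv",
              transects = "transects.csv")
    save_raster(ortho, file.path(out_dir, "ortho"))
    save_raster(dsm, file.path(out_dir, "dsm"))
    save_raster(truth$depth, file.path(out_dir, "truth_depth"))
    save_raster(truth$substrate, file.path(out_dir, "truth_substrate"),
                legend = truth$substrate_legend)
    save_raster(truth$biotope, file.path(out_dir, "truth_biotope"),
                legend = truth$biotope_legend)
    utils::write.csv(quad$points, file.path(out_dir, "quadrat_points.csv"),
                     row.names = FALSE)
    utils::write.csv(quad$metadata,
                     file.path(out_dir, "sample_metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(trans, file.path(out_dir, "transects.csv"),
                     row.names = FALSE)
    st$truth <- truth; st$ortho <- ortho; st$dsm <- dsm
    st$quadrats <- quad; st$transects <- trans
    st$profiles <- profiles; st$catalog <- catalog; st$binning <- binning
    log_info("simulate: %d x %d px scene, %d quadrat points, %d transects",
             sc$shape[1], sc$shape[2], nrow(quad$points),
             length(unique(trans$transect_id)))
    record("simulate", sd, as.list(outs))
  }

  if ("map-physiography" %in% stages) {
    if (is.null(st$ortho)) stop("map-physiography needs the simulate stage ",
                                "outputs (or user-supplied ortho/dsm)")
    sd <- stage_seed(config$seed, "map-physiography")
    binning <- depth_binning(config$obia$edges)
    sp <- segmentation_params(config$segmentation$scale,
                              config$segmentation$shape_weight,
                              config$segmentation$compactness_weight)
    dcm <- estimate_depth_class_map(st$ortho, st$dsm,
                                    seg_params = sp, binning = binning,
                                    kparams = knn_params(config$obia$k),
                                    quality_quantile =
                                      config$obia$quality_quantile,
                                    smooth_factor = config$obia$smooth_factor,
                                    presmooth_px = config$obia$presmooth_px,
                                    index_scaling = config$obia$index_scaling)
    log_info("map-physiography: %d segments, %d depth classes present",
             nrow(attr(dcm, "segmap")$features),
             length(unique(stats::na.omit(as.vector(rg_band(dcm))))))
    training <- sample_substrate_training(st$truth, dcm,
                                          n_per_class =
                                            config$obia$training_points_per_class,
                                          seed = sd)
    physio <- classify_substrate_map(st$ortho, st$dsm, dcm, training,
                                     seg_params = sp,
                                     smooth_factor = config$obia$smooth_factor,
                                     presmooth_px = config$obia$presmooth_px,
                                     index_scaling = config$obia$index_scaling)
    save_raster(dcm, file.path(out_dir, "depth_class"),
                legend = attr(dcm, "legend"))
    save_raster(physio$substrate, file.path(out_dir, "substrate"),
                legend = physio$substrate_legend)
    write_polygons_geojson(labels_to_polygons(physio$substrate,
                                              physio$substrate_legend),
                           file.path(out_dir, "substrate.geojson"))
    st$depth_class <- dcm; st$physio <- physio
    record("map-physiography", sd,
           list(depth_class = "depth_class.json",
                substrate = "substrate.json",
                substrate_polygons = "substrate.geojson"),
           inputs = c("ortho.json", "dsm.json"))
  }

  if ("analyze-community" %in% stages) {
    if (is.null(st$quadrats)) stop("analyze-community needs the simulate ",
                                   "stage outputs (quadrat points)")
    sd <- stage_seed(config$seed, "analyze-community")
    qp <- st$quadrats
    cm_s_raw <- percent_cover_from_points(qp$points, "sample_id")
    cm_s <- prepare_community_matrix(cm_s_raw)
    cm_s_sq <- transform_sqrt(cm_s)
    grouping <- cluster_simprof(cm_s_sq, n_perm = config$community$n_perm,
                                alpha = config$community$alpha, seed = sd)
    log_info("analyze-community: SIMPROF found %d groups over %d samples",
             length(unique(grouping$groups)), nrow(cm_s_sq$cover))
    simp <- simper(cm_s_sq, grouping, raw = cm_s)
    # quadrat-level check of the sample-derived grouping
    cm_q_raw <- percent_cover_from_points(qp$points, "quadrat_id")
    cm_q <- transform_sqrt(prepare_community_matrix(cm_q_raw))
    qsample <- sub("_Q\\d+$", "", rownames(cm_q$cover))
    qgroups <- setNames(unname(grouping$groups[qsample]),
                        rownames(cm_q$cover))
    sim_q <- bray_curtis(cm_q)
    anosim_q <- anosim(sim_q, qgroups, n_perm = config$community$n_perm,
                       seed = sd + 1L)
    ord <- nmds(bray_curtis(cm_s_sq), n_dim = 2, seed = sd + 2L)
    md <- qp$metadata
    preds_s <- data.frame(depth = factor(md$depth_class[match(
      rownames(cm_s_sq$cover), md$sample_id)]),
      substrate = factor(md$substrate[match(rownames(cm_s_sq$cover),
                                            md$sample_id)]))
    dlm_s <- distlm_dbrda(bray_curtis(cm_s_sq), preds_s,
                          n_perm = config$community$n_perm, seed = sd + 3L)
    preds_q <- data.frame(depth = factor(md$depth_class[match(
      qsample, md$sample_id)]),
      substrate = factor(md$substrate[match(qsample, md$sample_id)]))
    dlm_q <- distlm_dbrda(sim_q, preds_q,
                          n_perm = config$community$n_perm, seed = sd + 4L)
    cap_q <- cap_analysis(sim_q, qgroups, predictors = preds_q,
                          seed = sd + 5L)
    utils::write.csv(data.frame(unit = names(grouping$groups),
                                group = unname(grouping$groups)),
                     file.path(out_dir, "grouping.csv"), row.names = FALSE)
    simper_tab <- do.call(rbind, lapply(names(simp$within), function(gn)
      cbind(assemblage = gn, simp$within[[gn]])))
    utils::write.csv(simper_tab, file.path(out_dir, "simper.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(unit = rownames(ord$points), ord$points,
                                stress = ord$stress),
                     file.path(out_dir, "nmds.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      anosim_quadrats = list(R = anosim_q$statistic, p = anosim_q$p_value,
                             n_perm = anosim_q$n_permutations),
      distlm_samples = list(r2 = dlm_s$r2, pseudo_F = dlm_s$pseudo_F,
                            p = dlm_s$p_value,
                            best_subset = dlm_s$best_subset),
      distlm_quadrats = list(r2 = dlm_q$r2, pseudo_F = dlm_q$pseudo_F,
                             p = dlm_q$p_value),
      cap = list(m = cap_q$m,
                 allocation_success = cap_q$allocation_success)),
      file.path(out_dir, "community_tests.json"), auto_unbox = TRUE,
      digits = NA)
    st$cm_sample <- cm_s; st$cm_sample_sqrt <- cm_s_sq
    st$cm_quadrat <- cm_q; st$grouping <- grouping; st$simper <- simp
    st$anosim_quadrats <- anosim_q; st$nmds <- ord
    st$distlm_samples <- dlm_s; st$distlm_quadrats <- dlm_q
    st$cap <- cap_q
    record("analyze-community", sd,
           list(grouping = "grouping.csv", simper = "simper.csv",
                nmds = "nmds.csv", tests = "community_tests.json"),
           inputs = c("quadrat_points.csv", "sample_metadata.csv"))
  }

  if ("map-biotopes" %in% stages) {
    if (is.null(st$grouping) || is.null(st$physio))
      stop("map-biotopes needs analyze-community (grouping) and ",
           "map-physiography (physiographic map) outputs")
    sd <- stage_seed(config$seed, "map-biotopes")
    cat_rec <- derive_biotope_catalog(st$grouping, st$quadrats$metadata,
                                      force_majority =
                                        config$biotope$force_majority)
    biomap <- extrapolate_biotope_map(st$physio, cat_rec)
    save_raster(biomap$raster, file.path(out_dir, "biotope"),
                legend = biomap$legend)
    write_polygons_geojson(labels_to_polygons(biomap$raster, biomap$legend),
                           file.path(out_dir, "biotope.geojson"))
    utils::write.csv(biomap$areas, file.path(out_dir, "biotope_areas.csv"),
                     row.names = FALSE)
    st$catalog_recovered <- cat_rec; st$biomap <- biomap
    log_info("map-biotopes: %d biotopes, %.2f ha assigned",
             nrow(biomap$areas), attr(biomap$areas, "assigned_m2") / 1e4)
    record("map-biotopes", sd,
           list(biotope = "biotope.json",
                biotope_polygons = "biotope.geojson",
                areas = "biotope_areas.csv"),
           inputs = c("grouping.csv", "depth_class.json", "substrate.json"))
  }

  if ("validate" %in% stages) {
    if (is.null(st$biomap) || is.null(st$transects))
      stop("validate needs map-biotopes output and transect records")
    sd <- stage_seed(config$seed, "validate")
    val <- validate_with_transects(st$transects, st$biomap,
                                   n_perm = config$community$n_perm,
                                   seed = sd)
    jsonlite::write_json(list(R = val$test$statistic,
                              p = val$test$p_value,
                              n_perm = val$test$n_permutations,
                              predicted = as.list(val$predicted)),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    st$validation <- val
    log_info("validate: ANOSIM R = %.3f, p = %.4g", val$test$statistic,
             val$test$p_value)
    record("validate", sd, list(validation = "validation.json"),
           inputs = c("transects.csv", "biotope.json"))
  }

  st$manifest <- manifest
  st$out_dir <- out_dir
  invisible(st)
}
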