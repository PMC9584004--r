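#' Candidate hearth detection on a terrain model
#'
#' The detection chain in one call: Horn slope, grayscale closing with a
#' disc element, seed selection on the closed slope, seeded region
#' growing, zonal statistics over terrain layers and per-object shape
#' metrics.
#'
#' @param dem A [dem_grid()] of elevations.
#' @param disc_diameter_px Structuring element diameter (default 7 px).
#' @param min_seed_distance_m,flatness_quantile Passed to [select_seeds()]
#'   (defaults 10 m and 0.10, calibrated on the synthetic suite so the
#'   default scenario segments into roughly the intended object mix).
#' @param similarity_threshold Region-growing threshold in degrees of
#'   closed slope (default 5).
#' @param max_area_m2 Region area cap (default 340).
#' @param extra_layers Optional [covariate_stack()] of additional layers to
#'   summarise per object.
#' @return A list: `slope`, `closed`, `seeds`, `labels`, `features`
#'   (zonal statistics joined with shape metrics), `shapes`.
#' @export
detect_candidates <- function(dem, disc_diameter_px = 7,
                              min_seed_distance_m = 10,
                              flatness_quantile = 0.10,
                              similarity_threshold = 5,
                              max_area_m2 = 340,
                              extra_layers = NULL) {
  slope <- terrain_slope(dem)
  closed <- grayscale_closing(slope, disc_element(disc_diameter_px))
  closed$layer <- "closed_slope"
  seeds <- select_seeds(closed, min_seed_distance_m, flatness_quantile)
  labels <- compact_labels(
    region_growing(closed, seeds, similarity_threshold, max_area_m2)
  )
  layers <- list(elevation = dem, slope = slope, closed_slope = closed,
                 tri = terrain_tri(dem))
  if (!is.null(extra_layers)) layers <- c(layers, extra_layers)
  stack <- covariate_stack(layers)
  zonal <- zonal_summaries(labels, stack)
  shapes <- shape_metrics(labels)
  features <- dplyr::inner_join(
    shapes, zonal, by = c("label", "n_cells")
  )
  list(slope = slope, closed = closed, seeds = seeds, labels = labels,
       features = features, shapes = shapes)
}

#' Label segmented objects against generator ground truth
#'
#' An object is a hearth when more than `min_overlap` of its pixels fall
#' inside any true platform footprint.
#'
#' @param labels Label [dem_grid()].
#' @param truth Truth tibble from [generate_dtm()].
#' @param min_overlap Pixel fraction required (default 0.5).
#' @return Tibble with `label`, `overlap_fraction`, `class`
#'   (factor rch/non_rch).
#' @export
truth_labels_for_objects <- function(labels, truth, min_overlap = 0.5) {
  v <- labels$values
  v[is.na(v)] <- 0
  tm <- matrix(FALSE, nrow(v), ncol(v))
  for (fp in truth$footprint) tm[fp] <- TRUE
  ids <- sort(unique(as.vector(v)))
  ids <- ids[ids > 0]
  tot <- tabulate(v, nbins = max(ids))
  hit <- tabulate(v[tm], nbins = max(ids))
  frac <- hit[ids] / tot[ids]
  tibble::tibble(
    label = ids,
    overlap_fraction = frac,
    class = factor(ifelse(frac > min_overlap, "rch", "non_rch"),
                   levels = c("rch", "non_rch"))
  )
}

#' Default pipeline configuration
#'
#' Every stage parameter of [run_pipeline()] with its default; the single
#' `seed` feeds per-stage derived seeds so a run is reproducible end to
#' end.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for the run.
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 42, out_dir = "charcoalscape-run") {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, detect = TRUE, classify = TRUE,
                  summarise = TRUE, composition = TRUE, ordinate = TRUE),
    scenario = list(extent_m = c(600, 600), cell_size_m = 0.5,
                    base_slope_deg = 25, relief_amplitude_m = 0.35,
                    noise_bandwidth_m = 4, n_platforms = 212,
                    platform_area_range_m2 = c(20, 170),
                    lip_width_range_m = c(1, 2), n_confusers = 453),
    detect = list(disc_diameter_px = 7, min_seed_distance_m = 10,
                  flatness_quantile = 0.10, similarity_threshold = 5,
                  max_area_m2 = 340),
    classify = list(n_trees = 500, k_folds = 5, min_overlap = 0.5),
    composition = list(cell_m = 10, power = 2, n_neighbours = 50,
                       frags_per_rch = c(2, 6)),
    ordinate = list(n_plots = 267, n_perm = 999)
  ), class = "pipeline_config")
}

config_keys <- function() {
  names(default_pipeline_config())
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown top-level keys are rejected; missing keys fall back to the
#' defaults, so a config file only needs the values it changes.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  merge_list <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_list(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  out <- merge_list(unclass(base), raw)
  structure(out, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic detection-to-ordination pipeline
#'
#' Executes the toggled stages in order — simulate, detect (slope, close,
#' segment, features), classify, summarise, composition, ordinate — and
#' writes every artefact plus a manifest (package version, configuration
#' hash, seed) and a log under the run directory. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [default_pipeline_config()] (possibly modified) or a
#'   path to a YAML config.
#' @return Invisibly, a list with the run directory and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  results <- list()
  out <- function(...) file.path(config$out_dir, ...)

  if (!isTRUE(config$stages$simulate)) {
    stop("this pipeline runs on simulated input; enable the simulate stage",
         call. = FALSE)
  }
  note("simulate: %d platforms, %d confusers, seed %d",
       config$scenario$n_platforms, config$scenario$n_confusers, config$seed)
  sc <- do.call(terrain_scenario, c(config$scenario, list(seed = config$seed)))
  sim <- generate_dtm(sc)
  results$sim <- sim
  write_esri_ascii(sim$dem, out("dtm.asc"))
  utils::write.csv(sim$truth[setdiff(names(sim$truth), "footprint")],
                   out("truth.csv"), row.names = FALSE)

  if (isTRUE(config$stages$detect)) {
    note("detect: disc %d px, threshold %.2f deg",
         config$detect$disc_diameter_px, config$detect$similarity_threshold)
    det <- do.call(detect_candidates, c(list(sim$dem), config$detect))
    results$det <- det
    write_esri_ascii(det$closed, out("closed_slope.asc"))
    utils::write.csv(det$features, out("objects.csv"), row.names = FALSE)
    note("detect: %d seeds, %d objects", nrow(det$seeds), nrow(det$features))
  }

  if (isTRUE(config$stages$classify)) {
    det <- results$det
    lab <- truth_labels_for_objects(det$labels, sim$truth,
                                    config$classify$min_overlap)
    feats <- dplyr::select(det$features, -"label", -"centroid_x", -"centroid_y")
    cv <- cross_validate(feats, lab$class, k = config$classify$k_folds,
                         n_trees = config$classify$n_trees,
                         seed = config$seed + 1)
    model <- train_classifier(feats, lab$class,
                              n_trees = config$classify$n_trees,
                              seed = config$seed + 2)
    pred <- predict(model, feats)
    detections <- dplyr::bind_cols(det$shapes, pred)
    results$cv <- cv
    results$detections <- detections
    jsonlite::write_json(
      list(overall_accuracy = cv$means$overall, kappa = cv$means$kappa,
           users = as.list(cv$means$users),
           producers = as.list(cv$means$producers),
           pooled_confusion = cv$pooled$confusion),
      out("accuracy.json"), auto_unbox = TRUE, digits = NA
    )
    hearths <- detections[detections$.pred_class == "rch", ]
    write_geojson_points(
      dplyr::transmute(hearths, x = .data$centroid_x, y = .data$centroid_y,
                       label = .data$label, area_m2 = .data$area_m2,
                       prob = .data$.prob_rch),
      out("detections.geojson")
    )
    note("classify: mean OA %.3f, kappa %.3f, %d predicted hearths",
         cv$means$overall, cv$means$kappa, nrow(hearths))
  }

  if (isTRUE(config$stages$summarise)) {
    det <- results$det
    hearths <- results$detections
    hearths <- hearths[hearths$.pred_class == "rch", ]
    inv <- rch_inventory(hearths, sim$dem, det$slope)
    geom <- geometry_report(inv)
    area_ha <- prod(config$scenario$extent_m) / 1e4
    dens <- rch_density(nrow(inv), area_ha)
    results$inventory <- inv
    results$geometry <- geom
    utils::write.csv(inv, out("inventory.csv"), row.names = FALSE)
    utils::write.csv(geom$summary, out("geometry_summary.csv"), row.names = FALSE)
    utils::write.csv(geom$correlations, out("geometry_correlations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(dens, out("density.json"), auto_unbox = TRUE, digits = NA)
    note("summarise: %d hearths, density %.3f per ha", nrow(inv),
         dens$density_per_ha)
  }

  if (isTRUE(config$stages$composition)) {
    cfgc <- config$composition
    charcoal <- generate_charcoal_samples(
      sim$truth, frags_per_rch = cfgc$frags_per_rch, seed = config$seed + 3
    )
    hist_prop <- to_proportions(charcoal)
    utils::write.csv(hist_prop, out("historical_proportions.csv"),
                     row.names = FALSE)
    taxa <- names(default_taxon_probs())
    grid <- idw_grid_for(hist_prop, cfgc$cell_m)
    hist_surf <- interpolate_composition(hist_prop, taxa, grid = grid,
                                         power = cfgc$power,
                                         n_neighbours = cfgc$n_neighbours)
    acc <- dplyr::bind_rows(lapply(taxa, function(t) {
      dplyr::mutate(
        idw_accuracy(hist_prop, t, cfgc$power, cfgc$n_neighbours),
        taxon = t, era = "historical", .before = 1
      )
    }))
    results$idw_accuracy <- acc
    utils::write.csv(acc, out("idw_accuracy.csv"), row.names = FALSE)
    for (t in taxa) {
      write_esri_ascii(hist_surf[[t]], out(sprintf("%s_historical.asc", t)))
    }
    results$hist_surfaces <- hist_surf
    note("composition: %d hearth samples interpolated over %d x %d cells",
         nrow(hist_prop), nrow(grid$values), ncol(grid$values))
  }

  if (isTRUE(config$stages$ordinate)) {
    cfgo <- config$ordinate
    fp <- generate_forest_plots(cfgo$n_plots, seed = config$seed + 4)
    Y <- as.matrix(fp$plots[table1_response_names()])
    X <- as.matrix(fp$env[table1_env_names()])
    fit <- rda_permutation_test(Y, X, n_perm = cfgo$n_perm,
                                seed = config$seed + 5)
    results$rda <- fit
    utils::write.csv(tidy(fit), out("rda_axes.csv"), row.names = FALSE)
    utils::write.csv(
      cbind(variable = rownames(fit$biplot_scores),
            as.data.frame(fit$biplot_scores)),
      out("rda_biplot_scores.csv"), row.names = FALSE
    )
    utils::write.csv(
      cbind(variable = rownames(fit$response_scores),
            as.data.frame(fit$response_scores)),
      out("rda_response_scores.csv"), row.names = FALSE
    )
    jsonlite::write_json(as.list(glance(fit)), out("rda_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note("ordinate: axis1 %.1f%%, axis2 %.1f%%, p = %.4g",
         fit$proportion_pct[1], fit$proportion_pct[2], fit$p_value)
  }

  manifest <- list(
    package = "charcoalscape",
    version = as.character(utils::packageVersion("charcoalscape")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = config$stages
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(out_dir = config$out_dir, results = results))
}
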