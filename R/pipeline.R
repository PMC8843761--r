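#' Full-analysis run configuration
#'
#' Bundles every stage parameter with its conventional default: 1,200 m
#' occurrence thinning radius; pseudo-absences outside a 3,000 m presence
#' buffer, below 4,000 m elevation and 50 degree slope, spaced 1,200 m, in
#' ten sets; six candidate scales (1-6 km); 500-tree forests; 0.85
#' collinearity cutoff; 0.1 MIR increments; 70/30 split AUC with ten
#' repetitions; resistant-kernel thresholds 6,000 / 12,000 / 20,000 cost
#' units; 50,000 cost-unit cap for factorial least-cost paths; 5% core
#' cutoff. The serialized configuration plus the package version fully
#' determine every output.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param landscape a [landscape_config()] (defaults to one built on
#'   `seed`).
#' @param model generative [true_suitability_model()].
#' @param variables covariate vocabulary for the stack and model.
#' @param scales candidate scales (m).
#' @param thin_radius thinning radius (m).
#' @param constraints an [absence_constraints()].
#' @param num_trees,cor_threshold,mir_step forest and selection settings.
#' @param auc_split,auc_reps evaluation settings.
#' @param kernel_thresholds,lcp_max,lcp_bandwidth,core_fraction
#'   connectivity settings.
#' @param lcp_sources maximum number of (thinned) occurrences used as
#'   factorial-LCP sources; the first `lcp_sources` thinned points are
#'   used when the thinned set is larger.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            landscape = landscape_config(seed = seed),
                            model = default_suitability_model(),
                            variables = c(SCALABLE_VARS, DISTANCE_VARS),
                            scales = seq(1000, 6000, by = 1000),
                            thin_radius = 1200,
                            constraints = absence_constraints(),
                            num_trees = 500,
                            cor_threshold = 0.85,
                            mir_step = 0.1,
                            auc_split = 0.7,
                            auc_reps = 10,
                            kernel_thresholds = c(6000, 12000, 20000),
                            lcp_max = 50000,
                            lcp_bandwidth = 2,
                            core_fraction = 0.05,
                            lcp_sources = 80) {
  stopifnot(thin_radius > 0, num_trees > 0, cor_threshold > 0,
            auc_split > 0, auc_split < 1, all(kernel_thresholds > 0),
            lcp_max > 0, core_fraction > 0, core_fraction < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

content_checksum <- function(v) {
  v <- as.vector(v)
  ok <- !is.na(v)
  sprintf("n=%d;na=%d;s=%.12e;s2=%.12e", length(v), sum(!ok),
          sum(v[ok]), sum(v[ok]^2))
}

#' Run the complete analysis pipeline
#'
#' simulate -> prep -> covariates -> model -> resistance -> connect ->
#' report, writing every artifact (ESRI ASCII rasters, CSVs, GeoJSON) and
#' a JSON manifest of parameters, seeds, stage summaries and content
#' checksums to `out_dir`. Identical configurations produce identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param quiet suppress progress messages?
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  say("stage simulate: %dx%d cells, seed %d", config$landscape$nrow,
      config$landscape$ncol, config$landscape$seed)
  ls <- synthetic_landscape(config$landscape, config$model)

  say("stage prep: thinning %d occurrences at %g m", nrow(ls$occurrences),
      config$thin_radius)
  thinned <- thin_occurrences(ls$occurrences, config$thin_radius)
  td <- terrain_derivatives(ls$terrain)
  absences <- generate_pseudo_absences(
    thinned, config$constraints, ls$terrain, td$slope,
    seed = config$seed + 100L)
  say("  retained %d presences; %d pseudo-absence sets of %d",
      nrow(thinned), length(absences), nrow(absences[[1]]))

  say("stage covariates: %d variables x %d scales",
      length(config$variables), length(config$scales))
  base <- list(elevation = ls$terrain, npp = ls$npp, bamboo = ls$bamboo,
               landcover = ls$landcover, villages = ls$features$villages,
               roads_major = ls$features$roads[ls$features$road_class == "major"],
               roads_minor = ls$features$roads[ls$features$road_class == "minor"])
  stack <- build_multiscale_stack(base, config$scales, config$variables)

  say("stage model: univariate scale optimization")
  datasets <- make_model_datasets(thinned, absences, stack)
  scalable <- intersect(config$variables, SCALABLE_VARS)
  profile <- univariate_scale_selection(datasets, scalable, config$scales,
                                        config$num_trees,
                                        seed = config$seed + 200L)
  chosen_layers <- paste0(scalable, "_", profile$chosen[scalable])
  # mean univariate OOB at the chosen scale, used to order collinear drops
  prio <- stats::setNames(
    vapply(seq_along(scalable), function(i)
      mean(profile$oob[i, match(profile$chosen[i], profile$scales), ]), 0),
    chosen_layers)
  cand <- c(chosen_layers, intersect(config$variables, DISTANCE_VARS))
  screen <- collinearity_screen(stack, cand, config$cor_threshold,
                                priority = prio)
  say("  screened out %d collinear layer(s)", nrow(screen$removed))
  ensemble <- fit_rf_ensemble(datasets, screen$retained, config$num_trees,
                              seed = config$seed + 300L,
                              step = config$mir_step)
  hs <- ensemble_predict(ensemble, stack)
  auc <- evaluate_auc(ensemble, config$auc_split, config$auc_reps,
                      seed = config$seed + 400L, config$num_trees)
  say("  mean AUC %.3f (sd %.3f)", auc$mean, auc$sd)

  say("stage resistance")
  res <- suitability_to_resistance(hs)

  say("stage connect: kernels at {%s} cost units",
      paste(config$kernel_thresholds, collapse = ", "))
  cg <- cost_graph(res)
  kernels <- lapply(config$kernel_thresholds, function(thr)
    resistant_kernel(cg, thinned, thr))
  names(kernels) <- config$kernel_thresholds
  lcp_src <- thinned[seq_len(min(nrow(thinned), config$lcp_sources)), ]
  corridors <- factorial_lcp_density(cg, lcp_src, config$lcp_max,
                                     config$lcp_bandwidth)

  say("stage report: core extraction at %g of kernel max",
      config$core_fraction)
  cores <- lapply(kernels, extract_core_patches,
                  fraction = config$core_fraction)
  report <- protection_report(cores, corridors,
                              ls$features$protected_areas)

  manifest <- list(
    seed = config$seed,
    parameters = list(
      thin_radius = config$thin_radius,
      exclusion_radius = config$constraints$exclusion_radius,
      max_elevation = config$constraints$max_elevation,
      max_slope = config$constraints$max_slope,
      min_spacing = config$constraints$min_spacing,
      n_sets = config$constraints$n_sets,
      scales = config$scales, num_trees = config$num_trees,
      cor_threshold = config$cor_threshold, mir_step = config$mir_step,
      auc_split = config$auc_split, auc_reps = config$auc_reps,
      kernel_thresholds = config$kernel_thresholds,
      lcp_max = config$lcp_max, lcp_bandwidth = config$lcp_bandwidth,
      core_fraction = config$core_fraction),
    n_occurrences = nrow(ls$occurrences),
    n_thinned = nrow(thinned),
    chosen_scales = as.list(profile$chosen),
    screened_out = screen$removed$removed,
    model_oob = vapply(ensemble$models, `[[`, 0, "oob"),
    auc_mean = auc$mean, auc_sd = auc$sd,
    core_extent_km2 = stats::setNames(
      vapply(cores, `[[`, 0, "total_km2"), names(cores)),
    corridor_extent_km2 = corridor_extent(corridors),
    report = report,
    checksums = list(
      terrain = content_checksum(ls$terrain$values),
      suitability = content_checksum(hs$values),
      resistance = content_checksum(res$values),
      corridors = content_checksum(corridors$values),
      kernels = lapply(kernels, function(k) content_checksum(k$values))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(out_dir)) {
    write_ascii_grid(ls$terrain, file.path(out_dir, "terrain.asc"))
    write_ascii_grid(ls$suitability, file.path(out_dir, "suitability_true.asc"))
    write_occurrences(ls$occurrences, file.path(out_dir, "occurrences.csv"))
    write_occurrences(thinned, file.path(out_dir, "occurrences_thinned.csv"))
    write_occurrences(do.call(rbind, absences),
                      file.path(out_dir, "pseudo_absences.csv"))
    write_features_geojson(ls$features, file.path(out_dir, "features.geojson"))
    write_stack(stack, file.path(out_dir, "stack"))
    write_ascii_grid(hs, file.path(out_dir, "habitat_suitability.asc"))
    write_ascii_grid(res, file.path(out_dir, "resistance.asc"))
    for (nm in names(kernels)) {
      write_ascii_grid(kernels[[nm]],
                       file.path(out_dir, paste0("kernel_", nm, ".asc")))
      write_ascii_grid(cores[[nm]]$labels,
                       file.path(out_dir, paste0("core_patches_", nm, ".asc")))
    }
    write_ascii_grid(corridors, file.path(out_dir, "corridor_density.asc"))
    utils::write.csv(report, file.path(out_dir, "protection_report.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(variable = profile$variables, chosen = profile$chosen,
                 frequency = profile$frequency),
      file.path(out_dir, "scale_profile.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"),
               file.path(out_dir, "manifest.json"))
  }
  say("pipeline complete in %.1f s", manifest$elapsed_s)
  invisible(manifest)
}
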