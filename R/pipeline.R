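# End-to-end orchestration: synth -> hydro -> plume -> coral -> prioritize
# (baseline and cyclone-risk scenarios) -> report, with YAML configuration,
# per-stage seeds derived from one base seed, and a checksum manifest.

#' Default pipeline configuration
#'
#' Stage seeds are derived from `seed` by fixed offsets (landscape +0,
#' surveys +1, posterior draws +2, annealing base +3), so one integer
#' reproduces the whole run.
#'
#' @param seed base integer seed.
#' @param landscape a [landscape_config()].
#' @param musle a [musle_params()].
#' @param dispersion a [dispersion_params()].
#' @param coral list: `k`, `method`, `n_draws`, `threshold`, plus survey
#'   design `n_sites`, `transects`, `points_per_transect`.
#' @param targets named feature target fractions.
#' @param certainty required coral certainty in the cyclone scenario.
#' @param anneal an [anneal_config()].
#' @param cost_radius_cells kernel radius of the fisher cost surface (cells).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            landscape = landscape_config(),
                            musle = musle_params(),
                            dispersion = dispersion_params(),
                            coral = list(k = 10, method = "REML",
                                         n_draws = 1000, threshold = 0.30,
                                         n_sites = 72, transects = 3,
                                         points_per_transect = 100),
                            targets = c(coral = 0.3, mangrove = 0.3,
                                        seagrass = 0.3, turtle_grounds = 0.1),
                            certainty = 0.9,
                            anneal = anneal_config(),
                            cost_radius_cells = 10) {
  structure(list(seed = as.integer(seed), landscape = landscape,
                 musle = musle, dispersion = dispersion, coral = coral,
                 targets = targets, certainty = certainty, anneal = anneal,
                 cost_radius_cells = cost_radius_cells),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any key omitted from the file keeps its default. The file must contain a
#' `seed` key. Nested blocks `landscape`, `musle`, `dispersion`, `coral`,
#' `anneal` override the corresponding constructor arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must contain a `seed` key")
  cfg <- pipeline_config(seed = y$seed)
  if (!is.null(y$landscape))
    cfg$landscape <- do.call(landscape_config, y$landscape)
  if (!is.null(y$musle)) cfg$musle <- do.call(musle_params, y$musle)
  if (!is.null(y$dispersion))
    cfg$dispersion <- do.call(dispersion_params, y$dispersion)
  if (!is.null(y$coral)) cfg$coral[names(y$coral)] <- y$coral
  if (!is.null(y$targets)) cfg$targets[names(y$targets)] <- unlist(y$targets)
  if (!is.null(y$certainty)) cfg$certainty <- y$certainty
  if (!is.null(y$anneal)) cfg$anneal <- do.call(anneal_config, y$anneal)
  if (!is.null(y$cost_radius_cells))
    cfg$cost_radius_cells <- y$cost_radius_cells
  cfg
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full land-sea prioritization pipeline
#'
#' Generates the synthetic world, runs hydrology, plume dispersion, the
#' coral condition model, solves the baseline (deterministic targets) and
#' cyclone-risk (coral certainty-constrained) scenarios, and writes all
#' artifacts plus a manifest of MD5 checksums under `out_dir`. Re-running
#' with an unchanged config reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; may be NULL to skip writing).
#' @return invisible list with all stage objects (`bundle`, `hydro`, `tss`,
#'   `coral`, `problems`, `ensembles`, `comparison`, `manifest_path`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t_start <- Sys.time()
  say <- function(stage, fmt, ...)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...)))
  wants_files <- !is.null(out_dir)
  if (wants_files) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- synth ---
  say("synth", "generating landscape (seed %d)", config$seed)
  bundle <- generate_landscape(config$landscape, seed = config$seed)
  validate_bundle(bundle)
  cost_grid <- kernel_density_cost(
    bundle$population_points, bundle$dem,
    radius_m = config$cost_radius_cells * bundle$dem$cell_size)

  # --- hydro ---
  say("hydro", "MUSLE a=%.3g b=%.3g, storm %gh", config$musle$a,
      config$musle$b, config$musle$storm_duration_h)
  hy <- run_hydrology(bundle, config$musle)
  say("hydro", "%d pour points, total load %.4g", nrow(hy$pour_points),
      sum(hy$pour_points$load))

  # --- plume ---
  say("plume", "alpha=%.3g, metric=%s", config$dispersion$alpha,
      config$dispersion$distance_metric)
  tss <- run_plume(hy$pour_points, bundle, config$dispersion)

  # --- coral ---
  surveys <- generate_surveys(
    tss, bundle$feature_grids$coral, bundle$truth,
    n_sites = config$coral$n_sites, transects = config$coral$transects,
    points_per_transect = config$coral$points_per_transect,
    seed = config$seed + 1L)
  cr <- run_coral(surveys, tss, bundle$feature_grids$coral,
                  k = config$coral$k, method = config$coral$method,
                  n_draws = config$coral$n_draws, seed = config$seed + 2L,
                  threshold = config$coral$threshold)
  say("coral", "deviance explained %.1f%%, dispersion ratio %.2f (%s)",
      100 * cr$model$deviance_explained, cr$overdispersion$ratio,
      cr$overdispersion$verdict)

  # --- prioritize, both scenarios ---
  ac <- config$anneal
  ac$base_seed <- config$seed + 3L
  prob_base <- build_problem(bundle, cost_grid, condition = NULL,
                             target_fractions = config$targets)
  prob_cyc <- build_problem(bundle, cost_grid, condition = cr$surface,
                            target_fractions = config$targets,
                            certainty = config$certainty)
  say("prioritize", "baseline: %d units, %d features, %d runs x %d iters",
      length(prob_base$pu_ids), length(prob_base$features), ac$n_solutions,
      ac$n_iterations)
  ens_base <- solve_ensemble(prob_base, ac)
  say("prioritize", "cyclone-risk scenario (coral certainty %.2f)",
      config$certainty)
  ens_cyc <- solve_ensemble(prob_cyc, ac)

  # --- report ---
  area <- cell_area_km2(bundle$dem)
  unit_areas <- rep(area, length(prob_base$pu_ids))
  comparison <- compare_best(ens_base$best$selection, ens_cyc$best$selection,
                             prob_cyc, ac, unit_areas)
  hp_base <- high_priority_area(ens_base$selection_frequency /
                                  ac$n_solutions, 0.8, unit_areas)
  hp_cyc <- high_priority_area(ens_cyc$selection_frequency /
                                 ac$n_solutions, 0.8, unit_areas)
  say("report", "baseline %0.f km2 / cost %.4g; cyclone %0.f km2 / cost %.4g",
      comparison$scenario_a$area_km2, comparison$scenario_a$cost,
      comparison$scenario_b$area_km2, comparison$scenario_b$cost)

  manifest_path <- NULL
  if (wants_files) {
    manifest_path <- .write_artifacts(out_dir, config, bundle, cost_grid, hy,
                                      tss, surveys, cr, prob_base, prob_cyc,
                                      ens_base, ens_cyc, comparison,
                                      hp_base, hp_cyc)
  }
  say("pipeline", "done in %.1f s",
      as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(list(bundle = bundle, cost_grid = cost_grid, hydro = hy,
                 tss = tss, surveys = surveys, coral = cr,
                 problems = list(baseline = prob_base, cyclone = prob_cyc),
                 ensembles = list(baseline = ens_base, cyclone = ens_cyc),
                 comparison = comparison,
                 high_priority = c(baseline = hp_base, cyclone = hp_cyc),
                 manifest_path = manifest_path))
}

.write_artifacts <- function(out_dir, config, bundle, cost_grid, hy, tss,
                             surveys, cr, prob_base, prob_cyc, ens_base,
                             ens_cyc, comparison, hp_base, hp_cyc) {
  p <- function(...) file.path(out_dir, ...)
  write_asc(bundle$dem, p("dem.asc"))
  write_asc(bundle$landcover, p("landcover.asc"))
  write_asc(bundle$k_factor, p("k_factor.asc"))
  write_asc(bundle$curve_number, p("curve_number.asc"))
  write_asc(bundle$storm_precip, p("storm_precip.asc"))
  write_asc(bundle$sea_mask, p("sea_mask.asc"))
  for (nm in names(bundle$feature_grids))
    write_asc(bundle$feature_grids[[nm]], p(sprintf("feature_%s.asc", nm)))
  write.csv(bundle$population_points, p("towns.csv"), row.names = FALSE)
  .write_json(list(
    type = "FeatureCollection",
    features = lapply(seq_len(nrow(bundle$population_points)), function(i)
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(bundle$population_points$x[i],
                                           bundle$population_points$y[i])),
           properties = list(count = bundle$population_points$count[i])))),
    p("towns.geojson"))
  write_asc(cost_grid, p("cost.asc"))
  write_asc(hy$filled, p("dem_filled.asc"))
  write_asc(hy$directions, p("flow_directions.asc"))
  write_asc(hy$yield, p("sediment_yield.asc"))
  write_asc(hy$watersheds$watersheds, p("watersheds.asc"))
  write.csv(hy$pour_points, p("pour_points.csv"), row.names = FALSE)
  write_asc(tss$tss, p("tss.asc"))
  write_asc(tss$log_tss, p("log_tss.asc"))
  write_surveys_csv(surveys, p("surveys.csv"))
  write_asc(cr$surface$prob_good, p("prob_good.asc"))
  .write_json(list(
    coefficients = as.list(cr$model$coefficients),
    smoothing_param = as.list(cr$model$smoothing_param),
    site_effect_sd = cr$model$site_effect_sd,
    deviance_explained = cr$model$deviance_explained,
    overdispersion_ratio = cr$overdispersion$ratio,
    overdispersion_verdict = cr$overdispersion$verdict,
    threshold = cr$surface$threshold, n_draws = cr$surface$n_draws),
    p("condition_model.json"))
  for (sc in c("baseline", "cyclone")) {
    ens <- if (sc == "baseline") ens_base else ens_cyc
    prob <- if (sc == "baseline") prob_base else prob_cyc
    write.csv(data.frame(pu_id = prob$pu_ids,
                         best = as.integer(ens$best$selection),
                         frequency = ens$selection_frequency),
              p(sprintf("%s_solution.csv", sc)), row.names = FALSE)
    write_asc(rasterize_solution(prob, as.numeric(ens$best$selection)),
              p(sprintf("%s_best.asc", sc)))
    write_asc(rasterize_solution(prob, ens$selection_frequency /
                                   ens$n_solutions),
              p(sprintf("%s_frequency.asc", sc)))
  }
  .write_json(list(
    baseline = comparison$scenario_a[c("area_km2", "cost")],
    cyclone = comparison$scenario_b[c("area_km2", "cost")],
    baseline_held = as.list(comparison$scenario_a$held),
    cyclone_held = as.list(comparison$scenario_b$held),
    baseline_target_met = as.list(comparison$scenario_a$target_met),
    cyclone_target_met = as.list(comparison$scenario_b$target_met),
    overlap_cyclone_in_baseline = comparison$overlap_a_in_b,
    overlap_baseline_in_cyclone = comparison$overlap_b_in_a,
    area_difference_pct_region = comparison$area_difference_pct_region,
    high_priority_km2 = list(baseline = hp_base, cyclone = hp_cyc)),
    p("comparison.json"))

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    stages = c("synth", "hydro", "plume", "coral", "prioritize", "report"),
    checksums = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  file.path(out_dir, "manifest.json")
}
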