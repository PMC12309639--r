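# Scenario comparison: areas, costs, representation, overlap and
# high-priority (selection-frequency) summaries between the baseline and
# probability-constrained reserve designs.

#' Compare two best solutions
#'
#' @param solution_a,solution_b logical selection vectors on the same
#'   planning-unit universe (a = baseline, b = comparison scenario).
#' @param problem the shared `planning_problem`.
#' @param config an [anneal_config()] (for the objective breakdown).
#' @param unit_areas per-unit areas in km^2 (default 1 km^2 cells).
#' @param region_area total planning-region area (km^2); defaults to the sum
#'   of unit areas.
#' @return a `scenario_comparison` list: per-scenario area, cost, per-feature
#'   held amounts and target flags; intersection area; overlap fractions
#'   `a_in_b` (|A∩B|/|A|) and `b_in_a` (|A∩B|/|B|); area difference as % of
#'   the region.
#' @export
compare_best <- function(solution_a, solution_b, problem,
                         config = anneal_config(),
                         unit_areas = rep(1, length(problem$pu_ids)),
                         region_area = sum(unit_areas)) {
  a <- as.logical(solution_a); b <- as.logical(solution_b)
  if (length(a) != length(problem$pu_ids) || length(b) != length(a))
    stop("solutions must live on the problem's planning-unit universe")
  oa <- objective(a, problem, config)
  ob <- objective(b, problem, config)
  area_a <- sum(unit_areas[a]); area_b <- sum(unit_areas[b])
  inter <- sum(unit_areas[a & b])
  tgt <- vapply(problem$features, `[[`, numeric(1), "target")
  met <- function(o) {
    vapply(seq_along(problem$features), function(j) {
      f <- problem$features[[j]]
      if (f$probabilistic) o$prob_target_met[j] >= f$certainty
      else o$held[j] >= f$target
    }, logical(1))
  }
  structure(list(
    scenario_a = list(area_km2 = area_a, cost = oa$cost, held = oa$held,
                      prob_target_met = oa$prob_target_met,
                      target_met = met(oa)),
    scenario_b = list(area_km2 = area_b, cost = ob$cost, held = ob$held,
                      prob_target_met = ob$prob_target_met,
                      target_met = met(ob)),
    targets = tgt,
    intersection_km2 = inter,
    overlap_a_in_b = if (area_a > 0) inter / area_a else NA_real_,
    overlap_b_in_a = if (area_b > 0) inter / area_b else NA_real_,
    area_difference_pct_region = 100 * (area_b - area_a) / region_area,
    region_area_km2 = region_area
  ), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>\n")
  cat(sprintf("  A: %.0f km2, cost %.4g | B: %.0f km2, cost %.4g\n",
              x$scenario_a$area_km2, x$scenario_a$cost,
              x$scenario_b$area_km2, x$scenario_b$cost))
  cat(sprintf("  overlap: %.0f km2 (%.0f%% of A, %.0f%% of B)\n",
              x$intersection_km2, 100 * x$overlap_a_in_b,
              100 * x$overlap_b_in_a))
  invisible(x)
}

#' Area consistently selected at high frequency
#'
#' Sums unit areas over units whose normalized selection frequency strictly
#' exceeds `threshold` (strict, so exactly-at-threshold units are excluded).
#'
#' @param frequency per-unit selection frequency, normalized to \[0,1\].
#' @param threshold frequency cutoff (default 0.8).
#' @param unit_areas per-unit areas (km^2), default 1.
#' @return area in km^2.
#' @export
high_priority_area <- function(frequency, threshold = 0.8,
                               unit_areas = rep(1, length(frequency))) {
  if (any(frequency < 0 | frequency > 1))
    stop("frequencies must be normalized to [0,1]")
  sum(unit_areas[frequency > threshold])
}
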