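# Minimum-set reserve selection by simulated annealing, in the Marxan
# tradition: minimize cost + BLM * boundary + feature penalties, with either
# deterministic representation targets or probability-constrained targets
# (the per-unit condition probabilities make held amounts random).

#' Feature specification
#'
#' @param feature_id integer id.
#' @param name feature name.
#' @param target minimum amount to represent (km^2).
#' @param spf shortfall penalty factor (> 0).
#' @param probabilistic should the target be probability-constrained?
#' @param certainty required probability `P_j` of meeting the target
#'   (in (0,1)); only used when `probabilistic`.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(feature_id, name, target, spf,
                         probabilistic = FALSE, certainty = NA_real_) {
  if (target < 0) stop("target must be non-negative")
  if (spf <= 0) stop("spf must be positive")
  if (probabilistic && (is.na(certainty) || certainty <= 0 || certainty >= 1))
    stop("probabilistic features need certainty in (0, 1)")
  list(feature_id = feature_id, name = name, target = target, spf = spf,
       probabilistic = isTRUE(probabilistic), certainty = certainty)
}

#' Planning problem
#'
#' @param pu_ids planning-unit ids (integer vector, length n).
#' @param cost per-unit cost (length n, >= 0).
#' @param amounts n x m matrix of feature amounts (km^2), columns named.
#' @param features list of [feature_spec()]s (length m).
#' @param prob_good per-unit probability the unit's coral is in good
#'   condition (length n, in \[0,1\]); 1 for units without coral. Only
#'   consulted by probabilistic features.
#' @param adjacency data.frame `id1`, `id2`, `boundary` (km) of shared edges.
#' @param perimeter per-unit total perimeter (km); default 4 km (1x1-km unit).
#' @param geometry optional list (`template` grid_layer, `cell_index`) for
#'   rasterizing solutions.
#' @return a `planning_problem`.
#' @export
planning_problem <- function(pu_ids, cost, amounts, features,
                             prob_good = rep(1, length(pu_ids)),
                             adjacency = NULL,
                             perimeter = rep(4, length(pu_ids)),
                             geometry = NULL) {
  n <- length(pu_ids)
  amounts <- as.matrix(amounts)
  if (length(cost) != n || nrow(amounts) != n)
    stop("cost/amounts dimensions do not match pu_ids")
  if (length(features) != ncol(amounts))
    stop("features list must match amounts columns")
  if (any(cost < 0) || any(amounts < 0)) stop("costs and amounts must be >= 0")
  if (any(prob_good < 0 | prob_good > 1)) stop("prob_good must be in [0,1]")
  if (is.null(adjacency))
    adjacency <- data.frame(id1 = integer(0), id2 = integer(0),
                            boundary = numeric(0))
  structure(list(pu_ids = as.integer(pu_ids), cost = as.numeric(cost),
                 amounts = amounts, features = features,
                 prob_good = as.numeric(prob_good), adjacency = adjacency,
                 perimeter = as.numeric(perimeter), geometry = geometry),
            class = "planning_problem")
}

#' Annealing configuration
#'
#' @param n_iterations flip attempts per run (default 1e5).
#' @param initial_temp starting temperature, or `"auto"` (90th percentile of
#'   `|delta objective|` over 1000 probe flips).
#' @param cooling_factor geometric cooling multiplier per iteration.
#' @param blm boundary-length modifier (cost per km exposed edge).
#' @param n_solutions ensemble size (default 100).
#' @param base_seed seed of run 1; run r uses `base_seed + r - 1`.
#' @param final_improvement run a greedy improvement pass to a fixpoint.
#' @param prop_init probability a unit starts selected.
#' @return an `anneal_config` list.
#' @export
anneal_config <- function(n_iterations = 1e5, initial_temp = "auto",
                          cooling_factor = 0.999, blm = 0,
                          n_solutions = 100, base_seed = 1,
                          final_improvement = TRUE, prop_init = 0.2) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (cooling_factor <= 0 || cooling_factor >= 1)
    stop("cooling_factor must be in (0, 1)")
  if (blm < 0) stop("blm must be >= 0")
  list(n_iterations = as.integer(n_iterations), initial_temp = initial_temp,
       cooling_factor = cooling_factor, blm = blm,
       n_solutions = as.integer(n_solutions), base_seed = as.integer(base_seed),
       final_improvement = isTRUE(final_improvement), prop_init = prop_init)
}

#' Amount of a feature held by a selection
#' @param selection logical/0-1 vector over planning units.
#' @param problem a `planning_problem`.
#' @param feature column index or name.
#' @return held amount (km^2).
#' @export
held_amount <- function(selection, problem, feature) {
  sum(problem$amounts[as.logical(selection), feature])
}

#' Probability a probabilistic feature meets its target (normal approximation)
#'
#' The held amount of the reserve is `X = sum over selected i of a_i B_i`
#' with independent `B_i ~ Bernoulli(p_i)`. Returns
#' `1 - Phi((T - mu) / sigma)` with `mu = sum a_i p_i`,
#' `sigma^2 = sum a_i^2 p_i (1 - p_i)`; if `sigma = 0`, returns 1 when
#' `mu >= T`, else 0.
#'
#' @param selection logical/0-1 vector.
#' @param amounts per-unit amounts of the feature.
#' @param p per-unit condition probabilities.
#' @param target the target T.
#' @return probability in \[0,1\].
#' @export
prob_target_met <- function(selection, amounts, p, target) {
  sel <- as.logical(selection)
  a <- amounts[sel]; pp <- p[sel]
  mu <- sum(a * pp)
  s2 <- sum(a^2 * pp * (1 - pp))
  if (s2 > 0) 1 - pnorm((target - mu) / sqrt(s2))
  else as.numeric(mu >= target)
}

#' Exact probability the target is met (Poisson-binomial enumeration)
#'
#' Exact distribution of the random held amount by dynamic programming over
#' units: the support doubles per distinct amount but collapses for repeated
#' amounts, so equal-amount instances stay linear. Intended as a test oracle
#' for [prob_target_met()].
#'
#' @inheritParams prob_target_met
#' @return exact probability `P(X >= target)`.
#' @export
exact_prob_target_met <- function(selection, amounts, p, target) {
  sel <- as.logical(selection)
  a <- amounts[sel]; pp <- p[sel]
  keep <- a > 0 & pp > 0
  base <- 0
  vals <- 0; probs <- 1
  for (i in which(keep)) {
    if (pp[i] >= 1) { base <- base + a[i]; next }
    vals2 <- c(vals, vals + a[i])
    probs2 <- c(probs * (1 - pp[i]), probs * pp[i])
    o <- order(vals2)
    vals2 <- vals2[o]; probs2 <- probs2[o]
    grp <- cumsum(c(TRUE, diff(vals2) > 1e-9))
    vals <- as.numeric(tapply(vals2, grp, function(v) v[1]))
    probs <- as.numeric(tapply(probs2, grp, sum))
    if (length(vals) > 2^21) stop("exact enumeration too large")
  }
  sum(probs[vals + base >= target - 1e-9])
}

# exposed boundary length of a selection
.boundary_length <- function(selection, problem) {
  sel <- as.logical(selection)
  b <- sum(problem$perimeter[sel])
  adj <- problem$adjacency
  if (nrow(adj)) {
    i1 <- match(adj$id1, problem$pu_ids)
    i2 <- match(adj$id2, problem$pu_ids)
    both <- sel[i1] & sel[i2]
    b <- b - 2 * sum(adj$boundary[both])
  }
  b
}

#' Objective function value and breakdown
#'
#' `total = sum(cost) + blm * boundary + sum_j penalty_j` where deterministic
#' features pay `spf_j * max(0, T_j - held_j)` and probabilistic features pay
#' the certainty-equivalent shortfall
#' `spf_j * max(0, T_j + qnorm(P_j) * sigma_j - mu_j)` under the
#' independent-Bernoulli normal approximation. The probabilistic penalty is
#' zero exactly when `prob_target_met >= P_j`, is expressed in amount units
#' with a linear gradient in the expected held amount (so the annealer can
#' climb toward feasibility), and collapses to the deterministic shortfall
#' when every `p_i = 1`.
#'
#' @param selection logical/0-1 vector.
#' @param problem a `planning_problem`.
#' @param config an [anneal_config()] (for `blm`).
#' @return list: `total`, `cost`, `boundary`, `penalty_deterministic`,
#'   `penalty_probabilistic`, per-feature `held` and `prob_target_met`.
#' @export
objective <- function(selection, problem, config = anneal_config()) {
  sel <- as.logical(selection)
  cost <- sum(problem$cost[sel])
  boundary <- .boundary_length(sel, problem)
  pen_det <- 0; pen_prob <- 0
  m <- length(problem$features)
  held <- numeric(m); probv <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    f <- problem$features[[j]]
    held[j] <- sum(problem$amounts[sel, j])
    if (f$probabilistic) {
      a <- problem$amounts[sel, j]; pp <- problem$prob_good[sel]
      mu <- sum(a * pp)
      sdv <- sqrt(sum(a^2 * pp * (1 - pp)))
      probv[j] <- prob_target_met(sel, problem$amounts[, j],
                                  problem$prob_good, f$target)
      pen_prob <- pen_prob +
        f$spf * max(0, f$target + stats::qnorm(f$certainty) * sdv - mu)
    } else {
      pen_det <- pen_det + f$spf * max(0, f$target - held[j])
    }
  }
  names(held) <- names(probv) <-
    vapply(problem$features, `[[`, character(1), "name")
  list(total = cost + config$blm * boundary + pen_det + pen_prob,
       cost = cost, boundary = boundary, penalty_deterministic = pen_det,
       penalty_probabilistic = pen_prob, held = held,
       prob_target_met = probv)
}

#' Default shortfall penalty factor
#'
#' `spf_j = 10 * mean(cost) / mean(nonzero amounts of j)`: a shortfall of one
#' average unit's worth of feature costs ten average units, so feasibility
#' dominates cost once targets are reachable.
#'
#' @param cost unit costs.
#' @param amounts_j amounts of feature j.
#' @return scalar spf.
#' @export
default_spf <- function(cost, amounts_j) {
  pos <- amounts_j[amounts_j > 0]
  if (!length(pos)) return(10 * max(mean(cost), 1))
  10 * max(mean(cost), 1e-9) / mean(pos)
}

#' One simulated-annealing run
#'
#' Single-unit flips; moves that lower the objective are always accepted,
#' uphill moves with probability `exp(-delta / T)` under geometric cooling;
#' an optional greedy improvement pass runs to a fixpoint afterwards.
#' Deterministic given `seed`.
#'
#' @param problem a `planning_problem`.
#' @param config an [anneal_config()].
#' @param seed integer seed for this run.
#' @return list: `selection` (logical), objective breakdown fields as in
#'   [objective()].
#' @export
anneal <- function(problem, config = anneal_config(), seed = 1) {
  n <- length(problem$pu_ids)
  m <- length(problem$features)
  target <- vapply(problem$features, `[[`, numeric(1), "target")
  spf <- vapply(problem$features, `[[`, numeric(1), "spf")
  probl <- vapply(problem$features, `[[`, logical(1), "probabilistic")
  cert <- vapply(problem$features, function(f)
    if (f$probabilistic) f$certainty else 1, numeric(1))
  adj <- problem$adjacency
  i1 <- match(adj$id1, problem$pu_ids)
  i2 <- match(adj$id2, problem$pu_ids)
  t0 <- if (identical(config$initial_temp, "auto")) -1
  else as.numeric(config$initial_temp)
  res <- with_seed_(seed, {
    x0 <- as.integer(runif(n) < config$prop_init)
    anneal_cpp(problem$cost, problem$amounts, target, spf,
               as.integer(probl), cert, problem$prob_good,
               problem$perimeter, as.integer(i1), as.integer(i2),
               adj$boundary, config$blm, config$n_iterations, t0,
               config$cooling_factor, x0, config$final_improvement)
  })
  nm <- vapply(problem$features, `[[`, character(1), "name")
  names(res$held) <- nm
  res$prob_target_met <- ifelse(probl, res$prob_target_met, NA_real_)
  names(res$prob_target_met) <- nm
  list(selection = res$x == 1L, total = res$total, cost = res$cost,
       boundary = res$boundary,
       penalty_deterministic = res$penalty_deterministic,
       penalty_probabilistic = res$penalty_probabilistic,
       held = res$held, prob_target_met = res$prob_target_met)
}

#' Solve an ensemble of annealing runs
#'
#' Runs `n_solutions` independent anneals (run r seeded `base_seed + r - 1`),
#' records each selection and objective breakdown, the best solution
#' (lowest total, ties to the lowest run index) and per-unit selection
#' frequency.
#'
#' @param problem a `planning_problem`.
#' @param config an [anneal_config()].
#' @return a `solution_ensemble`: `selections` (n_solutions x n logical
#'   matrix), `objectives` (data.frame), `best_index`, `best` (run result),
#'   `selection_frequency` (counts in \[0, n_solutions\]).
#' @export
solve_ensemble <- function(problem, config = anneal_config()) {
  ns <- config$n_solutions
  n <- length(problem$pu_ids)
  selections <- matrix(FALSE, ns, n)
  runs <- vector("list", ns)
  for (r in seq_len(ns)) {
    runs[[r]] <- anneal(problem, config, seed = config$base_seed + r - 1)
    selections[r, ] <- runs[[r]]$selection
  }
  totals <- vapply(runs, `[[`, numeric(1), "total")
  best <- which.min(totals)   # which.min takes the first minimum: lowest index
  obj <- data.frame(
    run = seq_len(ns), total = totals,
    cost = vapply(runs, `[[`, numeric(1), "cost"),
    boundary = vapply(runs, `[[`, numeric(1), "boundary"),
    penalty_deterministic = vapply(runs, `[[`, numeric(1),
                                   "penalty_deterministic"),
    penalty_probabilistic = vapply(runs, `[[`, numeric(1),
                                   "penalty_probabilistic")
  )
  structure(list(selections = selections, objectives = obj,
                 best_index = best, best = runs[[best]],
                 selection_frequency = colSums(selections),
                 n_solutions = ns, problem = problem, config = config),
            class = "solution_ensemble")
}

#' @export
print.solution_ensemble <- function(x, ...) {
  cat(sprintf("<solution_ensemble> %d runs over %d units\n", x$n_solutions,
              ncol(x$selections)))
  cat(sprintf("  best run %d: objective %.4g, cost %.4g, %d units\n",
              x$best_index, x$best$total, x$best$cost, sum(x$best$selection)))
  invisible(x)
}

#' Check that probabilistic mode collapses to deterministic mode
#'
#' With all `prob_good = 1` the held amount is degenerate, so the certainty
#' shortfall is zero exactly when the deterministic shortfall is zero, and
#' paired annealing runs in the two modes are identical.
#'
#' @param problem a `planning_problem` with all `prob_good = 1`.
#' @param config an [anneal_config()].
#' @param seed paired-run seed.
#' @return TRUE if both modes give identical selections and objectives.
#' @export
reduce_check_deterministic <- function(problem, config = anneal_config(),
                                       seed = 1) {
  if (any(problem$prob_good != 1)) stop("all prob_good must equal 1")
  prob_feats <- lapply(problem$features, function(f) {
    f$probabilistic <- TRUE
    if (is.na(f$certainty)) f$certainty <- 0.9
    f
  })
  det_feats <- lapply(problem$features, function(f) {
    f$probabilistic <- FALSE
    f
  })
  p1 <- problem; p1$features <- det_feats
  p2 <- problem; p2$features <- prob_feats
  r1 <- anneal(p1, config, seed)
  r2 <- anneal(p2, config, seed)
  identical(r1$selection, r2$selection) &&
    isTRUE(all.equal(r1$total, r2$total))
}

# ---- problem construction from pipeline artifacts -----------------------

#' Build a planning problem from a landscape bundle
#'
#' Planning units are the sea cells. Costs come from the kernel-density
#' fisher surface (expected count per cell plus a small base cost); feature
#' amounts from the bundle's feature grids; coral condition probabilities
#' from a `condition_surface` (cells without coral get 1). Fractional
#' targets are resolved against total feature amounts. Adjacency is
#' rook-neighbour shared edges of `cell_size` km.
#'
#' @param bundle a `landscape_bundle`.
#' @param cost_grid `grid_layer` of fisher density (from
#'   [kernel_density_cost()]).
#' @param condition a `condition_surface` or NULL (baseline: all 1).
#' @param target_fractions named fractions of total amount per feature.
#' @param probabilistic_features names of features under the certainty
#'   constraint (default "coral" when `condition` is given).
#' @param certainty required certainty for probabilistic features.
#' @param spf named per-feature penalty factors; default via [default_spf()].
#' @param base_cost additive base unit cost.
#' @return a `planning_problem`.
#' @export
build_problem <- function(bundle, cost_grid, condition = NULL,
                          target_fractions = c(coral = 0.3, mangrove = 0.3,
                                               seagrass = 0.3,
                                               turtle_grounds = 0.1),
                          probabilistic_features =
                            if (is.null(condition)) character(0) else "coral",
                          certainty = 0.9, spf = NULL, base_cost = 0.1) {
  sea <- bundle$sea_mask$values == 1
  sea_idx <- which(sea)
  n <- length(sea_idx)
  cell_km <- bundle$dem$cell_size / 1000
  cost <- cost_grid$values[sea_idx] * bundle$dem$cell_size^2 + base_cost
  feats <- names(bundle$feature_grids)
  amounts <- sapply(feats, function(nm)
    bundle$feature_grids[[nm]]$values[sea_idx])
  amounts[is.na(amounts)] <- 0
  pg <- rep(1, n)
  if (!is.null(condition)) {
    pv <- condition$prob_good$values[sea_idx]
    pg[!is.na(pv)] <- pv[!is.na(pv)]
  }
  features <- vector("list", length(feats))
  for (j in seq_along(feats)) {
    tgt <- sum(amounts[, j]) * target_fractions[[feats[j]]]
    sj <- if (!is.null(spf) && feats[j] %in% names(spf)) spf[[feats[j]]]
    else default_spf(cost, amounts[, j])
    features[[j]] <- feature_spec(
      j, feats[j], tgt, sj,
      probabilistic = feats[j] %in% probabilistic_features,
      certainty = if (feats[j] %in% probabilistic_features) certainty
      else NA_real_)
  }
  # rook adjacency among sea cells
  nr <- nrow(sea)
  id_of <- integer(length(sea)); id_of[sea_idx] <- seq_len(n)
  r <- ((sea_idx - 1) %% nr) + 1; cc <- ((sea_idx - 1) %/% nr) + 1
  edges <- list()
  for (k in c(1, 3)) {  # east and south neighbours cover each pair once
    rr <- r + D8_DROW[k]; c2 <- cc + D8_DCOL[k]
    ok <- rr >= 1 & rr <= nr & c2 >= 1 & c2 <= ncol(sea)
    j <- (c2[ok] - 1) * nr + rr[ok]
    ok2 <- sea[j]
    edges[[length(edges) + 1]] <- data.frame(
      id1 = id_of[sea_idx[ok][ok2]], id2 = id_of[j[ok2]],
      boundary = cell_km)
  }
  adjacency <- do.call(rbind, edges)
  planning_problem(
    pu_ids = seq_len(n), cost = cost, amounts = amounts, features = features,
    prob_good = pg, adjacency = adjacency,
    perimeter = rep(4 * cell_km, n),
    geometry = list(template = bundle$dem, cell_index = sea_idx))
}

#' Rasterize a per-unit vector onto the problem's grid
#' @param problem a `planning_problem` with geometry attached.
#' @param values per-unit numeric vector.
#' @return a `grid_layer`.
#' @export
rasterize_solution <- function(problem, values) {
  g <- problem$geometry
  if (is.null(g)) stop("problem has no grid geometry attached")
  m <- matrix(NA_real_, nrow(g$template$values), ncol(g$template$values))
  m[g$cell_index] <- as.numeric(values)
  with_values(g$template, m)
}

# ---- Marxan-dialect file I/O --------------------------------------------

#' Write a planning problem in the Marxan file dialect
#'
#' Emits `pu.dat` (id, cost, status), `spec.dat` (id, target, spf, name and,
#' for probabilistic features, prob-target columns), `puvspr.dat`
#' (species, pu, amount) and `bound.dat` (id1, id2, boundary).
#'
#' @param problem a `planning_problem`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_marxan <- function(problem, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(id = problem$pu_ids, cost = problem$cost, status = 0,
                       prob = problem$prob_good),
            file.path(dir, "pu.dat"), row.names = FALSE, quote = FALSE)
  fs <- problem$features
  write.csv(data.frame(
    id = vapply(fs, `[[`, numeric(1), "feature_id"),
    target = vapply(fs, `[[`, numeric(1), "target"),
    spf = vapply(fs, `[[`, numeric(1), "spf"),
    name = vapply(fs, `[[`, character(1), "name"),
    prob = vapply(fs, `[[`, logical(1), "probabilistic"),
    ptarget = vapply(fs, `[[`, numeric(1), "certainty")),
    file.path(dir, "spec.dat"), row.names = FALSE, quote = FALSE)
  idx <- which(problem$amounts > 0, arr.ind = TRUE)
  write.csv(data.frame(species = idx[, 2], pu = problem$pu_ids[idx[, 1]],
                       amount = problem$amounts[idx]),
            file.path(dir, "puvspr.dat"), row.names = FALSE, quote = FALSE)
  write.csv(problem$adjacency, file.path(dir, "bound.dat"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a planning problem from Marxan-dialect files
#' @param dir directory holding pu.dat, spec.dat, puvspr.dat, bound.dat.
#' @return a `planning_problem`.
#' @export
read_marxan <- function(dir) {
  pu <- read.csv(file.path(dir, "pu.dat"))
  sp <- read.csv(file.path(dir, "spec.dat"))
  pv <- read.csv(file.path(dir, "puvspr.dat"))
  bd <- read.csv(file.path(dir, "bound.dat"))
  n <- nrow(pu); m <- nrow(sp)
  amounts <- matrix(0, n, m, dimnames = list(NULL, sp$name))
  amounts[cbind(match(pv$pu, pu$id), pv$species)] <- pv$amount
  features <- lapply(seq_len(m), function(j)
    feature_spec(sp$id[j], sp$name[j], sp$target[j], sp$spf[j],
                 probabilistic = isTRUE(sp$prob[j]),
                 certainty = sp$ptarget[j]))
  prob_good <- if ("prob" %in% names(pu)) pu$prob else rep(1, n)
  planning_problem(pu$id, pu$cost, amounts, features, prob_good, bd)
}
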