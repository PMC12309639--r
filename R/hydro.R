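#' @useDynLib ridge2reef, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor dist lm median pnorm predict quantile
#'   rbinom rnorm runif sd setNames vcov plogis qlogis rbeta var
#' @importFrom utils read.csv write.csv
NULL

# Land/sea convention throughout the hydrology stage: hydrology grids carry NA
# on sea cells; land = !is.na(values).

land_mask <- function(dem) !is.na(dem$values)

#' Fill depressions in a DEM
#'
#' Priority-flood filling to spill elevation with a small epsilon gradient
#' (`1e-6 * cell_size` per step) imposed on flats so that every land cell ends
#' up with a strictly descending 8-connected path to the coast. Sea cells are
#' `NA` and act as drainage boundaries, as does the grid edge.
#'
#' @param dem a `grid_layer`; `NA` marks sea.
#' @return a `grid_layer` with `values >= dem$values` everywhere on land and no
#'   interior local minima.
#' @export
fill_depressions <- function(dem) {
  land <- land_mask(dem)
  if (!any(land)) stop("DEM contains no land cells")
  eps <- 1e-6 * dem$cell_size
  filled <- fill_depressions_cpp(dem$values, land, eps)
  with_values(dem, filled)
}

#' D8 flow directions
#'
#' Each land cell points to its steepest-descent 8-neighbour (drop divided by
#' centre distance). Codes run clockwise from east: 1 = E, 2 = SE, 3 = S,
#' 4 = SW, 5 = W, 6 = NW, 7 = N, 8 = NE; 0 marks an outlet (steepest descent
#' into the sea or off the grid edge); sea is `NA`. Ties break on the fixed
#' clockwise order, so output is deterministic.
#'
#' @param dem depression-filled `grid_layer` (see [fill_depressions()]).
#' @return integer-coded `grid_layer` of directions.
#' @export
d8_flow_direction <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  land <- land_mask(dem)
  dir <- matrix(NA_integer_, nr, nc)
  # pad with sea (treated as elevation 0: mean sea level)
  zp <- matrix(NA_real_, nr + 2, nc + 2)
  zp[2:(nr + 1), 2:(nc + 1)] <- z
  best_grad <- matrix(-Inf, nr, nc)
  best_k <- matrix(0L, nr, nc)
  for (k in seq_len(8)) {
    zn <- zp[2:(nr + 1) + D8_DROW[k], 2:(nc + 1) + D8_DCOL[k]]
    target_sea <- is.na(zn)
    zn[target_sea] <- 0          # sea surface elevation
    grad <- (z - zn) / (D8_DIST[k] * dem$cell_size)
    take <- land & grad > best_grad
    best_grad[take] <- grad[take]
    best_k[take] <- ifelse(target_sea[take], 0L, k)
  }
  no_desc <- land & best_grad <= 0
  if (any(no_desc))
    stop(sprintf("%d land cells have no downslope neighbour; fill the DEM first",
                 sum(no_desc)))
  dir[land] <- best_k[land]
  with_values(dem, dir)
}

# downstream linear index (column-major) for every land cell; 0 for outlets
.downstream_index <- function(dir_values) {
  nr <- nrow(dir_values); nc <- ncol(dir_values)
  idx <- which(!is.na(dir_values))
  k <- dir_values[idx]
  r <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  ds <- integer(length(idx))
  inner <- k > 0
  rr <- r[inner] + D8_DROW[k[inner]]
  c2 <- cc[inner] + D8_DCOL[k[inner]]
  ds[inner] <- (c2 - 1) * nr + rr
  list(idx = idx, downstream = ds)
}

#' Flow accumulation
#'
#' Sums `weights` over every cell draining through each cell (itself
#' included), following D8 directions. Processing is in topological order
#' (Kahn), so a cycle in the direction grid is detected and raised.
#'
#' @param directions direction `grid_layer` from [d8_flow_direction()].
#' @param weights `grid_layer` of per-cell weights (defaults to 1 on land).
#' @return `grid_layer` of accumulated weights.
#' @export
flow_accumulation <- function(directions, weights = NULL) {
  dv <- directions$values
  if (is.null(weights)) {
    w <- ifelse(is.na(dv), NA_real_, 1)
  } else {
    stopifnot_same_shape(directions, weights)
    w <- weights$values
  }
  link <- .downstream_index(dv)
  acc <- w
  indeg <- integer(length(dv))
  has_ds <- link$downstream > 0
  tab <- table(link$downstream[has_ds])
  indeg[as.integer(names(tab))] <- as.integer(tab)
  queue <- link$idx[indeg[link$idx] == 0]
  ds_of <- integer(length(dv))
  ds_of[link$idx] <- link$downstream
  processed <- 0L
  head <- 1L
  queue <- c(queue, integer(length(link$idx)))  # preallocate
  tail <- sum(indeg[link$idx] == 0)
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    processed <- processed + 1L
    d <- ds_of[i]
    if (d > 0) {
      acc[d] <- acc[d] + acc[i]
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) { tail <- tail + 1L; queue[tail] <- d }
    }
  }
  if (processed < length(link$idx))
    stop("cycle detected in flow directions")
  with_values(directions, acc)
}

#' Watershed delineation
#'
#' Labels every land cell with the outlet its D8 flow path terminates at.
#' Outlets (direction code 0) are numbered row-major in grid order.
#'
#' @param directions direction `grid_layer`.
#' @return list with `watersheds` (integer `grid_layer` of outlet ids) and
#'   `pour_points` (data.frame: outlet_id, row, col, x, y, watershed_id).
#' @export
delineate_watersheds <- function(directions) {
  dv <- directions$values
  nr <- nrow(dv)
  link <- .downstream_index(dv)
  lab <- integer(length(dv))       # 0 = unlabelled
  outlets <- link$idx[link$downstream == 0]
  # row-major outlet numbering for stable ids
  r_o <- ((outlets - 1) %% nr) + 1
  c_o <- ((outlets - 1) %/% nr) + 1
  ord <- order(r_o, c_o)
  outlets <- outlets[ord]
  lab[outlets] <- seq_along(outlets)
  ds_of <- integer(length(dv))
  ds_of[link$idx] <- link$downstream
  for (i in link$idx) {
    if (lab[i] > 0) next
    path <- i
    j <- i
    while (lab[j] == 0L) {
      j <- ds_of[j]
      if (j == 0L) stop("flow path left the labelled set (corrupt directions)")
      path <- c(path, j)
    }
    lab[path] <- lab[j]
  }
  wmat <- matrix(NA_integer_, nrow(dv), ncol(dv))
  wmat[link$idx] <- lab[link$idx]
  wg <- with_values(directions, wmat)
  ro <- ((outlets - 1) %% nr) + 1
  co <- ((outlets - 1) %/% nr) + 1
  pp <- data.frame(outlet_id = seq_along(outlets), row = ro, col = co,
                   watershed_id = seq_along(outlets))
  cc <- cell_centers(directions, rows = ro, cols = co)
  pp$x <- cc$x; pp$y <- cc$y
  list(watersheds = wg, pour_points = pp[, c("outlet_id", "row", "col",
                                             "x", "y", "watershed_id")])
}

#' SCS curve-number storm runoff depth
#'
#' Retention `S_ret = 25400 / CN - 254` (mm); runoff
#' `Q = (P - 0.2 S_ret)^2 / (P + 0.8 S_ret)` when `P > 0.2 S_ret`, else 0.
#' Always `0 <= Q <= P`.
#'
#' @param precip storm rainfall depth `grid_layer` (mm).
#' @param curve_number CN `grid_layer`, values in \[30, 100\] on land.
#' @return runoff-depth `grid_layer` (mm).
#' @export
scs_runoff_depth <- function(precip, curve_number) {
  stopifnot_same_shape(precip, curve_number)
  cn <- curve_number$values
  P <- precip$values
  land <- !is.na(cn)
  if (any(cn[land] < 30 | cn[land] > 100))
    stop("curve numbers must lie in [30, 100] on land")
  if (any(P[land] < 0)) stop("precipitation must be non-negative")
  s_ret <- 25400 / cn - 254
  ia <- 0.2 * s_ret
  q <- ifelse(P > ia, (P - ia)^2 / (P + 0.8 * s_ret), 0)
  q[!land] <- NA_real_
  with_values(precip, q)
}

#' Peak runoff rate (uniform-release proxy)
#'
#' `q_p = (Q/1000 * cell_size^2) / (duration * 3600)` in m^3/s: the cell's
#' event runoff volume released uniformly over the storm duration. A proxy
#' that preserves relative ordering across cells, which is what the relative
#' sediment-yield interpretation requires.
#'
#' @param runoff_depth runoff-depth `grid_layer` (mm).
#' @param storm_duration_h event duration in hours (default 24).
#' @return `grid_layer` of peak rates (m^3/s).
#' @export
peak_flow <- function(runoff_depth, storm_duration_h = 24) {
  if (storm_duration_h <= 0) stop("storm_duration_h must be positive")
  qp <- (runoff_depth$values / 1000) * runoff_depth$cell_size^2 /
    (storm_duration_h * 3600)
  with_values(runoff_depth, qp)
}

#' RUSLE LS value for one slope-length/steepness pair
#'
#' `LS = (lambda / 22.13)^m * (65.41 sin^2 t + 4.56 sin t + 0.065)` with the
#' length exponent `m` tabulated on percent slope (tan t * 100):
#' 0.5 at >= 5%, 0.4 at 3.5-5%, 0.3 at 1-3.5%, 0.2 below 1%.
#'
#' @param lambda_m slope length in metres.
#' @param sin_theta sine of the slope angle.
#' @return dimensionless LS.
#' @export
ls_value <- function(lambda_m, sin_theta) {
  theta <- asin(pmin(1, pmax(0, sin_theta)))
  slope_pct <- tan(theta) * 100
  m <- ifelse(slope_pct >= 5, 0.5,
              ifelse(slope_pct >= 3.5, 0.4,
                     ifelse(slope_pct >= 1, 0.3, 0.2)))
  (lambda_m / 22.13)^m * (65.41 * sin_theta^2 + 4.56 * sin_theta + 0.065)
}

#' LS factor grid from a filled DEM
#'
#' Slope is taken along each cell's D8 steepest-descent direction; slope
#' length is the longest upstream flow-path length reaching the cell (cell
#' centre to cell centre) plus half a cell for the overland distance inside
#' the source cell. Computed in topological order.
#'
#' @param dem filled DEM `grid_layer`.
#' @param directions matching direction `grid_layer`; computed if `NULL`.
#' @return LS `grid_layer`.
#' @export
ls_factor <- function(dem, directions = NULL) {
  if (is.null(directions)) directions <- d8_flow_direction(dem)
  dv <- directions$values
  z <- dem$values
  nr <- nrow(z)
  link <- .downstream_index(dv)
  cs <- dem$cell_size

  # slope along flow direction
  sin_t <- matrix(NA_real_, nr, ncol(z))
  k <- dv[link$idx]
  r <- ((link$idx - 1) %% nr) + 1
  cc <- ((link$idx - 1) %/% nr) + 1
  zn <- numeric(length(link$idx))
  inner <- k > 0
  zn[inner] <- z[link$downstream[inner]]
  zn[!inner] <- 0                       # outlets drop to sea level
  run <- ifelse(k == 0, cs, D8_DIST[pmax(k, 1)] * cs)
  drop <- pmax(0, z[link$idx] - zn)
  sin_t[link$idx] <- drop / sqrt(drop^2 + run^2)

  # longest upstream flow length, topological order
  lam <- numeric(length(z))
  lam[link$idx] <- cs / 2
  indeg <- integer(length(z))
  has_ds <- link$downstream > 0
  tab <- table(link$downstream[has_ds])
  indeg[as.integer(names(tab))] <- as.integer(tab)
  ds_of <- integer(length(z)); ds_of[link$idx] <- link$downstream
  step_len <- numeric(length(z))
  step_len[link$idx] <- run
  queue <- c(link$idx[indeg[link$idx] == 0], integer(length(link$idx)))
  tail <- sum(indeg[link$idx] == 0); head <- 1L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    d <- ds_of[i]
    if (d > 0) {
      lam[d] <- max(lam[d], lam[i] + step_len[i])
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) { tail <- tail + 1L; queue[tail] <- d }
    }
  }
  ls <- matrix(NA_real_, nr, ncol(z))
  ls[link$idx] <- ls_value(lam[link$idx], sin_t[link$idx])
  with_values(dem, ls)
}

#' MUSLE parameters
#'
#' @param a calibration coefficient (default 11.8, metric MUSLE).
#' @param b calibration exponent (default 0.56).
#' @param p_practice supporting-practices factor P (default 1).
#' @param storm_duration_h event duration used by the peak-flow proxy.
#' @return a `musle_params` list.
#' @export
musle_params <- function(a = 11.8, b = 0.56, p_practice = 1,
                         storm_duration_h = 24) {
  if (a <= 0) stop("a must be positive")
  if (b <= 0 || b > 1) stop("b must be in (0, 1]")
  if (p_practice <= 0 || p_practice > 1) stop("p_practice must be in (0, 1]")
  if (storm_duration_h <= 0) stop("storm_duration_h must be positive")
  structure(list(a = a, b = b, p_practice = p_practice,
                 storm_duration_h = storm_duration_h),
            class = "musle_params")
}

#' Storm-event sediment yield per cell (MUSLE)
#'
#' `S = a (Q q_p)^b K C P LS` with Q the runoff volume (m^3), q_p the peak
#' rate (m^3/s), K soil erodibility, C cover management, P supporting
#' practices and LS the topographic factor. Yields are in relative units.
#'
#' @param runoff_volume_m3 `grid_layer` of event runoff volume per cell (m^3).
#' @param peak_rate `grid_layer` (m^3/s).
#' @param k_factor,c_factor,ls `grid_layer`s of the multiplicative factors.
#' @param params a [musle_params()].
#' @return sediment-yield `grid_layer` (relative units).
#' @export
musle_cell_yield <- function(runoff_volume_m3, peak_rate, k_factor, c_factor,
                             ls, params = musle_params()) {
  stopifnot_same_shape(runoff_volume_m3, peak_rate, k_factor, c_factor, ls)
  grids <- list(runoff_volume_m3, peak_rate, k_factor, c_factor, ls)
  for (g in grids) {
    vv <- g$values
    if (any(vv[!is.na(vv)] < 0)) stop("all MUSLE factors must be non-negative")
  }
  energy <- runoff_volume_m3$values * peak_rate$values
  s <- params$a * energy^params$b * k_factor$values * c_factor$values *
    params$p_practice * ls$values
  s[energy == 0] <- 0
  with_values(runoff_volume_m3, s)
}

#' Runoff depth (mm) to per-cell volume (m^3)
#' @param runoff_depth `grid_layer` in mm.
#' @return `grid_layer` in m^3.
#' @export
runoff_volume <- function(runoff_depth) {
  with_values(runoff_depth,
              runoff_depth$values / 1000 * runoff_depth$cell_size^2)
}

#' Accumulate sediment yields to pour points
#'
#' Sums cell yields over each watershed and attaches the totals (the
#' source-strength of each river mouth) to the pour points. No in-stream
#' deposition is applied, so total load equals total yield exactly.
#'
#' @param yields sediment-yield `grid_layer`.
#' @param watersheds result of [delineate_watersheds()].
#' @return the pour-point data.frame with a `load` column appended.
#' @export
accumulate_sediment <- function(yields, watersheds) {
  wv <- watersheds$watersheds$values
  stopifnot_same_shape(yields, watersheds$watersheds)
  pp <- watersheds$pour_points
  sums <- tapply(yields$values[!is.na(wv)], wv[!is.na(wv)], sum)
  pp$load <- 0
  pp$load[match(as.integer(names(sums)), pp$watershed_id)] <- as.numeric(sums)
  pp
}

#' Full hydrology stage on a landscape bundle
#'
#' Fills the DEM, routes flow, delineates watersheds, computes curve-number
#' runoff, the peak-flow proxy, LS, MUSLE cell yields, and accumulates loads
#' to coastal pour points.
#'
#' @param bundle a `landscape_bundle` from [generate_landscape()].
#' @param params a [musle_params()].
#' @return list: `filled`, `directions`, `watersheds` (delineation result),
#'   `runoff_depth`, `yield` (grids) and `pour_points` (with loads).
#' @export
run_hydrology <- function(bundle, params = musle_params()) {
  filled <- fill_depressions(bundle$dem)
  dirs <- d8_flow_direction(filled)
  ws <- delineate_watersheds(dirs)
  q_mm <- scs_runoff_depth(bundle$storm_precip, bundle$curve_number)
  q_vol <- runoff_volume(q_mm)
  qp <- peak_flow(q_mm, params$storm_duration_h)
  ls <- ls_factor(filled, dirs)
  cvals <- bundle$c_factor_table[as.character(bundle$landcover$values)]
  cgrid <- with_values(bundle$landcover,
                       matrix(unname(cvals), nrow(bundle$landcover$values)))
  yield <- musle_cell_yield(q_vol, qp, bundle$k_factor, cgrid, ls, params)
  pp <- accumulate_sediment(yield, ws)
  list(filled = filled, directions = dirs, watersheds = ws,
       runoff_depth = q_mm, yield = yield, pour_points = pp)
}
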