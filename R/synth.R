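# Synthetic island-seascape generator: every downstream stage of the pipeline
# is testable against a world whose data-generating process is known exactly.

with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Smooth Gaussian random field by spectral synthesis: white noise filtered
# with a |k|^(-beta/2) amplitude spectrum, standardized to mean 0 / sd 1.
.smooth_field <- function(nr, nc, beta = 3) {
  wn <- matrix(rnorm(nr * nc), nr, nc)
  kx <- seq_len(nc) - 1; kx[kx > nc / 2] <- kx[kx > nc / 2] - nc
  ky <- seq_len(nr) - 1; ky[ky > nr / 2] <- ky[ky > nr / 2] - nr
  k <- sqrt(outer((ky / nr)^2, (kx / nc)^2, "+"))
  filt <- ifelse(k == 0, 0, k^(-beta / 2))
  f <- Re(stats::fft(stats::fft(wn) * filt, inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / sd(f)
}

# 8-connected component labelling of a logical matrix (iterative BFS)
.connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      r <- ((i - 1) %% nr) + 1; cc <- ((i - 1) %/% nr) + 1
      for (k in 1:8) {
        rr <- r + D8_DROW[k]; c2 <- cc + D8_DCOL[k]
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        j <- (c2 - 1) * nr + rr
        if (mask[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  lab
}

# Chebyshev distance (in cells) from every cell to the nearest TRUE cell,
# by multi-source BFS over the 8-neighbourhood.
.chebyshev_distance_to <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[mask] <- 0
  frontier <- which(mask)
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- integer(0)
    for (i in frontier) {
      r <- ((i - 1) %% nr) + 1; cc <- ((i - 1) %/% nr) + 1
      for (k in 1:8) {
        rr <- r + D8_DROW[k]; c2 <- cc + D8_DCOL[k]
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        j <- (c2 - 1) * nr + rr
        if (d[j] > lev) { d[j] <- lev; nxt <- c(nxt, j) }
      }
    }
    frontier <- nxt
  }
  d
}

#' Synthetic ground truth for the coral condition model
#'
#' The true cover curve is linear on the logit scale: cover is
#' `cover_clean` in the cleanest water and declines by `drop_logits` across
#' the central (`q_lo`-`q_hi` quantile) span of the realized log-TSS field.
#' Because modelled TSS is in relative units, the covariate anchors
#' `x_lo`/`x_hi` are resolved once against an actual log-TSS field (see
#' [resolve_truth()]); afterwards the curve is a fixed, evaluable function.
#'
#' @param cover_clean true hard-coral cover fraction in the cleanest water.
#' @param drop_logits total decline (logit scale) across the anchor span.
#' @param site_sd standard deviation of site-level random intercepts (logits).
#' @param q_lo,q_hi quantiles of coral-cell log-TSS used as anchors.
#' @param x_lo,x_hi explicit anchors (log-TSS); resolved from data if `NULL`.
#' @return a `synthetic_truth` object.
#' @export
synthetic_truth <- function(cover_clean = 0.55, drop_logits = 2.2,
                            site_sd = 0.5, q_lo = 0.1, q_hi = 0.9,
                            x_lo = NULL, x_hi = NULL) {
  if (site_sd < 0) stop("site_sd must be non-negative")
  structure(list(cover_intercept = qlogis(cover_clean),
                 drop_logits = drop_logits, site_sd = site_sd,
                 q_lo = q_lo, q_hi = q_hi, x_lo = x_lo, x_hi = x_hi),
            class = "synthetic_truth")
}

#' Resolve the truth curve's covariate anchors against a log-TSS field
#' @param truth a [synthetic_truth()].
#' @param log_tss_values numeric log-TSS values (e.g. over coral cells).
#' @return the truth object with concrete `x_lo`, `x_hi`.
#' @export
resolve_truth <- function(truth, log_tss_values) {
  if (is.null(truth$x_lo) || is.null(truth$x_hi)) {
    qs <- quantile(log_tss_values, c(truth$q_lo, truth$q_hi), na.rm = TRUE,
                   names = FALSE)
    if (qs[2] <= qs[1]) stop("log-TSS range degenerate; cannot anchor truth")
    truth$x_lo <- qs[1]; truth$x_hi <- qs[2]
  }
  truth
}

#' True logit-cover curve of a resolved truth
#' @param truth a resolved [synthetic_truth()].
#' @return function mapping log-TSS to logit(cover).
#' @export
truth_curve <- function(truth) {
  if (is.null(truth$x_lo)) stop("truth anchors unresolved; see resolve_truth()")
  function(x) truth$cover_intercept -
    truth$drop_logits * (x - truth$x_lo) / (truth$x_hi - truth$x_lo)
}

#' Landscape generator configuration
#'
#' @param nrow,ncol grid shape (>= 32).
#' @param cell_size cell side, metres (default 1000: the planning-unit size).
#' @param n_islands number of island nuclei (>= 1).
#' @param land_fraction target land fraction of the interior (0-1 exclusive).
#' @param relief_m maximum island elevation, metres.
#' @param spectral_beta terrain roughness spectrum exponent (higher=smoother).
#' @param storm_rain_mm base cyclone-event rainfall depth, mm.
#' @param orographic_mm_per_m rainfall increase per metre elevation.
#' @param n_towns coastal population centres.
#' @param reef_band offshore Chebyshev distance band (cells) of the reef arc.
#' @param truth a [synthetic_truth()].
#' @return a config list.
#' @export
landscape_config <- function(nrow = 64, ncol = 64, cell_size = 1000,
                             n_islands = 1, land_fraction = 0.3,
                             relief_m = 600, spectral_beta = 3,
                             storm_rain_mm = 250, orographic_mm_per_m = 0.25,
                             n_towns = 6, reef_band = c(3, 8),
                             truth = synthetic_truth()) {
  if (nrow < 32 || ncol < 32) stop("grid must be at least 32 x 32")
  if (n_islands < 1) stop("need at least one island")
  if (land_fraction <= 0 || land_fraction >= 1)
    stop("degenerate config: land_fraction must be in (0, 1)")
  list(nrow = nrow, ncol = ncol, cell_size = cell_size, n_islands = n_islands,
       land_fraction = land_fraction, relief_m = relief_m,
       spectral_beta = spectral_beta, storm_rain_mm = storm_rain_mm,
       orographic_mm_per_m = orographic_mm_per_m, n_towns = n_towns,
       reef_band = reef_band, truth = truth)
}

# per-class constants: cover-management factor C and curve number
.LC_CLASSES <- data.frame(
  code = 1:4,
  name = c("forest", "grassland", "cropland", "bare"),
  c_factor = c(0.003, 0.05, 0.2, 0.35),
  cn = c(60, 70, 78, 86)
)

#' Generate a synthetic island landscape and seascape
#'
#' Spectral random-field terrain with radial island bumps, thresholded to the
#' configured land fraction; a two-cell sea ring is enforced at the grid edge
#' and minor land fragments are flooded so the landmass is connected per
#' island nucleus. Land layers: categorical cover (forest / grassland /
#' cropland / bare) with per-class C factors and curve numbers, soil
#' erodibility K, and orographic storm rainfall. Sea layers: mangrove fringe,
#' inshore seagrass patches, an offshore reef arc, and a few large turtle
#' feeding grounds overlapping seagrass and coral. Coastal towns provide the
#' population for the fisher cost surface.
#'
#' @param config a [landscape_config()].
#' @param seed integer; the generator is deterministic given (config, seed).
#' @return a `landscape_bundle`.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1) {
  with_seed_(seed, {
    nr <- config$nrow; nc <- config$ncol; cs <- config$cell_size

    base <- .smooth_field(nr, nc, config$spectral_beta)
    rows <- row(base); cols <- col(base)
    bump <- matrix(0, nr, nc)
    centers <- cbind(runif(config$n_islands, 0.3, 0.7) * nr,
                     runif(config$n_islands, 0.3, 0.7) * nc)
    rad <- 0.35 * min(nr, nc) / sqrt(config$n_islands)
    for (ii in seq_len(config$n_islands)) {
      d2 <- ((rows - centers[ii, 1])^2 + (cols - centers[ii, 2])^2) / rad^2
      bump <- pmax(bump, pmax(0, 1 - d2))
    }
    score <- 0.45 * base + 2.2 * bump
    border <- rows <= 2 | rows > nr - 2 | cols <= 2 | cols > nc - 2
    score[border] <- -Inf
    sea_level <- quantile(score[!border], 1 - config$land_fraction,
                          names = FALSE)
    land <- score > sea_level
    if (!any(land)) stop("degenerate config: all sea")
    if (all(land[!border])) stop("degenerate config: all land")
    # flood minor fragments: keep the n_islands largest components
    comp <- .connected_components(land)
    sizes <- sort(table(comp[comp > 0]), decreasing = TRUE)
    keep <- as.integer(names(sizes))[seq_len(min(config$n_islands,
                                                 length(sizes)))]
    land <- land & (comp %in% keep)
    if (!any(land)) stop("degenerate config: all sea after cleaning")

    elev <- matrix(NA_real_, nr, nc)
    rng <- max(score[land]) - sea_level
    elev[land] <- (score[land] - sea_level) / rng * config$relief_m + 0.01
    dem <- grid_layer(elev, cs, c(0, nr * cs))
    sea <- grid_layer(ifelse(land, 0, 1), cs, c(0, nr * cs))

    # land cover: noise plus elevation preference (forest uphill)
    lc_score <- 0.8 * .smooth_field(nr, nc, 2.5) -
      1.2 * (elev / config$relief_m)
    qs <- quantile(lc_score[land], c(0.45, 0.70, 0.90), names = FALSE)
    lc <- matrix(NA_real_, nr, nc)
    lc[land] <- cut(lc_score[land], c(-Inf, qs, Inf), labels = FALSE)
    landcover <- grid_layer(lc, cs, c(0, nr * cs))
    c_tab <- setNames(.LC_CLASSES$c_factor, .LC_CLASSES$code)

    kf <- matrix(NA_real_, nr, nc)
    kf[land] <- pmin(0.45, pmax(0.05,
                                0.25 + 0.08 * .smooth_field(nr, nc, 2.5)[land]))
    k_factor <- grid_layer(kf, cs, c(0, nr * cs))

    cnv <- matrix(NA_real_, nr, nc)
    cnv[land] <- .LC_CLASSES$cn[lc[land]] + 4 * .smooth_field(nr, nc, 2)[land]
    cnv[land] <- pmin(100, pmax(30, cnv[land]))
    curve_number <- grid_layer(cnv, cs, c(0, nr * cs))

    pr <- matrix(NA_real_, nr, nc)
    pr[land] <- pmax(50, config$storm_rain_mm +
                       config$orographic_mm_per_m * elev[land] +
                       15 * .smooth_field(nr, nc, 2.5)[land])
    storm_precip <- grid_layer(pr, cs, c(0, nr * cs))

    # marine features on the sea side
    dist_land <- .chebyshev_distance_to(land)   # 0 on land
    area <- (cs / 1000)^2
    sea_idx <- which(!land)
    zero_sea <- function() {
      m <- matrix(NA_real_, nr, nc); m[sea_idx] <- 0; m
    }

    mg <- zero_sea()
    fringe <- !land & dist_land == 1
    mg[fringe] <- runif(sum(fringe), 0.05, 0.3) * area

    sg <- zero_sea()
    sg_noise <- .smooth_field(nr, nc, 2.5)
    sg_cells <- !land & dist_land >= 1 & dist_land <= 3 & sg_noise > 0.2
    sg[sg_cells] <- runif(sum(sg_cells), 0.1, 0.5) * area

    co <- zero_sea()
    reef_noise <- .smooth_field(nr, nc, 2.5)
    reef <- !land & dist_land >= config$reef_band[1] &
      dist_land <= config$reef_band[2] & reef_noise > -0.3
    co[reef] <- runif(sum(reef), 0.2, 0.9) * area

    tg <- zero_sea()
    habitat_idx <- which(sg_cells | reef)
    n_tg <- min(3, length(habitat_idx))
    tg_centers <- sample(habitat_idx, n_tg)
    for (i in tg_centers) {
      r0 <- ((i - 1) %% nr) + 1; c0 <- ((i - 1) %/% nr) + 1
      disc <- !land & (rows - r0)^2 + (cols - c0)^2 <= 5^2
      tg[disc] <- pmax(tg[disc], runif(sum(disc), 0.3, 0.8) * area)
    }

    feature_grids <- list(
      coral = grid_layer(co, cs, c(0, nr * cs)),
      mangrove = grid_layer(mg, cs, c(0, nr * cs)),
      seagrass = grid_layer(sg, cs, c(0, nr * cs)),
      turtle_grounds = grid_layer(tg, cs, c(0, nr * cs))
    )

    # coastal towns (land cells touching the sea), log-uniform populations
    coast <- which(land & .chebyshev_distance_to(!land) == 1)
    towns <- sample(coast, min(config$n_towns, length(coast)))
    cc <- cell_centers(dem, rows = ((towns - 1) %% nr) + 1,
                       cols = ((towns - 1) %/% nr) + 1)
    population_points <- data.frame(
      x = cc$x, y = cc$y,
      count = round(exp(runif(length(towns), log(2000), log(50000))))
    )

    structure(list(
      dem = dem, landcover = landcover, c_factor_table = c_tab,
      k_factor = k_factor, curve_number = curve_number,
      storm_precip = storm_precip, sea_mask = sea,
      feature_grids = feature_grids, population_points = population_points,
      truth = config$truth, config = config, seed = seed
    ), class = "landscape_bundle")
  })
}

#' Validate landscape-bundle invariants
#'
#' Checks layer shapes, curve-number and erodibility ranges on land, absence
#' of hydrology inputs on sea, feature amounts within \[0, cell area\], and
#' coral restricted to sea cells. Errors on the first violation.
#'
#' @param bundle a `landscape_bundle`.
#' @return `TRUE`, invisibly.
#' @export
validate_bundle <- function(bundle) {
  land <- land_mask(bundle$dem)
  sea <- bundle$sea_mask$values == 1
  if (any(land & sea)) stop("land/sea masks overlap")
  stopifnot_same_shape(bundle$dem, bundle$landcover, bundle$k_factor,
                       bundle$curve_number, bundle$storm_precip,
                       bundle$sea_mask)
  cn <- bundle$curve_number$values
  if (any(is.na(cn[land]))) stop("curve number missing on land")
  if (any(cn[land] < 30 | cn[land] > 100)) stop("curve number outside [30,100]")
  if (any(bundle$k_factor$values[land] < 0)) stop("negative K factor")
  for (nm in c("k_factor", "curve_number", "storm_precip"))
    if (any(!is.na(bundle[[nm]]$values[sea])))
      stop(sprintf("%s defined on sea cells", nm))
  area <- cell_area_km2(bundle$dem)
  for (nm in names(bundle$feature_grids)) {
    fv <- bundle$feature_grids[[nm]]$values
    vals <- fv[!is.na(fv)]
    if (any(vals < 0) || any(vals > area + 1e-12))
      stop(sprintf("feature %s outside [0, cell area]", nm))
  }
  cov <- bundle$feature_grids$coral$values
  if (any(!is.na(cov[land]) & cov[land] > 0)) stop("coral on land cells")
  invisible(TRUE)
}

#' Quartic (biweight) kernel density surface from weighted points
#'
#' The density at distance `d` from a point of weight `w` is
#' `w * 3/(pi r^2) * (1 - (d/r)^2)^2` for `d < r` and 0 beyond, summed over
#' points; integrating the surface over the plane recovers the total weight.
#' This mirrors the kernel-density tool of desktop GIS used to turn coastal
#' population counts into a relative fishing-pressure cost surface.
#'
#' @param points data.frame with columns `x`, `y`, `count` (metres, people).
#' @param template `grid_layer` supplying the geometry of the output.
#' @param radius_m kernel search radius in metres (default 10 cells).
#' @return `grid_layer` of density (people per m^2) on all cells.
#' @export
kernel_density_cost <- function(points, template,
                                radius_m = 10 * template$cell_size) {
  if (radius_m <= 0) stop("radius_m must be positive")
  v <- matrix(0, nrow(template$values), ncol(template$values))
  if (is.null(points) || nrow(points) == 0) {
    warning("no population points; returning all-zero cost surface")
    return(with_values(template, v))
  }
  cc <- cell_centers(template)
  for (i in seq_len(nrow(points))) {
    d2 <- (cc$x - points$x[i])^2 + (cc$y - points$y[i])^2
    u2 <- d2 / radius_m^2
    contrib <- ifelse(u2 < 1,
                      points$count[i] * 3 / (pi * radius_m^2) * (1 - u2)^2, 0)
    v <- v + matrix(contrib, nrow(v))
  }
  with_values(template, v)
}

#' Simulate point-intercept reef surveys
#'
#' Sites are placed on coral-bearing sea cells, stratified over the log-TSS
#' range so the condition covariate is identified. Each site gets a random
#' intercept `u ~ N(0, site_sd^2)`; each of `transects` transects records
#' `points_per_transect` benthic points with hard-coral hits drawn
#' `Binomial(n, plogis(f(logTSS) + u))` where `f` is the truth curve.
#'
#' @param tss a `tss_field` (see [tss_field()]) or a log-TSS `grid_layer`.
#' @param coral_mask logical matrix or `grid_layer` of coral-bearing cells.
#' @param truth a [synthetic_truth()]; anchors resolved here if needed.
#' @param n_sites number of survey sites (default 72).
#' @param transects transects per site (default 3).
#' @param points_per_transect benthic points per transect (default 100).
#' @param seed integer RNG seed.
#' @return a `survey_table` data.frame, one row per transect, with columns
#'   site_id, transect, x, y, n_points, n_hard_coral, log_tss, plus the
#'   resolved truth as attribute `"truth"`.
#' @export
generate_surveys <- function(tss, coral_mask, truth = synthetic_truth(),
                             n_sites = 72, transects = 3,
                             points_per_transect = 100, seed = 1) {
  log_tss <- if (inherits(tss, "tss_field")) tss$log_tss else tss
  mask <- if (is_grid_layer(coral_mask)) {
    !is.na(coral_mask$values) & coral_mask$values > 0
  } else coral_mask
  cells <- which(mask & !is.na(log_tss$values))
  if (length(cells) < n_sites)
    stop(sprintf("only %d coral cells with TSS; need %d sites",
                 length(cells), n_sites))
  truth <- resolve_truth(truth, log_tss$values[cells])
  f <- truth_curve(truth)
  with_seed_(seed, {
    x <- log_tss$values[cells]
    ord <- cells[order(x)]
    strata <- split(ord, cut(seq_along(ord), n_sites, labels = FALSE))
    site_cells <- vapply(strata, function(s)
      if (length(s) == 1) s else sample(s, 1), integer(1))
    nr <- nrow(log_tss$values)
    rr <- ((site_cells - 1) %% nr) + 1
    cc <- ((site_cells - 1) %/% nr) + 1
    ctr <- cell_centers(log_tss, rows = rr, cols = cc)
    lt <- log_tss$values[site_cells]
    u <- rnorm(n_sites, 0, truth$site_sd)
    p <- plogis(f(lt) + u)
    out <- data.frame(
      site_id = rep(seq_len(n_sites), each = transects),
      transect = rep(seq_len(transects), n_sites),
      x = rep(ctr$x, each = transects), y = rep(ctr$y, each = transects),
      n_points = points_per_transect,
      n_hard_coral = rbinom(n_sites * transects, points_per_transect,
                            rep(p, each = transects)),
      log_tss = rep(lt, each = transects)
    )
    attr(out, "truth") <- truth
    class(out) <- c("survey_table", "data.frame")
    out
  })
}

#' Pool a transect-level survey table to one row per site
#' @param surveys a `survey_table`.
#' @return data.frame with columns site_id, x, y, n_points, n_hard_coral,
#'   log_tss (`n_points` is the per-site total, e.g. 3 x 100 = 300).
#' @export
pool_surveys <- function(surveys) {
  agg <- stats::aggregate(cbind(n_points, n_hard_coral) ~ site_id,
                          data = surveys, FUN = sum)
  first <- surveys[!duplicated(surveys$site_id),
                   c("site_id", "x", "y", "log_tss")]
  out <- merge(first, agg, by = "site_id")
  out[order(out$site_id),
      c("site_id", "x", "y", "n_points", "n_hard_coral", "log_tss")]
}

#' Write a survey table as CSV (pooled per-site schema)
#' @param surveys a `survey_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surveys_csv <- function(surveys, path) {
  write.csv(pool_surveys(surveys), path, row.names = FALSE)
  invisible(path)
}
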