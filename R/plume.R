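# Power-law sediment plume: river-mouth loads decay with distance over the
# marine grid, z_ij = beta_j * d_ij^alpha, summed over sources. The resulting
# log-TSS field is the covariate of the coral condition model.

#' Dispersion parameters
#'
#' @param alpha dispersion exponent; negative for decay with distance
#'   (default -2.3, a fitted value for a high-island fringing-reef coast).
#' @param distance_metric `"euclidean"` (default; the plume model carries no
#'   land-barrier routing) or `"overwater"` (shortest 8-connected sea path).
#' @param min_distance_km floor on distances to avoid the `d -> 0`
#'   singularity of `d^alpha`; default 0.5 km (half a planning-unit side).
#' @return a `dispersion_params` list.
#' @export
dispersion_params <- function(alpha = -2.3,
                              distance_metric = c("euclidean", "overwater"),
                              min_distance_km = 0.5) {
  if (!is.finite(alpha)) stop("alpha must be finite")
  if (min_distance_km <= 0) stop("min_distance_km must be positive")
  structure(list(alpha = alpha,
                 distance_metric = match.arg(distance_metric),
                 min_distance_km = min_distance_km),
            class = "dispersion_params")
}

#' Pour-point-to-sea-cell distance matrix (km)
#'
#' Euclidean: straight-line centre-to-centre distance. Overwater: shortest
#' 8-connected path through sea cells (orthogonal step = cell size, diagonal
#' step = sqrt(2) cell size), entered from the sea neighbours of each pour
#' point; unreachable cells get `Inf` (zero influence) with a warning. All
#' distances are floored at `min_distance_km`.
#'
#' @param pour_points data.frame with `row`, `col`, `x`, `y` (from
#'   [delineate_watersheds()] / [accumulate_sediment()]).
#' @param sea a logical matrix or sea-mask `grid_layer` (1/TRUE = sea).
#' @param template `grid_layer` giving geometry (any hydrology grid).
#' @param params a [dispersion_params()].
#' @return matrix, `nrow(pour_points)` x number of sea cells; columns ordered
#'   by the linear (column-major) index of the sea cells, given in
#'   `attr(, "sea_index")`.
#' @export
distance_matrix <- function(pour_points, sea, template,
                            params = dispersion_params()) {
  sv <- if (is_grid_layer(sea)) sea$values == 1 else sea
  sea_idx <- which(sv)
  if (nrow(pour_points) < 1) stop("need at least one pour point")
  if (length(sea_idx) < 1) stop("need at least one sea cell")
  nr <- nrow(sv)
  cc <- cell_centers(template, rows = ((sea_idx - 1) %% nr) + 1,
                     cols = ((sea_idx - 1) %/% nr) + 1)
  if (params$distance_metric == "euclidean") {
    d <- outer(seq_len(nrow(pour_points)), seq_along(sea_idx),
               function(i, j) sqrt((pour_points$x[i] - cc$x[j])^2 +
                                     (pour_points$y[i] - cc$y[j])^2)) / 1000
  } else {
    d <- .overwater_distances(pour_points, sv, template) / 1000
    if (any(is.infinite(d)))
      warning("some sea cells are unreachable over water; influence set to 0")
  }
  d <- pmax(d, params$min_distance_km)
  attr(d, "sea_index") <- sea_idx
  d
}

# shortest sea paths via a lattice graph over sea cells (igraph)
.overwater_distances <- function(pour_points, sv, template) {
  nr <- nrow(sv); nc <- ncol(sv)
  sea_idx <- which(sv)
  id_of <- integer(nr * nc); id_of[sea_idx] <- seq_along(sea_idx)
  cs <- template$cell_size
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (k in 1:4) {  # E, SE, S, SW cover each undirected pair once
    dr <- D8_DROW[k]; dc <- D8_DCOL[k]
    r <- ((sea_idx - 1) %% nr) + 1; cc <- ((sea_idx - 1) %/% nr) + 1
    rr <- r + dr; c2 <- cc + dc
    ok <- rr >= 1 & rr <= nr & c2 >= 1 & c2 <= nc
    j <- (c2[ok] - 1) * nr + rr[ok]
    ok2 <- sv[j]
    ef <- c(ef, id_of[sea_idx[ok][ok2]])
    et <- c(et, id_of[j[ok2]])
    ew <- c(ew, rep(D8_DIST[k] * cs, sum(ok2)))
  }
  g <- igraph::make_graph(as.vector(rbind(ef, et)), n = length(sea_idx),
                          directed = FALSE)
  out <- matrix(Inf, nrow(pour_points), length(sea_idx))
  for (i in seq_len(nrow(pour_points))) {
    r0 <- pour_points$row[i]; c0 <- pour_points$col[i]
    # seed the sea neighbours of the (land) outlet cell
    seeds <- integer(0); seed_d <- numeric(0)
    for (k in 1:8) {
      rr <- r0 + D8_DROW[k]; c2 <- c0 + D8_DCOL[k]
      if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
      j <- (c2 - 1) * nr + rr
      if (sv[j]) {
        seeds <- c(seeds, id_of[j])
        seed_d <- c(seed_d, D8_DIST[k] * cs)
      }
    }
    if (!length(seeds)) next
    dmat <- igraph::distances(g, v = seeds, weights = ew)
    out[i, ] <- apply(dmat + seed_d, 2, min)
  }
  out
}

#' Total-suspended-sediment field from dispersed pour-point loads
#'
#' `tss_i = sum_j load_j * d_ij^alpha`; `log_tss` is the natural log where
#' `tss > 0` and no-data otherwise. Land stays no-data.
#'
#' @param loads pour-point data.frame with a `load` column
#'   (see [accumulate_sediment()]).
#' @param distances matrix from [distance_matrix()] (km).
#' @param template `grid_layer` geometry.
#' @param params a [dispersion_params()].
#' @return a `tss_field`: list of `tss` and `log_tss` grids.
#' @export
tss_field <- function(loads, distances, template,
                      params = dispersion_params()) {
  if (any(loads$load < 0)) stop("loads must be non-negative")
  sea_idx <- attr(distances, "sea_index")
  infl <- distances^params$alpha
  infl[is.infinite(distances)] <- 0
  z <- as.numeric(crossprod(infl, loads$load))
  tssm <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  tssm[sea_idx] <- z
  ltm <- matrix(NA_real_, nrow(tssm), ncol(tssm))
  pos <- sea_idx[z > 0]
  ltm[pos] <- log(tssm[pos])
  structure(list(tss = with_values(template, tssm),
                 log_tss = with_values(template, ltm),
                 params = params),
            class = "tss_field")
}

#' Run the plume stage on hydrology output
#'
#' @param pour_points loaded pour points from [accumulate_sediment()].
#' @param bundle the `landscape_bundle` (for the sea mask and geometry).
#' @param params a [dispersion_params()].
#' @return a `tss_field`.
#' @export
run_plume <- function(pour_points, bundle, params = dispersion_params()) {
  d <- distance_matrix(pour_points, bundle$sea_mask, bundle$dem, params)
  tss_field(pour_points, d, bundle$dem, params)
}
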