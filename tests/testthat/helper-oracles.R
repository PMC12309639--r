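# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (path following, enumeration, brute force)
# and never call the implementation paths they check.

# a grid with NA sea ring and the given land values
make_dem <- function(values, cell_size = 100) {
  grid_layer(values, cell_size, c(0, nrow(as.matrix(values)) * cell_size))
}

# random rough island DEM: positive land elevations inside a sea ring
random_island_dem <- function(nr = 16, nc = 16, seed = 1, cell_size = 100) {
  set.seed(seed)
  v <- matrix(NA_real_, nr, nc)
  land <- matrix(FALSE, nr, nc)
  land[3:(nr - 2), 3:(nc - 2)] <- TRUE
  v[land] <- runif(sum(land), 1, 50)
  grid_layer(v, cell_size, c(0, nr * cell_size))
}

# neighbour offsets in the package's fixed clockwise-from-east order
ORACLE_DROW <- c(0, 1, 1, 1, 0, -1, -1, -1)
ORACLE_DCOL <- c(1, 1, 0, -1, -1, -1, 0, 1)
ORACLE_DIST <- sqrt(ORACLE_DROW^2 + ORACLE_DCOL^2)

# follow steepest descent on a (filled) DEM from cell (r, c); returns
# "sea" if the path exits to sea/off-grid, "stuck" if trapped in a pit
follow_steepest_descent <- function(dem, r, c, max_steps = 1e5) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  for (step in seq_len(max_steps)) {
    best <- -Inf; best_k <- NA
    for (k in 1:8) {
      rr <- r + ORACLE_DROW[k]; cc <- c + ORACLE_DCOL[k]
      zn <- if (rr < 1 || rr > nr || cc < 1 || cc > nc) NA else z[rr, cc]
      if (is.na(zn)) zn <- 0  # sea level
      g <- (z[r, c] - zn) / ORACLE_DIST[k]
      if (g > best) { best <- g; best_k <- k }
    }
    if (best <= 0) return("stuck")
    rr <- r + ORACLE_DROW[best_k]; cc <- c + ORACLE_DCOL[best_k]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc || is.na(z[rr, cc]))
      return("sea")
    r <- rr; c <- cc
  }
  "loop"
}

# brute-force flow accumulation: for every cell, walk its full flow path and
# add its weight to every cell visited (O(n^2) path following)
oracle_accumulation <- function(directions, weights = NULL) {
  dv <- directions$values
  nr <- nrow(dv); nc <- ncol(dv)
  w <- if (is.null(weights)) ifelse(is.na(dv), NA, 1) else weights$values
  acc <- matrix(0, nr, nc)
  acc[is.na(dv)] <- NA
  for (i in which(!is.na(dv))) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    repeat {
      acc[r, c] <- acc[r, c] + w[i]
      k <- dv[r, c]
      if (k == 0) break
      r <- r + ORACLE_DROW[k]; c <- c + ORACLE_DCOL[k]
    }
  }
  acc
}

# exact P(sum of selected a_i * Bernoulli(p_i) >= target) by full 2^n
# enumeration (n <= 20)
enumerate_prob <- function(a, p, target) {
  n <- length(a)
  stopifnot(n <= 20)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    amt <- sum(a[bits == 1])
    if (amt >= target - 1e-9)
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
  }
  total
}

# small random planning problem for solver tests
random_problem <- function(n = 12, m = 3, seed = 1, prob_mode = FALSE) {
  set.seed(seed)
  amounts <- matrix(round(runif(n * m), 2) *
                      (matrix(runif(n * m), n, m) < 0.6), n, m)
  colnames(amounts) <- paste0("f", seq_len(m))
  cost <- round(runif(n, 0.5, 3), 2)
  pg <- if (prob_mode) round(runif(n, 0.4, 1), 2) else rep(1, n)
  features <- lapply(seq_len(m), function(j) {
    tot <- sum(amounts[, j])
    feature_spec(j, paste0("f", j), target = 0.4 * tot, spf = 20,
                 probabilistic = prob_mode && j == 1,
                 certainty = if (prob_mode && j == 1) 0.9 else NA_real_)
  })
  # a ring adjacency so boundary terms are exercised
  adjacency <- data.frame(id1 = seq_len(n), id2 = c(2:n, 1),
                          boundary = 1)
  planning_problem(seq_len(n), cost, amounts, features, pg, adjacency,
                   perimeter = rep(4, n))
}

# exhaustive minimum over all 2^n selections of a small problem
exhaustive_optimum <- function(problem, config = anneal_config()) {
  n <- length(problem$pu_ids)
  stopifnot(n <= 14)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    sel <- as.integer(intToBits(mask))[1:n] == 1
    tot <- objective(sel, problem, config)$total
    if (tot < best) best <- tot
  }
  best
}

# small synthetic world shared by slower tests (built once per test run)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- generate_landscape(landscape_config(), seed = 42)
      hy <- run_hydrology(b)
      tss <- run_plume(hy$pour_points, b)
      cache <<- list(bundle = b, hydro = hy, tss = tss)
    }
    cache
  }
})
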