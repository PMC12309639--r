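# Hydrology stage: depression filling, D8 routing, accumulation, watersheds,
# curve-number runoff, LS, MUSLE and pour-point sediment loads.

test_that("depression filling leaves pit-free DEMs unchanged and never lowers", {
  tilt <- make_dem(outer(rep(1, 6), 6:1) + 0.1 * outer(6:1, rep(1, 6)))
  filled <- fill_depressions(tilt)
  expect_equal(filled$values, tilt$values)

  for (seed in 1:5) {
    dem <- random_island_dem(12, 12, seed = seed)
    filled <- fill_depressions(dem)
    expect_true(all(filled$values >= dem$values, na.rm = TRUE))
  }
  expect_error(fill_depressions(make_dem(matrix(NA_real_, 4, 4))), "no land")
})

test_that("a single pit rises to its spill elevation", {
  v <- outer(rep(1, 7), 7:1)  # plane tilted west... descending eastwards
  v <- v + 10
  pit <- c(4, 4)
  v[pit[1], pit[2]] <- v[pit[1], pit[2]] - 5
  dem <- make_dem(v)
  filled <- fill_depressions(dem)
  # brute-force spill: the lowest neighbour elevation on the original DEM
  nb <- c()
  for (k in 1:8)
    nb <- c(nb, v[pit[1] + ORACLE_DROW[k], pit[2] + ORACLE_DCOL[k]])
  expect_equal(filled$values[pit[1], pit[2]], min(nb), tolerance = 1e-3)
  # and no interior land cell remains a strict local minimum
  fv <- filled$values
  for (r in 2:6) for (c in 2:6) {
    nbv <- sapply(1:8, function(k) fv[r + ORACLE_DROW[k], c + ORACLE_DCOL[k]])
    expect_gt(max(fv[r, c] - nbv), 0)
  }
})

test_that("D8 points a tilted plane east and splits a symmetric ridge", {
  east <- make_dem(outer(rep(1, 5), 5:1))
  d <- d8_flow_direction(fill_depressions(east))
  inner <- d$values[2:4, 2:4]
  expect_true(all(inner == 1))

  # ridge crest along column 3: west side flows west, east side flows east
  ridge <- make_dem(outer(rep(1, 5), c(1, 2, 3, 2, 1)) * 10)
  dr <- d8_flow_direction(fill_depressions(ridge))
  expect_true(all(dr$values[2:4, 2] %in% c(5, 0)))  # west side -> west
  expect_true(all(dr$values[2:4, 4] %in% c(1, 0)))  # east side -> east

  # determinism incl. tie-breaking
  d2 <- d8_flow_direction(fill_depressions(east))
  expect_identical(d$values, d2$values)
})

test_that("flow accumulation sums a chain and matches the path-following oracle", {
  # interior channel of 4 cells flanked by high walls, draining east; wall
  # cells drain straight to the sea, so the channel outlet accumulates the
  # chain and nothing else
  v <- matrix(NA_real_, 5, 8)
  v[2:4, 2:7] <- 100
  v[3, 3:6] <- c(50, 40, 30, 20)
  v[3, 7] <- 10
  dem <- make_dem(v)
  d <- d8_flow_direction(dem)
  acc <- flow_accumulation(d)
  expect_equal(acc$values[3, 7], 5)

  for (seed in 1:6) {
    dem <- fill_depressions(random_island_dem(16, 16, seed = seed))
    d <- d8_flow_direction(dem)
    acc <- flow_accumulation(d)
    expect_equal(acc$values, oracle_accumulation(d))
    # conservation: outlet accumulation sums to land cell count
    outlets <- which(d$values == 0)
    expect_equal(sum(acc$values[outlets]), sum(!is.na(d$values)))
  }
})

test_that("watershed labels partition land and split a two-basin DEM as designed", {
  # one-outlet island: a cone draining to a single lowest coastal cell
  v <- matrix(NA_real_, 7, 7)
  for (r in 2:6) for (c in 2:6) v[r, c] <- 11 - abs(r - 4) - 2 * (c - 2)
  dem <- fill_depressions(make_dem(v))
  d <- d8_flow_direction(dem)
  ws <- delineate_watersheds(d)
  expect_true(all(!is.na(ws$watersheds$values[!is.na(d$values)])))

  # two designed basins: ridge along column 4, west basin and east basin
  v2 <- matrix(NA_real_, 5, 7)
  v2[2:4, 2:6] <- rep(c(1, 5, 9, 5, 1), each = 3)
  dem2 <- fill_depressions(make_dem(v2))
  d2 <- d8_flow_direction(dem2)
  ws2 <- delineate_watersheds(d2)
  wv <- ws2$watersheds$values
  west <- unique(as.vector(wv[2:4, 2]))
  east <- unique(as.vector(wv[2:4, 6]))
  expect_length(intersect(west, east), 0)

  # partition property on random islands
  dem3 <- fill_depressions(random_island_dem(14, 14, seed = 3))
  d3 <- d8_flow_direction(dem3)
  ws3 <- delineate_watersheds(d3)
  land <- !is.na(d3$values)
  expect_true(all(!is.na(ws3$watersheds$values[land])))
  expect_true(all(is.na(ws3$watersheds$values[!land])))
})

test_that("curve-number runoff obeys its closed form and bounds", {
  g <- function(x) grid_layer(matrix(x, 1, 1), 90, c(0, 90))
  expect_equal(scs_runoff_depth(g(0), g(80))$values[1, 1], 0)
  expect_equal(scs_runoff_depth(g(123), g(100))$values[1, 1], 123)
  # CN = 80, P = 100 mm: S_ret = 63.5, Q = 87.3^2 / 150.8
  q <- scs_runoff_depth(g(100), g(80))$values[1, 1]
  expect_equal(q, 87.3^2 / 150.8, tolerance = 1e-12)
  expect_equal(q, 50.539, tolerance = 1e-4)
  expect_error(scs_runoff_depth(g(10), g(20)), "\\[30, 100\\]")

  # 0 <= Q <= P and Q increasing in CN beyond the initial abstraction
  set.seed(9)
  P <- matrix(runif(100, 0, 300), 10)
  CN <- matrix(runif(100, 30, 100), 10)
  gp <- grid_layer(P, 90, c(0, 900)); gc <- grid_layer(CN, 90, c(0, 900))
  Q <- scs_runoff_depth(gp, gc)$values
  expect_true(all(Q >= 0 & Q <= P))
  q1 <- scs_runoff_depth(g(150), g(70))$values[1, 1]
  q2 <- scs_runoff_depth(g(150), g(75))$values[1, 1]
  expect_gt(q2, q1)
})

test_that("peak flow is the uniform-release volume rate and linear in Q", {
  g <- grid_layer(matrix(50.54, 1, 1), 90, c(0, 90))
  qp <- peak_flow(g, storm_duration_h = 24)$values[1, 1]
  expect_equal(qp, 0.05054 * 8100 / 86400, tolerance = 1e-12)
  g2 <- with_values(g, matrix(2 * 50.54, 1, 1))
  expect_equal(peak_flow(g2, 24)$values[1, 1], 2 * qp)
  expect_equal(peak_flow(with_values(g, matrix(0, 1, 1)), 24)$values[1, 1], 0)
})

test_that("LS closed forms: flat constant, worked slope value, sqrt-2 length scaling", {
  expect_equal(ls_value(22.13, 0), 0.065)
  expect_equal(ls_value(22.13, 0.1), 65.41 * 0.01 + 4.56 * 0.1 + 0.065,
               tolerance = 1e-12)
  expect_equal(ls_value(22.13, 0.1), 1.1751, tolerance = 1e-10)
  expect_equal(ls_value(2 * 22.13, 0.1) / ls_value(22.13, 0.1), sqrt(2),
               tolerance = 1e-12)
})

test_that("MUSLE yield: unit factors, annihilation, worked value, monotone", {
  g <- function(x) grid_layer(matrix(x, 1, 1), 90, c(0, 90))
  p <- musle_params()  # a = 11.8, b = 0.56
  expect_equal(musle_cell_yield(g(1), g(1), g(1), g(1), g(1), p)$values[1, 1],
               11.8)
  expect_equal(musle_cell_yield(g(10), g(10), g(0.3), g(0), g(1.5),
                                p)$values[1, 1], 0)
  # Q*qp = 100, K = 0.3, C = 0.2, LS = 1.5 -> 11.8 * 100^0.56 * 0.09
  got <- musle_cell_yield(g(100), g(1), g(0.3), g(0.2), g(1.5), p)$values[1, 1]
  expect_equal(got, 11.8 * 100^0.56 * 0.3 * 0.2 * 1.5, tolerance = 1e-12)
  expect_equal(got, 14.00, tolerance = 1e-2)
  expect_error(musle_cell_yield(g(-1), g(1), g(1), g(1), g(1), p),
               "non-negative")
  expect_error(musle_params(a = -1), "positive")
})

test_that("sediment mass is conserved from cells to pour points, with K-scale equivariance", {
  w <- small_world()
  pp <- w$hydro$pour_points
  expect_equal(sum(pp$load), sum(w$hydro$yield$values, na.rm = TRUE))
  # two-basin hand DEM with unit yields: loads equal basin cell counts
  v2 <- matrix(NA_real_, 5, 7)
  v2[2:4, 2:6] <- rep(c(1, 5, 9, 5, 1), each = 3)
  dem2 <- fill_depressions(make_dem(v2))
  d2 <- d8_flow_direction(dem2)
  ws2 <- delineate_watersheds(d2)
  ones <- with_values(dem2, ifelse(is.na(v2), NA, 1))
  loads <- accumulate_sediment(ones, ws2)
  counts <- table(ws2$watersheds$values)
  expect_equal(loads$load[match(as.integer(names(counts)),
                                loads$watershed_id)],
               as.numeric(counts))
  # scaling K scales every load by the same constant
  b <- w$bundle
  b2 <- b
  b2$k_factor <- with_values(b$k_factor, 2.5 * b$k_factor$values)
  pp2 <- run_hydrology(b2)$pour_points
  expect_equal(pp2$load, 2.5 * pp$load, tolerance = 1e-12)
})
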