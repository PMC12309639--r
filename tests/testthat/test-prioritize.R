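# Reserve selection: objective arithmetic, probability approximations vs the
# exact enumeration oracle, annealing vs exhaustive search, mode reduction.

test_that("held_amount sums selected amounts", {
  pr <- random_problem(3, 1, seed = 1)
  pr$amounts[, 1] <- c(2, 5, 1)
  expect_equal(held_amount(c(FALSE, FALSE, FALSE), pr, 1), 0)
  expect_equal(held_amount(c(TRUE, TRUE, TRUE), pr, 1), 8)
  expect_equal(held_amount(c(TRUE, FALSE, TRUE), pr, 1), 3)
})

test_that("prob_target_met: closed form, degenerate branches, exact oracle", {
  # one unit, a = 10, p = 0.8, T = 5
  approx <- prob_target_met(TRUE, 10, 0.8, 5)
  expect_equal(approx, 1 - pnorm((5 - 8) / 4), tolerance = 1e-12)
  expect_equal(approx, pnorm(0.75), tolerance = 1e-12)
  expect_equal(exact_prob_target_met(TRUE, 10, 0.8, 5), 0.8)
  # sigma = 0 branches
  expect_equal(prob_target_met(rep(TRUE, 3), c(4, 4, 4), rep(1, 3), 10), 1)
  expect_equal(prob_target_met(rep(FALSE, 3), c(4, 4, 4), rep(1, 3), 1), 0)
  # 50 equal units: normal approximation within 0.05 of exact
  a <- rep(1, 50); p <- rep(0.8, 50)
  expect_lt(abs(prob_target_met(rep(TRUE, 50), a, p, 35) -
                  exact_prob_target_met(rep(TRUE, 50), a, p, 35)), 0.05)
  # exact matches 2^n enumeration on small irregular instances
  for (seed in 1:5) {
    set.seed(seed)
    n <- 8
    a <- round(runif(n, 0.5, 3), 2)
    p <- round(runif(n, 0.1, 0.95), 2)
    tgt <- 0.4 * sum(a)
    expect_equal(exact_prob_target_met(rep(TRUE, n), a, p, tgt),
                 enumerate_prob(a, p, tgt), tolerance = 1e-10)
  }
})

test_that("prob_target_met is monotone under unit addition", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 10
    a <- round(runif(n, 0.2, 2), 2)
    p <- round(runif(n, 0.05, 1), 2)
    tgt <- 0.5 * sum(a)
    sel <- runif(n) < 0.5
    add <- which(!sel)
    if (!length(add)) next
    i <- add[1]
    sel2 <- sel; sel2[i] <- TRUE
    expect_gte(exact_prob_target_met(sel2, a, p, tgt) + 1e-12,
               exact_prob_target_met(sel, a, p, tgt))
  }
})

test_that("objective: boundary arithmetic and penalty structure", {
  # two adjacent 1x1-km units plus an isolated one
  f <- list(feature_spec(1, "f1", target = 0, spf = 1))
  adj <- data.frame(id1 = 1, id2 = 2, boundary = 1)
  pr <- planning_problem(1:3, cost = c(2, 3, 4),
                         amounts = matrix(0, 3, 1,
                                          dimnames = list(NULL, "f1")),
                         features = f, adjacency = adj)
  cfg <- anneal_config(blm = 1)
  expect_equal(objective(c(FALSE, FALSE, FALSE), pr, cfg)$total, 0)
  o1 <- objective(c(TRUE, FALSE, FALSE), pr, cfg)
  expect_equal(o1$boundary, 4)
  expect_equal(o1$total, 2 + 4)
  o2 <- objective(c(TRUE, TRUE, FALSE), pr, cfg)
  expect_equal(o2$boundary, 6)   # 8 km perimeter - 2 x 1 km shared edge
  expect_equal(o2$total, 5 + 6)
  # deterministic shortfall is linear below target
  f2 <- list(feature_spec(1, "f1", target = 10, spf = 7))
  pr2 <- planning_problem(1:3, cost = c(0, 0, 0),
                          amounts = matrix(c(2, 3, 1), 3, 1,
                                           dimnames = list(NULL, "f1")),
                          features = f2)
  expect_equal(objective(c(TRUE, FALSE, FALSE), pr2)$total, 7 * 8)
  # probabilistic penalty vanishes exactly when certainty is met
  f3 <- list(feature_spec(1, "f1", target = 4, spf = 7,
                          probabilistic = TRUE, certainty = 0.9))
  pr3 <- planning_problem(1:6, cost = rep(0, 6),
                          amounts = matrix(1, 6, 1,
                                           dimnames = list(NULL, "f1")),
                          features = f3, prob_good = rep(0.95, 6))
  o_all <- objective(rep(TRUE, 6), pr3)
  expect_gte(o_all$prob_target_met[1], 0.9)
  expect_equal(o_all$penalty_probabilistic, 0)
  o_few <- objective(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), pr3)
  expect_lt(o_few$prob_target_met[1], 0.9)
  expect_gt(o_few$penalty_probabilistic, 0)
})

test_that("annealer: unique optimum found, deterministic, agrees with R objective", {
  # one unit holds every target at cost 1; all others are expensive
  m <- 2
  amounts <- rbind(c(5, 5), matrix(0.1, 9, 2))
  colnames(amounts) <- c("f1", "f2")
  feats <- list(feature_spec(1, "f1", 5, 50), feature_spec(2, "f2", 5, 50))
  pr <- planning_problem(1:10, cost = c(1, rep(10, 9)), amounts, feats)
  cfg <- anneal_config(n_iterations = 5000, n_solutions = 1, base_seed = 5)
  r <- anneal(pr, cfg, seed = 5)
  expect_identical(which(r$selection), 1L)
  # determinism
  r2 <- anneal(pr, cfg, seed = 5)
  expect_identical(r$selection, r2$selection)
  expect_equal(r$total, r2$total)
  # the C++ breakdown agrees with the independent R objective
  for (seed in 1:4) {
    prr <- random_problem(10, 3, seed = seed, prob_mode = TRUE)
    rr <- anneal(prr, anneal_config(n_iterations = 2000), seed = seed)
    oo <- objective(rr$selection, prr)
    expect_equal(rr$total, oo$total, tolerance = 1e-9)
    expect_equal(rr$cost, oo$cost, tolerance = 1e-9)
    expect_equal(rr$boundary, oo$boundary, tolerance = 1e-9)
    expect_equal(unname(rr$held), unname(oo$held), tolerance = 1e-9)
  }
})

test_that("best-of-ensemble matches the exhaustive optimum on small problems", {
  hits <- 0
  n_prob <- 6
  for (seed in seq_len(n_prob)) {
    pr <- random_problem(12, 3, seed = 100 + seed, prob_mode = (seed %% 2 == 0))
    cfg <- anneal_config(n_iterations = 3000, n_solutions = 20,
                         base_seed = 1000 + seed)
    ens <- solve_ensemble(pr, cfg)
    opt <- exhaustive_optimum(pr, cfg)
    if (abs(ens$best$total - opt) <= 1e-6 * max(1, abs(opt))) hits <- hits + 1
  }
  expect_gte(hits, n_prob - 1)
})

test_that("probabilistic mode reduces exactly to deterministic mode at p = 1", {
  for (seed in 1:5) {
    pr <- random_problem(10, 3, seed = 200 + seed, prob_mode = FALSE)
    expect_true(reduce_check_deterministic(
      pr, anneal_config(n_iterations = 2000), seed = seed))
  }
})

test_that("ensembles: frequency bounds, trivial problems, reproducibility", {
  pr <- random_problem(8, 2, seed = 9)
  cfg <- anneal_config(n_iterations = 1500, n_solutions = 12, base_seed = 77)
  ens <- solve_ensemble(pr, cfg)
  expect_true(all(ens$selection_frequency >= 0 &
                    ens$selection_frequency <= 12))
  ens2 <- solve_ensemble(pr, cfg)
  expect_identical(ens$selections, ens2$selections)
  expect_equal(ens$best_index, ens2$best_index)
  # single-run ensemble: frequency equals the selection
  cfg1 <- anneal_config(n_iterations = 1500, n_solutions = 1, base_seed = 3)
  e1 <- solve_ensemble(pr, cfg1)
  expect_equal(e1$selection_frequency, as.numeric(e1$best$selection))
  # a unit holding everything cheaply is selected in every run
  amounts <- rbind(c(5, 5), matrix(0, 7, 2))
  colnames(amounts) <- c("f1", "f2")
  feats <- list(feature_spec(1, "f1", 5, 50), feature_spec(2, "f2", 5, 50))
  pru <- planning_problem(1:8, cost = c(1, rep(10, 7)), amounts, feats)
  ensu <- solve_ensemble(pru, anneal_config(n_iterations = 2000,
                                            n_solutions = 10, base_seed = 4))
  expect_equal(ensu$selection_frequency[1], 10)
})

test_that("Marxan-dialect round trip preserves the problem", {
  pr <- random_problem(10, 3, seed = 11, prob_mode = TRUE)
  dir <- tempfile()
  write_marxan(pr, dir)
  expect_setequal(list.files(dir),
                  c("pu.dat", "spec.dat", "puvspr.dat", "bound.dat"))
  pr2 <- read_marxan(dir)
  expect_equal(pr2$cost, pr$cost)
  expect_equal(unname(pr2$amounts), unname(pr$amounts))
  expect_equal(pr2$prob_good, pr$prob_good)
  expect_equal(vapply(pr2$features, `[[`, numeric(1), "target"),
               vapply(pr$features, `[[`, numeric(1), "target"))
  expect_equal(vapply(pr2$features, `[[`, logical(1), "probabilistic"),
               vapply(pr$features, `[[`, logical(1), "probabilistic"))
  # identical objective under identical selections
  sel <- rep(c(TRUE, FALSE), 5)
  expect_equal(objective(sel, pr2)$total, objective(sel, pr)$total)
})
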