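test_that("build_lp assembles objective, bounds and steady-state constraints", {
  m <- make_chain(1, 10)
  p <- build_lp(m)
  expect_identical(unname(p$obj), c(0, 0, 1))
  expect_identical(p$sense, "max")
  expect_identical(p$b, c(0, 0))
  expect_identical(p$lb, rep(0, 3))
  expect_identical(p$ub, c(10, 1000, 1000))

  # explicit objective overrides the model coefficients
  p2 <- build_lp(m, objective = c(EX_S_e = 2))
  expect_identical(unname(p2$obj), c(2, 0, 0))

  noobj <- make_chain(1, 10)
  noobj$reactions$objective_coefficient <- 0
  expect_error(build_lp(noobj), "no objective")
})

test_that("solve_lp reports optimal, infeasible and unbounded faithfully", {
  m <- make_chain(1, 10)
  s <- solve_lp(build_lp(m))
  expect_identical(s$status, "optimal")
  expect_equal(s$objective_value, 10, tolerance = 1e-9)
  # steady state and bounds hold at the vertex
  S <- as.matrix(stoichiometry_matrix(m))
  expect_lt(max(abs(S %*% s$fluxes)), 1e-6)
  expect_true(all(s$fluxes >= m$reactions$lower_bound - 1e-6))
  expect_true(all(s$fluxes <= m$reactions$upper_bound + 1e-6))

  # demanding more export than the uptake admits violates conservation
  starved <- change_bounds(m, "EX_P_e", lower = 11)
  expect_identical(solve_lp(build_lp(starved))$status, "infeasible")

  # a two-reaction loop with no finite cap is unbounded
  loop <- metabolic_model(
    id = "loop", metabolites = c("A", "B"),
    reactions = data.frame(id = c("f", "r"), upper_bound = Inf,
                           objective_coefficient = c(1, 0)),
    stoichiometry = list(f = c(A = -1, B = 1), r = c(B = -1, A = 1)))
  expect_identical(solve_lp(build_lp(loop))$status, "unbounded")
})

test_that("fba composes modifications on a private copy", {
  m <- make_branched(10, 1, 0.5, gene_gating = TRUE)
  snapshot <- serialize(m, NULL)
  expect_equal(fba(m)$objective_value, 10, tolerance = 1e-8)
  expect_equal(fba(m, list(mod_bounds("EX_S_e", 0, 0)))$objective_value, 0,
               tolerance = 1e-8)
  # efficient branch knocked out: flux reroutes at half yield
  expect_equal(fba(m, list(mod_knockout("gP")))$objective_value, 5,
               tolerance = 1e-8)
  expect_identical(serialize(m, NULL), snapshot)
})

test_that("diamond optimum is bound by uptake regardless of route split", {
  s <- solve_lp(build_lp(make_diamond(10)))
  expect_equal(s$objective_value, 10, tolerance = 1e-9)
  o <- oracle_fba(make_diamond(10))
  expect_equal(s$objective_value, o$objective, tolerance = 1e-9)
})

test_that("fba matches the independent LP oracle on random fixtures", {
  for (seed in 1:40) {
    m <- make_random_viable(n_pathways = 1 + seed %% 5,
                            pathway_len = 1 + seed %% 4, seed = seed)
    mine <- fba(m)
    ora <- oracle_fba(m)
    expect_identical(mine$status, "optimal")
    expect_equal(mine$objective_value, ora$objective,
                 tolerance = 1e-6, label = paste("seed", seed))
    expect_equal(mine$objective_value, m$annotations$fixture$optimum,
                 tolerance = 1e-6)
  }
})

test_that("restrictions never increase the maximized objective", {
  set.seed(99)
  for (trial in 1:10) {
    m <- make_random_viable(4, 3, seed = trial + 100)
    z <- fba(m)$objective_value
    for (step in 1:5) {
      k <- sample(n_reactions(m), 1)
      r <- m$reactions[k, ]
      new_ub <- r$upper_bound * stats::runif(1)
      m <- change_bounds(m, r$id, upper = max(r$lower_bound, new_ub))
      s <- fba(m)
      z_new <- if (identical(s$status, "optimal")) s$objective_value else 0
      expect_lte(z_new, z + 1e-6)
      z <- z_new
    }
  }
})

test_that("column permutation leaves the optimum unchanged", {
  m <- make_random_viable(4, 4, seed = 77)
  p <- build_lp(m)
  z <- solve_lp(p)$objective_value
  set.seed(7)
  for (trial in 1:5) {
    perm <- sample(length(p$obj))
    q <- p
    q$A <- p$A[, perm]
    q$obj <- p$obj[perm]
    q$lb <- p$lb[perm]
    q$ub <- p$ub[perm]
    q$reaction_ids <- p$reaction_ids[perm]
    expect_equal(solve_lp(q)$objective_value, z, tolerance = 1e-9)
  }
})
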