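test_that("a single member with an open environment reproduces its optimum", {
  ch <- make_chain(1, 10)
  comm <- join_models(community_spec(
    members = list(community_member("x", ch, 1)),
    shared_metabolites = "S"))
  obj <- community_objective(comm, c(x = "EX_P_e"))
  expect_identical(names(obj), "x#EX_P_e")
  expect_equal(unname(obj), 1)
  expect_equal(fba(comm, objective = obj)$objective_value,
               fba(ch)$objective_value, tolerance = 1e-6)
  # and against the independent LP path on the joined model
  expect_equal(fba(comm, objective = obj)$objective_value,
               oracle_solve(comm, obj)$objective, tolerance = 1e-6)
})

test_that("two members share a limited substrate through the environment", {
  ch <- make_chain(1, 10)
  comm <- join_models(community_spec(
    members = list(community_member("a", ch, 1), community_member("b", ch, 1)),
    shared_metabolites = "S",
    environment_bounds = list(S = c(-10, 0))))
  obj <- community_objective(comm, c(a = "EX_P_e", b = "EX_P_e"))
  expect_equal(unname(obj), c(0.5, 0.5))
  s <- fba(comm, objective = obj)
  expect_equal(s$objective_value, 10, tolerance = 1e-6)
  expect_equal(s$objective_value, oracle_solve(comm, obj)$objective,
               tolerance = 1e-6)
  # conservation holds on environment rows too
  S <- as.matrix(stoichiometry_matrix(comm))
  expect_lt(max(abs(S %*% s$fluxes)), 1e-6)
})

test_that("the community matrix is block-diagonal plus environment coupling", {
  ch <- make_chain(2, 10)
  comm <- join_models(community_spec(
    members = list(community_member("a", ch, 2), community_member("b", ch, 1)),
    shared_metabolites = "S",
    environment_bounds = list(S = c(-10, 0))))
  S <- as.matrix(stoichiometry_matrix(comm))
  env_rows <- grepl("_env$", rownames(S))
  env_cols <- grepl("^EX_.*_env$", colnames(S))
  for (mem in c("a", "b")) {
    rows <- startsWith(rownames(S), paste0(mem, "#"))
    cols <- startsWith(colnames(S), paste0(mem, "#"))
    # member rows touch only member columns ...
    expect_true(all(S[rows, !cols] == 0))
    # ... and member columns touch nothing outside member + environment rows
    expect_true(all(S[!(rows | env_rows), cols] == 0))
  }
  # abundance scaling on the environment side: 2:1 normalized to 2/3, 1/3
  expect_equal(unname(S["S_env", "a#EX_S_e"]), -2 / 3, tolerance = 1e-12)
  expect_equal(unname(S["S_env", "b#EX_S_e"]), -1 / 3, tolerance = 1e-12)
  expect_true(all(S[env_rows, env_cols] == -1))
})

test_that("relaxing environment uptake never decreases the optimum", {
  ch <- make_chain(1, 10)
  prev <- -Inf
  for (cap in c(0, 2, 5, 10, 50)) {
    comm <- join_models(community_spec(
      members = list(community_member("a", ch, 1), community_member("b", ch, 1)),
      shared_metabolites = "S",
      environment_bounds = list(S = c(-cap, 0))))
    z <- fba(comm,
             objective = community_objective(comm, c(a = "EX_P_e", b = "EX_P_e")))
    expect_identical(z$status, "optimal")
    expect_gte(z$objective_value, prev - 1e-7)
    prev <- z$objective_value
  }
  expect_equal(prev, 10, tolerance = 1e-6)  # member uptakes cap out at 10 each
})

test_that("joining validates ids, abundances and exchanges", {
  ch <- make_chain(1, 10)
  expect_error(community_member("a#b", ch), "#")
  expect_error(community_spec(list(community_member("a", ch, 0)), "S"),
               "positive")
  expect_error(community_spec(list(community_member("a", ch),
                                   community_member("a", ch)), "S"),
               "duplicate member")
  # a member without an exchange for the shared metabolite is named
  expect_error(join_models(community_spec(
    list(community_member("a", ch)), shared_metabolites = "Q")),
    "'a'.*'Q'")
  # zero-weight member stays in the model but out of the objective
  comm <- join_models(community_spec(
    list(community_member("a", ch, 1), community_member("b", ch, 0)),
    shared_metabolites = "S"))
  obj <- community_objective(comm, c(a = "EX_P_e", b = "EX_P_e"))
  expect_identical(names(obj), "a#EX_P_e")
  expect_true("b#EX_P_e" %in% reaction_ids(comm))
})
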