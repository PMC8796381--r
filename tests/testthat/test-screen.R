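test_that("variants apply descriptors left-to-right on a private copy", {
  m <- make_branched(10, 1, 0.5, gene_gating = TRUE)
  snapshot <- serialize(m, NULL)

  v <- variant("combo", mod_knockout("gP"), mod_bounds("EX_S_e", 0, 5))
  out <- apply_variant(m, v)
  expect_identical(unname(unlist(
    out$reactions[match("PCONV", out$reactions$id),
                  c("lower_bound", "upper_bound")])), c(0, 0))
  expect_identical(out$reactions$upper_bound[match("EX_S_e", out$reactions$id)], 5)

  # empty variant is the identity; base model never aliased
  expect_identical(apply_variant(m, variant("id")), m)
  expect_identical(serialize(m, NULL), snapshot)

  # last write wins when descriptors touch the same reaction
  v1 <- variant("bounds then ko", mod_bounds("PCONV", 0, 5), mod_knockout("gP"))
  expect_identical(
    apply_variant(m, v1)$reactions$upper_bound[match("PCONV", m$reactions$id)], 0)
  v2 <- variant("ko then bounds", mod_knockout("gP"), mod_bounds("PCONV", 0, 5))
  expect_identical(
    apply_variant(m, v2)$reactions$upper_bound[match("PCONV", m$reactions$id)], 5)

  # errors carry the variant label
  expect_error(apply_variant(m, variant("bad", mod_knockout("gNOPE"))), "bad")
  # objective replacement
  obj <- apply_variant(m, variant("w", mod_objective(c(EX_W_e = 1))))
  expect_identical(obj$reactions$objective_coefficient,
                   as.numeric(m$reactions$id == "EX_W_e"))
})

test_that("variant grids enumerate the Cartesian product in row-major order", {
  ax1 <- list(variant("a1"), variant("a2"))
  ax2 <- list(variant("b1"), variant("b2"), variant("b3"))
  g <- variant_grid(list(ax1, ax2))
  expect_identical(g$shape, c(2L, 3L))
  expect_identical(vapply(g$variants, function(v) v$label, character(1)),
                   c("a1 + b1", "a1 + b2", "a1 + b3",
                     "a2 + b1", "a2 + b2", "a2 + b3"))

  g1 <- variant_grid(list(ax2))
  expect_identical(g1$shape, 3L)

  g3 <- variant_grid(list(ax1, ax1, ax1))
  expect_identical(g3$shape, c(2L, 2L, 2L))
  expect_identical(length(g3$variants), 8L)
  expect_identical(g3$variants[[2]]$label, "a1 + a1 + a2")  # last axis fastest

  expect_error(variant_grid(list()), "non-empty")
  expect_error(variant_grid(list(ax1, list())), "non-empty")
})

test_that("screening a knockout axis reproduces per-cell direct FBA", {
  m <- make_branched(10, 1, 0.5, gene_gating = TRUE)
  r <- screen(m, list(list(variant("wt"), variant("koP", mod_knockout("gP")))),
              analysis = "fba_objective")
  expect_identical(r$shape, 2L)
  expect_equal(unlist(r$values), c(10, 5), tolerance = 1e-7)
  expect_identical(as.character(r$labels), c("wt", "koP"))
  # per-cell oracle
  expect_equal(unlist(r$values)[2],
               oracle_fba(apply_knockout(m, "gP"))$objective, tolerance = 1e-6)

  # identity embedding: a singleton empty variant equals the direct analysis
  direct <- fva(m, gamma = 1)
  via_screen <- screen(m, list(list(variant("wt"))), analysis = "fva",
                       args = list(gamma = 1))
  expect_identical(via_screen$values[[1]], direct)
})

test_that("the knockout-FVA composition matches the brute-force oracle", {
  m <- make_branched(10, 1, 0.5, gene_gating = TRUE)
  r <- screen(m, list(list(variant("wt"), variant("koP", mod_knockout("gP")))),
              analysis = "fva", args = list(gamma = 1))
  ko_fva <- r$values[[2]]
  # knockout pins the efficient branch to zero at the knockout's own optimum
  expect_equal(ko_fva$minimum[match("PCONV", ko_fva$reaction)], 0,
               tolerance = 1e-7)
  expect_equal(ko_fva$maximum[match("PCONV", ko_fva$reaction)], 0,
               tolerance = 1e-7)
  ora <- oracle_fva(apply_knockout(m, "gP"), gamma = 1)
  expect_equal(ko_fva$minimum, ora$minimum, tolerance = 1e-6)
  expect_equal(ko_fva$maximum, ora$maximum, tolerance = 1e-6)
})

test_that("screens are deterministic across worker counts and runs", {
  m <- make_random_viable(4, 3, seed = 17)
  genes <- gene_ids(m)[1:4]
  axes <- list(
    c(list(variant("wt")),
      lapply(genes, function(g) variant(paste0("ko_", g), mod_knockout(g)))),
    list(variant("open", mod_bounds("EX_S_e", 0, 1000)),
         variant("cap3", mod_bounds("EX_S_e", 0, 3)))
  )
  snapshot <- serialize(m, NULL)
  r1 <- screen(m, axes, "fba_objective", workers = 1)
  r2 <- screen(m, axes, "fba_objective", workers = 2)
  r4 <- screen(m, axes, "fba_objective", workers = 4)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_identical(serialize(r1, NULL), serialize(r4, NULL))
  expect_identical(serialize(r1, NULL),
                   serialize(screen(m, axes, "fba_objective", workers = 1), NULL))
  expect_identical(dim(r1$values), c(5L, 2L))
  expect_identical(sum(lengths(r1$values) > 0), 10L)  # no missing cells
  # base model untouched by the whole campaign
  expect_identical(serialize(m, NULL), snapshot)
  # capped column can never beat the open column
  vals <- array(unlist(r1$values), dim = dim(r1$values))
  expect_true(all(vals[, 2] <= vals[, 1] + 1e-6))
})

test_that("screen_fallible stores structured errors instead of aborting", {
  m <- make_branched(10, 1, 0.5, gene_gating = TRUE)
  axes <- list(list(variant("wt"), variant("bad", mod_knockout("gNOPE")),
                    variant("koP", mod_knockout("gP"))))
  expect_error(screen(m, axes, "fba_objective"), "bad")
  expect_warning(r <- screen_fallible(m, axes, "fba_objective"),
                 "1 of 3")
  expect_equal(r$values[[1]], 10, tolerance = 1e-7)
  err <- r$values[[2]]
  expect_s3_class(err, "screen_error")
  expect_identical(err$variant, "bad")
  expect_equal(r$values[[3]], 5, tolerance = 1e-7)

  # no failures: identical to the strict screen
  ok_axes <- list(list(variant("wt"), variant("koP", mod_knockout("gP"))))
  expect_identical(serialize(screen_fallible(m, ok_axes, "fba_objective"), NULL),
                   serialize(screen(m, ok_axes, "fba_objective"), NULL))

  expect_error(screen(m, ok_axes, "not_registered"), "no analysis registered")
})

test_that("user-registered analyses run through the same machinery", {
  register_analysis("uptake_flux", function(model, rxn) {
    s <- fba(model)
    unname(s$fluxes[rxn])
  })
  m <- make_chain(1, 10)
  r <- screen(m, list(list(variant("wt"),
                           variant("cap4", mod_bounds("EX_S_e", 0, 4)))),
              analysis = "uptake_flux", args = list(rxn = "EX_S_e"))
  expect_equal(unlist(r$values), c(10, 4), tolerance = 1e-7)
  expect_true("uptake_flux" %in% list_analyses())
})
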