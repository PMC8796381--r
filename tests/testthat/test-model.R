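chain2 <- function() {
  metabolic_model(
    id = "chain2",
    metabolites = c("A", "B"),
    reactions = data.frame(id = c("r1", "r2", "r3"),
                           upper_bound = c(10, 1000, 1000),
                           objective_coefficient = c(0, 0, 1)),
    stoichiometry = list(r1 = c(A = 1), r2 = c(A = -1, B = 1), r3 = c(B = -1)))
}

test_that("stoichiometry matrix transcribes reaction dictionaries", {
  S <- stoichiometry_matrix(chain2())
  expect_identical(dim(S), c(2L, 3L))
  expect_equal(as.matrix(S),
               matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE,
                      dimnames = list(c("A", "B"), c("r1", "r2", "r3"))))

  empty <- metabolic_model(id = "m0", metabolites = c("A", "B"), check = FALSE)
  expect_identical(dim(stoichiometry_matrix(empty)), c(2L, 0L))
})

test_that("matrix columns reproduce every reaction dictionary exactly", {
  m <- make_random_viable(6, 5, seed = 11)
  S <- as.matrix(stoichiometry_matrix(m))
  for (k in seq_len(n_reactions(m))) {
    col <- S[, k]
    rebuilt <- col[col != 0]
    expect_identical(sort(names(rebuilt)), sort(names(m$stoichiometry[[k]])))
    expect_equal(rebuilt[names(m$stoichiometry[[k]])],
                 m$stoichiometry[[k]], tolerance = 0)
  }
})

test_that("change_bounds edits a copy and checks its inputs", {
  m <- chain2()
  snapshot <- serialize(m, NULL)
  m2 <- change_bounds(m, "r2", 0, 0)
  expect_identical(m2$reactions$lower_bound[2], 0)
  expect_identical(m2$reactions$upper_bound[2], 0)
  # all other reactions untouched, source model byte-identical
  expect_identical(m2$reactions[-2, ], m$reactions[-2, ])
  expect_identical(serialize(m, NULL), snapshot)

  m3 <- change_bounds(m, "r1", lower = -5)
  expect_identical(unname(unlist(m3$reactions[1, c("lower_bound", "upper_bound")])),
                   c(-5, 10))
  expect_error(change_bounds(m, "r2", 1, -1), "inverted")
  expect_error(change_bounds(m, "nope", 0, 0), "unknown reaction")
})

test_that("apply_knockout zeroes gated reactions and is idempotent", {
  m <- make_branched(10, 1, 0.5, gene_gating = TRUE, isozyme = TRUE)
  snapshot <- serialize(m, NULL)

  ko <- apply_knockout(m, "gU")
  k <- match("UPT", ko$reactions$id)
  expect_identical(unname(unlist(ko$reactions[k, c("lower_bound", "upper_bound")])),
                   c(0, 0))

  # isozyme survives a single knockout
  iso <- apply_knockout(m, "gP")
  expect_identical(iso$reactions, m$reactions)

  both <- apply_knockout(m, c("gP", "gP2"))
  k <- match("PCONV", both$reactions$id)
  expect_identical(unname(unlist(both$reactions[k, c("lower_bound", "upper_bound")])),
                   c(0, 0))

  # idempotent; empty knockout is the identity; source unchanged
  expect_identical(apply_knockout(both, c("gP", "gP2")), both)
  expect_identical(apply_knockout(m, character(0)), m)
  expect_identical(serialize(m, NULL), snapshot)
  expect_error(apply_knockout(m, "gNOPE"), "unknown gene")
})

test_that("validate_model reports structural problems without throwing", {
  expect_identical(nrow(validate_model(chain2())$errors), 0L)
  expect_identical(nrow(validate_model(chain2())$warnings), 0L)

  bad <- chain2()
  bad$stoichiometry$r2 <- c(A = -1, X = 1)
  rep <- validate_model(bad)
  expect_true("dangling_metabolite" %in% rep$errors$code)

  orphan <- metabolic_model(id = "o", metabolites = c("A", "B", "unused"),
                            reactions = data.frame(id = "r1"),
                            stoichiometry = list(r1 = c(A = -1, B = 1)),
                            check = FALSE)
  rep <- validate_model(orphan)
  expect_identical(nrow(rep$errors), 0L)
  expect_true("orphan_metabolite" %in% rep$warnings$code)

  dup <- chain2()
  dup$metabolites <- rbind(dup$metabolites, dup$metabolites[1, ])
  expect_true("duplicate_id" %in% validate_model(dup)$errors$code)

  inv <- chain2()
  inv$reactions$lower_bound[1] <- 5
  inv$reactions$upper_bound[1] <- 4
  expect_true("inverted_bounds" %in% validate_model(inv)$errors$code)

  gpr_bad <- make_branched(gene_gating = TRUE)
  gpr_bad$genes <- gpr_bad$genes[gpr_bad$genes$id != "gP", ]
  expect_true("dangling_gene" %in% validate_model(gpr_bad)$errors$code)
})
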