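test_that("parser builds the expected trees with and/or precedence", {
  r <- parse_gpr("g1 and g2")
  expect_identical(r$op, "and")
  expect_identical(vapply(r$args, `[[`, "", "gene"), c("g1", "g2"))

  # and binds tighter than or
  r <- parse_gpr("g1 or g2 and g3")
  expect_identical(r$op, "or")
  expect_identical(r$args[[1]]$gene, "g1")
  expect_identical(r$args[[2]]$op, "and")

  r <- parse_gpr("(g1 or g2) and (g3 or g4)")
  expect_identical(r$op, "and")
  expect_identical(vapply(r$args, `[[`, "", "op"), c("or", "or"))

  # whitespace-insensitive, case-insensitive keywords
  expect_identical(parse_gpr("  g1   AND g2 "), parse_gpr("g1 and g2"))

  # blank text is the always-satisfied rule
  expect_identical(parse_gpr("")$op, "true")
  expect_identical(parse_gpr("   ")$op, "true")
  expect_true(eval_gpr(parse_gpr(""), c("g1", "g2")))
})

test_that("malformed rules fail with a character offset", {
  expect_error(parse_gpr("g1 and (g2 or g3"), "character 8")
  expect_error(parse_gpr("g1 and"), "character 7")
  expect_error(parse_gpr("and g1"), "character 1")
  expect_error(parse_gpr("g1 g2"), "character 4")
})

test_that("evaluation matches the documented semantics", {
  r <- parse_gpr("g1 and g2 or g3")      # OR(AND(g1,g2), g3)
  expect_true(eval_gpr(r, "g1"))          # g3 keeps the reaction alive
  expect_false(eval_gpr(parse_gpr("g1 and g2"), "g2"))
  expect_true(eval_gpr(r, character(0)))  # no knockouts: always true
})

test_that("eval_gpr equals brute-force truth-table evaluation on random rules", {
  # independent evaluator: translate to an R logical expression and eval()
  to_expr <- function(rule) {
    switch(rule$op,
      "true" = "TRUE",
      "gene" = rule$gene,
      "and" = paste0("(", paste(vapply(rule$args, to_expr, ""),
                                collapse = " & "), ")"),
      "or" = paste0("(", paste(vapply(rule$args, to_expr, ""),
                               collapse = " | "), ")"))
  }
  random_rule_text <- function(genes, depth = 0) {
    if (depth > 2 || stats::runif(1) < 0.4) {
      return(sample(genes, 1))
    }
    op <- sample(c(" and ", " or "), 1)
    k <- sample(2:3, 1)
    kids <- vapply(seq_len(k), function(i) {
      random_rule_text(genes, depth + 1)
    }, character(1))
    paste0("(", paste(kids, collapse = op), ")")
  }

  set.seed(421)
  for (trial in 1:25) {
    g <- sample(2:6, 1)
    genes <- paste0("g", seq_len(g))
    text <- random_rule_text(genes)
    rule <- parse_gpr(text)
    expr <- parse(text = to_expr(rule))
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), g))
    names(grid) <- genes
    for (row in seq_len(nrow(grid))) {
      present <- as.logical(grid[row, ])
      absent <- genes[!present]
      expect_identical(eval_gpr(rule, absent),
                       eval(expr, envir = as.list(grid[row, ])))
    }
  }
})

test_that("deparse and parse are mutually inverse on parsed trees", {
  for (text in c("g1", "g1 and g2 and g3", "g1 or g2 and g3",
                 "(g1 or g2) and (g3 or g4)",
                 "((g1 and g2) or g3) and g4", "")) {
    rule <- parse_gpr(text)
    expect_identical(parse_gpr(deparse_gpr(rule)), rule)
  }
  expect_setequal(gpr_genes(parse_gpr("(g1 or g2) and g1 and g3")),
                  c("g1", "g2", "g3"))
})
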