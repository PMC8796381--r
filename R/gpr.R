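#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers that states which
#' gene products must be present for a reaction to carry flux. `parse_gpr()`
#' turns the conventional string form (`"g1 and (g2 or g3)"`) into an
#' expression tree; `eval_gpr()` evaluates a tree against a set of absent
#' (knocked-out) genes; `deparse_gpr()` renders the canonical string form;
#' `gpr_genes()` lists the gene identifiers a rule references.
#'
#' The grammar follows the dominant COBRA convention: identifiers are maximal
#' runs of non-whitespace characters excluding parentheses; the keywords
#' `and` / `or` are case-insensitive; `and` binds tighter than `or`;
#' parentheses group. There is no negation. An empty or blank string is the
#' distinguished always-satisfied rule (the reaction is not gene-gated).
#'
#' Consecutive applications of the same operator are flattened into a single
#' n-ary node, so `parse_gpr(deparse_gpr(x))` is the identity on parsed trees.
#'
#' @param text GPR rule string.
#' @param rule A `gpr_rule` object.
#' @param absent_genes Character vector of knocked-out gene identifiers.
#' @return `parse_gpr()` returns an object of class `gpr_rule`: a list with
#'   element `op` (one of `"gene"`, `"and"`, `"or"`, `"true"`), plus `gene`
#'   for leaves or `args` (a list of child rules) for internal nodes.
#'   `eval_gpr()` returns a single logical: `TRUE` when the reaction remains
#'   available. `deparse_gpr()` returns the canonical string (`""` for the
#'   always-true rule).
#' @examples
#' r <- parse_gpr("g1 or g2 and g3")
#' deparse_gpr(r)           # "g1 or g2 and g3" (and binds tighter)
#' eval_gpr(r, "g1")        # TRUE: g2 and g3 still present
#' eval_gpr(r, c("g1", "g3"))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(gpr_true())
  }
  toks <- gpr_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  rule <- gpr_parse_or(state, text)
  if (state$pos <= length(toks$type)) {
    stop(sprintf("GPR parse error at character %d in %s: unexpected '%s'",
                 toks$offset[state$pos], sQuote(text), toks$value[state$pos]),
         call. = FALSE)
  }
  rule
}

gpr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  type <- character(0); value <- character(0); offset <- integer(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      type <- c(type, ch); value <- c(value, ch); offset <- c(offset, i)
      i <- i + 1L
      next
    }
    start <- i
    while (i <= n && !grepl("^\\s$", chars[i]) && chars[i] != "(" && chars[i] != ")") {
      i <- i + 1L
    }
    word <- paste(chars[start:(i - 1L)], collapse = "")
    lw <- tolower(word)
    if (lw == "and" || lw == "or") {
      type <- c(type, lw); value <- c(value, word)
    } else {
      type <- c(type, "id"); value <- c(value, word)
    }
    offset <- c(offset, start)
  }
  list(type = type, value = value, offset = offset)
}

gpr_peek <- function(state) {
  if (state$pos > length(state$toks$type)) NA_character_ else state$toks$type[state$pos]
}

gpr_parse_or <- function(state, text) {
  args <- list(gpr_parse_and(state, text))
  while (identical(gpr_peek(state), "or")) {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_and(state, text)))
  }
  if (length(args) == 1L) args[[1L]] else gpr_node("or", args)
}

gpr_parse_and <- function(state, text) {
  args <- list(gpr_parse_atom(state, text))
  while (identical(gpr_peek(state), "and")) {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_atom(state, text)))
  }
  if (length(args) == 1L) args[[1L]] else gpr_node("and", args)
}

gpr_parse_atom <- function(state, text) {
  tk <- gpr_peek(state)
  off <- if (state$pos <= length(state$toks$offset)) {
    state$toks$offset[state$pos]
  } else {
    nchar(text) + 1L
  }
  if (is.na(tk)) {
    stop(sprintf("GPR parse error at character %d in %s: unexpected end of rule",
                 off, sQuote(text)), call. = FALSE)
  }
  if (tk == "(") {
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state, text)
    if (!identical(gpr_peek(state), ")")) {
      stop(sprintf("GPR parse error at character %d in %s: unbalanced parenthesis",
                   off, sQuote(text)), call. = FALSE)
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  if (tk == "id") {
    gene <- state$toks$value[state$pos]
    state$pos <- state$pos + 1L
    return(gpr_leaf(gene))
  }
  stop(sprintf("GPR parse error at character %d in %s: dangling operator '%s'",
               off, sQuote(text), state$toks$value[state$pos]), call. = FALSE)
}

gpr_true <- function() structure(list(op = "true"), class = "gpr_rule")

gpr_leaf <- function(gene) structure(list(op = "gene", gene = gene), class = "gpr_rule")

# n-ary node; children with the same operator are flattened
gpr_node <- function(op, args) {
  flat <- list()
  for (a in args) {
    if (identical(a$op, op)) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  structure(list(op = op, args = flat), class = "gpr_rule")
}

#' @rdname parse_gpr
#' @export
eval_gpr <- function(rule, absent_genes = character(0)) {
  stopifnot(inherits(rule, "gpr_rule"))
  switch(rule$op,
    "true" = TRUE,
    "gene" = !(rule$gene %in% absent_genes),
    "and"  = all(vapply(rule$args, eval_gpr, logical(1), absent_genes = absent_genes)),
    "or"   = any(vapply(rule$args, eval_gpr, logical(1), absent_genes = absent_genes)),
    stop("corrupt gpr_rule node: ", rule$op)
  )
}

#' @rdname parse_gpr
#' @export
deparse_gpr <- function(rule) {
  stopifnot(inherits(rule, "gpr_rule"))
  switch(rule$op,
    "true" = "",
    "gene" = rule$gene,
    "and"  = paste(vapply(rule$args, function(a) {
      s <- deparse_gpr(a)
      if (identical(a$op, "or")) paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    "or"   = paste(vapply(rule$args, deparse_gpr, character(1)), collapse = " or ")
  )
}

#' @rdname parse_gpr
#' @export
gpr_genes <- function(rule) {
  stopifnot(inherits(rule, "gpr_rule"))
  switch(rule$op,
    "true" = character(0),
    "gene" = rule$gene,
    unique(unlist(lapply(rule$args, gpr_genes)))
  )
}

#' @export
print.gpr_rule <- function(x, ...) {
  s <- deparse_gpr(x)
  cat("<gpr_rule> ", if (nzchar(s)) s else "(always satisfied)", "\n", sep = "")
  invisible(x)
}
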