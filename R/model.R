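#' Construct a metabolic model
#'
#' A `metabolic_model` represents an organism's metabolism as a constrained
#' linear system: a set of metabolites (the rows of the stoichiometric
#' matrix), a set of reactions with flux bounds and sparse stoichiometry (the
#' columns), a gene list, and per-reaction boolean gene-protein-reaction
#' (GPR) rules gating reaction availability. All editing functions return
#' modified copies; a model is never mutated in place, which is what makes it
#' safe to screen many variants of the same base model concurrently.
#'
#' @param id Model identifier string.
#' @param metabolites Data frame with columns `id` (required, unique,
#'   non-empty) and optionally `name`, `compartment`, `formula`, `charge`.
#'   A bare character vector of ids is also accepted.
#' @param reactions Data frame with columns `id` (required, unique) and
#'   optionally `name`, `lower_bound`, `upper_bound` (defaults `0` and
#'   `1000`, the conventional irreversible bounds in mmol/gDW/h),
#'   `objective_coefficient` (default `0`) and `gpr` (GPR rule string,
#'   default `""` = not gene-gated).
#' @param stoichiometry Named list, one entry per reaction id, each a named
#'   numeric vector mapping metabolite id to coefficient (negative =
#'   consumed, positive = produced). Reactions without an entry have empty
#'   stoichiometry.
#' @param genes Data frame with columns `id` and optionally `name`, or a
#'   character vector of gene ids. Defaults to the genes referenced by the
#'   GPR rules.
#' @param annotations Arbitrary string-keyed list carried along with the
#'   model (and preserved through JSON round trips).
#' @param check If `TRUE` (default) run [validate_model()] and stop on
#'   structural errors.
#' @return An object of class `metabolic_model`.
#' @examples
#' m <- metabolic_model(
#'   id = "chain",
#'   metabolites = c("A", "B"),
#'   reactions = data.frame(
#'     id = c("r1", "r2", "r3"),
#'     upper_bound = c(10, 1000, 1000),
#'     objective_coefficient = c(0, 0, 1)
#'   ),
#'   stoichiometry = list(r1 = c(A = 1), r2 = c(A = -1, B = 1), r3 = c(B = -1))
#' )
#' stoichiometry_matrix(m)
#' @seealso [validate_model()], [stoichiometry_matrix()], [change_bounds()],
#'   [apply_knockout()], [read_model()]
#' @export
metabolic_model <- function(id = "model", metabolites = character(0),
                            reactions = NULL, stoichiometry = list(),
                            genes = NULL, annotations = list(),
                            check = TRUE) {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites, stringsAsFactors = FALSE)
  }
  metabolites <- fill_columns(metabolites, list(
    id = character(0), name = NA_character_, compartment = NA_character_,
    formula = NA_character_, charge = NA_real_))

  if (is.null(reactions)) {
    reactions <- data.frame(id = character(0), stringsAsFactors = FALSE)
  }
  reactions <- fill_columns(reactions, list(
    id = character(0), name = NA_character_, lower_bound = 0,
    upper_bound = 1000, objective_coefficient = 0, gpr = ""))

  stoich <- setNames(vector("list", nrow(reactions)), reactions$id)
  for (rid in names(stoichiometry)) {
    s <- stoichiometry[[rid]]
    s <- setNames(as.numeric(s), names(s))  # normalize integer coefficients
    stoich[[rid]] <- s[s != 0]
  }
  for (i in seq_along(stoich)) {
    if (is.null(stoich[[i]])) stoich[[i]] <- setNames(numeric(0), character(0))
  }

  if (is.null(genes)) {
    gids <- unique(unlist(lapply(reactions$gpr, function(g) gpr_genes(parse_gpr(g)))))
    genes <- data.frame(id = as.character(gids %||% character(0)),
                        stringsAsFactors = FALSE)
  } else if (is.character(genes)) {
    genes <- data.frame(id = genes, stringsAsFactors = FALSE)
  }
  genes <- fill_columns(genes, list(id = character(0), name = NA_character_))

  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoichiometry = stoich, genes = genes, annotations = annotations),
    class = "metabolic_model")
  if (check) {
    rep <- validate_model(model)
    if (nrow(rep$errors) > 0) {
      stop("invalid metabolic model:\n",
           paste0("  [", rep$errors$code, "] ", rep$errors$message,
                  collapse = "\n"), call. = FALSE)
    }
  }
  model
}

fill_columns <- function(df, defaults) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  for (col in names(defaults)) {
    if (!col %in% names(df)) {
      df[[col]] <- rep(defaults[[col]], length.out = max(n, 0L))
    }
  }
  rownames(df) <- NULL
  df[names(defaults)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metabolic_model <- function(x, ...) {
  n_obj <- sum(x$reactions$objective_coefficient != 0)
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   genes: ", nrow(x$genes), "\n", sep = "")
  if (n_obj > 0) {
    cat("  objective: ",
        paste(x$reactions$id[x$reactions$objective_coefficient != 0],
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Model accessors
#'
#' Small helpers returning the identifier vectors and counts of a model, and
#' the model-level objective as a named coefficient vector over reactions.
#'
#' @param model A [metabolic_model()].
#' @return Character vectors of ids, integer counts, or a named numeric
#'   objective vector.
#' @export
reaction_ids <- function(model) model$reactions$id

#' @rdname reaction_ids
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' @rdname reaction_ids
#' @export
gene_ids <- function(model) model$genes$id

#' @rdname reaction_ids
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname reaction_ids
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' @rdname reaction_ids
#' @export
objective_vector <- function(model) {
  setNames(model$reactions$objective_coefficient, model$reactions$id)
}

#' Assemble the stoichiometric matrix
#'
#' Builds the sparse stoichiometric matrix S of a model: one row per
#' metabolite and one column per reaction (both in model order), with entry
#' (i, j) the coefficient of metabolite i in reaction j. Metabolite/reaction
#' pairs not participating are structural zeros. At steady state the flux
#' vector v satisfies `S %*% v = 0`.
#'
#' @param model A valid [metabolic_model()].
#' @return A `dgCMatrix` (sparse) with metabolite ids as row names and
#'   reaction ids as column names.
#' @export
stoichiometry_matrix <- function(model) {
  rep <- validate_model(model)
  if (nrow(rep$errors) > 0) {
    stop("invalid metabolic model: ",
         paste0("[", rep$errors$code, "] ", rep$errors$message,
                collapse = "; "), call. = FALSE)
  }
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  met_index <- setNames(seq_len(m), model$metabolites$id)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_len(n)) {
    s <- model$stoichiometry[[k]]
    if (length(s) == 0) next
    i <- c(i, met_index[names(s)])
    j <- c(j, rep.int(k, length(s)))
    x <- c(x, unname(s))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(m, n),
                       dimnames = list(model$metabolites$id,
                                       model$reactions$id))
}

#' Change the flux bounds of a reaction
#'
#' Returns a copy of the model with the stated bounds replaced; an omitted
#' side is left unchanged. The input model is not modified.
#'
#' @param model A [metabolic_model()].
#' @param reaction_id Reaction to edit.
#' @param lower,upper New bounds (mmol/gDW/h); `NULL` keeps the current
#'   value.
#' @return The edited model.
#' @export
change_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  k <- match(reaction_id, model$reactions$id)
  if (is.na(k)) {
    stop("unknown reaction id: ", sQuote(reaction_id), call. = FALSE)
  }
  lb <- if (is.null(lower)) model$reactions$lower_bound[k] else as.numeric(lower)
  ub <- if (is.null(upper)) model$reactions$upper_bound[k] else as.numeric(upper)
  if (lb > ub) {
    stop(sprintf("inverted bounds for %s: lower %g > upper %g",
                 reaction_id, lb, ub), call. = FALSE)
  }
  model$reactions$lower_bound[k] <- lb
  model$reactions$upper_bound[k] <- ub
  model
}

#' Apply a gene knockout to a model
#'
#' Evaluates every reaction's GPR rule with the given genes marked absent;
#' reactions whose rule evaluates to false get bounds (0, 0). Reactions with
#' no GPR rule are untouched, and disabled reactions are kept in place (not
#' deleted) so that matrix dimensions and reaction indices stay stable across
#' model variants. The input model is not modified.
#'
#' @param model A [metabolic_model()].
#' @param genes Character vector of gene ids to knock out. An empty vector
#'   returns the model unchanged.
#' @return The knocked-out model.
#' @export
apply_knockout <- function(model, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) return(model)
  missing <- setdiff(genes, model$genes$id)
  if (length(missing) > 0) {
    stop("unknown gene id(s): ", paste(sQuote(missing), collapse = ", "),
         call. = FALSE)
  }
  for (k in seq_len(nrow(model$reactions))) {
    g <- model$reactions$gpr[k]
    if (!nzchar(g)) next
    if (!eval_gpr(parse_gpr(g), absent_genes = genes)) {
      model$reactions$lower_bound[k] <- 0
      model$reactions$upper_bound[k] <- 0
    }
  }
  model
}

#' Validate the structural invariants of a model
#'
#' Checks id uniqueness, dangling metabolite references in stoichiometries,
#' dangling gene references in GPR rules, and bound ordering. Orphan
#' metabolites (used by no reaction) and reactions with empty stoichiometry
#' are reported as warnings. Nothing is thrown: all findings go into the
#' report.
#'
#' @param model A [metabolic_model()].
#' @return A `validation_report`: a list of two data frames `errors` and
#'   `warnings`, each with columns `code` and `message`. The model satisfies
#'   all structural invariants iff `errors` is empty.
#' @export
validate_model <- function(model) {
  errs <- list(); warns <- list()
  add_err <- function(code, message) {
    errs[[length(errs) + 1L]] <<- data.frame(code = code, message = message,
                                             stringsAsFactors = FALSE)
  }
  add_warn <- function(code, message) {
    warns[[length(warns) + 1L]] <<- data.frame(code = code, message = message,
                                               stringsAsFactors = FALSE)
  }

  for (what in c("metabolites", "reactions", "genes")) {
    ids <- model[[what]]$id
    if (any(!nzchar(ids) | is.na(ids))) {
      add_err("empty_id", sprintf("empty or missing id in %s", what))
    }
    dup <- unique(ids[duplicated(ids)])
    for (d in dup) {
      add_err("duplicate_id", sprintf("duplicate %s id %s", sub("s$", "", what),
                                      sQuote(d)))
    }
  }

  used_mets <- character(0)
  for (k in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[k]
    s <- model$stoichiometry[[k]]
    dangling <- setdiff(names(s), model$metabolites$id)
    for (d in dangling) {
      add_err("dangling_metabolite",
              sprintf("reaction %s references unknown metabolite %s",
                      sQuote(rid), sQuote(d)))
    }
    used_mets <- c(used_mets, names(s))
    if (length(s) == 0) {
      add_warn("empty_stoichiometry",
               sprintf("reaction %s has no stoichiometry", sQuote(rid)))
    }
    if (model$reactions$lower_bound[k] > model$reactions$upper_bound[k]) {
      add_err("inverted_bounds",
              sprintf("reaction %s has lower bound %g > upper bound %g",
                      sQuote(rid), model$reactions$lower_bound[k],
                      model$reactions$upper_bound[k]))
    }
    g <- model$reactions$gpr[k]
    if (nzchar(g)) {
      rule_genes <- tryCatch(gpr_genes(parse_gpr(g)), error = function(e) {
        add_err("gpr_parse_error",
                sprintf("reaction %s: %s", sQuote(rid), conditionMessage(e)))
        character(0)
      })
      for (d in setdiff(rule_genes, model$genes$id)) {
        add_err("dangling_gene",
                sprintf("reaction %s GPR references unknown gene %s",
                        sQuote(rid), sQuote(d)))
      }
    }
  }

  for (orphan in setdiff(model$metabolites$id, unique(used_mets))) {
    add_warn("orphan_metabolite",
             sprintf("metabolite %s participates in no reaction", sQuote(orphan)))
  }

  empty_report <- data.frame(code = character(0), message = character(0),
                             stringsAsFactors = FALSE)
  structure(list(
    errors = if (length(errs)) do.call(rbind, errs) else empty_report,
    warnings = if (length(warns)) do.call(rbind, warns) else empty_report
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$errors), " error(s), ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  if (nrow(x$errors)) {
    cat(paste0("  error [", x$errors$code, "] ", x$errors$message, "\n"), sep = "")
  }
  if (nrow(x$warnings)) {
    cat(paste0("  warning [", x$warnings$code, "] ", x$warnings$message, "\n"),
        sep = "")
  }
  invisible(x)
}
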