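#' Formulate the steady-state linear program of a model
#'
#' Builds the LP behind flux balance analysis: maximize (or minimize) a
#' linear objective c'v over flux vectors v subject to the steady-state mass
#' balance `S %*% v = 0` and the per-reaction bounds `lb <= v <= ub`.
#'
#' @param model A valid [metabolic_model()].
#' @param objective Optional named numeric vector of objective weights keyed
#'   by reaction id; overrides the model's `objective_coefficient`s. When
#'   omitted the model must carry at least one nonzero coefficient.
#' @param sense `"max"` (default) or `"min"`.
#' @return An `lp_problem`: list with the sparse constraint matrix `A`, the
#'   equality right-hand side `b` (zeros), bound vectors `lb` / `ub`, the
#'   objective vector `obj` (reaction order), `sense`, and `reaction_ids`.
#' @seealso [solve_lp()], [fba()]
#' @export
build_lp <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  S <- stoichiometry_matrix(model)
  n <- ncol(S)
  obj <- setNames(numeric(n), model$reactions$id)
  if (is.null(objective)) {
    obj[] <- model$reactions$objective_coefficient
    if (all(obj == 0)) {
      stop("model carries no objective: set objective_coefficient on a ",
           "reaction or pass `objective` explicitly", call. = FALSE)
    }
  } else {
    if (is.null(names(objective)) || any(!nzchar(names(objective)))) {
      stop("`objective` must be a named vector keyed by reaction id",
           call. = FALSE)
    }
    missing <- setdiff(names(objective), model$reactions$id)
    if (length(missing)) {
      stop("objective references unknown reaction(s): ",
           paste(sQuote(missing), collapse = ", "), call. = FALSE)
    }
    obj[names(objective)] <- as.numeric(objective)
  }
  structure(list(
    A = S,
    b = numeric(nrow(S)),
    lb = model$reactions$lower_bound,
    ub = model$reactions$upper_bound,
    obj = obj,
    sense = sense,
    reaction_ids = model$reactions$id
  ), class = "lp_problem")
}

#' Solver tolerances
#'
#' @param feasibility Absolute feasibility tolerance on constraint residuals.
#' @param optimality Reduced-cost tolerance at which the simplex declares
#'   optimality (relative to unit-scale costs).
#' @param max_iterations Simplex iteration cap per phase; `0` derives a cap
#'   from the problem size.
#' @return A list of tolerances accepted by [solve_lp()].
#' @export
lp_tolerances <- function(feasibility = 1e-9, optimality = 1e-9,
                          max_iterations = 0L) {
  list(feasibility = feasibility, optimality = optimality,
       max_iterations = as.integer(max_iterations))
}

#' Solve a steady-state LP
#'
#' Dispatches an [build_lp()] problem to the package's solver backend, a
#' dense bounded-variable two-phase primal simplex. The adapter contract is
#' deliberately narrow — matrix, bounds and objective in; status, objective
#' value and a primal vector out — so alternative backends can be swapped in.
#'
#' When the problem has alternate optima the returned flux vector is *one*
#' optimal vertex; only the objective value (and flux-variability bounds
#' computed from it) are deterministic quantities. Callers must not rely on
#' which vertex is reported.
#'
#' @param problem An `lp_problem`.
#' @param tolerances See [lp_tolerances()].
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value` (`NA` unless
#'   optimal) and `fluxes` (named vector, present only when optimal).
#' @export
solve_lp <- function(problem, tolerances = lp_tolerances()) {
  stopifnot(inherits(problem, "lp_problem"))
  res <- solve_bounded(problem$A, problem$b, problem$obj, problem$lb,
                       problem$ub, maximize = identical(problem$sense, "max"),
                       tol = tolerances)
  if (!identical(res$status, "optimal")) {
    return(flux_solution(res$status))
  }
  flux_solution("optimal", objective_value = res$objective,
                fluxes = setNames(res$x, problem$reaction_ids))
}

# core seam to the compiled simplex; A may be sparse or dense, extra rows
# (e.g. the FVA objective-fraction constraint) are passed already appended
solve_bounded <- function(A, b, obj, lb, ub, maximize, tol = lp_tolerances()) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  res <- .simplex_solve(A, as.numeric(b), as.numeric(obj), as.numeric(lb),
                        as.numeric(ub), isTRUE(maximize),
                        tol_feas = tol$feasibility, tol_opt = tol$optimality,
                        max_iter = tol$max_iterations)
  if (identical(res$status, "iteration_limit")) {
    stop("LP solver hit its iteration limit; raise `max_iterations` in ",
         "lp_tolerances()", call. = FALSE)
  }
  if (identical(res$status, "optimal")) {
    res$x <- as.numeric(res$x)
    resid <- max(abs(A %*% res$x - b), 0)
    if (resid > 1e-6) {
      warning(sprintf("solver returned residual %g above steady-state tolerance",
                      resid))
    }
  }
  res
}

flux_solution <- function(status, objective_value = NA_real_, fluxes = NULL) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (identical(x$status, "optimal")) {
    cat("   objective: ", format(x$objective_value, digits = 10), sep = "")
  }
  cat("\n")
  if (!is.null(x$fluxes) && length(x$fluxes) <= 25) {
    print(round(x$fluxes, 6))
  } else if (!is.null(x$fluxes)) {
    cat("  (", length(x$fluxes), " fluxes; access via $fluxes)\n", sep = "")
  }
  invisible(x)
}
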