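#' Flux variability analysis
#'
#' Computes, for each requested reaction, the minimum and maximum flux it can
#' carry while the model retains at least a fraction `gamma` of its optimal
#' objective. The wild-type optimum Z* is computed first; the requirement is
#' then imposed as a linear constraint on the objective *expression*
#' (`c'v >= gamma * Z*` for maximization, `<=` for minimization) rather than
#' by fixing bounds on an objective reaction, which stays correct when the
#' objective spans several reactions. Each per-reaction minimization and
#' maximization is an independent LP dispatched through the package task
#' pool.
#'
#' When Z* = 0 the constraint degenerates to `c'v >= 0` for every `gamma`;
#' this is the documented behaviour, not special-cased.
#'
#' @param model A valid [metabolic_model()] with an objective.
#' @param gamma Required optimum fraction in `[0, 1]`; default `1` (ranges
#'   at the optimum itself).
#' @param reactions Reaction ids to analyse; default all reactions.
#' @param workers Worker processes for the task pool.
#' @param tolerances See [lp_tolerances()].
#' @return A data frame with one row per requested reaction: `reaction`,
#'   `minimum`, `maximum`, `status_min`, `status_max`. Flux columns are `NA`
#'   where the corresponding subproblem is not optimal.
#' @examples
#' m <- make_diamond(uptake_ub = 10)
#' fva(m, gamma = 1)   # each parallel route spans [0, 10]
#' @export
fva <- function(model, gamma = 1, reactions = NULL, workers = 1L,
                tolerances = lp_tolerances()) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1)
  prob <- build_lp(model)
  if (is.null(reactions)) {
    reactions <- model$reactions$id
  } else {
    missing <- setdiff(reactions, model$reactions$id)
    if (length(missing)) {
      stop("unknown reaction id(s): ", paste(sQuote(missing), collapse = ", "),
           call. = FALSE)
    }
  }
  wt <- solve_lp(prob, tolerances = tolerances)
  if (!identical(wt$status, "optimal")) {
    stop("wild-type FBA is ", wt$status,
         "; flux variability is undefined", call. = FALSE)
  }
  zstar <- wt$objective_value

  aug <- fva_augment(prob, gamma * zstar)
  n <- length(prob$reaction_ids)
  idx <- match(reactions, prob$reaction_ids)

  tasks <- unlist(lapply(idx, function(k) {
    list(list(k = k, maximize = FALSE), list(k = k, maximize = TRUE))
  }), recursive = FALSE)
  sols <- fs_lapply(tasks, function(task) {
    obj <- numeric(n + 1L)
    obj[task$k] <- 1
    solve_bounded(aug$A, aug$b, obj, aug$lb, aug$ub,
                  maximize = task$maximize, tol = tolerances)
  }, workers = workers)

  lo <- sols[seq(1, length(sols), by = 2)]
  hi <- sols[seq(2, length(sols), by = 2)]
  data.frame(
    reaction = reactions,
    minimum = vapply(lo, function(s) {
      if (identical(s$status, "optimal")) s$objective else NA_real_
    }, numeric(1)),
    maximum = vapply(hi, function(s) {
      if (identical(s$status, "optimal")) s$objective else NA_real_
    }, numeric(1)),
    status_min = vapply(lo, function(s) s$status, character(1)),
    status_max = vapply(hi, function(s) s$status, character(1)),
    stringsAsFactors = FALSE
  )
}

# append the objective-fraction constraint via one slack column:
#   maximize: c'v - s = z0, s >= 0   <=>  c'v >= z0
#   minimize: c'v + s = z0, s >= 0   <=>  c'v <= z0
fva_augment <- function(prob, z0) {
  A <- as.matrix(prob$A)
  slack_sign <- if (identical(prob$sense, "max")) -1 else 1
  A_aug <- rbind(cbind(A, 0), c(unname(prob$obj), slack_sign))
  list(A = A_aug, b = c(prob$b, z0),
       lb = c(prob$lb, 0), ub = c(prob$ub, Inf))
}
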