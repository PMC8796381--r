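#' Flux balance analysis
#'
#' Maximizes the model objective c'v over flux vectors v subject to the
#' steady-state constraint `S %*% v = 0` and the reaction bounds. An
#' optional ordered list of modifications — [variant()] descriptors
#' (`mod_knockout()`, `mod_bounds()`, `mod_objective()`), whole
#' `model_variant`s, or plain functions `model -> model` — is applied
#' left-to-right to a copy of the model before solving; the caller's model
#' is never touched.
#'
#' @param model A valid [metabolic_model()] with an objective (or a
#'   modification that sets one).
#' @param modifications Optional list of modifications, applied in order.
#' @param objective,sense Passed to [build_lp()].
#' @param tolerances See [lp_tolerances()].
#' @return A `flux_solution` (see [solve_lp()]).
#' @examples
#' m <- make_chain(n_internal = 1, uptake_ub = 10)
#' fba(m)$objective_value                         # 10
#' fba(m, list(mod_bounds("EX_S_e", 0, 0)))$objective_value   # starved: 0
#' @export
fba <- function(model, modifications = NULL, objective = NULL,
                sense = "max", tolerances = lp_tolerances()) {
  for (mod in modifications %||% list()) {
    model <- if (inherits(mod, "model_modification")) {
      apply_modification(model, mod)
    } else if (inherits(mod, "model_variant")) {
      apply_variant(model, mod)
    } else if (is.function(mod)) {
      mod(model)
    } else {
      stop("each modification must be a model_modification, a ",
           "model_variant, or a function(model)", call. = FALSE)
    }
  }
  solve_lp(build_lp(model, objective = objective, sense = sense),
           tolerances = tolerances)
}
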