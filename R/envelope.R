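#' Production envelope
#'
#' Sweeps a modulated reaction across its feasible flux range and records the
#' achievable extremes of a target reaction at each level — the classic
#' phenotype phase-plane table. The feasible range `[lo, hi]` of the
#' modulated reaction is found first by two LPs with no objective-fraction
#' constraint; `n_points` evenly spaced levels spanning it (endpoints
#' included) are then taken, the modulated reaction's bounds are fixed to
#' each level, and the target's minimum and maximum flux are solved as
#' independent tasks. When the modulated reaction is fully determined by
#' stoichiometry (`hi - lo < 1e-9`) a single-level table is emitted.
#'
#' @param model A valid [metabolic_model()].
#' @param target_reaction Reaction whose flux extremes are tabulated.
#' @param modulated_reaction Reaction swept across its feasible range.
#' @param n_points Number of levels (>= 2).
#' @param workers Worker processes for the task pool.
#' @param tolerances See [lp_tolerances()].
#' @return A data frame with strictly increasing `level` and columns
#'   `target_min`, `target_max`, `status_min`, `status_max`.
#' @examples
#' m <- make_branched(uptake_ub = 10, yield_p = 1, yield_w = 0)
#' production_envelope(m, "EX_P_e", "EX_W_e", n_points = 3)
#' # waste levels 0, 5, 10 cap the product maximum at 10, 5, 0
#' @export
production_envelope <- function(model, target_reaction, modulated_reaction,
                                n_points = 10L, workers = 1L,
                                tolerances = lp_tolerances()) {
  stopifnot(n_points >= 2)
  for (r in c(target_reaction, modulated_reaction)) {
    if (!r %in% model$reactions$id) {
      stop("unknown reaction id: ", sQuote(r), call. = FALSE)
    }
  }
  # feasible range of the modulated reaction, no objective involvement
  range_lo <- fba(model, objective = setNames(1, modulated_reaction),
                  sense = "min", tolerances = tolerances)
  range_hi <- fba(model, objective = setNames(1, modulated_reaction),
                  sense = "max", tolerances = tolerances)
  if (!identical(range_lo$status, "optimal") ||
      !identical(range_hi$status, "optimal")) {
    stop("base model is ", range_lo$status,
         "; production envelope is undefined", call. = FALSE)
  }
  lo <- range_lo$objective_value
  hi <- range_hi$objective_value
  levels <- if (hi - lo < 1e-9) lo else seq(lo, hi, length.out = n_points)

  cells <- fs_lapply(as.list(levels), function(lv) {
    fixed <- change_bounds(model, modulated_reaction, lower = lv, upper = lv)
    list(
      lo = fba(fixed, objective = setNames(1, target_reaction),
               sense = "min", tolerances = tolerances),
      hi = fba(fixed, objective = setNames(1, target_reaction),
               sense = "max", tolerances = tolerances)
    )
  }, workers = workers)

  data.frame(
    level = levels,
    target_min = vapply(cells, function(c) {
      if (identical(c$lo$status, "optimal")) c$lo$objective_value else NA_real_
    }, numeric(1)),
    target_max = vapply(cells, function(c) {
      if (identical(c$hi$status, "optimal")) c$hi$objective_value else NA_real_
    }, numeric(1)),
    status_min = vapply(cells, function(c) c$lo$status, character(1)),
    status_max = vapply(cells, function(c) c$hi$status, character(1)),
    stringsAsFactors = FALSE
  )
}
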