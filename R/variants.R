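#' Serializable model modifications and variants
#'
#' A *variant* is an ordered list of plain-value transformation descriptors
#' plus a human-readable label. Because descriptors are data (no closures or
#' environments), variants can be serialized, logged, and shipped to worker
#' processes, and applied fresh to a copy of a base model in each screening
#' task.
#'
#' Three descriptor kinds are provided: `mod_knockout()` disables every
#' reaction whose GPR rule fails with the given genes absent;
#' `mod_bounds()` replaces one reaction's flux bounds; `mod_objective()`
#' replaces the model objective with the given weight map. Descriptors are
#' applied left-to-right, so later descriptors win when they touch the same
#' reaction.
#'
#' @param genes Character vector of gene ids to knock out.
#' @param reaction_id Reaction to re-bound.
#' @param lower,upper New bounds; `NULL` leaves that side unchanged.
#' @param weights Named numeric vector of objective coefficients keyed by
#'   reaction id; all other coefficients are set to zero.
#' @param label Human-readable variant label used in screen results and
#'   error values.
#' @param ... Descriptors (or a single list of descriptors).
#' @return `variant()` returns a `model_variant`; the `mod_*` constructors
#'   return `model_modification` descriptors.
#' @examples
#' v <- variant("koP+cap", mod_knockout("gP"), mod_bounds("EX_S_e", upper = 5))
#' @export
variant <- function(label, ...) {
  mods <- list(...)
  if (length(mods) == 1 && is.list(mods[[1]]) &&
      !inherits(mods[[1]], "model_modification")) {
    mods <- mods[[1]]
  }
  for (m in mods) {
    if (!inherits(m, "model_modification")) {
      stop("variant descriptors must be created with mod_knockout(), ",
           "mod_bounds() or mod_objective()", call. = FALSE)
    }
  }
  structure(list(label = as.character(label), modifications = mods),
            class = "model_variant")
}

#' @rdname variant
#' @export
mod_knockout <- function(genes) {
  structure(list(kind = "knockout", genes = unique(as.character(genes))),
            class = "model_modification")
}

#' @rdname variant
#' @export
mod_bounds <- function(reaction_id, lower = NULL, upper = NULL) {
  structure(list(kind = "bounds", reaction_id = as.character(reaction_id),
                 lower = lower, upper = upper),
            class = "model_modification")
}

#' @rdname variant
#' @export
mod_objective <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("`weights` must be named by reaction id", call. = FALSE)
  }
  structure(list(kind = "objective", weights = weights),
            class = "model_modification")
}

apply_modification <- function(model, mod) {
  stopifnot(inherits(mod, "model_modification"))
  switch(mod$kind,
    knockout = apply_knockout(model, mod$genes),
    bounds = change_bounds(model, mod$reaction_id, mod$lower, mod$upper),
    objective = {
      missing <- setdiff(names(mod$weights), model$reactions$id)
      if (length(missing)) {
        stop("objective modification references unknown reaction(s): ",
             paste(sQuote(missing), collapse = ", "), call. = FALSE)
      }
      model$reactions$objective_coefficient <-
        ifelse(model$reactions$id %in% names(mod$weights),
               as.numeric(mod$weights[model$reactions$id]), 0)
      model
    },
    stop("unknown modification kind: ", mod$kind)
  )
}

#' Apply a variant to a model
#'
#' Applies the variant's descriptors left-to-right to a copy of the model;
#' the base model is untouched. Errors raised by a descriptor (unknown
#' reaction or gene id) are re-signalled carrying the variant label.
#'
#' @param model A [metabolic_model()].
#' @param variant A [variant()]. An empty variant returns the model
#'   unchanged.
#' @return The transformed model copy.
#' @export
apply_variant <- function(model, variant) {
  stopifnot(inherits(variant, "model_variant"))
  for (mod in variant$modifications) {
    model <- tryCatch(apply_modification(model, mod), error = function(e) {
      stop(sprintf("variant %s: %s", sQuote(variant$label),
                   conditionMessage(e)), call. = FALSE)
    })
  }
  model
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant> ", x$label, " (", length(x$modifications),
      " modification(s))\n", sep = "")
  invisible(x)
}
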