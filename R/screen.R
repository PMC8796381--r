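#' The analysis registry
#'
#' Screens reference analyses by registered name, never by closure: a name
#' plus serializable keyword arguments is what crosses the worker boundary,
#' which keeps tasks process-safe and screen logs reproducible. Registered
#' functions must be pure: a function of `(model, ...)` with no shared
#' mutable state.
#'
#' Built-in analyses registered at load time:
#' \describe{
#'   \item{`fba_objective`}{FBA objective value as a bare number (`NA` when
#'     not optimal).}
#'   \item{`fba`}{full `flux_solution`.}
#'   \item{`fva`}{flux variability table; accepts `gamma`, `reactions`.}
#'   \item{`envelope`}{production envelope table; accepts
#'     `target_reaction`, `modulated_reaction`, `n_points`.}
#' }
#'
#' @param name Analysis name (character scalar).
#' @param fn Pure function of `(model, ...)`.
#' @return `register_analysis()` invisibly returns `name`;
#'   `list_analyses()` the sorted registered names; `get_analysis()` the
#'   function itself.
#' @export
register_analysis <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.function(fn))
  assign(name, fn, envir = .analysis_registry)
  invisible(name)
}

#' @rdname register_analysis
#' @export
list_analyses <- function() sort(ls(.analysis_registry))

#' @rdname register_analysis
#' @export
get_analysis <- function(name) {
  if (!exists(name, envir = .analysis_registry, inherits = FALSE)) {
    stop("no analysis registered under ", sQuote(name),
         "; see list_analyses()", call. = FALSE)
  }
  get(name, envir = .analysis_registry, inherits = FALSE)
}

.analysis_registry <- new.env(parent = emptyenv())

register_builtin_analyses <- function() {
  register_analysis("fba_objective", function(model, ...) {
    s <- fba(model, ...)
    if (identical(s$status, "optimal")) s$objective_value else NA_real_
  })
  register_analysis("fba", function(model, ...) fba(model, ...))
  register_analysis("fva", function(model, ...) fva(model, ...))
  register_analysis("envelope", function(model, ...) {
    production_envelope(model, ...)
  })
}

#' Build a Cartesian grid of variants
#'
#' Combines one list of variants per axis into their Cartesian product. The
#' combined variant of a grid cell concatenates the descriptor lists of its
#' axis variants (axis 1 first) and joins their labels with `" + "`. Cells
#' are enumerated in row-major order — the last axis varies fastest — and
#' this ordering is part of the interface, so array indices are stable.
#'
#' @param axes A non-empty list; each element a non-empty list of
#'   [variant()]s spanning one grid axis.
#' @return A `variant_grid`: list with `variants` (row-major list of
#'   combined variants), `shape` (integer axis lengths) and `axis_labels`.
#' @examples
#' g <- variant_grid(list(
#'   list(variant("wt"), variant("koP", mod_knockout("gP"))),
#'   list(variant("cap5", mod_bounds("EX_S_e", upper = 5)),
#'        variant("cap10", mod_bounds("EX_S_e", upper = 10)))
#' ))
#' g$shape  # 2 x 2
#' @export
variant_grid <- function(axes) {
  if (!is.list(axes) || length(axes) == 0) {
    stop("`axes` must be a non-empty list of variant lists", call. = FALSE)
  }
  for (ax in axes) {
    if (!is.list(ax) || length(ax) == 0) {
      stop("every axis must be a non-empty list of variants", call. = FALSE)
    }
    for (v in ax) {
      if (!inherits(v, "model_variant")) {
        stop("axis elements must be model_variant objects", call. = FALSE)
      }
    }
  }
  shape <- vapply(axes, length, integer(1))
  axis_labels <- lapply(axes, function(ax) {
    vapply(ax, function(v) v$label, character(1))
  })
  # row-major: last axis fastest
  combos <- expand_rowmajor(shape)
  variants <- lapply(seq_len(nrow(combos)), function(r) {
    parts <- lapply(seq_along(axes), function(a) axes[[a]][[combos[r, a]]])
    variant(paste(vapply(parts, function(v) v$label, character(1)),
                  collapse = " + "),
            do.call(c, c(lapply(parts, function(v) v$modifications),
                         list(list()))))
  })
  structure(list(variants = variants, shape = shape,
                 axis_labels = axis_labels, index = combos),
            class = "variant_grid")
}

# all index combinations, last axis varying fastest (row-major)
expand_rowmajor <- function(shape) {
  total <- prod(shape)
  combos <- matrix(0L, nrow = total, ncol = length(shape))
  rep_each <- rev(cumprod(rev(c(shape[-1], 1L))))
  for (a in seq_along(shape)) {
    combos[, a] <- rep(rep(seq_len(shape[a]), each = rep_each[a]),
                       length.out = total)
  }
  combos
}

#' Screen many model variants with one analysis
#'
#' The composable heart of the package: take a base model, a Cartesian grid
#' of serializable [variant()]s, and the name of a registered analysis; for
#' every grid cell apply the cell's variant to a fresh copy of the base
#' model, run the analysis on the variant model, and collect the outputs
#' into a dense multi-dimensional array whose axes are the grid axes. Every
#' cell is an independent task executed on the worker pool; execution order
#' is unspecified, but the assembled result is deterministic — identical for
#' any worker count and scheduling.
#'
#' `screen()` is strict: the first failing cell aborts the whole screen.
#' `screen_fallible()` instead stores a structured `screen_error` value
#' (code, message, variant label) in each failing cell and completes the
#' rest, which is what long screens over flaky subproblems need; a summary
#' of failed cells is reported as a warning.
#'
#' An optional integer `seed` is threaded to the cells (cell seed =
#' `seed + cell_index - 1`, set before the analysis call). No built-in
#' analysis is stochastic; the parameter exists so registered stochastic
#' analyses stay reproducible.
#'
#' @param model The base model; deep-unchanged after the screen.
#' @param axes Passed to [variant_grid()] (or an existing `variant_grid`).
#' @param analysis Registered analysis name; see [register_analysis()].
#' @param args Named list of fixed keyword arguments for the analysis.
#' @param workers Worker processes.
#' @param seed Optional integer seed threaded per cell.
#' @return A `screen_result`: list with `values` (a list-mode array of
#'   dimension `shape`, cells in axis order), `labels` (character array of
#'   combined variant labels, same shape), `shape`, and `analysis`.
#' @examples
#' m <- make_branched(gene_gating = TRUE)
#' r <- screen(m, list(list(variant("wt"), variant("koP", mod_knockout("gP")))),
#'             analysis = "fba_objective")
#' unlist(r$values)   # 10 5
#' @export
screen <- function(model, axes, analysis, args = list(), workers = 1L,
                   seed = NULL) {
  run_screen(model, axes, analysis, args, workers, seed, fallible = FALSE)
}

#' @rdname screen
#' @export
screen_fallible <- function(model, axes, analysis, args = list(),
                            workers = 1L, seed = NULL) {
  run_screen(model, axes, analysis, args, workers, seed, fallible = TRUE)
}

run_screen <- function(model, axes, analysis, args, workers, seed, fallible) {
  grid <- if (inherits(axes, "variant_grid")) axes else variant_grid(axes)
  fn <- get_analysis(analysis)   # fails fast on unregistered names

  cell_fn <- function(i) {
    v <- grid$variants[[i]]
    run_one <- function() {
      if (!is.null(seed)) set.seed(as.integer(seed) + i - 1L)
      do.call(fn, c(list(apply_variant(model, v)), args))
    }
    if (!fallible) return(run_one())
    tryCatch(run_one(), error = function(e) {
      structure(list(code = "analysis_error",
                     message = conditionMessage(e), variant = v$label),
                class = "screen_error")
    })
  }
  cells <- fs_lapply(as.list(seq_along(grid$variants)), cell_fn,
                     workers = workers)

  if (fallible) {
    failed <- vapply(cells, inherits, logical(1), what = "screen_error")
    if (any(failed)) {
      warning(sprintf("%d of %d screen cell(s) failed: %s", sum(failed),
                      length(cells),
                      paste(vapply(cells[failed], function(c) c$variant,
                                   character(1)), collapse = ", ")),
              call. = FALSE)
    }
  }

  labels <- vapply(grid$variants, function(v) v$label, character(1))
  structure(list(
    values = rowmajor_array(cells, grid$shape),
    labels = rowmajor_array(as.list(labels), grid$shape, simplify = TRUE),
    shape = grid$shape,
    analysis = analysis
  ), class = "screen_result")
}

# place row-major cell list into an R array (column-major storage) such that
# values[i, j, ...] corresponds to axis indices (i, j, ...)
rowmajor_array <- function(cells, shape, simplify = FALSE) {
  if (length(shape) == 1) {
    a <- if (simplify) unlist(cells) else cells
    dim(a) <- shape
    return(a)
  }
  a <- if (simplify) unlist(cells) else cells
  dim(a) <- rev(shape)
  aperm(a, rev(seq_along(shape)))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> analysis: ", x$analysis, "   shape: ",
      paste(x$shape, collapse = " x "), "\n", sep = "")
  flat <- x$values
  dim(flat) <- NULL
  if (all(vapply(flat, function(v) is.numeric(v) && length(v) == 1,
                 logical(1)))) {
    vals <- array(unlist(flat), dim = dim(x$values))
    dimnames(vals) <- NULL
    print(vals)
  } else {
    cat("  (cells hold structured values; access via $values)\n")
  }
  invisible(x)
}
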