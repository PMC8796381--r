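#' Gene deletion screens
#'
#' `single_gene_deletion()` knocks out each gene in turn and reports the FBA
#' objective of the knockout model; `pair_gene_deletion()` does the same for
#' two-gene sets (knockouts have set semantics, so a duplicated gene in a
#' pair equals the single deletion). Each deletion is an independent task
#' dispatched through the package task pool; results are returned in the
#' input order regardless of execution order.
#'
#' A deletion that still solves but grows at rate zero is reported as status
#' `"optimal"` with objective `0` — deliberately distinct from
#' `"infeasible"`, where no steady-state flux distribution exists at all and
#' the objective is `NA`. The two outcomes carry different information and
#' are never coerced into one another.
#'
#' @param model A valid [metabolic_model()] with an objective.
#' @param genes Gene ids to delete one at a time; default all model genes.
#' @param pairs Gene pairs: a list of length-2 character vectors, or a
#'   2-column matrix / data frame of gene ids.
#' @param workers Worker processes for the task pool.
#' @param tolerances See [lp_tolerances()].
#' @return A data frame with columns `gene` (or `gene1`, `gene2`), `status`
#'   and `objective` (`NA` unless status is `"optimal"`).
#' @examples
#' m <- make_branched(gene_gating = TRUE)
#' single_gene_deletion(m, genes = c("gP", "gX"))
#' @export
single_gene_deletion <- function(model, genes = NULL, workers = 1L,
                                 tolerances = lp_tolerances()) {
  if (is.null(genes)) {
    genes <- model$genes$id
  } else {
    missing <- setdiff(genes, model$genes$id)
    if (length(missing)) {
      stop("unknown gene id(s): ", paste(sQuote(missing), collapse = ", "),
           call. = FALSE)
    }
  }
  res <- deletion_tasks(model, as.list(genes), workers, tolerances)
  data.frame(gene = as.character(genes), status = res$status,
             objective = res$objective, stringsAsFactors = FALSE)
}

#' @rdname single_gene_deletion
#' @export
pair_gene_deletion <- function(model, pairs, workers = 1L,
                               tolerances = lp_tolerances()) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    stopifnot(ncol(pairs) == 2)
    pairs <- lapply(seq_len(nrow(pairs)), function(i) {
      as.character(unlist(pairs[i, ], use.names = FALSE))
    })
  }
  for (p in pairs) {
    if (length(p) != 2) stop("each pair must hold exactly two gene ids",
                             call. = FALSE)
    missing <- setdiff(p, model$genes$id)
    if (length(missing)) {
      stop("unknown gene id(s): ", paste(sQuote(missing), collapse = ", "),
           call. = FALSE)
    }
  }
  res <- deletion_tasks(model, pairs, workers, tolerances)
  data.frame(gene1 = vapply(pairs, `[`, character(1), 1),
             gene2 = vapply(pairs, `[`, character(1), 2),
             status = res$status, objective = res$objective,
             stringsAsFactors = FALSE)
}

deletion_tasks <- function(model, gene_sets, workers, tolerances) {
  sols <- fs_lapply(gene_sets, function(gs) {
    fba(apply_knockout(model, gs), tolerances = tolerances)
  }, workers = workers)
  list(
    status = vapply(sols, function(s) s$status, character(1)),
    objective = vapply(sols, function(s) {
      if (identical(s$status, "optimal")) s$objective_value else NA_real_
    }, numeric(1))
  )
}
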