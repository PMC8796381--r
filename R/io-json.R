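#' Read and write models in the COBRA JSON dialect
#'
#' The COBRA JSON schema (v1, the COBRApy interchange format) stores a model
#' as top-level arrays `metabolites`, `reactions` and `genes`; each reaction
#' carries its stoichiometry as an id-to-coefficient map under
#' `metabolites`, bounds as `lower_bound` / `upper_bound`, its GPR rule as
#' the string `gene_reaction_rule`, and `objective_coefficient`.
#'
#' Reading fills missing bounds with the irreversible defaults `(0, 1000)`
#' (a reaction is reversible exactly when its stated lower bound is
#' negative; the dialect has no separate flag), parses every
#' `gene_reaction_rule` with [parse_gpr()] (storing the canonical deparse),
#' and validates the result. Unrecognized *top-level* keys are preserved in
#' `annotations$json_extra` and re-emitted on write.
#'
#' Writing emits keys in a fixed order with full binary64 precision, so the
#' same model always serializes to the same bytes and a write/read round
#' trip is lossless.
#'
#' @param path File path, or for `read_model_json()` a connection / literal
#'   JSON string.
#' @param model A valid [metabolic_model()].
#' @return `read_model_json()` returns a [metabolic_model()];
#'   `write_model_json()` invisibly returns `path`.
#' @export
read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed JSON: ", conditionMessage(e), call. = FALSE)
                  })
  for (key in c("metabolites", "reactions", "genes")) {
    if (is.null(doc[[key]])) {
      stop(sprintf("not a COBRA JSON model: missing required key $.%s", key),
           call. = FALSE)
    }
  }

  mets <- do.call(rbind, lapply(seq_along(doc$metabolites), function(i) {
    m <- doc$metabolites[[i]]
    if (is.null(m$id)) {
      stop(sprintf("missing id at $.metabolites[%d]", i - 1), call. = FALSE)
    }
    data.frame(id = as.character(m$id),
               name = as.character(m$name %||% NA),
               compartment = as.character(m$compartment %||% NA),
               formula = as.character(m$formula %||% NA),
               charge = as.numeric(m$charge %||% NA),
               stringsAsFactors = FALSE)
  }))

  stoich <- list()
  rxns <- do.call(rbind, lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    if (is.null(r$id)) {
      stop(sprintf("missing id at $.reactions[%d]", i - 1), call. = FALSE)
    }
    gpr_text <- as.character(r$gene_reaction_rule %||% "")
    rule <- tryCatch(parse_gpr(gpr_text), error = function(e) {
      stop(sprintf("reaction %s: %s", sQuote(r$id), conditionMessage(e)),
           call. = FALSE)
    })
    s <- unlist(r$metabolites %||% list())
    stoich[[as.character(r$id)]] <<- if (length(s)) s else
      setNames(numeric(0), character(0))
    data.frame(id = as.character(r$id),
               name = as.character(r$name %||% NA),
               lower_bound = as.numeric(r$lower_bound %||% 0),
               upper_bound = as.numeric(r$upper_bound %||% 1000),
               objective_coefficient = as.numeric(r$objective_coefficient %||% 0),
               gpr = deparse_gpr(rule),
               stringsAsFactors = FALSE)
  }))

  genes <- if (length(doc$genes)) {
    do.call(rbind, lapply(doc$genes, function(g) {
      data.frame(id = as.character(g$id %||% ""),
                 name = as.character(g$name %||% NA),
                 stringsAsFactors = FALSE)
    }))
  } else NULL

  known <- c("id", "metabolites", "reactions", "genes", "annotations")
  extra <- doc[setdiff(names(doc), known)]
  ann <- doc$annotations %||% list()
  if (length(extra)) ann$json_extra <- extra

  model <- metabolic_model(
    id = as.character(doc$id %||% "model"),
    metabolites = mets, reactions = rxns, stoichiometry = stoich,
    genes = genes, annotations = ann, check = FALSE)
  rep <- validate_model(model)
  if (nrow(rep$errors) > 0) {
    stop("invalid model in JSON document:\n",
         paste0("  [", rep$errors$code, "] ", rep$errors$message,
                collapse = "\n"), call. = FALSE)
  }
  # counts must match the document: the reader never silently drops entries
  stopifnot(nrow(model$metabolites) == length(doc$metabolites),
            nrow(model$reactions) == length(doc$reactions))
  model
}

#' @rdname read_model_json
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  na_null <- function(x) if (length(x) == 0 || is.na(x)) NULL else x

  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    drop_nulls(list(id = m$id, name = na_null(m$name),
                    compartment = na_null(m$compartment),
                    formula = na_null(m$formula),
                    charge = na_null(m$charge)))
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[[i]]
    drop_nulls(list(id = r$id, name = na_null(r$name),
                    metabolites = as.list(s),
                    lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                    gene_reaction_rule = r$gpr,
                    objective_coefficient = r$objective_coefficient))
  })
  genes <- lapply(seq_len(nrow(model$genes)), function(i) {
    g <- model$genes[i, ]
    drop_nulls(list(id = g$id, name = na_null(g$name)))
  })

  ann <- model$annotations
  extra <- ann$json_extra
  ann$json_extra <- NULL
  doc <- c(list(id = model$id, metabolites = mets, reactions = rxns,
                genes = genes),
           extra,
           if (length(ann)) list(annotations = ann))

  # I(17) = 17 significant digits: exact round trip for binary64
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]
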