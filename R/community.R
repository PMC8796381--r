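#' Specify a multi-organism community
#'
#' A community specification lists member organisms (each a model with a
#' relative abundance), the metabolites they trade through a shared
#' environment compartment, and the exchange bounds of that environment.
#' [join_models()] turns the specification into one joint model.
#'
#' @param members List of [community_member()]s with unique ids; abundances
#'   must sum to a positive value and are normalized internally to sum 1.
#' @param shared_metabolites Character vector of *bare* environment
#'   metabolite ids (compartment suffixes `"_e"` / `"[e]"` stripped when
#'   matching member metabolites). Per-member overrides go through
#'   `metabolite_map`.
#' @param environment_bounds Named list (or 2-column matrix with shared ids
#'   as rownames) giving `(lower, upper)` flux bounds for each environment
#'   exchange reaction, COBRA sign convention: the exchange consumes the
#'   environment metabolite, so negative flux imports it into the shared
#'   compartment. Defaults to `(-1000, 1000)` (wide open).
#' @param id Member identifier; `"#"` is reserved for prefixing and
#'   forbidden.
#' @param model The member's [metabolic_model()].
#' @param abundance Non-negative relative abundance weight.
#' @param metabolite_map Optional named character vector mapping shared
#'   metabolite id to this member's metabolite id, overriding the
#'   suffix-stripping match.
#' @return `community_spec()` / `community_member()` return the
#'   corresponding specification objects.
#' @export
community_spec <- function(members, shared_metabolites,
                           environment_bounds = NULL) {
  stopifnot(is.list(members), length(members) >= 1)
  for (m in members) stopifnot(inherits(m, "community_member"))
  ids <- vapply(members, function(m) m$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate member id(s): ",
         paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", "),
         call. = FALSE)
  }
  ab <- vapply(members, function(m) m$abundance, numeric(1))
  if (any(ab < 0) || sum(ab) <= 0) {
    stop("abundances must be non-negative and sum to a positive value",
         call. = FALSE)
  }
  eb <- list()
  for (s in shared_metabolites) {
    b <- environment_bounds[[s]] %||% c(-1000, 1000)
    stopifnot(length(b) == 2, b[1] <= b[2])
    eb[[s]] <- as.numeric(b)
  }
  structure(list(members = members, shared_metabolites = shared_metabolites,
                 environment_bounds = eb),
            class = "community_spec")
}

#' @rdname community_spec
#' @export
community_member <- function(id, model, abundance = 1,
                             metabolite_map = NULL) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (grepl("#", id, fixed = TRUE)) {
    stop("member ids must not contain '#' (reserved as the prefix separator)",
         call. = FALSE)
  }
  stopifnot(inherits(model, "metabolic_model"), abundance >= 0)
  structure(list(id = id, model = model, abundance = abundance,
                 metabolite_map = metabolite_map),
            class = "community_member")
}

# strip conventional extracellular suffixes to get the bare metabolite id
bare_metabolite_id <- function(x) sub("(_e|\\[e\\])$", "", x)

# exchange = reaction with exactly one participating metabolite; the "EX_"
# naming convention is accepted as a hint but the structural criterion wins
# when they disagree
is_exchange_reaction <- function(model) {
  vapply(model$stoichiometry, length, integer(1)) == 1L
}

#' Join member models into one community model
#'
#' Builds a single model in which each member keeps its full internal
#' network (all ids prefixed `"memberId#"`) and members trade the shared
#' metabolites through a common environment compartment:
#'
#' * for every shared metabolite `X` an environment metabolite `X_env` is
#'   created, plus one environment exchange reaction `EX_X_env`
#'   (stoichiometry `{X_env: -1}`, bounds from the specification);
#' * every member exchange reaction for `X` (a reaction touching only the
#'   member's `X`) is rewired into a transfer between the member metabolite
#'   and `X_env`, with the environment-side coefficient scaled by the
#'   member's normalized abundance — member fluxes stay per unit of member
#'   biomass while environment totals are community-weighted;
#' * everything else is untouched, so the community stoichiometric matrix is
#'   block-diagonal over members except for the environment rows and
#'   columns.
#'
#' @param spec A [community_spec()].
#' @return A [metabolic_model()]; the member ids, normalized abundances and
#'   shared metabolites are recorded in `annotations$community`.
#' @examples
#' m <- make_chain(1, 10)
#' comm <- join_models(community_spec(
#'   members = list(community_member("a", m, 1), community_member("b", m, 1)),
#'   shared_metabolites = "S",
#'   environment_bounds = list(S = c(-10, 0))
#' ))
#' obj <- community_objective(comm, c(a = "EX_P_e", b = "EX_P_e"))
#' fba(comm, objective = obj)$objective_value   # 10: members split the substrate
#' @export
join_models <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  ab <- vapply(spec$members, function(m) m$abundance, numeric(1))
  ab <- ab / sum(ab)

  mets <- list(); rxns <- list(); stoich <- list(); genes <- list()
  for (i in seq_along(spec$members)) {
    mem <- spec$members[[i]]
    model <- mem$model
    rep <- validate_model(model)
    if (nrow(rep$errors) > 0) {
      stop("member ", sQuote(mem$id), " is invalid: ",
           rep$errors$message[1], call. = FALSE)
    }
    pre <- function(x) paste0(mem$id, "#", x)

    exch <- is_exchange_reaction(model)
    # which exchange serves which shared metabolite, for this member
    shared_map <- setNames(rep(NA_character_, length(spec$shared_metabolites)),
                           spec$shared_metabolites)
    for (s in spec$shared_metabolites) {
      target <- mem$metabolite_map[[s]] %||% NA_character_
      for (k in which(exch)) {
        met <- names(model$stoichiometry[[k]])
        hit <- if (!is.na(target)) identical(met, target)
               else identical(bare_metabolite_id(met), s)
        if (hit) { shared_map[[s]] <- model$reactions$id[k]; break }
      }
      if (is.na(shared_map[[s]])) {
        stop("member ", sQuote(mem$id), " has no exchange reaction for ",
             "shared metabolite ", sQuote(s), call. = FALSE)
      }
    }

    mm <- model$metabolites; mm$id <- pre(mm$id)
    mets[[i]] <- mm
    gg <- model$genes
    if (nrow(gg)) gg$id <- pre(gg$id)
    genes[[i]] <- gg

    rr <- model$reactions
    rr$gpr <- vapply(rr$gpr, function(g) {
      if (!nzchar(g)) return("")
      deparse_gpr(prefix_gpr(parse_gpr(g), paste0(mem$id, "#")))
    }, character(1))
    ss <- model$stoichiometry
    for (k in seq_along(ss)) names(ss[[k]]) <- pre(names(ss[[k]]))
    names(ss) <- pre(names(ss))
    rr$id <- pre(rr$id)

    # rewire the member's shared exchanges into env transfers
    for (s in spec$shared_metabolites) {
      rid <- paste0(mem$id, "#", shared_map[[s]])
      k <- match(rid, rr$id)
      coeff <- unname(ss[[rid]][1])
      ss[[rid]] <- setNames(c(coeff, -coeff * ab[i]),
                            c(names(ss[[rid]])[1], paste0(s, "_env")))
    }
    rxns[[i]] <- rr
    stoich <- c(stoich, ss)
  }

  env_mets <- data.frame(id = paste0(spec$shared_metabolites, "_env"),
                         name = NA_character_, compartment = "env",
                         formula = NA_character_, charge = NA_real_,
                         stringsAsFactors = FALSE)
  env_rxns <- data.frame(
    id = paste0("EX_", spec$shared_metabolites, "_env"),
    name = NA_character_,
    lower_bound = vapply(spec$shared_metabolites,
                         function(s) spec$environment_bounds[[s]][1],
                         numeric(1)),
    upper_bound = vapply(spec$shared_metabolites,
                         function(s) spec$environment_bounds[[s]][2],
                         numeric(1)),
    objective_coefficient = 0, gpr = "", stringsAsFactors = FALSE)
  for (s in spec$shared_metabolites) {
    stoich[[paste0("EX_", s, "_env")]] <- setNames(-1, paste0(s, "_env"))
  }

  member_ids <- vapply(spec$members, function(m) m$id, character(1))
  metabolic_model(
    id = paste0("community_", paste(member_ids, collapse = "_")),
    metabolites = rbind(do.call(rbind, mets), env_mets),
    reactions = rbind(do.call(rbind, rxns), env_rxns),
    stoichiometry = stoich,
    genes = do.call(rbind, genes),
    annotations = list(community = list(
      members = member_ids,
      abundances = setNames(ab, member_ids),
      shared_metabolites = spec$shared_metabolites))
  )
}

prefix_gpr <- function(rule, prefix) {
  switch(rule$op,
    "true" = rule,
    "gene" = { rule$gene <- paste0(prefix, rule$gene); rule },
    { rule$args <- lapply(rule$args, prefix_gpr, prefix = prefix); rule }
  )
}

#' Community growth objective
#'
#' Builds the abundance-weighted sum objective over the members' growth
#' (or growth-proxy) reactions of a joined community model, ready to pass
#' to [fba()] or [build_lp()] as `objective`.
#'
#' @param model A community model produced by [join_models()].
#' @param member_growth_reactions Named character vector mapping member id
#'   to that member's growth reaction id (unprefixed).
#' @param weights Optional named weights per member; defaults to the
#'   normalized abundances recorded in the model. A zero-weight member is
#'   excluded from the objective but stays in the model.
#' @return Named numeric objective map over prefixed reaction ids.
#' @export
community_objective <- function(model, member_growth_reactions,
                                weights = NULL) {
  info <- model$annotations$community
  if (is.null(info)) {
    stop("`model` does not look like a joined community model ",
         "(missing community annotations)", call. = FALSE)
  }
  members <- names(member_growth_reactions)
  unknown <- setdiff(members, info$members)
  if (length(unknown)) {
    stop("unknown member id(s): ", paste(sQuote(unknown), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) weights <- info$abundances[members]
  obj <- setNames(as.numeric(weights),
                  paste0(members, "#", member_growth_reactions))
  missing <- setdiff(names(obj), model$reactions$id)
  if (length(missing)) {
    stop("unknown growth reaction(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  obj[obj != 0]
}
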