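#' Synthetic fixture models with known analytic optima
#'
#' Deterministic generators of small metabolic models whose FBA / FVA /
#' deletion answers are known in closed form. They stand in for external
#' model repositories in tests and benchmarks, and follow the naming
#' conventions of real genome-scale models (`EX_` exchange prefixes, `_e`
#' extracellular suffixes) so that exchange-detection heuristics are
#' exercised honestly.
#'
#' `make_chain()` builds a linear pathway `uptake -> n_internal conversions
#' -> export` with the objective on the export: the FBA optimum equals
#' `uptake_ub` and at `gamma = 1` every reaction's flux range collapses to
#' `[uptake_ub, uptake_ub]`.
#'
#' `make_branched()` splits the substrate into an efficient product branch
#' (yield `yield_p` product per substrate) and an ungated wasteful branch
#' that still makes the product, at yield `yield_w`, while excreting one
#' waste molecule per substrate consumed. The objective sits on the product
#' export, so the optimum is `uptake_ub * max(yield_p, yield_w)`. With
#' `gene_gating` the uptake is gated by gene `gU` and the efficient
#' conversion by `gP` (or the isozyme pair `"gP or gP2"` when
#' `isozyme = TRUE`); gene `gX` is present but unused. Knocking out the
#' efficient branch therefore reroutes flux through the wasteful one and
#' drops the optimum to `uptake_ub * yield_w` instead of killing growth.
#'
#' `make_diamond()` routes the substrate through two equivalent parallel
#' reactions: at `gamma = 1` each route's flux range is `[0, uptake_ub]`
#' while their sum is pinned to `uptake_ub`.
#'
#' `make_random_viable()` unions `n_pathways` independently parameterized
#' linear pathways drawing on one shared substrate. Pathway p has a random
#' capacity cap_p (its first conversion's upper bound), a random product
#' yield y_p, and — with probability 1/2 each — a single-gene gate `g<p>`
#' or an isozyme gate `g<p> or g<p>b` on its first conversion. The shared
#' uptake bound is the sum of all capacities, so the analytic optimum is
#' `sum(cap_p * y_p)` (stored, with the per-pathway parameters, in the
#' model's annotations under `fixture`). Same seed, same model, byte for
#' byte.
#'
#' @param n_internal Number of internal conversion reactions (chain).
#' @param uptake_ub Upper bound of the substrate uptake (mmol/gDW/h).
#' @param yield_p,yield_w Product / waste yields per unit substrate.
#' @param gene_gating Attach GPR rules to the branched fixture?
#' @param isozyme Gate the product branch with `"gP or gP2"` instead of
#'   `"gP"`.
#' @param n_pathways,pathway_len Shape of the random fixture.
#' @param seed Integer seed; the generator touches R's RNG only inside a
#'   save/restore guard, so callers' RNG state is unaffected.
#' @return A valid [metabolic_model()].
#' @examples
#' fba(make_chain(1, 10))$objective_value               # 10
#' fba(make_branched(10, 1, 0.5, TRUE))$objective_value # 10
#' m <- make_random_viable(3, 4, seed = 1)
#' m$annotations$fixture$optimum
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
make_chain <- function(n_internal = 1L, uptake_ub = 10) {
  stopifnot(n_internal >= 1, uptake_ub >= 0)
  mets <- c("S_e", if (n_internal > 1) paste0("C", seq_len(n_internal - 1), "_c"),
            "P_e")
  comp <- c("e", rep("c", n_internal - 1), "e")
  rxn_ids <- c("EX_S_e", paste0("CONV", seq_len(n_internal)), "EX_P_e")
  stoich <- c(
    list(EX_S_e = c(S_e = 1)),
    lapply(seq_len(n_internal), function(i) {
      setNames(c(-1, 1), c(mets[i], mets[i + 1]))
    }),
    list(EX_P_e = c(P_e = -1))
  )
  names(stoich) <- rxn_ids
  metabolic_model(
    id = sprintf("chain_%d", n_internal),
    metabolites = data.frame(id = mets, compartment = comp,
                             stringsAsFactors = FALSE),
    reactions = data.frame(
      id = rxn_ids,
      lower_bound = 0,
      upper_bound = c(uptake_ub, rep(1000, n_internal), 1000),
      objective_coefficient = c(rep(0, n_internal + 1), 1),
      stringsAsFactors = FALSE),
    stoichiometry = stoich,
    annotations = list(fixture = list(recipe = "chain",
                                      n_internal = n_internal,
                                      uptake_ub = uptake_ub,
                                      optimum = uptake_ub))
  )
}

#' @rdname fixtures
#' @export
make_branched <- function(uptake_ub = 10, yield_p = 1, yield_w = 0.5,
                          gene_gating = FALSE, isozyme = FALSE) {
  stopifnot(uptake_ub >= 0, yield_p >= 0, yield_w >= 0)
  genes <- if (gene_gating) c("gU", "gP", if (isozyme) "gP2", "gX") else NULL
  metabolic_model(
    id = "branched",
    metabolites = data.frame(
      id = c("S_e", "A_c", "P_e", "W_e"),
      compartment = c("e", "c", "e", "e"), stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_S_e", "UPT", "PCONV", "WCONV", "EX_P_e", "EX_W_e"),
      lower_bound = 0,
      upper_bound = c(uptake_ub, rep(1000, 5)),
      objective_coefficient = c(0, 0, 0, 0, 1, 0),
      gpr = if (gene_gating) {
        c("", "gU", if (isozyme) "gP or gP2" else "gP", "", "", "")
      } else "",
      stringsAsFactors = FALSE),
    stoichiometry = list(
      EX_S_e = c(S_e = 1),
      UPT = c(S_e = -1, A_c = 1),
      PCONV = c(A_c = -1, P_e = yield_p),
      WCONV = if (yield_w > 0) c(A_c = -1, P_e = yield_w, W_e = 1) else
        c(A_c = -1, W_e = 1),
      EX_P_e = c(P_e = -1),
      EX_W_e = c(W_e = -1)),
    genes = genes,
    annotations = list(fixture = list(
      recipe = "branched", uptake_ub = uptake_ub,
      yield_p = yield_p, yield_w = yield_w,
      optimum = uptake_ub * max(yield_p, yield_w)))
  )
}

#' @rdname fixtures
#' @export
make_diamond <- function(uptake_ub = 10) {
  stopifnot(uptake_ub >= 0)
  metabolic_model(
    id = "diamond",
    metabolites = data.frame(id = c("A_e", "B_e"), compartment = "e",
                             stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_A_e", "ROUTE1", "ROUTE2", "EX_B_e"),
      lower_bound = 0,
      upper_bound = c(uptake_ub, 1000, 1000, 1000),
      objective_coefficient = c(0, 0, 0, 1),
      stringsAsFactors = FALSE),
    stoichiometry = list(
      EX_A_e = c(A_e = 1),
      ROUTE1 = c(A_e = -1, B_e = 1),
      ROUTE2 = c(A_e = -1, B_e = 1),
      EX_B_e = c(B_e = -1)),
    annotations = list(fixture = list(recipe = "diamond",
                                      uptake_ub = uptake_ub,
                                      optimum = uptake_ub))
  )
}

#' @rdname fixtures
#' @export
make_random_viable <- function(n_pathways = 3L, pathway_len = 4L, seed = 1L) {
  stopifnot(n_pathways >= 1, pathway_len >= 1)
  with_seed(seed, {
    caps <- round(stats::runif(n_pathways, 1, 10), 3)
    yields <- round(stats::runif(n_pathways, 0.25, 2), 3)
    gating <- sample(c("single", "isozyme"), n_pathways, replace = TRUE)

    mets <- data.frame(id = "S_e", compartment = "e", stringsAsFactors = FALSE)
    rxns <- list(); stoich <- list(); genes <- character(0)
    add_rxn <- function(id, s, lb = 0, ub = 1000, obj = 0, gpr = "") {
      rxns[[length(rxns) + 1L]] <<- data.frame(
        id = id, lower_bound = lb, upper_bound = ub,
        objective_coefficient = obj, gpr = gpr, stringsAsFactors = FALSE)
      stoich[[id]] <<- s
    }

    add_rxn("EX_S_e", c(S_e = 1), ub = sum(caps))
    for (p in seq_len(n_pathways)) {
      chain_mets <- c(if (pathway_len > 1) {
        paste0("M", p, "_", seq_len(pathway_len - 1), "_c")
      }, paste0("P", p, "_e"))
      mets <- rbind(mets, data.frame(
        id = chain_mets,
        compartment = c(rep("c", pathway_len - 1), "e"),
        stringsAsFactors = FALSE))
      gp <- paste0("g", p)
      gpr <- if (gating[p] == "single") gp else paste0(gp, " or ", gp, "b")
      genes <- c(genes, gp, if (gating[p] == "isozyme") paste0(gp, "b"))
      prev <- "S_e"
      for (s in seq_len(pathway_len)) {
        cur <- chain_mets[s]
        coeff <- if (s == pathway_len) yields[p] else 1
        add_rxn(sprintf("P%d_STEP%d", p, s),
                setNames(c(-1, coeff), c(prev, cur)),
                ub = if (s == 1) caps[p] else 1000,
                gpr = if (s == 1) gpr else "")
        prev <- cur
      }
      add_rxn(sprintf("EX_P%d_e", p), setNames(-1, chain_mets[pathway_len]),
              obj = 1)
    }

    metabolic_model(
      id = sprintf("random_viable_s%d", as.integer(seed)),
      metabolites = mets,
      reactions = do.call(rbind, rxns),
      stoichiometry = stoich,
      genes = genes,
      annotations = list(fixture = list(
        recipe = "random_viable", seed = as.integer(seed),
        n_pathways = n_pathways, pathway_len = pathway_len,
        caps = caps, yields = yields, gating = gating,
        optimum = sum(caps * yields)))
    )
  })
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}
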