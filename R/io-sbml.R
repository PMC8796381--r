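#' Read an SBML Level 3 fbc model
#'
#' Reads genome-scale models stored as SBML Level 3 documents using the
#' flux-balance-constraints (`fbc`) package, version 2: flux bounds are
#' parameter references in the `fbc:lowerFluxBound` / `fbc:upperFluxBound`
#' reaction attributes, the objective comes from the active objective in
#' `fbc:listOfObjectives`, GPR rules from `fbc:geneProductAssociation`
#' trees, and genes from `fbc:listOfGeneProducts`.
#'
#' Species are mapped to metabolites (compartment preserved) and reactions
#' get their stoichiometry from `listOfReactants` (negative) and
#' `listOfProducts` (positive). Species flagged `boundaryCondition="true"`
#' are outside the steady-state constraint set and are therefore excluded:
#' they contribute no row to the stoichiometric matrix. When a reaction has
#' both a `reversible` attribute and bound parameters, the parameters win;
#' a reaction with no bound attributes at all falls back to the
#' reversibility defaults `(-1000, 1000)` / `(0, 1000)`. A bound attribute
#' pointing at a parameter that does not exist is an error naming the
#' reaction.
#'
#' Only reading is supported; JSON is the canonical write format (see
#' [write_model_json()]).
#'
#' @param path Path to the SBML file.
#' @return A validated [metabolic_model()].
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  if (!any(grepl("fbc", ns, fixed = TRUE))) {
    stop("unsupported SBML dialect: the document does not use the 'fbc' ",
         "package; only SBML L3 fbc models are readable", call. = FALSE)
  }

  attr_any <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }

  model_node <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  model_id <- attr_any(model_node, "id") %na% "model"

  # parameters: bound values referenced by id
  par_nodes <- xml2::xml_find_all(doc,
    "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pars <- setNames(as.numeric(vapply(par_nodes, attr_any, character(1), "value")),
                   vapply(par_nodes, attr_any, character(1), "id"))

  sp_nodes <- xml2::xml_find_all(doc,
    "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  boundary <- vapply(sp_nodes, function(s) {
    identical(tolower(attr_any(s, "boundaryCondition") %na% "false"), "true")
  }, logical(1))
  sp_ids <- vapply(sp_nodes, attr_any, character(1), "id")
  mets <- data.frame(
    id = sp_ids[!boundary],
    name = vapply(sp_nodes[!boundary], attr_any, character(1), "name"),
    compartment = vapply(sp_nodes[!boundary], attr_any, character(1),
                         "compartment"),
    formula = vapply(sp_nodes[!boundary], attr_any, character(1),
                     "chemicalFormula"),
    charge = suppressWarnings(as.numeric(
      vapply(sp_nodes[!boundary], attr_any, character(1), "charge"))),
    stringsAsFactors = FALSE)
  boundary_ids <- sp_ids[boundary]

  # gene products: id used in associations, label kept as the name
  gp_nodes <- xml2::xml_find_all(doc,
    "//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  genes <- if (length(gp_nodes)) {
    gids <- vapply(gp_nodes, attr_any, character(1), "id")
    labels <- vapply(gp_nodes, attr_any, character(1), "label")
    # a label merely echoing the id carries no separate name
    data.frame(id = gids,
               name = ifelse(labels == gids, NA_character_, labels),
               stringsAsFactors = FALSE)
  } else NULL

  # active objective
  obj_lists <- xml2::xml_find_first(doc, "//*[local-name()='listOfObjectives']")
  obj_coeffs <- setNames(numeric(0), character(0))
  if (!inherits(obj_lists, "xml_missing")) {
    active <- attr_any(obj_lists, "activeObjective")
    objs <- xml2::xml_find_all(obj_lists, "./*[local-name()='objective']")
    pick <- objs[[1]]
    if (!is.na(active)) {
      ids <- vapply(objs, attr_any, character(1), "id")
      if (active %in% ids) pick <- objs[[match(active, ids)]]
    }
    fo <- xml2::xml_find_all(pick,
      ".//*[local-name()='fluxObjective']")
    obj_coeffs <- setNames(
      as.numeric(vapply(fo, attr_any, character(1), "coefficient")),
      vapply(fo, attr_any, character(1), "reaction"))
  }

  rxn_nodes <- xml2::xml_find_all(doc,
    "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  stoich <- list()
  rxns <- do.call(rbind, lapply(rxn_nodes, function(rn) {
    rid <- attr_any(rn, "id")
    refs <- function(which, sign) {
      nodes <- xml2::xml_find_all(rn, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", which))
      if (!length(nodes)) return(setNames(numeric(0), character(0)))
      setNames(sign * as.numeric(vapply(nodes, function(x) {
        attr_any(x, "stoichiometry") %na% "1"
      }, character(1))),
      vapply(nodes, attr_any, character(1), "species"))
    }
    s <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    s <- s[!names(s) %in% boundary_ids]
    if (length(s)) {  # merge duplicate species references, keep first-seen order
      s <- tapply(s, names(s), sum)[unique(names(s))]
      s <- setNames(as.numeric(s), names(s))
    }
    stoich[[rid]] <<- if (length(s)) s else setNames(numeric(0), character(0))

    reversible <- identical(tolower(attr_any(rn, "reversible") %na% "false"),
                            "true")
    bound_of <- function(attr, default) {
      ref <- attr_any(rn, attr)
      if (is.na(ref)) return(default)
      if (!ref %in% names(pars)) {
        stop(sprintf("reaction %s: flux bound parameter %s not found",
                     sQuote(rid), sQuote(ref)), call. = FALSE)
      }
      pars[[ref]]
    }
    lb <- bound_of("lowerFluxBound", if (reversible) -1000 else 0)
    ub <- bound_of("upperFluxBound", 1000)

    gpa <- xml2::xml_find_first(rn,
      "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_find_all(gpa, "./*")
      deparse_gpr(sbml_gpr_tree(kids[[1]], attr_any))
    }

    data.frame(id = rid, name = attr_any(rn, "name"),
               lower_bound = lb, upper_bound = ub,
               objective_coefficient = unname(obj_coeffs[rid] %na% 0),
               gpr = gpr, stringsAsFactors = FALSE)
  }))

  model <- metabolic_model(id = model_id, metabolites = mets,
                           reactions = rxns, stoichiometry = stoich,
                           genes = genes, check = FALSE)
  rep <- validate_model(model)
  if (nrow(rep$errors) > 0) {
    stop("invalid model in SBML document:\n",
         paste0("  [", rep$errors$code, "] ", rep$errors$message,
                collapse = "\n"), call. = FALSE)
  }
  stopifnot(nrow(model$reactions) == length(rxn_nodes))
  model
}

# fbc association subtree -> gpr_rule
sbml_gpr_tree <- function(node, attr_any) {
  nm <- xml2::xml_name(node)  # local name, prefix stripped by xml2
  if (nm == "geneProductRef") {
    return(gpr_leaf(attr_any(node, "geneProduct")))
  }
  kids <- xml2::xml_find_all(node, "./*")
  args <- lapply(kids, sbml_gpr_tree, attr_any = attr_any)
  if (nm == "and") return(gpr_node("and", args))
  if (nm == "or") return(gpr_node("or", args))
  stop("unsupported geneProductAssociation element: ", nm, call. = FALSE)
}

`%na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Minimal SBML L3 fbc v2 serializer. Internal: it exists so that the fixture
# generators can materialize format twins of the same model for
# cross-format equivalence tests and the converter CLI; JSON remains the
# canonical write format.
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)))

  comps <- unique(model$metabolites$compartment)
  comps[is.na(comps)] <- "c"
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>',
                     esc(unique(comps))),
             "    </listOfCompartments>")

  lines <- c(lines, "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, sprintf(
      paste0('      <species id="%s"%s compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"/>'),
      esc(m$id),
      if (is.na(m$name)) "" else sprintf(' name="%s"', esc(m$name)),
      esc(if (is.na(m$compartment)) "c" else m$compartment)))
  }
  lines <- c(lines, "    </listOfSpecies>")

  # one shared parameter per distinct bound value
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  par_id <- function(v) {
    sprintf("fb_%s", gsub("[^0-9A-Za-z]", "_", num(v)))
  }
  lines <- c(lines, "    <listOfParameters>",
             vapply(bounds, function(v) {
               sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                       par_id(v), num(v))
             }, character(1)),
             "    </listOfParameters>")

  lines <- c(lines, "    <listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[[i]]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s"%s reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(r$id),
      if (is.na(r$name)) "" else sprintf(' name="%s"', esc(r$name)),
      if (r$lower_bound < 0) "true" else "false",
      par_id(r$lower_bound), par_id(r$upper_bound)))
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(names(reac)), num(-unname(reac))),
                 "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(names(prod)), num(unname(prod))),
                 "        </listOfProducts>")
    }
    if (nzchar(r$gpr)) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 sbml_gpr_xml(parse_gpr(r$gpr), indent = 10),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")

  active <- model$reactions$objective_coefficient != 0
  if (any(active)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      "        <fbc:listOfFluxObjectives>",
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                     'fbc:coefficient="%s"/>'),
              esc(model$reactions$id[active]),
              num(model$reactions$objective_coefficient[active])),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }

  if (nrow(model$genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               sprintf(paste0('      <fbc:geneProduct fbc:id="%s" ',
                              'fbc:label="%s"/>'),
                       esc(model$genes$id),
                       esc(ifelse(is.na(model$genes$name), model$genes$id,
                                  model$genes$name))),
               "    </fbc:listOfGeneProducts>")
  }

  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

sbml_gpr_xml <- function(rule, indent) {
  pad <- strrep(" ", indent)
  switch(rule$op,
    "gene" = sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                     pad, rule$gene),
    "and" = c(sprintf("%s<fbc:and>", pad),
              unlist(lapply(rule$args, sbml_gpr_xml, indent = indent + 2)),
              sprintf("%s</fbc:and>", pad)),
    "or" = c(sprintf("%s<fbc:or>", pad),
             unlist(lapply(rule$args, sbml_gpr_xml, indent = indent + 2)),
             sprintf("%s</fbc:or>", pad)),
    character(0)
  )
}
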