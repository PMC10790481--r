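# SBML Level 3 (core + fbc version 2) model I/O, via xml2.
#
# Conventions follow BiGG-style SBML: species ids carry an "M_" prefix,
# reactions "R_", gene products "G_"; prefixes are stripped on read and
# added on write. Flux bounds are fbc parameter references; GPR rules are
# fbc:geneProductAssociation trees; the active fbc objective becomes the
# model objective. Reaction categories are not persisted — they are
# re-inferred on read from id conventions and stoichiometry.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.strip_prefix <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

.compartment_letter <- function(met_id) {
  suffix <- sub("^.*_([A-Za-z0-9]+)$", "\\1", met_id)
  if (identical(suffix, met_id)) "x" else suffix
}

#' Read a metabolic model from SBML
#'
#' Parses SBML Level 3 with the fbc (flux-bounds and gene-product
#' association) package. Malformed XML raises a parse error naming the
#' offending line; species or gene references that do not resolve raise an
#' integrity error listing the ids.
#'
#' @param path path to an SBML file.
#' @return a \code{metabolic_model}.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("parse error: no <model> element in ", path)

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  met_ids_raw <- xml2::xml_attr(sp, "id")
  metabolites <- data.frame(
    id = .strip_prefix(met_ids_raw, "M"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  .strip_prefix(met_ids_raw, "M"),
                  xml2::xml_attr(sp, "name")),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    charge = suppressWarnings(
      as.integer(xml2::xml_attr(sp, "fbc:charge", ns = ns))),
    stringsAsFactors = FALSE)

  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                            ns)
  gp_ids <- xml2::xml_attr(gps, "fbc:id", ns = ns)
  gp_labels <- xml2::xml_attr(gps, "fbc:label", ns = ns)
  gp_labels[is.na(gp_labels)] <- .strip_prefix(gp_ids[is.na(gp_labels)], "G")
  gp_map <- stats::setNames(gp_labels, gp_ids)   # sbml id -> gene id

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "fbc:geneProduct", ns = ns)
      if (!(ref %in% names(gp_map)))
        stop("integrity error: unresolved gene product reference: ", ref)
      return(unname(gp_map[[ref]]))
    }
    kids <- xml2::xml_children(node)
    list(op = if (nm == "and") "and" else "or",
         args = lapply(kids, parse_assoc))
  }

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  met_lookup <- stats::setNames(metabolites$id, met_ids_raw)
  rx_ids <- character(0); rx_rows <- list(); stoich <- list()
  for (node in rx_nodes) {
    rid_raw <- xml2::xml_attr(node, "id")
    rid <- .strip_prefix(rid_raw, "R")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]]
          else 1000
    s <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, paste0("./s:", side, "/s:speciesReference"), ns)
      if (!length(refs)) next
      sp_ref <- xml2::xml_attr(refs, "species")
      bad <- setdiff(sp_ref, names(met_lookup))
      if (length(bad))
        stop("integrity error: unresolved species reference(s) in ",
             rid, ": ", paste(bad, collapse = ", "))
      coefs <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coefs[is.na(coefs)] <- 1
      if (side == "listOfReactants") coefs <- -coefs
      ids <- unname(met_lookup[sp_ref])
      for (k in seq_along(ids))
        s[ids[k]] <- (if (ids[k] %in% names(s)) s[[ids[k]]] else 0) + coefs[k]
    }
    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(ga, "xml_missing")) "" else gpr_deparse(parse_assoc(ga))
    rx_ids <- c(rx_ids, rid)
    rx_rows[[length(rx_rows) + 1L]] <- data.frame(
      id = rid, name = xml2::xml_attr(node, "name"),
      lower_bound = lb, upper_bound = ub, gpr = gpr,
      stringsAsFactors = FALSE)
    stoich[[rid]] <- s
  }
  reactions <- do.call(rbind, rx_rows)
  reactions$name[is.na(reactions$name)] <- reactions$id[is.na(reactions$name)]

  genes <- data.frame(id = unname(gp_map), name = unname(gp_map),
                      stringsAsFactors = FALSE)
  obj <- NA_character_
  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (!inherits(fo, "xml_missing"))
    obj <- .strip_prefix(xml2::xml_attr(fo, "fbc:reaction", ns = ns), "R")

  metabolic_model(metabolites, reactions, stoich,
                  genes = if (nrow(genes)) genes else NULL,
                  objective = obj,
                  id = xml2::xml_attr(mdl, "id") %||% "model")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write a metabolic model to SBML
#'
#' Emits SBML Level 3 Version 1 with the fbc version 2 package: species with
#' compartments, parameter-referenced flux bounds, gene products,
#' gene-product-association trees, and the objective. The written file reads
#' back (\code{\link{read_sbml}}) to a structurally identical model (same
#' ids, bounds, stoichiometry, GPR trees).
#'
#' @param model a \code{metabolic_model} (validated before writing).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "true")

  cmp_letters <- unique(vapply(model$metabolites$id, .compartment_letter,
                               character(1)))
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cl in cmp_letters)
    xml2::xml_add_child(loc, "compartment", id = cl, constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    attrs <- list(id = paste0("M_", mt$id), name = mt$name,
                  compartment = .compartment_letter(mt$id),
                  hasOnlySubstanceUnits = "false",
                  boundaryCondition = "false", constant = "false")
    if (!is.na(mt$formula)) attrs[["fbc:chemicalFormula"]] <- mt$formula
    if (!is.na(mt$charge)) attrs[["fbc:charge"]] <- as.character(mt$charge)
    do.call(xml2::xml_add_child, c(list(los, "species"), attrs))
  }

  if (nrow(model$genes)) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes$id)
      xml2::xml_add_child(logp, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", gsub("[^A-Za-z0-9_]", "_", g)),
                          "fbc:label" = g)
  }
  gene_sid <- stats::setNames(
    paste0("G_", gsub("[^A-Za-z0-9_]", "_", model$genes$id)),
    model$genes$id)

  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE,
                                digits = 15)
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    xml2::xml_add_child(lop, "parameter", id = paste0("R_", rx$id, "_lb"),
                        value = fmt_num(rx$lower_bound), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0("R_", rx$id, "_ub"),
                        value = fmt_num(rx$upper_bound), constant = "true")
  }

  add_assoc <- function(parent, tree) {
    if (is.character(tree)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = unname(gene_sid[[tree]]))
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
      for (a in tree$args) add_assoc(node, a)
    }
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    node <- xml2::xml_add_child(
      lor, "reaction", id = paste0("R_", rx$id), name = rx$name,
      reversible = if (rx$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = paste0("R_", rx$id, "_lb"),
      "fbc:upperFluxBound" = paste0("R_", rx$id, "_ub"))
    s <- model$stoichiometry[[rx$id]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (k in seq_along(reac))
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", names(reac)[k]),
                            stoichiometry = fmt_num(-unname(reac[k])),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (k in seq_along(prod))
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", names(prod)[k]),
                            stoichiometry = fmt_num(unname(prod[k])),
                            constant = "true")
    }
    tree <- gpr_parse(rx$gpr)
    if (!is.null(tree)) {
      ga <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      add_assoc(ga, tree)
    }
  }

  if (!is.na(model$objective)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    objn <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                                "fbc:type" = "maximize")
    lofo <- xml2::xml_add_child(objn, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lofo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", model$objective),
                        "fbc:coefficient" = "1")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
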