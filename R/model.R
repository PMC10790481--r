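#' @keywords internal
"_PACKAGE"

COMPARTMENT_SUFFIX <- c(c = "cytoplasm", p = "periplasm", e = "extracellular")

REACTION_CATEGORIES <- c("enzymatic", "transport", "exchange", "demand",
                         "sink", "spontaneous", "biomass", "maintenance")

#' Construct a genome-scale metabolic model
#'
#' The central container for constraint-based analysis: compartmentalised
#' metabolites, bounded reactions with gene-protein-reaction (GPR) rules,
#' genes, and a biomass (or other) objective reaction. Metabolite ids follow
#' the BiGG convention of a base id plus a compartment suffix
#' (\code{_c}, \code{_p}, \code{_e}); unknown suffixes are kept as extra
#' compartments rather than rejected.
#'
#' @param metabolites data.frame with columns \code{id}, and optionally
#'   \code{name}, \code{compartment}, \code{formula}, \code{charge}.
#'   Missing compartments are inferred from the id suffix.
#' @param reactions data.frame with columns \code{id}, and optionally
#'   \code{name}, \code{lower_bound}, \code{upper_bound} (mmol/gDCW/h),
#'   \code{gpr} (boolean rule string over gene ids), \code{category}.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param genes data.frame with column \code{id} (locus tags) and optional
#'   \code{name}; if \code{NULL}, genes are collected from the GPR rules.
#' @param objective id of the objective reaction, or \code{NA}.
#' @param id model identifier string.
#' @return An object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL, objective = NA_character_,
                            id = "model") {
  metabolites <- .complete_metabolites(metabolites)
  reactions <- .complete_reactions(reactions)
  stoichiometry <- lapply(stoichiometry, function(s) {
    stopifnot(is.numeric(s), !is.null(names(s)))
    s[s != 0]
  })
  if (is.null(genes)) {
    ids <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
    genes <- data.frame(id = as.character(ids), name = as.character(ids),
                        stringsAsFactors = FALSE)
  } else {
    genes <- .complete_genes(genes)
  }
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions, stoichiometry = stoichiometry,
                      genes = genes, objective = objective),
                 class = "metabolic_model")
  validate_model(m)
  m
}

.complete_metabolites <- function(df) {
  stopifnot(is.data.frame(df), "id" %in% names(df))
  df$id <- as.character(df$id)
  if (is.null(df$name)) df$name <- df$id
  if (is.null(df$compartment))
    df$compartment <- rep(NA_character_, nrow(df))
  missing_cmp <- is.na(df$compartment)
  df$compartment[missing_cmp] <-
    vapply(df$id[missing_cmp], compartment_of, character(1))
  if (is.null(df$formula)) df$formula <- rep(NA_character_, nrow(df))
  if (is.null(df$charge)) df$charge <- rep(NA_integer_, nrow(df))
  rownames(df) <- NULL
  df[c("id", "name", "compartment", "formula", "charge")]
}

.complete_reactions <- function(df) {
  stopifnot(is.data.frame(df), "id" %in% names(df))
  df$id <- as.character(df$id)
  if (is.null(df$name)) df$name <- df$id
  if (is.null(df$lower_bound)) df$lower_bound <- rep(-1000, nrow(df))
  if (is.null(df$upper_bound)) df$upper_bound <- rep(1000, nrow(df))
  if (is.null(df$gpr)) df$gpr <- rep("", nrow(df))
  df$gpr[is.na(df$gpr)] <- ""
  if (is.null(df$category)) df$category <- rep(NA_character_, nrow(df))
  rownames(df) <- NULL
  df[c("id", "name", "lower_bound", "upper_bound", "gpr", "category")]
}

.complete_genes <- function(df) {
  stopifnot(is.data.frame(df), "id" %in% names(df))
  df$id <- as.character(df$id)
  if (is.null(df$name)) df$name <- df$id
  rownames(df) <- NULL
  df[c("id", "name")]
}

#' Compartment of a metabolite id
#'
#' Strips the trailing \code{_<suffix>} and maps \code{c}/\code{p}/\code{e}
#' to cytoplasm/periplasm/extracellular; any other suffix is returned as-is
#' (treated as an extra compartment).
#' @param met_id metabolite id string.
#' @return compartment name (character scalar).
#' @export
compartment_of <- function(met_id) {
  suffix <- sub("^.*_([A-Za-z0-9]+)$", "\\1", met_id)
  if (identical(suffix, met_id)) return("unknown")
  if (suffix %in% names(COMPARTMENT_SUFFIX)) COMPARTMENT_SUFFIX[[suffix]]
  else suffix
}

#' Base (compartment-stripped) metabolite id
#' @param met_id metabolite id string.
#' @return base id with the compartment suffix removed.
#' @export
base_metabolite_id <- function(met_id) {
  sub("_[A-Za-z0-9]+$", "", met_id)
}

#' Validate model integrity
#'
#' Checks the structural invariants: unique metabolite/reaction/gene ids,
#' lower_bound <= upper_bound, non-empty stoichiometries whose keys resolve
#' to metabolites, GPR leaves resolving to genes, boundary reactions
#' (exchange/demand/sink) touching exactly one metabolite, and a resolvable
#' objective.
#' @param model a \code{metabolic_model}.
#' @return invisibly \code{TRUE}; stops with an integrity error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  if (anyDuplicated(mets))
    stop("integrity error: duplicate metabolite ids: ",
         paste(unique(mets[duplicated(mets)]), collapse = ", "))
  if (anyDuplicated(rxns))
    stop("integrity error: duplicate reaction ids: ",
         paste(unique(rxns[duplicated(rxns)]), collapse = ", "))
  if (anyDuplicated(model$genes$id))
    stop("integrity error: duplicate gene ids")
  if (any(model$reactions$lower_bound > model$reactions$upper_bound))
    stop("integrity error: lower_bound > upper_bound for: ",
         paste(rxns[model$reactions$lower_bound >
                    model$reactions$upper_bound], collapse = ", "))
  if (!setequal(names(model$stoichiometry), rxns))
    stop("integrity error: stoichiometry entries do not match reaction ids")
  empty <- vapply(model$stoichiometry, length, 1L) == 0L
  if (any(empty))
    stop("integrity error: empty stoichiometry for: ",
         paste(names(model$stoichiometry)[empty], collapse = ", "))
  bad <- setdiff(unlist(lapply(model$stoichiometry, names)), mets)
  if (length(bad))
    stop("integrity error: unresolved metabolite ids in stoichiometry: ",
         paste(bad, collapse = ", "))
  gpr_ids <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  badg <- setdiff(gpr_ids, model$genes$id)
  if (length(badg))
    stop("integrity error: GPR references unknown genes: ",
         paste(badg, collapse = ", "))
  cat_known <- reaction_categories(model)
  boundary <- rxns[cat_known %in% c("exchange", "demand", "sink")]
  n_touch <- vapply(model$stoichiometry[boundary], length, 1L)
  if (length(boundary) && any(n_touch != 1L))
    stop("integrity error: boundary reactions must touch exactly one ",
         "metabolite: ", paste(boundary[n_touch != 1L], collapse = ", "))
  if (!is.na(model$objective) && !(model$objective %in% rxns))
    stop("integrity error: objective reaction '", model$objective,
         "' not in model")
  invisible(TRUE)
}

#' Infer reaction categories
#'
#' Category precedence: explicit \code{category} field, then id prefix
#' (\code{EX_} exchange, \code{DM_} demand, \code{sink_}/\code{SK_} sink,
#' \code{ATPM} maintenance, id containing \code{biomass}/\code{BIOMASS}
#' biomass), then a single-extracellular-metabolite heuristic for exchanges,
#' then transport (spanning >1 compartment) vs enzymatic.
#' @param model a \code{metabolic_model}.
#' @return character vector of categories, one per reaction, in model order.
#' @export
reaction_categories <- function(model) {
  rx <- model$reactions
  out <- rx$category
  for (i in seq_len(nrow(rx))) {
    if (!is.na(out[i]) && nzchar(out[i])) next
    id <- rx$id[i]
    s <- model$stoichiometry[[id]]
    cmps <- unique(vapply(names(s), compartment_of, character(1)))
    out[i] <-
      if (grepl("^EX_", id)) "exchange"
      else if (grepl("^DM_", id)) "demand"
      else if (grepl("^(sink_|SK_)", id)) "sink"
      else if (grepl("^ATPM$", id)) "maintenance"
      else if (grepl("biomass", id, ignore.case = TRUE)) "biomass"
      else if (length(s) == 1L &&
               identical(cmps, "extracellular")) "exchange"
      else if (length(cmps) > 1L) "transport"
      else "enzymatic"
  }
  out
}

#' @exportS3Method base::print
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model <", x$id, ">\n", sep = "")
  cat("  metabolites:", nrow(x$metabolites),
      "(", length(unique(base_metabolite_id(x$metabolites$id))), "unique )\n")
  cat("  reactions:  ", nrow(x$reactions), "\n")
  cat("  genes:      ", nrow(x$genes), "\n")
  cat("  objective:  ", x$objective, "\n")
  invisible(x)
}

#' Look up a reaction row
#' @param model a \code{metabolic_model}.
#' @param id reaction id.
#' @return one-row data.frame.
#' @export
get_reaction <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("key error: unknown reaction id '", id, "'")
  model$reactions[i, ]
}

#' Set flux bounds on a reaction (returns a modified copy)
#' @param model a \code{metabolic_model}.
#' @param id reaction id.
#' @param lower,upper new bounds (mmol/gDCW/h); \code{NA} keeps the old value.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lower = NA, upper = NA) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("key error: unknown reaction id '", id, "'")
  if (!is.na(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.na(upper)) model$reactions$upper_bound[i] <- upper
  model
}

#' Add a reaction to a model (returns a modified copy)
#' @param model a \code{metabolic_model}.
#' @param id reaction id (must be new).
#' @param stoichiometry named numeric vector of metabolite coefficients;
#'   metabolites not yet in the model are added (compartment from suffix).
#' @param lower_bound,upper_bound flux bounds.
#' @param gpr GPR rule string (may be empty).
#' @param name reaction name.
#' @param category reaction category or \code{NA} to infer.
#' @return the modified model.
#' @export
add_reaction <- function(model, id, stoichiometry, lower_bound = -1000,
                         upper_bound = 1000, gpr = "", name = id,
                         category = NA_character_) {
  if (id %in% model$reactions$id)
    stop("integrity error: reaction '", id, "' already present")
  new_mets <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(new_mets)) {
    model$metabolites <- rbind(model$metabolites, .complete_metabolites(
      data.frame(id = new_mets, stringsAsFactors = FALSE)))
  }
  model$reactions <- rbind(model$reactions, .complete_reactions(
    data.frame(id = id, name = name, lower_bound = lower_bound,
               upper_bound = upper_bound, gpr = gpr, category = category,
               stringsAsFactors = FALSE)))
  model$stoichiometry[[id]] <- stoichiometry
  new_genes <- setdiff(gpr_genes(gpr), model$genes$id)
  if (length(new_genes)) {
    model$genes <- rbind(model$genes, data.frame(
      id = new_genes, name = new_genes, stringsAsFactors = FALSE))
  }
  model
}

#' Remove reactions from a model (returns a modified copy)
#' @param model a \code{metabolic_model}.
#' @param ids reaction ids to drop.
#' @return the modified model (orphan metabolites are kept).
#' @export
remove_reactions <- function(model, ids) {
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown))
    stop("key error: unknown reaction id(s): ", paste(unknown, collapse = ", "))
  keep <- !(model$reactions$id %in% ids)
  model$reactions <- model$reactions[keep, ]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  if (!is.na(model$objective) && model$objective %in% ids)
    model$objective <- NA_character_
  model
}
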