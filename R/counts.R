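#' Structural accounting of a metabolic model
#'
#' Produces the model-statistics report: total and per-category reaction
#' counts, per-compartment and unique (compartment-stripped) metabolite
#' counts, and gene-associated vs. non-gene-associated reaction counts.
#' Where the \code{category} field is absent, categories are inferred from
#' id conventions (exchange \code{EX_}, demand \code{DM_}, sink
#' \code{sink_}/\code{SK_}) and stoichiometric heuristics; see
#' \code{\link{reaction_categories}}.
#'
#' @param model a \code{metabolic_model}.
#' @return list with \code{n_genes}, \code{n_reactions}, \code{n_metabolites},
#'   \code{n_unique_metabolites}, \code{reactions_by_category} (named
#'   integer), \code{metabolites_by_compartment} (named integer),
#'   \code{gene_associated} and \code{not_gene_associated} reaction counts.
#' @export
classify_and_count <- function(model) {
  cats <- reaction_categories(model)
  by_cat <- table(factor(cats, levels = union(REACTION_CATEGORIES,
                                              unique(cats))))
  cmp <- model$metabolites$compartment
  has_gpr <- nzchar(trimws(model$reactions$gpr))
  list(
    n_genes = nrow(model$genes),
    n_reactions = nrow(model$reactions),
    n_metabolites = nrow(model$metabolites),
    n_unique_metabolites =
      length(unique(base_metabolite_id(model$metabolites$id))),
    reactions_by_category = c(unclass(by_cat)),
    metabolites_by_compartment = c(unclass(table(cmp))),
    gene_associated = sum(has_gpr),
    not_gene_associated = sum(!has_gpr)
  )
}

#' Write a model-statistics report as JSON
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_count_report <- function(model, path) {
  jsonlite::write_json(classify_and_count(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
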