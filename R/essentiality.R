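# GPR-aware single-gene deletion screening.
#
# Deleting a gene disables every reaction whose GPR rule evaluates false
# without it; disabling zeroes both flux bounds (rows are kept so the
# stoichiometric matrix and indexing are reusable across the whole sweep).

#' Delete one or more genes from a model
#'
#' Every reaction whose GPR evaluates false under the deletion set has both
#' bounds set to 0; reactions with no gene association are untouched. Note
#' that a multi-gene deletion must be passed as one vector: GPR rules are
#' re-evaluated against the whole set, which sequential single-gene calls
#' cannot reproduce.
#' @param model a \code{metabolic_model}.
#' @param gene character vector of gene ids (all must exist in the model).
#' @return a modified copy of the model.
#' @export
delete_gene <- function(model, gene) {
  unknown <- setdiff(gene, model$genes$id)
  if (length(unknown))
    stop("key error: unknown gene '", paste(unknown, collapse = ", "), "'")
  for (i in seq_len(nrow(model$reactions))) {
    rule <- model$reactions$gpr[i]
    if (!nzchar(trimws(rule))) next
    if (!evaluate_gpr(gpr_parse(rule), gene)) {
      model$reactions$lower_bound[i] <- 0
      model$reactions$upper_bound[i] <- 0
    }
  }
  model
}

#' Screen all single-gene deletions for essentiality
#'
#' Computes the wild-type growth on the medium, then for each gene disables
#' the reactions its deletion knocks out and re-solves; a gene is essential
#' when the deletion growth drops below \code{threshold} (default 5\%) of
#' wild type (growth exactly at the threshold is non-essential, matching
#' the strict "less than" rule). Genes appearing in no GPR, or whose
#' deletion disables nothing (isozyme backup), reuse the wild-type solution
#' without a new LP.
#'
#' @param model a \code{metabolic_model} with a biomass objective.
#' @param medium optional medium (named numeric) applied with
#'   \code{closed_by_default = TRUE} before screening.
#' @param threshold essentiality fraction of wild-type growth (default 0.05).
#' @return data.frame (\code{gene}, \code{growth}, \code{essential}) in
#'   model gene order; attribute \code{wild_type} carries the reference
#'   growth rate.
#' @export
screen_essential_genes <- function(model, medium = NULL, threshold = 0.05) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  wt <- solve_fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0)
    stop("configuration error: wild type does not grow on this medium ",
         "(status ", wt$status, ")")
  wt_growth <- wt$objective_value
  trees <- lapply(model$reactions$gpr, gpr_parse)
  has_rule <- !vapply(trees, is.null, logical(1))
  rows <- lapply(model$genes$id, function(g) {
    hit <- which(has_rule & !vapply(trees, evaluate_gpr, logical(1),
                                    deleted = g))
    growth <- if (!length(hit)) wt_growth else {
      ov <- stats::setNames(rep(list(c(0, 0)), length(hit)),
                            model$reactions$id[hit])
      sol <- solve_fba(model, bound_overrides = ov)
      if (sol$status == "optimal") max(sol$objective_value, 0) else 0
    }
    data.frame(gene = g, growth = growth,
               essential = growth < threshold * wt_growth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "wild_type") <- wt_growth
  out
}

#' Compare two essential-gene sets across models
#'
#' Maps set \code{b} into \code{a}'s gene namespace through an ortholog map
#' (identity by default) and partitions the union.
#' @param a,b character vectors of essential gene ids.
#' @param ortholog_map named character vector mapping ids of \code{b}'s
#'   namespace onto \code{a}'s; ids absent from the map are kept unchanged.
#' @return list with \code{shared}, \code{only_a}, \code{only_b} (sorted).
#' @export
compare_essential_sets <- function(a, b, ortholog_map = NULL) {
  b_mapped <- if (is.null(ortholog_map)) b else
    ifelse(b %in% names(ortholog_map), unname(ortholog_map[b]), b)
  a <- unique(a); b_mapped <- unique(b_mapped)
  list(shared = sort(intersect(a, b_mapped)),
       only_a = sort(setdiff(a, b_mapped)),
       only_b = sort(setdiff(b_mapped, a)))
}
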