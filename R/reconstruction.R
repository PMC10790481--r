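# Draft reconstruction from homology tables, gap-filling to biomass
# producibility, and phenotype-driven refinement.

#' Read a tabular homology (alignment) table
#'
#' Standard tabular alignment output with columns \code{qseqid},
#' \code{sseqid}, \code{pident}, \code{qcovs}, \code{evalue} (header
#' optional; the five columns are taken in this order when absent).
#' @param path TSV file.
#' @return data.frame of homology records.
#' @export
read_homology_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("qseqid|pident", first)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 5)
      stop("parse error: homology table needs 5 columns ",
           "(qseqid, sseqid, pident, qcovs, evalue)")
    names(df)[1:5] <- c("qseqid", "sseqid", "pident", "qcovs", "evalue")
  }
  need <- c("qseqid", "sseqid", "pident", "qcovs", "evalue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: homology table missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$pident) | df$pident < 0 | df$pident > 100 |
                 !is.finite(df$qcovs) | df$qcovs < 0 | df$qcovs > 100 |
                 !is.finite(df$evalue) | df$evalue < 0)
  if (length(bad))
    stop("parse error: malformed homology record at line ",
         bad[1] + has_header)
  df
}

#' Filter homology records to accepted homolog pairs
#'
#' A pair is a homolog when percent identity and query coverage are both
#' strictly over the thresholds ("over 90\%": 90.0 exactly is rejected),
#' and the E-value is at most \code{evalue_max}. One best hit is kept per
#' query, ordered by (identity, coverage, -E-value) with the
#' lexicographically smaller subject id breaking exact ties — the result is
#' invariant to record order.
#'
#' @param records data.frame of homology records
#'   (\code{\link{read_homology_table}}).
#' @param identity_min,coverage_min strict lower thresholds (default 90).
#' @param evalue_max inclusive E-value ceiling (default \code{Inf}; the
#'   automated-reconstruction screening mode uses coverage 90, identity 40,
#'   E-value 2e-21).
#' @return data.frame of accepted best hits (one row per query), sorted by
#'   query id.
#' @export
map_homologs <- function(records, identity_min = 90, coverage_min = 90,
                         evalue_max = Inf) {
  keep <- records$pident > identity_min & records$qcovs > coverage_min &
    records$evalue <= evalue_max
  df <- records[keep, , drop = FALSE]
  if (!nrow(df)) return(df)
  ord <- order(df$qseqid, -df$pident, -df$qcovs, df$evalue, df$sseqid)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$qseqid), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assemble a draft model from donor models
#'
#' Every donor reaction cited by a mapping is transplanted: reactions mapped
#' through the primary donor first, then secondary-donor reactions whose ids
#' are not already present (duplicates keep the primary donor's version),
#' then \code{extra_reactions}. GPR rules are rewritten from donor gene ids
#' to target gene ids using the mapping's gene pairs.
#'
#' @param primary_donor,secondary_donor donor \code{metabolic_model}s
#'   (secondary may be \code{NULL}).
#' @param mappings data.frame with columns \code{target_gene},
#'   \code{donor} ("primary"/"secondary"), \code{donor_gene},
#'   \code{donor_reaction}.
#' @param extra_reactions optional list of reaction specs, each a list with
#'   \code{id}, \code{stoichiometry} (named numeric), and optionally
#'   \code{lower_bound}, \code{upper_bound}, \code{gpr}, \code{name} —
#'   automated-reconstruction and curated additions.
#' @param objective objective reaction id for the draft (optional).
#' @param id model id of the draft.
#' @return a \code{metabolic_model}.
#' @export
assemble_draft <- function(primary_donor, secondary_donor = NULL, mappings,
                           extra_reactions = list(),
                           objective = NA_character_, id = "draft") {
  stopifnot(is.data.frame(mappings) || is.null(mappings))
  if (is.null(mappings))
    mappings <- data.frame(target_gene = character(0), donor = character(0),
                           donor_gene = character(0),
                           donor_reaction = character(0))
  draft <- metabolic_model(
    .complete_metabolites(data.frame(id = character(0))),
    .complete_reactions(data.frame(id = character(0))),
    list(), genes = data.frame(id = character(0), name = character(0)),
    id = id)
  take_from <- function(draft, donor, rows) {
    if (!nrow(rows)) return(draft)
    gene_map <- stats::setNames(rows$target_gene, rows$donor_gene)
    for (rid in unique(rows$donor_reaction)) {
      if (!(rid %in% donor$reactions$id))
        stop("integrity error: mapping cites reaction '", rid,
             "' absent from donor model '", donor$id, "'")
      if (rid %in% draft$reactions$id) next
      i <- match(rid, donor$reactions$id)
      draft <- add_reaction(
        draft, rid, donor$stoichiometry[[rid]],
        lower_bound = donor$reactions$lower_bound[i],
        upper_bound = donor$reactions$upper_bound[i],
        gpr = gpr_rewrite(donor$reactions$gpr[i], gene_map),
        name = donor$reactions$name[i])
    }
    draft
  }
  draft <- take_from(draft, primary_donor,
                     mappings[mappings$donor == "primary", , drop = FALSE])
  if (!is.null(secondary_donor))
    draft <- take_from(draft, secondary_donor,
                       mappings[mappings$donor == "secondary", ,
                                drop = FALSE])
  for (ex in extra_reactions) {
    if (ex$id %in% draft$reactions$id) next
    draft <- add_reaction(draft, ex$id, ex$stoichiometry,
                          lower_bound = ex$lower_bound %||% -1000,
                          upper_bound = ex$upper_bound %||% 1000,
                          gpr = ex$gpr %||% "",
                          name = ex$name %||% ex$id)
  }
  if (!is.na(objective)) draft$objective <- objective
  validate_model(draft)
  draft
}

#' Gap-fill a draft model to restore growth
#'
#' Searches candidate additions in deterministic pool order: first each
#' singleton, then every unordered pair (i < j); the first addition set
#' pushing growth above \code{threshold} is returned and verified minimal
#' (growth collapses when any member is removed). If no set of size
#' \code{<= max_set_size} works, an "unfillable" result is returned with
#' dead-end metabolite diagnostics (biomass-side metabolites that no open
#' reaction can produce).
#'
#' @param draft a \code{metabolic_model} whose objective currently carries
#'   zero flux (not growing).
#' @param candidate_pool list of reaction specs (as in
#'   \code{\link{assemble_draft}}'s \code{extra_reactions}).
#' @param objective objective reaction id (default: draft objective).
#' @param max_set_size largest addition set searched (default 2; the cost
#'   grows combinatorially above that).
#' @param threshold growth considered restored above this (default 1e-6).
#' @return list with \code{status} ("filled", "already_growing",
#'   "unfillable"), \code{added} (ordered ids), \code{growth}, and for
#'   unfillable drafts \code{dead_ends}.
#' @export
gap_fill <- function(draft, candidate_pool, objective = draft$objective,
                     max_set_size = 2, threshold = 1e-6) {
  if (!length(candidate_pool)) stop("validation error: empty candidate pool")
  if (max_set_size > 2)
    warning("gap_fill with max_set_size > 2 enumerates all subsets; ",
            "cost grows exponentially")
  growth_of <- function(model) {
    sol <- solve_fba(model, objective = objective)
    if (sol$status == "optimal") max(sol$objective_value, 0) else 0
  }
  g0 <- growth_of(draft)
  if (g0 > threshold)
    return(list(status = "already_growing", added = character(0),
                growth = g0))
  with_added <- function(idx) {
    m <- draft
    for (k in idx) {
      ex <- candidate_pool[[k]]
      m <- add_reaction(m, ex$id, ex$stoichiometry,
                        lower_bound = ex$lower_bound %||% -1000,
                        upper_bound = ex$upper_bound %||% 1000,
                        gpr = ex$gpr %||% "", name = ex$name %||% ex$id)
    }
    m
  }
  sets <- lapply(seq_along(candidate_pool), function(i) i)
  if (max_set_size >= 2 && length(candidate_pool) >= 2)
    sets <- c(sets, utils::combn(seq_along(candidate_pool),
                                 2, simplify = FALSE))
  if (max_set_size > 2)
    for (k in 3:min(max_set_size, length(candidate_pool)))
      sets <- c(sets, utils::combn(seq_along(candidate_pool), k,
                                   simplify = FALSE))
  for (idx in sets) {
    g <- growth_of(with_added(idx))
    if (g > threshold) {
      # minimality: removing any single added reaction must break growth
      for (drop in idx) {
        gd <- growth_of(with_added(setdiff(idx, drop)))
        if (gd > threshold)
          stop("gap_fill internal: non-minimal addition set found first; ",
               "pool ordering violated")
      }
      ids <- vapply(candidate_pool[idx], function(e) e$id, character(1))
      return(list(status = "filled", added = ids, growth = g))
    }
  }
  list(status = "unfillable", added = character(0), growth = 0,
       dead_ends = .dead_end_metabolites(draft))
}

# metabolites no open reaction can produce (considering reversibility)
.dead_end_metabolites <- function(model) {
  producible <- character(0)
  for (rid in model$reactions$id) {
    i <- match(rid, model$reactions$id)
    lb <- model$reactions$lower_bound[i]; ub <- model$reactions$upper_bound[i]
    s <- model$stoichiometry[[rid]]
    if (ub > 0) producible <- union(producible, names(s)[s > 0])
    if (lb < 0) producible <- union(producible, names(s)[s < 0])
  }
  setdiff(model$metabolites$id, producible)
}

#' Refine a model against phenotype-microarray observations
#'
#' For every false positive (growth predicted, non-growth observed) the
#' substrate's exchange reaction is removed; for every false negative with
#' transporter evidence the evidence's exchange and transport reactions are
#' added with their GPR; false negatives without evidence are logged and
#' left unchanged. The change log enumerates every modification.
#'
#' @param model a \code{metabolic_model}.
#' @param calls experimental \code{GrowthCallTable} (data.frame with
#'   \code{substrate}, \code{call}).
#' @param predictions predicted calls, same substrate set, with an
#'   \code{exchange} column naming each substrate's exchange reaction.
#' @param transporter_evidence named list (substrate -> list of reaction
#'   specs as in \code{\link{assemble_draft}}) supplying exchange +
#'   transport reactions for false negatives.
#' @return list with \code{model} (revised) and \code{log} (data.frame:
#'   substrate, action, reaction).
#' @export
refine_with_phenotypes <- function(model, calls, predictions,
                                   transporter_evidence = list()) {
  stopifnot(all(c("substrate", "call") %in% names(calls)),
            all(c("substrate", "call") %in% names(predictions)))
  if (!setequal(calls$substrate, predictions$substrate))
    stop("validation error: calls and predictions must index the same ",
         "substrates; differing: ",
         paste(c(setdiff(calls$substrate, predictions$substrate),
                 setdiff(predictions$substrate, calls$substrate)),
               collapse = ", "))
  log_rows <- list()
  note <- function(substrate, action, reaction)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      substrate = substrate, action = action, reaction = reaction,
      stringsAsFactors = FALSE)
  obs <- stats::setNames(calls$call, calls$substrate)
  for (i in seq_len(nrow(predictions))) {
    sub <- predictions$substrate[i]
    pred <- predictions$call[i]
    if (pred && !obs[[sub]]) {                      # false positive
      ex <- predictions$exchange[i]
      if (!is.null(ex) && !is.na(ex) && ex %in% model$reactions$id) {
        model <- remove_reactions(model, ex)
        note(sub, "remove_exchange", ex)
      } else {
        note(sub, "fp_no_exchange", NA_character_)
      }
    } else if (!pred && obs[[sub]]) {               # false negative
      ev <- transporter_evidence[[sub]]
      if (is.null(ev)) {
        note(sub, "fn_no_evidence", NA_character_)
      } else {
        for (spec in ev) {
          bad <- setdiff(names(spec$stoichiometry),
                         union(model$metabolites$id,
                               names(spec$stoichiometry)[
                                 grepl("_[cpe]$", names(spec$stoichiometry))]))
          if (length(bad))
            stop("integrity error: evidence for '", sub,
                 "' references unknown metabolites: ",
                 paste(bad, collapse = ", "))
          if (!(spec$id %in% model$reactions$id)) {
            model <- add_reaction(model, spec$id, spec$stoichiometry,
                                  lower_bound = spec$lower_bound %||% -1000,
                                  upper_bound = spec$upper_bound %||% 1000,
                                  gpr = spec$gpr %||% "",
                                  name = spec$name %||% spec$id)
            note(sub, "add_reaction", spec$id)
          }
        }
      }
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(substrate = character(0), action = character(0),
               reaction = character(0), stringsAsFactors = FALSE)
  list(model = model, log = log)
}
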