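# Tab-separated tabular model sheets (plain-text export of spreadsheet-form
# models). Reaction sheet columns: id, [name], equation, [lower_bound],
# [upper_bound], [gpr], [category]; metabolite sheet columns: id, [name],
# [formula], [charge]. Equation arrows: "->" (irreversible), "<=>"
# (reversible), "<-" (reverse irreversible). Default bounds when absent:
# reversible (-1000, 1000), irreversible (0, 1000).

#' Parse a reaction equation string
#'
#' Accepts strings like \code{"2 a_c + b_c -> c_c"} or
#' \code{"a_c <=> a_p"}; coefficients default to 1. A \code{"<-"} arrow is
#' normalised by swapping sides.
#'
#' @param equation equation string.
#' @return list with \code{stoichiometry} (named numeric, negative =
#'   consumed) and \code{reversible} (logical).
#' @export
parse_equation <- function(equation) {
  arrow <- regmatches(equation, regexpr("<=>|<->|-->|->|<-", equation))
  if (!length(arrow))
    stop("parse error: no reaction arrow in equation '", equation, "'")
  sides <- strsplit(equation, "<=>|<->|-->|->|<-", fixed = FALSE)[[1]]
  if (length(sides) > 2)
    stop("parse error: multiple arrows in equation '", equation, "'")
  if (length(sides) == 1) sides <- c(sides, "")
  reversible <- arrow %in% c("<=>", "<->")
  if (arrow == "<-") sides <- rev(sides)
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "\\+")[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) next
      parts <- strsplit(tm, "\\s+")[[1]]
      coef <- suppressWarnings(as.numeric(parts[1]))
      if (!is.na(coef) && length(parts) >= 2) {
        id <- paste(parts[-1], collapse = "_")
      } else {
        coef <- 1
        id <- paste(parts, collapse = "_")
      }
      out[id] <- (if (id %in% names(out)) out[[id]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  s <- lhs
  for (id in names(rhs))
    s[id] <- (if (id %in% names(s)) s[[id]] else 0) + rhs[[id]]
  list(stoichiometry = s[s != 0], reversible = reversible)
}

#' Read a metabolic model from tabular sheets
#'
#' @param reactions_path TSV reaction sheet (columns \code{id},
#'   \code{equation}, and optionally \code{name}, \code{lower_bound},
#'   \code{upper_bound}, \code{gpr}, \code{category}, \code{objective} —
#'   a logical/0-1 column marking the objective reaction).
#' @param metabolites_path optional TSV metabolite sheet (\code{id},
#'   optionally \code{name}, \code{formula}, \code{charge}); metabolites
#'   appearing only in equations are added automatically. Duplicate
#'   metabolite rows with conflicting content raise an integrity error.
#' @param id model identifier.
#' @return a \code{metabolic_model}; an empty reaction sheet yields an empty
#'   model.
#' @export
read_tabular_model <- function(reactions_path, metabolites_path = NULL,
                               id = "model") {
  rx <- utils::read.delim(reactions_path, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(rx)) {
    return(structure(list(id = id,
                          metabolites = .complete_metabolites(
                            data.frame(id = character(0))),
                          reactions = .complete_reactions(
                            data.frame(id = character(0))),
                          stoichiometry = list(),
                          genes = data.frame(id = character(0),
                                             name = character(0)),
                          objective = NA_character_),
                     class = "metabolic_model"))
  }
  if (!all(c("id", "equation") %in% names(rx)))
    stop("parse error: reaction sheet needs 'id' and 'equation' columns")
  stoich <- list()
  lb <- ub <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    pe <- tryCatch(parse_equation(rx$equation[i]), error = function(e)
      stop("parse error in reaction sheet row ", i, " (", rx$id[i], "): ",
           conditionMessage(e)))
    stoich[[rx$id[i]]] <- pe$stoichiometry
    lb[i] <- if (!is.null(rx$lower_bound) && !is.na(rx$lower_bound[i]))
      rx$lower_bound[i] else if (pe$reversible) -1000 else 0
    ub[i] <- if (!is.null(rx$upper_bound) && !is.na(rx$upper_bound[i]))
      rx$upper_bound[i] else 1000
  }
  reactions <- data.frame(
    id = rx$id,
    name = if (!is.null(rx$name)) rx$name else rx$id,
    lower_bound = lb, upper_bound = ub,
    gpr = if (!is.null(rx$gpr)) ifelse(is.na(rx$gpr), "", rx$gpr) else "",
    category = if (!is.null(rx$category)) rx$category else NA_character_,
    stringsAsFactors = FALSE)
  eq_mets <- unique(unlist(lapply(stoich, names)))
  if (!is.null(metabolites_path)) {
    mt <- utils::read.delim(metabolites_path, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (anyDuplicated(mt$id)) {
      dup <- unique(mt$id[duplicated(mt$id)])
      rows <- mt[mt$id %in% dup, ]
      if (nrow(unique(rows)) != length(dup))
        stop("integrity error: inconsistent duplicate metabolite rows: ",
             paste(dup, collapse = ", "))
      mt <- mt[!duplicated(mt$id), ]
    }
    extra <- setdiff(eq_mets, mt$id)
    if (length(extra))
      mt <- merge(mt, data.frame(id = extra, stringsAsFactors = FALSE),
                  all = TRUE)
    metabolites <- mt
  } else {
    metabolites <- data.frame(id = eq_mets, stringsAsFactors = FALSE)
  }
  obj <- NA_character_
  if (!is.null(rx$objective)) {
    hit <- which(rx$objective %in% c(TRUE, 1, "1", "TRUE", "true"))
    if (length(hit)) obj <- rx$id[hit[1]]
  } else {
    bm <- which(grepl("biomass", rx$id, ignore.case = TRUE))
    if (length(bm)) obj <- rx$id[bm[1]]
  }
  metabolic_model(metabolites, reactions, stoich, objective = obj, id = id)
}

#' Write a metabolic model to tabular sheets
#' @param model a \code{metabolic_model}.
#' @param reactions_path output TSV path for the reaction sheet.
#' @param metabolites_path optional output TSV path for the metabolite sheet.
#' @return \code{reactions_path}, invisibly.
#' @export
write_tabular_model <- function(model, reactions_path,
                                metabolites_path = NULL) {
  validate_model(model)
  fmt_side <- function(s) {
    term <- function(coef, id)
      if (coef == 1) id else paste(format(coef, trim = TRUE), id)
    paste(mapply(term, unname(s), names(s)), collapse = " + ")
  }
  eqs <- vapply(model$reactions$id, function(rid) {
    s <- model$stoichiometry[[rid]]
    rev <- model$reactions$lower_bound[model$reactions$id == rid] < 0
    paste(fmt_side(-s[s < 0]), if (rev) "<=>" else "->", fmt_side(s[s > 0]))
  }, character(1))
  df <- cbind(model$reactions[c("id", "name")], equation = unname(eqs),
              model$reactions[c("lower_bound", "upper_bound", "gpr")],
              objective = model$reactions$id %in% model$objective)
  utils::write.table(df, reactions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metabolites_path))
    utils::write.table(model$metabolites, metabolites_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(reactions_path)
}
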