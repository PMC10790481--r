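# Gene-protein-reaction (GPR) boolean rules.
#
# A rule is a boolean expression over gene ids with "and" (enzyme complex:
# all subunits required) and "or" (isozymes: any suffices), e.g.
# "(g1 and g2) or g3". The empty rule means "no gene association" and always
# evaluates TRUE. Parsed trees are nested lists: a leaf is a gene id string,
# an internal node is list(op = "and"|"or", args = list(...)).

.gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR rule string into an expression tree
#'
#' Grammar: \code{expr := term ("or" term)*}; \code{term := factor ("and"
#' factor)*}; \code{factor := gene-id | "(" expr ")"}. Keywords are
#' case-insensitive; \code{&&}/\code{&} and \code{||}/\code{|} are accepted
#' as synonyms. An empty or all-whitespace rule parses to \code{NULL}
#' (no gene association).
#'
#' @param rule GPR rule string.
#' @return parse tree (nested list) or \code{NULL} for the empty rule.
#' @export
gpr_parse <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- .gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) %in% kw
  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), c("or", "||", "|"))) {
      take()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), c("and", "&&", "&"))) {
      take()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("structural error: unexpected end of GPR rule '",
                       rule, "'")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")"))
        stop("structural error: unbalanced parentheses in GPR rule '",
             rule, "'")
      return(e)
    }
    if (t == ")" || is_kw(t, c("and", "or", "&", "|", "&&", "||")))
      stop("structural error: misplaced token '", t, "' in GPR rule '",
           rule, "'")
    t
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("structural error: trailing tokens in GPR rule '", rule, "'")
  out
}

#' Evaluate a GPR expression under a set of deleted genes
#'
#' AND nodes are true iff all children are true; OR nodes iff any child is;
#' a leaf is true iff its gene is not deleted; the empty expression
#' (\code{NULL} or empty string) is always true.
#'
#' @param expr a parse tree from \code{\link{gpr_parse}} or a rule string.
#' @param deleted character vector of deleted gene ids.
#' @return logical scalar: is the reaction still catalysable?
#' @export
evaluate_gpr <- function(expr, deleted = character()) {
  if (is.character(expr) && length(expr) == 1L &&
      (is.na(expr) || !nzchar(trimws(expr)) || grepl("[()]|\\s", expr)))
    expr <- gpr_parse(expr)
  rec <- function(e) {
    if (is.null(e)) return(TRUE)
    if (is.character(e)) return(!(e %in% deleted))
    if (!is.list(e) || is.null(e$op) || is.null(e$args))
      stop("structural error: malformed GPR tree")
    vals <- vapply(e$args, rec, logical(1))
    if (e$op == "and") all(vals) else if (e$op == "or") any(vals)
    else stop("structural error: unknown GPR operator '", e$op, "'")
  }
  rec(expr)
}

#' Gene ids referenced by a GPR rule
#' @param rule GPR rule string or parse tree.
#' @return character vector of distinct gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  tree <- if (is.character(rule)) gpr_parse(rule) else rule
  leaves <- function(e) {
    if (is.null(e)) character()
    else if (is.character(e)) e
    else unlist(lapply(e$args, leaves))
  }
  unique(leaves(tree))
}

#' Render a GPR tree back to a rule string
#' @param tree parse tree or \code{NULL}.
#' @return rule string ("" for \code{NULL}).
#' @export
gpr_deparse <- function(tree) {
  rec <- function(e, parent_op = NA) {
    if (is.null(e)) return("")
    if (is.character(e)) return(e)
    sep <- paste0(" ", e$op, " ")
    inner <- paste(vapply(e$args, rec, character(1), parent_op = e$op),
                   collapse = sep)
    if (!is.na(parent_op) && parent_op != e$op) paste0("(", inner, ")")
    else inner
  }
  rec(tree)
}

#' Rewrite gene ids inside a GPR rule
#'
#' Used when transplanting donor reactions into a draft model: every leaf
#' present in \code{map} is replaced by its target id; unmapped leaves are
#' kept unchanged.
#' @param rule GPR rule string.
#' @param map named character vector, donor gene id -> target gene id.
#' @return rewritten rule string.
#' @export
gpr_rewrite <- function(rule, map) {
  tree <- gpr_parse(rule)
  rec <- function(e) {
    if (is.null(e)) return(NULL)
    if (is.character(e))
      return(if (e %in% names(map)) unname(map[[e]]) else e)
    e$args <- lapply(e$args, rec)
    e
  }
  gpr_deparse(rec(tree))
}
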