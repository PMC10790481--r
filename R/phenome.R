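# Phenotype-microarray (PM) call tables, strain comparison, and
# model-vs-experiment concordance.

PM_CATEGORIES <- c("carbon", "nitrogen", "phosphorus", "sulfur",
                   "supplement", "stress", "inhibitor")

#' Construct/validate a growth-call table
#'
#' @param entries data.frame with columns \code{plate}, \code{well},
#'   \code{substrate}, \code{category} (one of carbon, nitrogen,
#'   phosphorus, sulfur, supplement, stress, inhibitor), \code{call}
#'   (logical). (plate, well) pairs must be unique; substrates non-empty.
#' @return the validated data.frame with class \code{growth_call_table}.
#' @export
growth_call_table <- function(entries) {
  need <- c("plate", "well", "substrate", "category", "call")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("validation error: growth-call table missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(entries[c("plate", "well")]))
    stop("validation error: duplicate (plate, well) entries")
  if (any(!nzchar(entries$substrate)))
    stop("validation error: empty substrate names")
  bad <- setdiff(unique(entries$category), PM_CATEGORIES)
  if (length(bad))
    stop("validation error: unknown PM categories: ",
         paste(bad, collapse = ", "))
  entries$call <- as.logical(entries$call)
  class(entries) <- c("growth_call_table", "data.frame")
  entries
}

#' Read a growth-call table from TSV
#' @param path TSV with columns plate, well, substrate, category, call.
#' @return a \code{growth_call_table}.
#' @export
read_growth_calls <- function(path) {
  growth_call_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Normalise substrate names
#'
#' Case-folds, strips punctuation and repeated whitespace, and resolves a
#' small built-in synonym table (e.g. "tricarballylate" ->
#' "tricarballylic acid"); used before joining tables from different
#' sources.
#' @param x character vector of substrate names.
#' @param synonyms optional named character vector (alias -> canonical)
#'   merged over the built-in table.
#' @return normalised character vector.
#' @export
normalize_substrate <- function(x, synonyms = NULL) {
  base <- c("tricarballylate" = "tricarballylic acid",
            "d serine" = "d-serine",
            "glucose" = "d-glucose",
            "2 3 butanediol" = "2,3-butanediol")
  if (!is.null(synonyms)) base[names(synonyms)] <- synonyms
  y <- tolower(trimws(x))
  y <- gsub("[[:space:]]+", " ", gsub("[_.]", " ", y))
  hit <- y %in% names(base)
  y[hit] <- unname(base[y[hit]])
  y
}

#' Compare growth calls between two strains
#'
#' Partitions the substrates shared by both tables (after optional category
#' filtering) by call pattern; substrates present in only one table land in
#' an \code{uncompared} bucket rather than erroring.
#'
#' @param a,b \code{growth_call_table}s (or plain data.frames with
#'   \code{substrate} and \code{call}).
#' @param category optional category filter (e.g. "carbon").
#' @return list with \code{both}, \code{only_a}, \code{only_b},
#'   \code{neither}, \code{uncompared} (sorted substrate vectors) and
#'   \code{counts}.
#' @export
compare_strain_calls <- function(a, b, category = NULL) {
  if (!is.null(category)) {
    a <- a[a$category %in% category, , drop = FALSE]
    b <- b[b$category %in% category, , drop = FALSE]
  }
  ca <- stats::setNames(a$call, a$substrate)
  cb <- stats::setNames(b$call, b$substrate)
  common <- intersect(names(ca), names(cb))
  out <- list(
    both = sort(common[ca[common] & cb[common]]),
    only_a = sort(common[ca[common] & !cb[common]]),
    only_b = sort(common[!ca[common] & cb[common]]),
    neither = sort(common[!ca[common] & !cb[common]]),
    uncompared = sort(c(setdiff(names(ca), common),
                        setdiff(names(cb), common))))
  out$counts <- vapply(out, length, integer(1))
  out
}

#' Score prediction-vs-experiment concordance
#'
#' Builds the confusion matrix over the shared substrate namespace:
#' predictions are rows of truth, experiments the reference. Mismatched
#' substrate sets are a validation error listing the differences.
#'
#' @param predictions,experiments tables with \code{substrate} and
#'   \code{call} columns covering the same substrates.
#' @return object of class \code{concordance_report}: counts \code{tp},
#'   \code{tn}, \code{fp}, \code{fn}, alphabetical substrate lists
#'   \code{fp_substrates}, \code{fn_substrates}, \code{n}, and
#'   \code{accuracy} = (TP+TN)/total.
#' @export
score_concordance <- function(predictions, experiments) {
  p <- stats::setNames(predictions$call, predictions$substrate)
  e <- stats::setNames(experiments$call, experiments$substrate)
  if (!setequal(names(p), names(e)))
    stop("validation error: substrate sets differ; only in predictions: ",
         paste(setdiff(names(p), names(e)), collapse = ", "),
         "; only in experiments: ",
         paste(setdiff(names(e), names(p)), collapse = ", "))
  e <- e[names(p)]
  tp <- sum(p & e); tn <- sum(!p & !e)
  fp <- sum(p & !e); fn <- sum(!p & e)
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn, n = length(p),
    fp_substrates = sort(names(p)[p & !e]),
    fn_substrates = sort(names(p)[!p & e]),
    accuracy = (tp + tn) / length(p)), class = "concordance_report")
}

#' @exportS3Method base::print
print.concordance_report <- function(x, ...) {
  cat("concordance_report: n =", x$n, "\n")
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d  accuracy %.4f\n",
              x$tp, x$tn, x$fp, x$fn, x$accuracy))
  invisible(x)
}

#' Write a concordance report as JSON
#' @param report a \code{concordance_report}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_concordance_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pearson correlation of normalised flux vectors
#'
#' Both vectors are divided by their own entry for the \code{normalizer}
#' reaction (the convention is normalising to the measured glucose uptake),
#' then Pearson's r is computed over the shared reaction ids.
#'
#' @param predicted,measured named numeric flux vectors (mmol/gDCW/h).
#' @param normalizer reaction id present in both with nonzero measured
#'   value.
#' @return Pearson correlation coefficient.
#' @export
correlate_fluxes <- function(predicted, measured, normalizer) {
  if (!(normalizer %in% names(predicted)) ||
      !(normalizer %in% names(measured)))
    stop("validation error: normalizer '", normalizer,
         "' missing from a flux vector")
  if (measured[[normalizer]] == 0 || predicted[[normalizer]] == 0)
    stop("validation error: zero normalizer flux")
  shared <- intersect(names(predicted), names(measured))
  if (length(shared) < 3)
    stop("insufficient-data error: fewer than 3 shared reactions")
  stats::cor(predicted[shared] / predicted[[normalizer]],
             measured[shared] / measured[[normalizer]])
}

#' Simple growth caller for kinetic curves
#'
#' Minimal respiration-curve caller for synthetic curves only: a well is
#' called growing when the maximum baseline-corrected signal reaches the
#' threshold. Real OmniLog kinetics deserve a dedicated curve package.
#'
#' @param signal numeric vector of a well's kinetic readings.
#' @param threshold call threshold on max(signal - signal[1]) (default 50).
#' @return logical call.
#' @export
call_from_curve <- function(signal, threshold = 50) {
  max(signal - signal[1]) >= threshold
}
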