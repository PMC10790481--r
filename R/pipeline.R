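# Single programmatic entry point wiring the stages together, plus medium
# file I/O. A thin command-line wrapper around these functions ships in
# inst/scripts/gemflux.R.

#' Read a medium definition
#'
#' JSON (an object \code{{"EX_glc__D_e": 10, ...}}) or TSV with columns
#' \code{exchange_id}, \code{uptake}.
#' @param path medium file.
#' @return named numeric vector of maximum uptake rates (mmol/gDCW/h).
#' @export
read_medium <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(unlist(x))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("exchange_id", "uptake") %in% names(df)))
    stop("parse error: medium TSV needs exchange_id and uptake columns")
  stats::setNames(df$uptake, df$exchange_id)
}

#' Write a medium definition as JSON
#' @param medium named numeric vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_medium <- function(medium, path) {
  jsonlite::write_json(as.list(medium), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All stage parameters default to the reference protocol: oxygen uptake
#' cap 18.5 mmol/gDCW/h, carbon-source screening uptake 10, essentiality
#' screening glucose 6, dFBA with 10 mM glucose / 0.01 g/L biomass / vmax
#' 6.5, and the 5\% growth-call threshold.
#'
#' @param model path to an SBML model, or a \code{metabolic_model}; when
#'   \code{NULL}, the default toy fixture is used.
#' @param medium path to a medium file, or a named numeric vector.
#' @param stages character vector out of \code{"counts"}, \code{"fba"},
#'   \code{"essentiality"}, \code{"dfba"}.
#' @param out_dir output directory for reports (default \code{tempdir()}).
#' @param seed integer seed recorded in the report and used by any
#'   stochastic stage.
#' @param ... overrides for the parameter list (\code{o2_uptake},
#'   \code{carbon_uptake}, \code{essentiality_glucose_uptake},
#'   \code{growth_threshold}, \code{dfba_glucose_mM},
#'   \code{dfba_biomass_gL}, \code{dfba_vmax}, \code{dfba_dt},
#'   \code{dfba_t_end}, \code{glucose_exchange}).
#' @return a \code{run_config} list.
#' @export
run_config <- function(model = NULL, medium = NULL,
                       stages = c("counts", "fba"),
                       out_dir = tempdir(), seed = 1L, ...) {
  params <- list(o2_uptake = 18.5, carbon_uptake = 10,
                 essentiality_glucose_uptake = 6, growth_threshold = 0.05,
                 dfba_glucose_mM = 10, dfba_biomass_gL = 0.01,
                 dfba_vmax = 6.5, dfba_dt = 0.1, dfba_t_end = 12,
                 glucose_exchange = "EX_glc__D_e")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown))
    stop("config error: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  params[names(dots)] <- dots
  dim_pos <- c("o2_uptake", "carbon_uptake", "essentiality_glucose_uptake",
               "dfba_glucose_mM", "dfba_vmax", "dfba_dt", "dfba_t_end")
  for (p in dim_pos) if (params[[p]] <= 0)
    stop("config error: parameter '", p, "' must be positive")
  structure(list(model = model, medium = medium, stages = stages,
                 out_dir = out_dir, seed = as.integer(seed),
                 params = params), class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order (model loading,
#' structural counts, FBA, single-gene essentiality, dynamic FBA), writes a
#' machine-readable JSON report plus per-stage TSV/CSV outputs under the
#' run directory, and returns the report. Inputs are never mutated;
#' identical config and inputs give identical numeric outputs.
#'
#' @param config a \code{run_config}.
#' @return the report (list), invisibly; side effect: files under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(config$model) && !file.exists(config$model))
    stop("config error: model file not found: ", config$model)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (is.null(config$model)) make_toy_model()$model
           else if (inherits(config$model, "metabolic_model")) config$model
           else read_sbml(config$model)
  medium <- if (is.null(config$medium)) NULL
            else if (is.character(config$medium)) read_medium(config$medium)
            else config$medium
  if (!is.null(medium)) model <- apply_medium(model, medium)
  report <- list(model_id = model$id, seed = config$seed,
                 parameters = config$params, stages = list())
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (check the stage inputs and parameter set)", call. = FALSE))
    report$stages[[name]] <<- res
  }
  for (stage in config$stages) {
    switch(stage,
      counts = run_stage("counts", function() classify_and_count(model)),
      fba = run_stage("fba", function() {
        sol <- solve_fba(model)
        utils::write.csv(
          data.frame(reaction = names(sol$fluxes), flux = sol$fluxes,
                     row.names = NULL),
          file.path(config$out_dir, "fba_fluxes.csv"), row.names = FALSE)
        list(status = sol$status, objective = sol$objective_value)
      }),
      essentiality = run_stage("essentiality", function() {
        res <- screen_essential_genes(
          model, threshold = config$params$growth_threshold)
        utils::write.table(res,
                           file.path(config$out_dir, "essentiality.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(n_genes = nrow(res), n_essential = sum(res$essential),
             wild_type_growth = attr(res, "wild_type"))
      }),
      dfba = run_stage("dfba", function() {
        glc <- config$params$glucose_exchange
        if (!(glc %in% model$reactions$id))
          glc <- exchange_reactions(model)[1]
        traj <- run_dfba(
          model, biomass0 = config$params$dfba_biomass_gL,
          substrates0 = stats::setNames(config$params$dfba_glucose_mM, glc),
          uptake_caps = stats::setNames(config$params$dfba_vmax, glc),
          dt = config$params$dfba_dt, t_end = config$params$dfba_t_end)
        utils::write.csv(traj, file.path(config$out_dir, "dfba.csv"),
                         row.names = FALSE)
        list(n_steps = nrow(traj), final_biomass = traj$biomass[nrow(traj)],
             final_substrate = traj[[4]][nrow(traj)])
      }),
      stop("config error: unknown stage '", stage, "'"))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
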