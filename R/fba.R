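# Flux balance analysis: maximise an objective flux subject to steady-state
# mass balance S v = 0 and flux bounds.

#' Build the stoichiometric matrix
#'
#' @param model a \code{metabolic_model}.
#' @return sparse \code{Matrix::dgCMatrix} (metabolites x reactions) with
#'   dimnames, entry (i, j) the coefficient of metabolite i in reaction j.
#' @export
build_stoichiometric_matrix <- function(model) {
  validate_model(model)
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxns)) {
    s <- model$stoichiometry[[rxns[j]]]
    ii <- c(ii, match(names(s), mets))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Solve a flux balance analysis problem
#'
#' Maximises the flux through \code{objective} subject to \code{S v = 0}
#' and the model's flux bounds (optionally overridden). Infeasibility and
#' unboundedness are reported in the \code{status} field, never as errors.
#' Only the objective value is guaranteed unique; individual fluxes of a
#' degenerate optimum are solver-dependent.
#'
#' @param model a \code{metabolic_model}.
#' @param objective reaction id to maximise (default: the model objective).
#' @param bound_overrides named list/vector of \code{c(lower, upper)} pairs
#'   (or single numbers interpreted as both bounds) keyed by reaction id.
#' @param minimize if \code{TRUE}, minimise the objective flux instead.
#' @return object of class \code{flux_solution}: list with \code{status}
#'   ("optimal"/"infeasible"/"unbounded"), \code{objective_value} (h^-1 for
#'   biomass objectives, mmol/gDCW/h otherwise; \code{NA} unless optimal)
#'   and \code{fluxes} (named vector, mmol/gDCW/h).
#' @export
solve_fba <- function(model, objective = model$objective,
                      bound_overrides = list(), minimize = FALSE) {
  if (is.na(objective) || !(objective %in% model$reactions$id))
    stop("key error: objective reaction '", objective, "' not in model")
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  names(lb) <- names(ub) <- model$reactions$id
  if (length(bound_overrides)) {
    unknown <- setdiff(names(bound_overrides), model$reactions$id)
    if (length(unknown))
      stop("key error: bound override for unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    for (id in names(bound_overrides)) {
      bo <- bound_overrides[[id]]
      if (length(bo) == 1L) bo <- c(bo, bo)
      lb[id] <- bo[1]; ub[id] <- bo[2]
    }
  }
  S <- build_stoichiometric_matrix(model)
  n <- ncol(S)
  c_obj <- numeric(n)
  c_obj[match(objective, colnames(S))] <- if (minimize) -1 else 1
  sol <- lp_solve(c_obj, as.matrix(S), rep(0, nrow(S)), lb, ub)
  fluxes <- sol$x
  names(fluxes) <- colnames(S)
  obj <- if (sol$status == "optimal") {
    if (minimize) -sol$objective else sol$objective
  } else NA_real_
  structure(list(status = sol$status, objective_value = obj,
                 objective_id = objective, fluxes = fluxes),
            class = "flux_solution")
}

#' @exportS3Method base::print
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status, "\n")
  cat("  objective", x$objective_id, "=",
      format(x$objective_value, digits = 6), "\n")
  invisible(x)
}

#' Exchange reaction ids of a model
#' @param model a \code{metabolic_model}.
#' @return character vector of reactions classified as exchanges.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[reaction_categories(model) == "exchange"]
}

#' Apply a growth medium to a model
#'
#' A medium maps exchange-reaction ids to maximum uptake rates (positive
#' numbers, mmol/gDCW/h); uptake being a negative exchange flux, the listed
#' exchanges get lower bound \code{-rate}. With \code{closed_by_default},
#' every other exchange's lower bound is set to 0 (secretion stays open:
#' upper bounds are never touched).
#'
#' @param model a \code{metabolic_model}.
#' @param medium named numeric vector (exchange id -> uptake rate >= 0).
#' @param closed_by_default close all unlisted exchanges? (default TRUE)
#' @return a modified copy of the model.
#' @export
apply_medium <- function(model, medium, closed_by_default = TRUE) {
  ex <- exchange_reactions(model)
  if (length(medium)) {
    if (is.null(names(medium)) || any(!nzchar(names(medium))))
      stop("validation error: medium must be a named vector")
    bad <- setdiff(names(medium), ex)
    if (length(bad))
      stop("validation error: medium entries are not exchange reactions: ",
           paste(bad, collapse = ", "))
    if (any(medium < 0))
      stop("validation error: medium uptake rates must be >= 0")
  }
  if (length(medium)) {
    idx <- match(model$reactions$id, names(medium))
    listed <- !is.na(idx)
    model$reactions$lower_bound[listed] <- -unname(medium[idx[listed]])
  }
  if (closed_by_default) {
    others <- model$reactions$id %in% setdiff(ex, names(medium))
    model$reactions$lower_bound[others] <-
      pmax(model$reactions$lower_bound[others], 0)
  }
  model
}

#' Simulate growth on a single carbon source
#'
#' Applies the carbon-free base medium (closing all unlisted exchanges),
#' opens one carbon exchange at \code{max_uptake}, and maximises the
#' objective. A carbon source with no exchange reaction in the model is the
#' model's prediction of non-growth, not an error: growth 0 is returned with
#' \code{no_exchange = TRUE}.
#'
#' @param model a \code{metabolic_model} with a biomass objective.
#' @param base_medium named numeric vector of carbon-free medium components.
#' @param carbon_exchange exchange reaction id of the carbon source.
#' @param max_uptake maximum uptake rate (default 10 mmol/gDCW/h).
#' @return list with \code{growth} (h^-1), \code{status}, and
#'   \code{no_exchange} flag.
#' @export
simulate_carbon_source <- function(model, base_medium, carbon_exchange,
                                   max_uptake = 10) {
  if (!(carbon_exchange %in% model$reactions$id))
    return(list(growth = 0, status = "no_exchange_reaction",
                no_exchange = TRUE))
  medium <- base_medium
  medium[carbon_exchange] <- max_uptake
  m <- apply_medium(model, medium, closed_by_default = TRUE)
  sol <- solve_fba(m)
  g <- if (sol$status == "optimal") max(sol$objective_value, 0) else 0
  list(growth = g, status = sol$status, no_exchange = FALSE)
}

#' Binary growth call from a simulated rate
#'
#' A substrate is called utilised when the simulated growth rate reaches at
#' least 5\% (by default) of the reference (glucose) growth rate; rates
#' strictly below the threshold are non-growth. Equality with the threshold
#' counts as growth.
#'
#' @param rate simulated growth rate (h^-1).
#' @param reference_rate reference growth rate, must be positive.
#' @param threshold fraction of the reference defining growth (default 0.05).
#' @return logical scalar.
#' @export
call_growth <- function(rate, reference_rate, threshold = 0.05) {
  if (!is.numeric(reference_rate) || reference_rate <= 0)
    stop("validation error: reference_rate must be > 0")
  rate >= threshold * reference_rate
}

#' Screen growth over a panel of carbon sources
#'
#' Runs \code{\link{simulate_carbon_source}} for each exchange id and applies
#' the growth-call rule against the reference substrate's rate.
#'
#' @param model a \code{metabolic_model}.
#' @param base_medium carbon-free medium (named numeric).
#' @param carbon_exchanges character vector of exchange ids to test.
#' @param reference_exchange exchange id of the reference substrate
#'   (simulated at the same uptake to get the reference rate).
#' @param max_uptake per-substrate maximum uptake (default 10 mmol/gDCW/h).
#' @param threshold growth-call fraction (default 0.05).
#' @return data.frame (substrate exchange id, growth rate, call).
#' @export
screen_carbon_sources <- function(model, base_medium, carbon_exchanges,
                                  reference_exchange, max_uptake = 10,
                                  threshold = 0.05) {
  ref <- simulate_carbon_source(model, base_medium, reference_exchange,
                                max_uptake)
  if (ref$growth <= 0)
    stop("configuration error: no growth on the reference substrate")
  rows <- lapply(carbon_exchanges, function(cx) {
    r <- simulate_carbon_source(model, base_medium, cx, max_uptake)
    data.frame(exchange = cx, growth = r$growth,
               call = call_growth(r$growth, ref$growth, threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mass-balance residual of a flux solution
#' @param model a \code{metabolic_model}.
#' @param solution a \code{flux_solution}.
#' @return max absolute entry of \code{S v}.
#' @export
mass_balance_residual <- function(model, solution) {
  S <- build_stoichiometric_matrix(model)
  max(abs(as.vector(S %*% solution$fluxes[colnames(S)])))
}
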