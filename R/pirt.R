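# Maintenance-energy calibration.
#
# Pirt's law links observed growth yield Y, specific growth rate mu,
# maintenance coefficient m and maximum yield Y_G:
#     1/Y = m/mu + 1/Y_G
# Chemostat literature often reports m and Y_G on a protein basis
# (g glucose/g protein/h, g protein/g glucose); FBA needs them per gram dry
# cell weight and per mmol glucose, giving the substrate-consumption line
#     q(mu) = inv_Yg_dcw * mu + m_dcw        [mmol glucose/gDCW/h].

#' Convert protein-based Pirt constants to DCW/molar units
#'
#' \code{m_dcw = m_protein * protein_fraction / glucose_molar_mass * 1000}
#' and \code{inv_Yg_dcw = (1/Yg_protein) * protein_fraction /
#' glucose_molar_mass * 1000}. With \code{m_protein = 0.023},
#' \code{Yg_protein = 1/3}, \code{protein_fraction = 0.60} this yields the
#' consumption line \code{q = 10 mu + 0.077} (after rounding).
#'
#' @param m_protein maintenance coefficient, g glucose/g protein/h.
#' @param Yg_protein maximum protein yield, g protein/g glucose.
#' @param protein_fraction protein mass fraction of dry cell weight.
#' @param glucose_molar_mass g/mol (default 180.16).
#' @return object of class \code{pirt_parameters}: the inputs plus
#'   \code{m_dcw} (mmol glucose/gDCW/h) and \code{inv_Yg_dcw}
#'   (mmol glucose/gDCW).
#' @export
convert_pirt_units <- function(m_protein, Yg_protein, protein_fraction,
                               glucose_molar_mass = 180.16) {
  vals <- c(m_protein, Yg_protein, protein_fraction, glucose_molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("validation error: all Pirt inputs must be positive")
  structure(list(
    m_protein = m_protein, Yg_protein = Yg_protein,
    protein_fraction = protein_fraction,
    glucose_molar_mass = glucose_molar_mass,
    m_dcw = m_protein * protein_fraction / glucose_molar_mass * 1000,
    inv_Yg_dcw = (1 / Yg_protein) * protein_fraction /
      glucose_molar_mass * 1000), class = "pirt_parameters")
}

#' @exportS3Method base::print
print.pirt_parameters <- function(x, ...) {
  cat("pirt_parameters: q(mu) =", format(x$inv_Yg_dcw, digits = 6),
      "* mu +", format(x$m_dcw, digits = 6), " [mmol glucose/gDCW/h]\n")
  invisible(x)
}

#' Predicted specific glucose consumption at a growth rate
#' @param params a \code{pirt_parameters}.
#' @param mu specific growth rate(s), h^-1.
#' @return q in mmol glucose/gDCW/h.
#' @export
pirt_q <- function(params, mu) params$inv_Yg_dcw * mu + params$m_dcw

#' Invert a DCW-based Pirt record back to protein units
#'
#' Algebraic inverse of \code{\link{convert_pirt_units}}; used for
#' consistency checks.
#' @param m_dcw,inv_Yg_dcw DCW/molar-based constants.
#' @param protein_fraction,glucose_molar_mass as in the forward conversion.
#' @return list with \code{m_protein} and \code{Yg_protein}.
#' @export
invert_pirt_units <- function(m_dcw, inv_Yg_dcw, protein_fraction,
                              glucose_molar_mass = 180.16) {
  list(m_protein = m_dcw * glucose_molar_mass / 1000 / protein_fraction,
       Yg_protein = protein_fraction /
         (inv_Yg_dcw * glucose_molar_mass / 1000))
}

#' Fit Pirt's law to chemostat data
#'
#' Ordinary least squares of \code{1/Y} on \code{1/mu}: the slope is the
#' maintenance coefficient m and the intercept is \code{1/Y_G}.
#'
#' @param chemostat data.frame with columns \code{dilution_rate} (h^-1,
#'   equals mu at steady state) and \code{yield} (same basis as m and Y_G,
#'   e.g. g protein/g glucose).
#' @return list with \code{m}, \code{Yg}, and \code{fit} (the underlying
#'   \code{lm} object with standard errors and residuals).
#' @export
fit_pirt <- function(chemostat) {
  stopifnot(is.data.frame(chemostat),
            all(c("dilution_rate", "yield") %in% names(chemostat)))
  mu <- chemostat$dilution_rate; Y <- chemostat$yield
  if (length(mu) < 2)
    stop("fit error: need at least 2 chemostat points")
  if (any(mu <= 0) || any(Y <= 0))
    stop("fit error: dilution rates and yields must be positive")
  x <- 1 / mu; y <- 1 / Y
  if (length(unique(signif(x, 12))) < 2)
    stop("fit error: zero variance in 1/mu")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(m = unname(cf["x"]), Yg = 1 / unname(cf["(Intercept)"]), fit = fit)
}

#' Locate the ATP-maintenance reaction
#'
#' Identified by id \code{"ATPM"} first, else by the stoichiometry pattern
#' ATP + H2O -> ADP + Pi (+ H) with no gene association.
#' @param model a \code{metabolic_model}.
#' @param atp,h2o,adp,pi ids of the cytoplasmic maintenance metabolites.
#' @return reaction id.
#' @export
find_atpm <- function(model, atp = "atp_c", h2o = "h2o_c", adp = "adp_c",
                      pi = "pi_c") {
  if ("ATPM" %in% model$reactions$id) return("ATPM")
  for (i in seq_len(nrow(model$reactions))) {
    s <- model$stoichiometry[[model$reactions$id[i]]]
    if (all(c(atp, adp) %in% names(s)) &&
        isTRUE(s[[atp]] < 0) && isTRUE(s[[adp]] > 0) &&
        (!(h2o %in% names(s)) || s[[h2o]] < 0) &&
        (!(pi %in% names(s)) || s[[pi]] > 0) &&
        !nzchar(trimws(model$reactions$gpr[i])) &&
        length(s) <= 5)
      return(model$reactions$id[i])
  }
  stop("configuration error: no ATP-maintenance (ATPM) reaction found")
}

#' Compute non-growth-associated maintenance (NGAM)
#'
#' Fixes the glucose uptake at the Pirt maintenance rate \code{m_dcw},
#' relaxes the ATPM lower bound to 0, does not require biomass production,
#' and maximises the ATPM flux: the optimum is the ATP the cell can spend on
#' maintenance while not growing.
#'
#' @param model a \code{metabolic_model}.
#' @param m_dcw maintenance glucose consumption, mmol glucose/gDCW/h.
#' @param glucose_exchange id of the glucose exchange reaction.
#' @param atpm id of the maintenance reaction; located automatically when
#'   \code{NULL}.
#' @return NGAM in mmol ATP/gDCW/h.
#' @export
compute_ngam <- function(model, m_dcw, glucose_exchange = "EX_glc__D_e",
                         atpm = NULL) {
  if (is.null(atpm)) atpm <- find_atpm(model)
  if (!(glucose_exchange %in% model$reactions$id))
    stop("key error: unknown glucose exchange '", glucose_exchange, "'")
  overrides <- list()
  overrides[[glucose_exchange]] <- c(-m_dcw, -m_dcw)
  overrides[[atpm]] <- c(0, model$reactions$upper_bound[
    model$reactions$id == atpm])
  sol <- solve_fba(model, objective = atpm, bound_overrides = overrides)
  if (sol$status != "optimal")
    stop("calibration error: NGAM FBA was ", sol$status)
  sol$objective_value
}

#' Set the growth-associated maintenance (GAM) of a biomass equation
#'
#' Overwrites the ATP-hydrolysis coefficients of the biomass reaction:
#' ATP and H2O get \code{-(gam + extra)}, ADP/Pi/H get \code{+(gam +
#' extra)}, where \code{extra} is any pre-existing non-GAM ATP demand kept
#' by the caller (default 0, i.e. the biomass ATP coefficient is the GAM).
#'
#' @param model a \code{metabolic_model}.
#' @param gam mmol ATP/gDCW, must be >= 0.
#' @param biomass id of the biomass reaction (default: model objective).
#' @param atp,h2o,adp,pi,h metabolite ids of the hydrolysis couple; ids not
#'   present in the model are skipped (toy models may omit H or H2O).
#' @param extra additional ATP demand added on top of \code{gam}.
#' @return the modified model.
#' @export
set_gam <- function(model, gam, biomass = model$objective, atp = "atp_c",
                    h2o = "h2o_c", adp = "adp_c", pi = "pi_c", h = "h_c",
                    extra = 0) {
  if (gam < 0) stop("validation error: GAM must be >= 0")
  if (!(biomass %in% model$reactions$id))
    stop("key error: unknown biomass reaction '", biomass, "'")
  s <- model$stoichiometry[[biomass]]
  tot <- gam + extra
  present <- function(id) id %in% model$metabolites$id
  for (id in c(atp, h2o)) if (present(id)) s[id] <- -tot
  for (id in c(adp, pi, h)) if (present(id)) s[id] <- tot
  model$stoichiometry[[biomass]] <- s[s != 0]
  model
}

#' Fit GAM against the Pirt consumption line
#'
#' For each candidate GAM the biomass ATP-hydrolysis coefficients are
#' rewritten, the NGAM is installed as the ATPM lower bound, and the
#' predicted specific glucose consumption q is computed at each evaluation
#' growth rate by fixing growth and minimising glucose uptake (LP with the
#' swapped objective — mirroring what a chemostat observes). The returned
#' GAM minimises the sum of squared deviations from the target line
#' \code{q(mu) = inv_Yg_dcw * mu + m_dcw}.
#'
#' @param model a \code{metabolic_model} with a biomass objective.
#' @param pirt a \code{pirt_parameters} record.
#' @param ngam NGAM (mmol ATP/gDCW/h), installed as the ATPM lower bound.
#' @param gam_grid numeric vector of candidate GAM values (mmol ATP/gDCW).
#' @param mu_values growth rates at which q is evaluated (default
#'   \code{seq(0.1, 0.7, by = 0.1)} h^-1).
#' @param glucose_exchange id of the glucose exchange reaction.
#' @param atpm maintenance reaction id (auto-located when \code{NULL}).
#' @param ... metabolite-id arguments passed to \code{\link{set_gam}}.
#' @return list with \code{gam} (best grid point), \code{sse}, and
#'   \code{profile} (data.frame gam x sse).
#' @export
fit_gam <- function(model, pirt, ngam, gam_grid,
                    mu_values = seq(0.1, 0.7, by = 0.1),
                    glucose_exchange = "EX_glc__D_e", atpm = NULL, ...) {
  stopifnot(length(gam_grid) >= 1)
  if (is.null(atpm)) atpm <- find_atpm(model)
  q_target <- pirt_q(pirt, mu_values)
  biomass <- model$objective
  sse <- rep(NA_real_, length(gam_grid))
  for (gi in seq_along(gam_grid)) {
    m_g <- set_gam(model, gam_grid[gi], ...)
    m_g <- set_bounds(m_g, atpm, lower = ngam)
    qs <- rep(NA_real_, length(mu_values))
    ok <- TRUE
    for (mi in seq_along(mu_values)) {
      ov <- list(); ov[[biomass]] <- c(mu_values[mi], mu_values[mi])
      sol <- solve_fba(m_g, objective = glucose_exchange,
                       bound_overrides = ov)
      if (sol$status != "optimal") { ok <- FALSE; break }
      # maximising the exchange flux minimises uptake; q = -flux
      qs[mi] <- -sol$objective_value
    }
    if (ok) sse[gi] <- sum((qs - q_target)^2)
  }
  if (all(is.na(sse)))
    stop("calibration error: FBA infeasible at every GAM grid point")
  best <- which.min(sse)
  list(gam = gam_grid[best], sse = sse[best],
       profile = data.frame(gam = gam_grid, sse = sse))
}
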