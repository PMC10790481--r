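# Dynamic FBA for batch culture: static optimisation with explicit Euler
# stepping (solve the FBA at the current state, advance biomass and
# extracellular pools, repeat). Concentrations are mM with the culture
# volume normalised to 1 L, so mmol pools equal mM values and specific
# rates (mmol/gDCW/h) times biomass (g/L) times dt (h) give concentration
# changes directly.

#' Run a dynamic FBA batch simulation
#'
#' At each step the effective uptake bound of every capped substrate is
#' \code{min(vmax, S / (X * dt))}, so pools can never go negative; the FBA
#' is solved, then biomass and substrates are advanced with first-order
#' Euler updates \code{X <- X * (1 + mu * dt)},
#' \code{S <- S + v_exchange * X * dt} (uptake fluxes are negative).
#' Simulation stops at \code{t_end}, when the FBA turns infeasible, or when
#' all capped substrates are exhausted (< 1e-9 mM) and growth has ceased
#' (< 1e-9 h^-1).
#'
#' @param model a \code{metabolic_model} with a biomass objective.
#' @param biomass0 initial biomass, g/L (default 0.01).
#' @param substrates0 named numeric of initial extracellular concentrations,
#'   mM, keyed by exchange reaction id (default \code{c(EX_glc__D_e = 10)}).
#' @param uptake_caps named numeric of maximum specific uptake rates vmax,
#'   mmol/gDCW/h, keyed by exchange id (default glucose 6.5).
#' @param dt Euler step, h (default 0.1).
#' @param t_end simulation horizon, h.
#' @param base_medium optional medium applied first (uncapped components,
#'   e.g. oxygen and minerals).
#' @return data.frame trajectory: \code{time}, \code{biomass}, \code{growth},
#'   and one column per tracked substrate; attribute \code{consumed} holds
#'   the flux-integrated total consumption of each substrate (for mass
#'   bookkeeping checks).
#' @export
run_dfba <- function(model, biomass0 = 0.01,
                     substrates0 = c(EX_glc__D_e = 10),
                     uptake_caps = c(EX_glc__D_e = 6.5),
                     dt = 0.1, t_end = 12, base_medium = NULL) {
  if (!is.numeric(dt) || dt <= 0)
    stop("validation error: dt must be positive")
  if (t_end < dt) stop("validation error: t_end must be >= dt")
  if (biomass0 < 0 || any(substrates0 < 0))
    stop("validation error: initial state must be non-negative")
  unknown <- setdiff(union(names(substrates0), names(uptake_caps)),
                     model$reactions$id)
  if (length(unknown))
    stop("key error: unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  if (!is.null(base_medium)) model <- apply_medium(model, base_medium)

  subs <- names(substrates0)
  X <- biomass0; S <- substrates0; t <- 0
  consumed <- stats::setNames(numeric(length(subs)), subs)
  steps <- list(c(time = 0, biomass = X, growth = NA_real_, S))
  first <- TRUE
  while (t < t_end - 1e-12) {
    ov <- list()
    for (id in subs) {
      cap <- if (id %in% names(uptake_caps)) uptake_caps[[id]] else Inf
      avail <- if (X > 0) S[[id]] / (X * dt) else cap
      # substrates present in the batch are available regardless of the
      # model's static medium bounds
      ov[[id]] <- c(min(-min(cap, avail), 0),
                    model$reactions$upper_bound[model$reactions$id == id])
    }
    sol <- solve_fba(model, bound_overrides = ov)
    if (sol$status != "optimal") {
      if (first)
        stop("configuration error: FBA infeasible at t = 0")
      break
    }
    mu <- max(sol$objective_value, 0)
    v <- sol$fluxes[subs]
    dS <- v * X * dt
    consumed <- consumed - pmin(dS, 0)
    X_new <- X * (1 + mu * dt)
    S <- pmax(S + dS, 0)
    t <- t + dt
    X <- X_new
    steps[[length(steps) + 1L]] <- c(time = t, biomass = X, growth = mu, S)
    first <- FALSE
    if (all(S < 1e-9) && mu < 1e-9) break
  }
  out <- as.data.frame(do.call(rbind, steps))
  names(out) <- c("time", "biomass", "growth", subs)
  attr(out, "consumed") <- consumed
  out
}
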