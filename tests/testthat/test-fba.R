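test_that("linear chain fixture: optimum is the minimum of the bounds", {
  # uptake <= 10, A -> B, B -> biomass 1:1
  chain <- metabolic_model(
    data.frame(id = c("a_e", "a_c", "b_c")),
    data.frame(id = c("EX_a_e", "T", "CONV", "BIO"),
               lower_bound = c(-10, 0, 0, 0),
               upper_bound = c(1000, 1000, 1000, 1000)),
    list(EX_a_e = c(a_e = -1), T = c(a_e = -1, a_c = 1),
         CONV = c(a_c = -1, b_c = 1), BIO = c(b_c = -1)),
    objective = "BIO")
  sol <- solve_fba(chain)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  # tightening any interior bound moves the optimum to the new minimum
  sol2 <- solve_fba(chain, bound_overrides = list(CONV = c(0, 3)))
  expect_equal(sol2$objective_value, 3, tolerance = 1e-9)
})

test_that("no uptake means no growth; infeasibility is a status, not an error", {
  toy <- make_toy_model()$model
  closed <- apply_medium(toy, c(), closed_by_default = TRUE)
  expect_equal(solve_fba(closed)$objective_value, 0, tolerance = 1e-9)
  # forcing flux through a blocked reaction is reported as infeasible
  ngam_toy <- make_toy_model(list(ngam = 1))$model
  sol <- solve_fba(apply_medium(ngam_toy, c()),
                   bound_overrides = list(BIOMASS_toy = c(1, 1)))
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("LP optimum equals the vertex-enumeration oracle on toy networks (<= 8 reactions)", {
  specs <- list(
    list(), list(gam = 5), list(ngam = 3), list(atp_per_carbon = 20),
    list(uptake_max = 2.5, gam = 1), list(biomass_scale = 2),
    list(atp_per_precursor = 4, gam = 0.5), list(ngam = 19, gam = 8))
  for (sp in specs) {
    toy <- make_toy_model(sp)
    sol <- solve_fba(toy$model)
    oracle <- oracle_fba_max(toy$model)
    expect_equal(sol$objective_value, oracle, tolerance = 1e-7,
                 info = paste("spec:", paste(names(sp), sp, collapse = " ")))
    expect_equal(sol$objective_value, toy$optimum, tolerance = 1e-7)
    expect_lt(mass_balance_residual(toy$model, sol), 1e-6)
  }
})

test_that("objective value is invariant to reaction order and to rescaling a non-objective reaction", {
  toy <- make_toy_model(list(gam = 3, ngam = 0.4))
  m <- toy$model
  base <- solve_fba(m)$objective_value
  # shuffle reaction order
  set.seed(11)
  perm <- sample(nrow(m$reactions))
  ms <- m
  ms$reactions <- ms$reactions[perm, ]
  rownames(ms$reactions) <- NULL
  ms$stoichiometry <- ms$stoichiometry[ms$reactions$id]
  expect_equal(solve_fba(ms)$objective_value, base, tolerance = 1e-8)
  # scale a non-objective reaction's stoichiometry and bounds together
  mr <- m
  mr$stoichiometry[["ENERGY1"]] <- 2 * mr$stoichiometry[["ENERGY1"]]
  i <- match("ENERGY1", mr$reactions$id)
  mr$reactions$lower_bound[i] <- mr$reactions$lower_bound[i] / 2
  mr$reactions$upper_bound[i] <- mr$reactions$upper_bound[i] / 2
  expect_equal(solve_fba(mr)$objective_value, base, tolerance = 1e-8)
})

test_that("LP value is concave in the uptake bound: doubling uptake at most doubles growth", {
  for (gam in c(1, 4, 9)) {
    m1 <- make_toy_model(list(uptake_max = 5, gam = gam))$model
    m2 <- make_toy_model(list(uptake_max = 10, gam = gam))$model
    g1 <- solve_fba(m1)$objective_value
    g2 <- solve_fba(m2)$objective_value
    expect_gte(g2, g1 - 1e-9)
    expect_lte(g2, 2 * g1 + 1e-9)
  }
})

test_that("apply_medium sets exactly the requested uptake bounds", {
  toy <- make_toy_model(list(n_carbons = 2))$model
  m <- apply_medium(toy, c(EX_carb1_e = 18.5, EX_carb2_e = 10))
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_carb1_e"],
               -18.5)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_carb2_e"],
               -10)
  # secretion stays open
  expect_equal(m$reactions$upper_bound[m$reactions$id == "EX_carb1_e"],
               1000)
  # closed_by_default zeroes unlisted exchanges only
  m2 <- apply_medium(toy, c(EX_carb1_e = 5))
  expect_equal(m2$reactions$lower_bound[m2$reactions$id == "EX_carb2_e"], 0)
  expect_error(apply_medium(toy, c(ATPM = 1)), "not exchange")
  expect_error(apply_medium(toy, c(EX_carb1_e = -2)), ">= 0")
})

test_that("single-carbon screening scales linearly and flags missing exchanges", {
  # planted yield: 0.1 biomass per mmol carbon -> rate 1.0 at uptake 10
  toy <- make_toy_model(list(gam = 18, atp_per_precursor = 0,
                             precursor_per_biomass = 1))
  # v* = (E*U)/(G + P*E) = 2U/20 = U/10
  r <- simulate_carbon_source(toy$model, c(), "EX_carb1_e", max_uptake = 10)
  expect_equal(r$growth, 1.0, tolerance = 1e-8)
  r5 <- simulate_carbon_source(toy$model, c(), "EX_carb1_e", max_uptake = 5)
  expect_equal(r5$growth, 0.5, tolerance = 1e-8)
  miss <- simulate_carbon_source(toy$model, c(), "EX_nothere_e")
  expect_equal(miss$growth, 0)
  expect_true(miss$no_exchange)
})

test_that("growth-call rule: strict 5% threshold with equality counting as growth", {
  expect_false(call_growth(0.049 * 0.99, 0.99))
  expect_true(call_growth(0.99, 0.99))
  expect_true(call_growth(0.05 * 0.99, 0.99))
  expect_error(call_growth(0.1, 0), "reference_rate")
})

test_that("FBA optimum matches cobrapy/GLPK on the written SBML", {
  toy <- make_toy_model(list(gam = 3, ngam = 0.25))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy$model, path)
  out <- tryCatch(
    system2("python",
            c("-c", shQuote(paste0(
              "import cobra;",
              "m = cobra.io.read_sbml_model('", path, "');",
              "print('%.10f' % m.slim_optimize())"))),
            stdout = TRUE, stderr = FALSE),
    error = function(e) NULL)
  expect_false(is.null(out))
  expect_equal(as.numeric(out[length(out)]),
               solve_fba(toy$model)$objective_value, tolerance = 1e-6)
})
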