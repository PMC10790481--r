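test_that("protein-to-DCW unit conversion reproduces the glucose consumption line", {
  pp <- convert_pirt_units(m_protein = 0.023, Yg_protein = 1 / 3,
                           protein_fraction = 0.60,
                           glucose_molar_mass = 180.16)
  # q = 10 mu + 0.077 at the printed precision
  expect_equal(round(pp$m_dcw, 3), 0.077)
  expect_equal(round(pp$inv_Yg_dcw, 0), 10)
  # identity case: everything unit
  expect_equal(convert_pirt_units(1, 1, 1, 1000)$m_dcw, 1)
  expect_error(convert_pirt_units(-1, 1, 1), "positive")
})

test_that("unit conversion round-trips algebraically over random inputs", {
  set.seed(3)
  for (i in 1:25) {
    m <- stats::runif(1, 1e-3, 1); yg <- stats::runif(1, 0.1, 2)
    pf <- stats::runif(1, 0.2, 0.9); mm <- stats::runif(1, 50, 400)
    pp <- convert_pirt_units(m, yg, pf, mm)
    inv <- invert_pirt_units(pp$m_dcw, pp$inv_Yg_dcw, pf, mm)
    expect_equal(inv$m_protein, m, tolerance = 1e-12)
    expect_equal(inv$Yg_protein, yg, tolerance = 1e-12)
    # q(mu) evaluation is exactly the slope/intercept form
    mu <- stats::runif(5, 0.05, 1)
    expect_equal(pirt_q(pp, mu), pp$inv_Yg_dcw * mu + pp$m_dcw)
  }
})

test_that("Pirt regression recovers parameters from chemostat data", {
  # noiseless forward simulation -> exact recovery
  ch <- make_chemostat_data(m = 0.023, Yg = 1 / 3, noise_sd = 0, n = 20)
  f <- fit_pirt(ch)
  expect_equal(f$m, 0.023, tolerance = 1e-10)
  expect_equal(f$Yg, 1 / 3, tolerance = 1e-10)
  # two points interpolate exactly
  ch2 <- make_chemostat_data(m = 0.05, Yg = 0.5, noise_sd = 0, n = 2)
  f2 <- fit_pirt(ch2)
  expect_equal(f2$m, 0.05, tolerance = 1e-10)
  expect_equal(max(abs(stats::residuals(f2$fit))), 0, tolerance = 1e-12)
  # noisy recovery within 3 standard errors (fixed seed, n = 50)
  chn <- make_chemostat_data(m = 0.023, Yg = 1 / 3, noise_sd = 0.1,
                             n = 50, seed = 42)
  fn <- fit_pirt(chn)
  se <- summary(fn$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(fn$m - 0.023), 3 * se[["x"]])
  expect_lt(abs(1 / fn$Yg - 3), 3 * se[["(Intercept)"]])
  # degenerate inputs
  expect_error(fit_pirt(data.frame(dilution_rate = 0.2, yield = 0.3)),
               "at least 2")
  expect_error(fit_pirt(data.frame(dilution_rate = c(0.2, 0.2),
                                   yield = c(0.3, 0.31))), "zero variance")
})

test_that("NGAM is the maximal maintenance ATP flux and is linear in m_dcw", {
  # planted stoichiometry: 1 glucose -> exactly 20 ATP
  toy <- make_toy_model(list(atp_per_carbon = 20))$model
  expect_equal(compute_ngam(toy, 0.077, glucose_exchange = "EX_carb1_e"),
               20 * 0.077, tolerance = 1e-8)
  expect_equal(compute_ngam(toy, 0, glucose_exchange = "EX_carb1_e"), 0,
               tolerance = 1e-10)
  # LP value homogeneity along the single bound ray
  n1 <- compute_ngam(toy, 0.05, glucose_exchange = "EX_carb1_e")
  n2 <- compute_ngam(toy, 0.10, glucose_exchange = "EX_carb1_e")
  expect_equal(n2, 2 * n1, tolerance = 1e-8)
  # the ATPM lower bound is relaxed inside compute_ngam even when active
  toyn <- make_toy_model(list(atp_per_carbon = 20, ngam = 5))$model
  expect_equal(compute_ngam(toyn, 0.077, glucose_exchange = "EX_carb1_e"),
               1.54, tolerance = 1e-8)
  expect_error(compute_ngam(toy, 0.1, glucose_exchange = "EX_none_e"),
               "key error")
})

test_that("ATPM is located by id or by stoichiometry pattern", {
  toy <- make_toy_model()$model
  expect_equal(find_atpm(toy), "ATPM")
  # rename it: the hydrolysis pattern with no GPR must still be found
  i <- match("ATPM", toy$reactions$id)
  toy$reactions$id[i] <- "MAINT"
  names(toy$stoichiometry)[names(toy$stoichiometry) == "ATPM"] <- "MAINT"
  expect_equal(find_atpm(toy), "MAINT")
})

test_that("GAM fitting recovers a planted value and respects the grid", {
  g0 <- 7
  toy <- make_toy_model(list(gam = g0))$model
  E <- 2; A <- 1; P <- 1
  # target line implied by the toy's stoichiometry at GAM = g0
  line <- list(inv_Yg_dcw = (g0 + P * (A + E)) / E, m_dcw = 0)
  fit <- fit_gam(toy, line, ngam = 0, gam_grid = seq(5, 9, by = 0.5),
                 glucose_exchange = "EX_carb1_e")
  expect_equal(fit$gam, g0)
  expect_lt(fit$sse, 1e-12)
  # grid of one value returns that value
  fit1 <- fit_gam(toy, line, ngam = 0, gam_grid = 3,
                  glucose_exchange = "EX_carb1_e")
  expect_equal(fit1$gam, 3)
  # off-grid planted value lands within one grid spacing
  line2 <- list(inv_Yg_dcw = (7.3 + P * (A + E)) / E, m_dcw = 0)
  fit2 <- fit_gam(toy, line2, ngam = 0, gam_grid = seq(5, 9, by = 0.5),
                  glucose_exchange = "EX_carb1_e")
  expect_lte(abs(fit2$gam - 7.3), 0.5)
})

test_that("set_gam rewrites the ATP-hydrolysis coefficients of the biomass", {
  toy <- make_toy_model(list(gam = 2))$model
  m2 <- set_gam(toy, 11)
  s <- m2$stoichiometry[["BIOMASS_toy"]]
  expect_equal(unname(s["atp_c"]), -11)
  expect_equal(unname(s["adp_c"]), 11)
  expect_error(set_gam(toy, -1), "GAM")
})

test_that("biomass coefficients match the hand-computed composition oracle", {
  fx <- make_reconstruction_fixture()
  mf <- c(protein = 0.55, dna = 0.031, rna = 0.205)
  bio <- biomass_from_genome(fx$cds, fx$genome, mf)
  # amino-acid fractions from planted codon counts (M2 G10 A5 of 17)
  expect_equal(unname(bio$amino_acids[c("M", "G", "A")]),
               c(2, 10, 5) / 17, tolerance = 1e-12)
  expect_equal(sum(bio$amino_acids), 1, tolerance = 1e-12)
  # protein coefficients via the stated formula, computed independently
  masses <- c(M = 131.1926, G = 57.0519, A = 71.0788)
  f <- c(M = 2, G = 10, A = 5) / 17
  denom <- sum(f * masses)
  expect_equal(unname(-bio$coefficients[c("aa_M", "aa_G", "aa_A")]),
               unname(0.55 * f / denom * 1000), tolerance = 1e-9)
  # multiplying back recovers the protein mass fraction
  aa <- bio$coefficients[grep("^aa_", names(bio$coefficients))]
  aam <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
           C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
           H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
           M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
           T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  expect_equal(sum(-aa * aam[sub("aa_", "", names(aa))]) / 1000, 0.55,
               tolerance = 1e-9)
})

test_that("dNTP fractions obey double-strand symmetry; single-strand A-run splits A/T", {
  fx <- make_reconstruction_fixture()
  bio <- biomass_from_genome(fx$cds, fx$genome,
                             c(protein = 0.5, dna = 0.03, rna = 0.2))
  expect_equal(unname(bio$dntp["dA"]), unname(bio$dntp["dT"]),
               tolerance = 1e-12)
  expect_equal(unname(bio$dntp["dC"]), unname(bio$dntp["dG"]),
               tolerance = 1e-12)
  # genome "AAAA": complementarity forces A:0.5, T:0.5
  onlyA <- Biostrings::DNAStringSet(c(chr = "AAAA"))
  cds <- Biostrings::DNAStringSet(c(g = "ATGGGTTAA"))
  b2 <- biomass_from_genome(cds, onlyA, c(protein = 0.5, dna = 0.3,
                                          rna = 0.2))
  expect_equal(unname(b2$dntp), c(0.5, 0, 0, 0.5), tolerance = 1e-12)
})

test_that("biomass coefficients are invariant to CDS order and concatenation", {
  fx <- make_reconstruction_fixture()
  mf <- c(protein = 0.6, dna = 0.03, rna = 0.1)
  a <- biomass_from_genome(fx$cds, fx$genome, mf)
  b <- biomass_from_genome(rev(fx$cds), fx$genome, mf)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-12)
  concat <- Biostrings::DNAStringSet(c(all = paste(
    as.character(fx$cds), collapse = "")))
  d <- biomass_from_genome(concat, fx$genome, mf)
  expect_equal(a$coefficients, d$coefficients, tolerance = 1e-12)
})
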