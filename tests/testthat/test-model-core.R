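test_that("model construction, compartments and validation invariants", {
  m <- fixture_mini_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(m$metabolites$compartment,
               c("extracellular", "cytoplasm", "cytoplasm"))
  expect_equal(base_metabolite_id(c("glc__D_e", "glc__D_c")),
               c("glc__D", "glc__D"))
  expect_equal(compartment_of("x_p"), "periplasm")
  expect_equal(compartment_of("x_mito"), "mito")  # extra compartment kept

  # violations are refused with integrity errors
  expect_error(metabolic_model(
    data.frame(id = "a_c"),
    data.frame(id = "R1", lower_bound = 1, upper_bound = 0),
    list(R1 = c(a_c = 1))), "lower_bound > upper_bound")
  expect_error(metabolic_model(
    data.frame(id = "a_c"), data.frame(id = "R1"),
    list(R1 = c(missing_c = 1))), "unresolved metabolite")
  expect_error(metabolic_model(
    data.frame(id = "a_c"),
    data.frame(id = "EX_a_c", gpr = ""),
    list(EX_a_c = c(a_c = -1, a_c2 = 1))), "unresolved|exactly one")
})

test_that("stoichiometric matrix equals a hand-written oracle", {
  toy <- make_toy_model()$model
  S <- build_stoichiometric_matrix(toy)
  # single-metabolite boundary columns
  expect_equal(sum(S[, "EX_carb1_e"] != 0), 1)
  expect_equal(S["carb1_e", "EX_carb1_e"], -1)
  # transport column (-1, +1)
  expect_equal(as.numeric(S[c("carb1_e", "carb1_p"), "CARB1tex"]), c(-1, 1))
  # nonzero count equals the summed stoichiometry lengths
  expect_equal(Matrix::nnzero(S),
               sum(vapply(toy$stoichiometry, length, 1L)))
  # 5-reaction hand fixture
  m5 <- metabolic_model(
    data.frame(id = c("a_c", "b_c", "c_c")),
    data.frame(id = paste0("R", 1:5)),
    list(R1 = c(a_c = -1, b_c = 1), R2 = c(b_c = -2, c_c = 1),
         R3 = c(a_c = -1, c_c = 3), R4 = c(c_c = -1), R5 = c(a_c = 1)))
  hand <- rbind(c(-1, 0, -1, 0, 1), c(1, -2, 0, 0, 0), c(0, 1, 3, -1, 0))
  dimnames(hand) <- list(c("a_c", "b_c", "c_c"), paste0("R", 1:5))
  expect_equal(as.matrix(build_stoichiometric_matrix(m5)), hand)
})

test_that("SBML round-trip preserves ids, bounds, stoichiometry, GPR trees", {
  fixtures <- list(
    fixture_mini_model(),
    make_toy_model()$model,
    make_toy_model(list(n_carbons = 2, gam = 5, ngam = 0.5))$model)
  for (m in fixtures) {
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, path)
    m2 <- read_sbml(path)
    expect_identical(m2$reactions$id, m$reactions$id)
    expect_identical(m2$metabolites$id, m$metabolites$id)
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_identical(m2$objective, m$objective)
    for (rid in m$reactions$id) {
      expect_equal(sort(m2$stoichiometry[[rid]]),
                   sort(m$stoichiometry[[rid]]))
      expect_identical(gpr_parse(m2$reactions$gpr[m2$reactions$id == rid]),
                       gpr_parse(m$reactions$gpr[m$reactions$id == rid]))
    }
    # round-trip once more: byte-identical after the first normalisation
    path2 <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m2, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("SBML reader reports malformed and unresolved input", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", bad)
  expect_error(read_sbml(bad))
  m <- fixture_mini_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  txt <- gsub('species="M_a_e"', 'species="M_ghost_e"', readLines(path))
  writeLines(txt, path)
  expect_error(read_sbml(path), "unresolved")
  # invariant-violating model refused by the writer
  broken <- unclass(m)
  broken$reactions$lower_bound[1] <- 99
  broken$reactions$upper_bound[1] <- -99
  class(broken) <- "metabolic_model"
  expect_error(write_sbml(broken, withr::local_tempfile()), "integrity")
})

test_that("tabular model sheets parse equations and match the SBML form", {
  # hand-checked equation parse
  pe <- parse_equation("a_c + b_c -> c_c")
  expect_equal(sort(pe$stoichiometry),
               sort(c(a_c = -1, b_c = -1, c_c = 1)))
  expect_false(pe$reversible)
  pe2 <- parse_equation("2 a_c <=> 3 b_c")
  expect_equal(sort(pe2$stoichiometry), sort(c(a_c = -2, b_c = 3)))
  expect_true(pe2$reversible)
  pe3 <- parse_equation("a_c <- b_c")          # reverse arrow swaps sides
  expect_equal(sort(pe3$stoichiometry), sort(c(a_c = 1, b_c = -1)))
  expect_error(parse_equation("a_c + b_c"), "no reaction arrow")

  # tabular form of the toy model equals its SBML form
  toy <- make_toy_model()$model
  rp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_model(toy, rp, mp)
  sp <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy, sp)
  mt <- read_tabular_model(rp, mp)
  ms <- read_sbml(sp)
  expect_setequal(mt$reactions$id, ms$reactions$id)
  expect_setequal(mt$metabolites$id, ms$metabolites$id)
  for (rid in ms$reactions$id) {
    expect_equal(sort(mt$stoichiometry[[rid]]), sort(ms$stoichiometry[[rid]]))
    i <- match(rid, mt$reactions$id); j <- match(rid, ms$reactions$id)
    expect_equal(mt$reactions$lower_bound[i], ms$reactions$lower_bound[j])
  }

  # empty reaction sheet -> empty model, no error
  ep <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tequation", ep)
  empty <- read_tabular_model(ep)
  expect_equal(nrow(empty$reactions), 0)

  # unparseable equation cites its row
  bp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation", "RX\tnonsense without arrow"), bp)
  expect_error(read_tabular_model(bp), "row 1")
})

test_that("classification report: categories, totals, unique metabolites", {
  toy2 <- make_toy_model(list(n_carbons = 2))$model
  rep <- classify_and_count(toy2)
  expect_equal(unname(rep$reactions_by_category["exchange"]), 2L)
  expect_equal(unname(rep$reactions_by_category["demand"]), 1L)
  expect_equal(unname(rep$reactions_by_category["maintenance"]), 1L)
  expect_equal(unname(rep$reactions_by_category["biomass"]), 1L)
  # per-category counts sum to the total
  expect_equal(sum(rep$reactions_by_category), rep$n_reactions)
  # unique <= total; strict here because carbons span three compartments
  expect_lt(rep$n_unique_metabolites, rep$n_metabolites)
  single <- metabolic_model(
    data.frame(id = c("a_c", "b_c")), data.frame(id = "R1"),
    list(R1 = c(a_c = -1, b_c = 1)))
  repc <- classify_and_count(single)
  expect_equal(repc$n_unique_metabolites, repc$n_metabolites)
  # JSON report writes and reads back
  jp <- withr::local_tempfile(fileext = ".json")
  write_count_report(toy2, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$n_reactions, rep$n_reactions)
})

test_that("category precedence: explicit field beats id prefix", {
  m <- metabolic_model(
    data.frame(id = c("a_c")),
    data.frame(id = c("EX_like", "plain"),
               category = c("enzymatic", NA)),
    list(EX_like = c(a_c = -1), plain = c(a_c = 1)))
  expect_equal(reaction_categories(m)[1], "enzymatic")
})
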