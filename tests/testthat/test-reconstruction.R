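test_that("homolog rule is strict at the 90/90 boundary and keeps one best hit", {
  rec <- data.frame(
    qseqid = c("q1", "q2", "q3", "q4", "q4"),
    sseqid = c("s1", "s2", "s3", "sB", "sA"),
    pident = c(95.0, 89.9, 95.0, 95.0, 95.0),
    qcovs = c(92.0, 95.0, 90.0, 95.0, 95.0),
    evalue = c(1e-50, 1e-50, 1e-50, 1e-50, 1e-50),
    stringsAsFactors = FALSE)
  out <- map_homologs(rec)
  expect_setequal(out$qseqid, c("q1", "q4"))   # q2, q3 fail strictly
  # exact tie on (identity, coverage, evalue): smaller subject id wins
  expect_equal(out$sseqid[out$qseqid == "q4"], "sA")
  # record order invariance
  out2 <- map_homologs(rec[rev(seq_len(nrow(rec))), ])
  expect_equal(out, out2)
  expect_equal(nrow(map_homologs(rec[0, ])), 0)
})

test_that("screening-mode thresholds (coverage 90, identity 40, E <= 2e-21) match a hand filter", {
  rec <- data.frame(
    qseqid = paste0("q", 1:5), sseqid = paste0("s", 1:5),
    pident = c(45, 39.9, 41, 95, 40.0),
    qcovs = c(95, 95, 90.0, 91, 92),
    evalue = c(1e-30, 1e-30, 1e-30, 3e-21, 2e-21),
    stringsAsFactors = FALSE)
  out <- map_homologs(rec, identity_min = 40, coverage_min = 90,
                      evalue_max = 2e-21)
  hand <- rec[rec$pident > 40 & rec$qcovs > 90 & rec$evalue <= 2e-21, ]
  expect_setequal(out$qseqid, hand$qseqid)
})

test_that("homology table reader validates records and cites the bad line", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("qseqid\tsseqid\tpident\tqcovs\tevalue",
               "q1\ts1\t95\t95\t1e-50",
               "q2\ts2\t190\t95\t1e-50"), p)
  expect_error(read_homology_table(p), "malformed homology record")
  writeLines(c("q1\ts1\t95\t95\t1e-50"), p)   # headerless form
  df <- read_homology_table(p)
  expect_equal(df$pident, 95)
})

test_that("draft assembly: primary-donor precedence, GPR rewriting, superset law", {
  fx <- make_reconstruction_fixture()
  draft <- fx$draft
  # duplicate id resolved from the primary donor (ub 1000, not 500)
  expect_equal(draft$reactions$upper_bound[
    draft$reactions$id == "ATPM"], 1000)
  # GPRs live in the target namespace now
  expect_true(all(grepl("^s12_", unlist(lapply(draft$reactions$gpr[
    nzchar(draft$reactions$gpr)], gpr_genes)))))
  # assemble(A, B, m) contains assemble(A, NULL, m restricted to A)
  mp <- fx$mappings[fx$mappings$donor == "primary", ]
  small <- assemble_draft(fx$primary_donor, NULL, mp,
                          objective = NA_character_)
  expect_true(all(small$reactions$id %in% draft$reactions$id))
  # empty mappings, no extras -> empty model
  empty <- assemble_draft(fx$primary_donor, NULL, NULL)
  expect_equal(nrow(empty$reactions), 0)
  # citing a reaction the donor lacks is an integrity error
  badmap <- data.frame(target_gene = "t", donor = "primary",
                       donor_gene = "kA_tA1", donor_reaction = "GHOST",
                       stringsAsFactors = FALSE)
  expect_error(assemble_draft(fx$primary_donor, NULL, badmap),
               "integrity error")
})

test_that("gap filling recovers planted gaps and matches exhaustive enumeration", {
  for (gap_size in 1:2) {
    fx <- make_reconstruction_fixture(list(gap_size = gap_size))
    res <- gap_fill(fx$gapped_draft, fx$pool)
    expect_equal(res$status, "filled")
    expect_setequal(res$added, fx$gap_ids)
    expect_gt(res$growth, 1e-6)
    # exhaustive oracle: all singletons and pairs, via independent re-adding
    grow_with <- function(idx) {
      m <- fx$gapped_draft
      for (k in idx) {
        ex <- fx$pool[[k]]
        m <- add_reaction(m, ex$id, ex$stoichiometry,
                          lower_bound = ex$lower_bound,
                          upper_bound = ex$upper_bound,
                          gpr = if (is.null(ex$gpr)) "" else ex$gpr)
      }
      sol <- solve_fba(m)
      if (sol$status == "optimal") max(sol$objective_value, 0) else 0
    }
    n <- length(fx$pool)
    all_sets <- c(lapply(seq_len(n), identity),
                  utils::combn(n, 2, simplify = FALSE))
    working <- Filter(function(idx) grow_with(idx) > 1e-6, all_sets)
    min_size <- min(lengths(working))
    expect_equal(length(res$added), min_size)
    ids_of <- function(idx) sort(vapply(fx$pool[idx],
                                        function(e) e$id, character(1)))
    expect_true(any(vapply(working, function(idx)
      setequal(ids_of(idx), res$added), logical(1))))
    # minimality: dropping any member breaks growth
    found_idx <- which(vapply(fx$pool, function(e)
      e$id %in% res$added, logical(1)))
    for (drop in found_idx)
      expect_lt(grow_with(setdiff(found_idx, drop)), 1e-6)
  }
})

test_that("gap filling: already-growing drafts and unfillable drafts", {
  fx <- make_reconstruction_fixture()
  ok <- gap_fill(fx$draft, fx$pool)
  expect_equal(ok$status, "already_growing")
  expect_length(ok$added, 0)
  decoys_only <- fx$pool[vapply(fx$pool, function(e)
    grepl("^DEC_", e$id), logical(1))]
  un <- gap_fill(fx$gapped_draft, decoys_only)
  expect_equal(un$status, "unfillable")
  expect_gt(length(un$dead_ends), 0)
  expect_true("carb2_p" %in% un$dead_ends)
  expect_error(gap_fill(fx$gapped_draft, list()), "empty candidate pool")
})

test_that("phenotype refinement flips planted false calls on re-simulation", {
  toy <- make_toy_model(list(n_carbons = 2))$model
  base_medium <- c()
  sim_call <- function(model, ex) {
    r <- simulate_carbon_source(model, base_medium, ex)
    call_growth(r$growth, 4)   # wild-type-scale reference
  }
  # before refinement: c1 and c2 grow, c3 has no route
  expect_true(sim_call(toy, "EX_carb1_e"))
  calls <- data.frame(
    substrate = c("c1", "c2", "c3"), call = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  predictions <- data.frame(
    substrate = c("c1", "c2", "c3"), call = c(TRUE, TRUE, FALSE),
    exchange = c("EX_carb1_e", "EX_carb2_e", NA), stringsAsFactors = FALSE)
  evidence <- list(c3 = list(
    list(id = "EX_carb3_e", stoichiometry = c(carb3_e = -1),
         lower_bound = -10, upper_bound = 1000),
    list(id = "CARB3tex", stoichiometry = c(carb3_e = -1, carb3_p = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "CARB3abc", stoichiometry = c(carb3_p = -1, carb2_c = 1),
         lower_bound = 0, upper_bound = 1000, gpr = "tEv1")))
  out <- refine_with_phenotypes(toy, calls, predictions, evidence)
  # false positive: exchange removed, prediction flips to non-growth
  expect_false("EX_carb1_e" %in% out$model$reactions$id)
  r1 <- simulate_carbon_source(out$model, base_medium, "EX_carb1_e")
  expect_true(r1$no_exchange)
  expect_false(call_growth(r1$growth, 4))
  # false negative with evidence: route added, prediction flips to growth
  expect_true(sim_call(out$model, "EX_carb3_e"))
  # the concordant substrate keeps its call (no new false positives)
  expect_true(sim_call(out$model, "EX_carb2_e"))
  # change log enumerates 1 removal + 3 additions
  expect_equal(sum(out$log$action == "remove_exchange"), 1)
  expect_equal(sum(out$log$action == "add_reaction"), 3)
  # perfectly concordant tables leave the model unchanged
  same <- refine_with_phenotypes(toy, calls = data.frame(
    substrate = "c2", call = TRUE), predictions = data.frame(
    substrate = "c2", call = TRUE, exchange = "EX_carb2_e"))
  expect_equal(nrow(same$log), 0)
  expect_identical(same$model$reactions, toy$reactions)
  # FN without evidence is logged and left alone
  noev <- refine_with_phenotypes(toy, calls = data.frame(
    substrate = "cX", call = TRUE), predictions = data.frame(
    substrate = "cX", call = FALSE, exchange = NA))
  expect_equal(noev$log$action, "fn_no_evidence")
})
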