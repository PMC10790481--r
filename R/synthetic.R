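# Deterministic fixture generators with analytically known ground truth.
# Every generator is a pure function of its spec (and seed, where noise is
# involved); fixtures can be written out in the same standard formats the
# real pipeline reads (SBML, TSV, FASTA), so I/O code is exercised rather
# than bypassed.

#' Generate a layered toy metabolic model with a planted FBA optimum
#'
#' The network is exchanges -> periplasmic/cytoplasmic transports -> an
#' energy reaction (carbon -> \code{atp_per_carbon} ATP), a precursor
#' reaction (carbon + \code{atp_per_precursor} ATP -> precursor), an ATPM
#' maintenance reaction, and a biomass reaction consuming
#' \code{precursor_per_biomass} precursor and \code{gam} ATP per unit flux.
#' The optimum is a closed-form path-flow computation: with total carbon
#' uptake U,
#' \deqn{v* = scale (E U - ngam) / (G + P (A + E))}
#' where E, A, P, G are the four stoichiometric parameters. The first
#' carbon's transport carries an isozyme ("or") rule and its energy
#' reaction a complex ("and") rule, so GPR logic is exercised.
#'
#' @param spec list of size/stoichiometry parameters: \code{seed},
#'   \code{n_carbons} (default 1), \code{uptake_max} (10),
#'   \code{atp_per_carbon} (2), \code{atp_per_precursor} (1),
#'   \code{precursor_per_biomass} (1), \code{gam} (2), \code{ngam} (0),
#'   \code{biomass_scale} (1; biomass coefficients are divided by it, so
#'   doubling it doubles the optimum).
#' @return list with \code{model} (a \code{metabolic_model}),
#'   \code{optimum} (planted LP optimum of the biomass objective) and
#'   \code{spec} (completed).
#' @export
make_toy_model <- function(spec = list()) {
  d <- list(seed = 1L, n_carbons = 1L, uptake_max = 10,
            atp_per_carbon = 2, atp_per_precursor = 1,
            precursor_per_biomass = 1, gam = 2, ngam = 0,
            biomass_scale = 1)
  d[names(spec)] <- spec
  if (d$n_carbons < 1) stop("validation error: need at least one carbon")
  if (d$uptake_max < 0 || d$ngam < 0 || d$biomass_scale <= 0)
    stop("validation error: degenerate toy-model spec")
  E <- d$atp_per_carbon; A <- d$atp_per_precursor
  P <- d$precursor_per_biomass; G <- d$gam; k <- d$biomass_scale

  mets <- data.frame(id = c("atp_c", "adp_c", "pi_c", "h2o_c", "h_c",
                            "pre_c"), stringsAsFactors = FALSE)
  rx <- list(); st <- list()
  addr <- function(id, s, lb, ub, gpr = "") {
    rx[[length(rx) + 1L]] <<- data.frame(
      id = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
      stringsAsFactors = FALSE)
    st[[id]] <<- s
  }
  for (i in seq_len(d$n_carbons)) {
    se <- sprintf("carb%d_e", i); sp <- sprintf("carb%d_p", i)
    sc <- sprintf("carb%d_c", i)
    mets <- rbind(mets, data.frame(id = c(se, sp, sc)))
    addr(sprintf("EX_carb%d_e", i), stats::setNames(-1, se),
         -d$uptake_max, 1000)
    addr(sprintf("CARB%dtex", i), stats::setNames(c(-1, 1), c(se, sp)),
         0, 1000)
    addr(sprintf("CARB%dabc", i), stats::setNames(c(-1, 1), c(sp, sc)),
         0, 1000,
         gpr = if (i == 1) "tA1 or tB1" else sprintf("tG%d", i))
    addr(sprintf("ENERGY%d", i),
         stats::setNames(c(-1, -E, -E, E, E),
                         c(sc, "adp_c", "pi_c", "atp_c", "h2o_c")),
         0, 1000, gpr = if (i == 1) "eA and eB" else sprintf("eG%d", i))
    addr(sprintf("PRECUR%d", i),
         stats::setNames(c(-1, -A, -A, 1, A, A, A),
                         c(sc, "atp_c", "h2o_c", "pre_c", "adp_c", "pi_c",
                           "h_c")),
         0, 1000, gpr = sprintf("pG%d", i))
  }
  addr("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
       d$ngam, 1000)
  addr("DM_h_c", c(h_c = -1), 0, 1000)
  addr("BIOMASS_toy",
       c(pre_c = -P / k, atp_c = -G / k, h2o_c = -G / k,
         adp_c = G / k, pi_c = G / k, h_c = G / k),
       0, 1000)
  reactions <- do.call(rbind, rx)
  model <- metabolic_model(mets, reactions, st, objective = "BIOMASS_toy",
                           id = sprintf("toy_seed%d", d$seed))
  U <- d$n_carbons * d$uptake_max
  optimum <- max(k * (E * U - d$ngam) / (G + P * (A + E)), 0)
  list(model = model, optimum = optimum, spec = d)
}

#' Generate chemostat data from Pirt's law
#'
#' Dilution rates are an even grid on [0.05, 0.7] h^-1 (the usual working
#' range of glucose-limited chemostats); observed yields come from
#' \code{1/Y = m/mu + 1/Yg} with Gaussian noise of sd \code{noise_sd} added
#' on the 1/Y scale.
#'
#' @param m maintenance coefficient (same basis as the yields).
#' @param Yg maximum growth yield.
#' @param noise_sd standard deviation of the 1/Y noise (>= 0).
#' @param n number of observations (>= 2).
#' @param seed RNG seed.
#' @return data.frame (\code{dilution_rate}, \code{yield}) with attributes
#'   \code{m}, \code{Yg} (the planted truth) and \code{noise_sd}.
#' @export
make_chemostat_data <- function(m = 0.023, Yg = 1 / 3, noise_sd = 0,
                                n = 50, seed = 1L) {
  if (noise_sd < 0) stop("validation error: noise_sd must be >= 0")
  if (n < 2) stop("validation error: need n >= 2")
  if (m <= 0 || Yg <= 0) stop("validation error: parameters must be positive")
  mu <- seq(0.05, 0.7, length.out = n)
  inv_y <- m / mu + 1 / Yg
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    inv_y <- inv_y + stats::rnorm(n, 0, noise_sd)
  }
  out <- data.frame(dilution_rate = mu, yield = 1 / inv_y)
  attr(out, "m") <- m; attr(out, "Yg") <- Yg
  attr(out, "noise_sd") <- noise_sd
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a reconstruction fixture with planted homologs and gaps
#'
#' Builds a primary donor (full single-carbon toy network, donor gene
#' namespace \code{kA*}) and a secondary donor (a second carbon's path,
#' gene namespace \code{kB*}, sharing the maintenance/demand reactions with
#' the primary so duplicate-id precedence is exercised), a homology table
#' whose records deliberately straddle the strict over-90/over-90 rule
#' (90.0 exactly must be rejected), the mapping and expected draft implied
#' by the rule, a gapped draft with \code{gap_size} reactions removed, the
#' candidate pool (gap reactions plus decoys) gap_fill must search, and a
#' genome/CDS pair with hand-countable codon composition.
#'
#' @param spec list: \code{seed} (1), \code{gap_size} (2; 1 or 2).
#' @return list with \code{primary_donor}, \code{secondary_donor},
#'   \code{homology}, \code{mappings} (accepted gene->reaction rows),
#'   \code{expected_draft_reactions}, \code{gapped_draft}, \code{gap_ids},
#'   \code{pool}, \code{genome} and \code{cds}
#'   (\code{Biostrings::DNAStringSet}), \code{aa_counts} (planted amino
#'   acid counts of the CDS set).
#' @export
make_reconstruction_fixture <- function(spec = list()) {
  d <- list(seed = 1L, gap_size = 2L)
  d[names(spec)] <- spec
  if (!d$gap_size %in% 1:2)
    stop("validation error: gap_size must be 1 or 2")

  primary <- make_toy_model(list(seed = d$seed))$model
  primary$id <- "donorA"
  # rename primary genes into the kA namespace
  pmap <- stats::setNames(paste0("kA_", primary$genes$id), primary$genes$id)
  primary$reactions$gpr <- vapply(primary$reactions$gpr, gpr_rewrite,
                                  character(1), map = pmap)
  primary$genes <- data.frame(id = unname(pmap), name = unname(pmap),
                              stringsAsFactors = FALSE)

  second_full <- make_toy_model(list(seed = d$seed, n_carbons = 2L))$model
  keep <- c(grep("2", second_full$reactions$id, value = TRUE),
            "ATPM", "DM_h_c")
  secondary <- remove_reactions(second_full,
                                setdiff(second_full$reactions$id, keep))
  secondary$id <- "donorB"
  smap <- stats::setNames(paste0("kB_", secondary$genes$id),
                          secondary$genes$id)
  secondary$reactions$gpr <- vapply(secondary$reactions$gpr, gpr_rewrite,
                                    character(1), map = smap)
  secondary$genes <- data.frame(id = unname(smap), name = unname(smap),
                                stringsAsFactors = FALSE)
  # make the shared ATPM differ in the secondary: primary version must win
  secondary$reactions$upper_bound[secondary$reactions$id == "ATPM"] <- 500

  target_of <- function(donor_gene) sub("^k[AB]_", "s12_", donor_gene)
  hom_pass <- data.frame(
    qseqid = target_of(primary$genes$id), sseqid = primary$genes$id,
    pident = 95.0, qcovs = 92.0, evalue = 1e-50, stringsAsFactors = FALSE)
  hom_boundary <- data.frame(
    qseqid = c("s12_bnd1", "s12_bnd2", "s12_bnd3"),
    sseqid = c("kA_tA1", "kA_eA", "kA_pG1"),
    pident = c(90.0, 89.9, 95.0), qcovs = c(95.0, 95.0, 90.0),
    evalue = 1e-30, stringsAsFactors = FALSE)
  hom_second <- data.frame(
    qseqid = target_of(secondary$genes$id), sseqid = secondary$genes$id,
    pident = 93.0, qcovs = 91.0, evalue = 1e-40, stringsAsFactors = FALSE)
  homology <- rbind(hom_pass, hom_boundary, hom_second)

  gene_rxns <- function(model, donor_label) {
    rows <- list()
    for (i in seq_len(nrow(model$reactions))) {
      gs <- gpr_genes(model$reactions$gpr[i])
      for (g in gs)
        rows[[length(rows) + 1L]] <- data.frame(
          target_gene = target_of(g), donor = donor_label,
          donor_gene = g, donor_reaction = model$reactions$id[i],
          stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  accepted <- map_homologs(homology)
  map_p <- gene_rxns(primary, "primary")
  map_s <- gene_rxns(secondary, "secondary")
  mappings <- rbind(map_p[map_p$donor_gene %in% accepted$sseqid, ],
                    map_s[map_s$donor_gene %in% accepted$sseqid, ])
  # GPR-free infrastructure travels as extras
  extras <- lapply(c("EX_carb1_e", "CARB1tex", "ATPM", "DM_h_c",
                     "BIOMASS_toy"), function(rid) {
    i <- match(rid, primary$reactions$id)
    list(id = rid, stoichiometry = primary$stoichiometry[[rid]],
         lower_bound = primary$reactions$lower_bound[i],
         upper_bound = primary$reactions$upper_bound[i])
  })
  draft <- assemble_draft(primary, secondary, mappings,
                          extra_reactions = extras,
                          objective = "BIOMASS_toy")
  gap_ids <- if (d$gap_size == 1L) "ENERGY1" else c("ENERGY1", "PRECUR1")
  gapped <- remove_reactions(draft, gap_ids)
  gapped$objective <- "BIOMASS_toy"
  gap_specs <- lapply(gap_ids, function(rid) {
    i <- match(rid, draft$reactions$id)
    list(id = rid, stoichiometry = draft$stoichiometry[[rid]],
         lower_bound = draft$reactions$lower_bound[i],
         upper_bound = draft$reactions$upper_bound[i],
         gpr = draft$reactions$gpr[i])
  })
  decoys <- list(
    list(id = "DEC_cycle", stoichiometry = c(foo_c = -1, bar_c = 1),
         lower_bound = -1000, upper_bound = 1000),
    list(id = "DEC_sinkish", stoichiometry = c(pre_c = -1, foo_c = 1),
         lower_bound = 0, upper_bound = 1000),
    list(id = "DEC_atp_waste",
         stoichiometry = c(atp_c = -1, adp_c = 1, pi_c = 1, h_c = 1,
                           h2o_c = -1),
         lower_bound = 0, upper_bound = 1000))
  pool <- c(decoys[1], gap_specs[length(gap_specs)], decoys[2],
            gap_specs[-length(gap_specs)], decoys[3])

  gly <- paste(rep("GGT", 10), collapse = "")
  ala <- paste(rep("GCT", 5), collapse = "")
  cds <- Biostrings::DNAStringSet(c(
    gene1 = paste0("ATG", gly, "TAA"),
    gene2 = paste0("ATG", ala, "TGA")))
  genome <- Biostrings::DNAStringSet(c(chr = paste0(
    "AAAATTTTGGCC", as.character(cds[[1]]), as.character(cds[[2]]))))
  aa_counts <- c(M = 2L, G = 10L, A = 5L)

  list(primary_donor = primary, secondary_donor = secondary,
       homology = homology, mappings = mappings,
       expected_draft_reactions = sort(draft$reactions$id),
       draft = draft, gapped_draft = gapped, gap_ids = gap_ids,
       pool = pool, genome = genome, cds = cds, aa_counts = aa_counts)
}

#' Generate a phenotype-microarray fixture with a planted agreement rate
#'
#' Experimental calls are Bernoulli(0.5) draws; a planted disagreement set
#' of size \code{round(n_substrates * (1 - agreement))} is flipped in the
#' predictions. The expected confusion matrix is computed directly from the
#' construction, independently of \code{\link{score_concordance}}.
#'
#' @param n_substrates number of substrates.
#' @param agreement fraction of substrates where prediction = experiment
#'   (0..1).
#' @param seed RNG seed.
#' @return list with \code{predictions}, \code{experiments}
#'   (\code{growth_call_table}s) and \code{expected} (list tp/tn/fp/fn/
#'   accuracy).
#' @export
make_phenome_fixture <- function(n_substrates = 203, agreement = 197 / 203,
                                 seed = 1L) {
  if (agreement < 0 || agreement > 1)
    stop("validation error: agreement must be in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subs <- sprintf("substrate_%03d", seq_len(n_substrates))
  exp_call <- stats::runif(n_substrates) < 0.5
  n_dis <- round(n_substrates * (1 - agreement))
  flip <- sample(n_substrates, n_dis)
  pred_call <- exp_call
  pred_call[flip] <- !pred_call[flip]
  mk <- function(call) growth_call_table(data.frame(
    plate = paste0("PM", (seq_len(n_substrates) - 1) %/% 96 + 1),
    well = sprintf("W%03d", (seq_len(n_substrates) - 1) %% 96 + 1),
    substrate = subs, category = "carbon", call = call,
    stringsAsFactors = FALSE))
  fp <- sum(pred_call & !exp_call); fn <- sum(!pred_call & exp_call)
  expected <- list(
    tp = sum(pred_call & exp_call), tn = sum(!pred_call & !exp_call),
    fp = fp, fn = fn,
    accuracy = (n_substrates - fp - fn) / n_substrates)
  list(predictions = mk(pred_call), experiments = mk(exp_call),
       expected = expected)
}
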