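# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the LP oracle enumerates basic solutions
# directly, the GPR oracle goes through R's own boolean parser.

# Brute-force LP maximum by vertex enumeration: every choice of a basis
# (column subset of rank r) and of nonbasic variables pinned at a finite
# bound gives a candidate point; the optimum over all feasible candidates
# is the LP optimum. Exponential, fine for <= 8 variables.
oracle_lp_max <- function(c_obj, A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  best <- NA_real_
  basis_sets <- if (r == 0) list(integer(0)) else
    utils::combn(n, r, simplify = FALSE)
  for (B in basis_sets) {
    AB <- A[, B, drop = FALSE]
    if (r > 0 && qr(AB)$rank < r) next
    N <- setdiff(seq_len(n), B)
    n_masks <- if (length(N)) 2^length(N) else 1
    for (mask in seq_len(n_masks) - 1) {
      at_ub <- bitwAnd(mask, 2^(seq_along(N) - 1)) > 0
      xn <- ifelse(at_ub, ub[N], lb[N])
      if (any(!is.finite(xn))) next
      rhs <- b - if (length(N)) as.vector(A[, N, drop = FALSE] %*% xn)
                 else rep(0, nrow(A))
      xb <- if (r > 0)
        tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      else if (max(abs(rhs)) < tol) numeric(0) else NULL
      if (is.null(xb)) next
      x <- numeric(n)
      x[N] <- xn; x[B] <- xb
      if (max(abs(as.vector(A %*% x) - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(c_obj * x)
      if (is.na(best) || val > best) best <- val
    }
  }
  best    # NA when no feasible vertex exists
}

# FBA oracle for a model: vertex enumeration on its stoichiometric matrix.
oracle_fba_max <- function(model, objective = model$objective,
                           overrides = list()) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  names(lb) <- names(ub) <- model$reactions$id
  for (id in names(overrides)) {
    bo <- overrides[[id]]
    if (length(bo) == 1L) bo <- c(bo, bo)
    lb[id] <- bo[1]; ub[id] <- bo[2]
  }
  c_obj <- as.numeric(colnames(S) == objective)
  oracle_lp_max(c_obj, S, rep(0, nrow(S)), lb, ub)
}

# GPR oracle: rewrite the rule into R syntax and let R's parser evaluate it.
oracle_gpr <- function(rule, deleted) {
  if (!nzchar(trimws(rule))) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule))
  genes <- unique(regmatches(rule,
                             gregexpr("[A-Za-z][A-Za-z0-9_]*", rule))[[1]])
  genes <- setdiff(genes, c("and", "or"))
  env <- as.list(stats::setNames(!(genes %in% deleted), genes))
  isTRUE(eval(parse(text = expr), envir = env))
}

# Random GPR tree over a fixed gene alphabet, returned as a rule string.
random_gpr <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35)
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- vapply(seq_len(k), function(i) random_gpr(genes, depth - 1),
                 character(1))
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}

# Small hand-specified 3-metabolite / 2-reaction / 1-gene SBML fixture.
fixture_mini_model <- function() {
  metabolic_model(
    data.frame(id = c("a_e", "a_c", "b_c")),
    data.frame(id = c("EX_a_e", "AB"),
               lower_bound = c(-5, 0), upper_bound = c(1000, 1000),
               gpr = c("", "g1")),
    list(EX_a_e = c(a_e = -1), AB = c(a_e = -1, b_c = 1)),
    objective = NA_character_, id = "mini")
}
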