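# Independent reference implementations used to cross-check the package.
# These are deliberately written as direct, brute-force constructions that
# share no code with the implementation under test.

# --- random GPR rules ------------------------------------------------------
# Generates a random Boolean rule of bounded depth and, alongside it, an R
# arithmetic expression encoding the E-Flux semantics directly
# (AND -> min(...), OR -> sum(...)). Evaluating that expression with
# eval(parse(...)) is the reference evaluator.
random_gpr <- function(genes, depth) {
  if (depth == 0 || runif(1) < 0.3) {
    g <- sample(genes, 1)
    return(list(rule = g, expr = g))
  }
  n_children <- sample(2:3, 1)
  kids <- lapply(seq_len(n_children), function(i) random_gpr(genes, depth - 1))
  op <- sample(c("and", "or"), 1)
  rule <- paste0("(", paste(vapply(kids, `[[`, "", "rule"),
                            collapse = paste0(" ", op, " ")), ")")
  fn <- if (op == "and") "min" else "sum"
  expr <- paste0(fn, "(", paste(vapply(kids, `[[`, "", "expr"),
                                collapse = ", "), ")")
  list(rule = rule, expr = expr)
}

reference_gpr_eval <- function(expr, values) {
  eval(parse(text = expr), envir = as.list(values))
}

# --- brute-force FBA -------------------------------------------------------
# Enumerates basic feasible solutions of max obj.v s.t. S v = 0,
# lb <= v <= ub by fixing (n - rank) variables at a bound and solving the
# rest. Exact for the small fixture models; returns -Inf when no feasible
# vertex exists.
vertex_fba_oracle <- function(model, objective = model$objective_reaction_id) {
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  obj <- numeric(n)
  obj[match(objective, model$reactions$id)] <- 1
  k <- n - qr(S)$rank
  best <- -Inf
  if (k <= 0) k <- 0
  combs <- utils::combn(n, k)
  for (ci in seq_len(ncol(combs))) {
    fixset <- combs[, ci, drop = TRUE]
    freeset <- setdiff(seq_len(n), fixset)
    n_fix <- length(fixset)
    for (mask in 0:(2^n_fix - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_len(n_fix) - 1)) > 0
      fixval <- ifelse(at_ub, ub[fixset], lb[fixset])
      v <- numeric(n)
      v[fixset] <- fixval
      if (length(freeset)) {
        rhs <- -S[, fixset, drop = FALSE] %*% fixval
        sol <- tryCatch(qr.solve(S[, freeset, drop = FALSE], rhs),
                        error = function(e) NULL)
        if (is.null(sol)) next
        v[freeset] <- sol
      }
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      best <- max(best, sum(obj * v))
    }
  }
  best
}

# --- uniform sampling oracles ---------------------------------------------
# Rejection sampler for a box with optional equality constraint handled by
# construction; for the plain box every proposal is accepted.
box_uniform_oracle <- function(n, lb, ub) {
  vapply(seq_along(lb), function(j) runif(n, lb[j], ub[j]), numeric(n))
}

# --- small fixture factory -------------------------------------------------
random_fixture_model <- function(seed) {
  set.seed(seed)
  generate_toy_model(
    n_chain = sample(2:5, 1),
    branches = if (runif(1) < 0.5) list(c(1, 1)) else NULL,
    reversible_fraction = runif(1, 0, 0.5),
    uptake_limit = round(runif(1, 5, 15), 1),
    gpr_pattern = sample(c("single", "and-pair", "or-pair", "mixed"), 1),
    seed = seed
  )
}
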