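# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves   min cost . z   s.t.  M z = q (q >= 0),  z >= 0.
#
# This is the package's LP kernel. It is written for reliability on the
# small, often highly degenerate flux LPs this package generates (blocked
# reactions, zero right-hand sides, fixed variables): Bland's rule cannot
# cycle, and degeneracy only costs extra pivots. Dense tableau arithmetic
# is entirely adequate at the model sizes the package targets.
#
# Returns list(status = "optimal" | "infeasible", x, value).
dense_simplex <- function(cost, M, q, tol = 1e-9) {
  m <- nrow(M); n <- ncol(M)
  stopifnot(length(q) == m, length(cost) == n, all(q >= -tol))
  q <- pmax(q, 0)
  if (m == 0L) {
    # no constraints: minimum of cost . z over z >= 0 is at z = 0
    return(list(status = "optimal", x = numeric(n), value = 0))
  }

  # phase 1: artificial basis
  Tb <- cbind(M, diag(m), q)
  basis <- n + seq_len(m)
  phase1_cost <- c(numeric(n), rep(1, m))
  res <- simplex_iterate(Tb, basis, phase1_cost, ncol_total = n + m, tol = tol)
  Tb <- res$Tb; basis <- res$basis
  if (res$value > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # pivot remaining artificials out of the basis where possible
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      piv <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(piv)) {
        Tb <- simplex_pivot(Tb, i, piv[1])
        basis[i] <- piv[1]
      }
      # else: redundant row, its artificial stays basic at value 0
    }
  }

  # phase 2 on the original columns (artificials pinned at zero by removal)
  Tb2 <- Tb[, c(seq_len(n), n + m + 1L), drop = FALSE]
  keep_rows <- basis <= n
  # rows still basic in an artificial are redundant (value 0); keep them but
  # they never pivot (their artificial column is gone, row is all-zero in
  # the kept columns or harmless)
  res2 <- simplex_iterate(Tb2, basis, cost, ncol_total = n, tol = tol,
                          frozen_rows = which(!keep_rows))
  Tb2 <- res2$Tb; basis <- res2$basis
  x <- numeric(n)
  rhs <- Tb2[, n + 1L]
  for (i in seq_len(m)) {
    if (basis[i] <= n) x[basis[i]] <- rhs[i]
  }
  list(status = "optimal", x = pmax(x, 0), value = sum(cost * x))
}

# Run simplex iterations (min) on tableau Tb (m x (ncol_total + 1), last
# column = rhs) from the given basis, using Bland's rule throughout.
simplex_iterate <- function(Tb, basis, cost, ncol_total, tol,
                            frozen_rows = integer(0)) {
  m <- nrow(Tb)
  max_iter <- 1000L + 50L * (m + ncol_total)
  eligible_rows <- setdiff(seq_len(m), frozen_rows)
  # artificials still basic on redundant rows sit beyond `cost`: cost 0
  basis_cost <- function(basis) {
    cb <- numeric(length(basis))
    sel <- basis <= length(cost)
    cb[sel] <- cost[basis[sel]]
    cb
  }
  for (it in seq_len(max_iter)) {
    # reduced costs: c_j - c_B . B^-1 A_j (tableau already holds B^-1 A)
    cb <- basis_cost(basis)
    red <- cost[seq_len(ncol_total)] -
      as.numeric(crossprod(Tb[, seq_len(ncol_total), drop = FALSE], cb))
    entering <- 0L
    for (j in seq_len(ncol_total)) {           # Bland: smallest index
      if (red[j] < -tol && !(j %in% basis)) { entering <- j; break }
    }
    if (entering == 0L) break
    col <- Tb[, entering]
    cand <- eligible_rows[col[eligible_rows] > tol]
    if (!length(cand)) {
      # unbounded direction; callers always bound every variable, so this
      # can only be numerical noise — treat as converged
      break
    }
    ratios <- Tb[cand, ncol(Tb)] / col[cand]
    best <- min(ratios)
    ties <- cand[ratios <= best + tol]
    leaving <- ties[which.min(basis[ties])]    # Bland: smallest basis index
    Tb <- simplex_pivot(Tb, leaving, entering)
    basis[leaving] <- entering
  }
  cb <- basis_cost(basis)
  value <- sum(cb * Tb[, ncol(Tb)])
  list(Tb = Tb, basis = basis, value = value)
}

simplex_pivot <- function(Tb, prow, pcol) {
  piv <- Tb[prow, pcol]
  Tb[prow, ] <- Tb[prow, ] / piv
  other <- setdiff(seq_len(nrow(Tb)), prow)
  if (length(other)) {
    Tb[other, ] <- Tb[other, , drop = FALSE] -
      outer(Tb[other, pcol], Tb[prow, ])
  }
  Tb
}
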