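# Thin LP layer. All flux LPs in the package go through solve_lp(), so the
# backend can be swapped in one place. The backend is the package's own
# two-phase Bland-rule simplex (R/simplex.R). Variables are shifted to
# x = v - lb >= 0, upper bounds become slack rows, and equality rows are
# sign-normalized. All bounds are finite (non-finite input bounds are
# clamped to +/- LP_BIG), so the LP can never be unbounded.

LP_BIG <- 1e6

#' Solve a bounded linear program
#'
#' Maximizes or minimizes `obj . v` subject to `A v = b` and
#' `lb <= v <= ub`. This is the pluggable LP interface behind [solve_fba()]
#' and the sampler's warm-up vertices.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A equality constraint matrix (m x n); may have zero rows.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; non-finite entries are clamped to
#'   `+/- 1e6`.
#' @param sense `"max"` or `"min"`.
#' @param tol feasibility tolerance used when screening degenerate rows.
#' @return list with `status` (`"optimal"` or `"infeasible"`),
#'   `objective` and `solution` (length n), the latter `NULL` unless optimal.
#' @export
solve_lp <- function(obj, A, b, lb, ub, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  }
  if (is.null(A)) A <- matrix(0, 0, n)
  A <- as.matrix(A)
  if (length(b) != nrow(A)) stop("b must match the rows of A")

  # eliminate fixed variables (ub == lb): the simplex backend mishandles
  # zero-width bounds, and blocked reactions (score 0) produce many
  v <- lb
  free <- (ub - lb) > 1e-12
  if (!all(free)) {
    b <- as.numeric(b - A[, !free, drop = FALSE] %*% lb[!free])
    A <- A[, free, drop = FALSE]
    obj_fixed <- sum(obj[!free] * lb[!free])
    obj_free <- obj[free]
    sub <- solve_lp(obj_free, A, b, lb[free], ub[free], sense = sense,
                    tol = tol)
    if (sub$status != "optimal") return(sub)
    v[free] <- sub$solution
    return(list(status = "optimal", objective = sub$objective + obj_fixed,
                solution = v))
  }
  if (n == 0L) {
    status <- if (all(abs(b) <= 1e-7)) "optimal" else "infeasible"
    return(list(status = status,
                objective = if (status == "optimal") 0 else NA_real_,
                solution = if (status == "optimal") numeric(0) else NULL))
  }

  # shift x = v - lb, so x >= 0 and A x = b - A lb
  beq <- as.numeric(b - A %*% lb)
  # drop all-zero rows (screen for inconsistency first)
  if (nrow(A) > 0) {
    zero_row <- apply(abs(A) < tol, 1, all)
    if (any(zero_row & abs(beq) > 1e-7)) {
      return(list(status = "infeasible", objective = NA_real_, solution = NULL))
    }
    A <- A[!zero_row, , drop = FALSE]
    beq <- beq[!zero_row]
  }
  # sign-normalize equality rows (the kernel wants non-negative rhs)
  neg <- beq < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    beq[neg] <- -beq[neg]
  }
  # standard form over z = [x, slack]: A x = beq, x + slack = ub - lb
  m <- nrow(A)
  M <- rbind(
    cbind(A, matrix(0, m, n)),
    cbind(diag(n), diag(n))
  )
  q <- c(beq, ub - lb)
  cost <- c(if (sense == "max") -obj else obj, numeric(n))
  res <- dense_simplex(cost, M, q)
  if (res$status != "optimal") {
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  }
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), solution = v)
}
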