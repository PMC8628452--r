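#' Construct a flux polytope
#'
#' The sampler's geometric object: `{v : A v = b, lb <= v <= ub}`. A
#' metabolic model converts to a polytope with `A = S` and `b = 0`
#' (steady-state mass balance); the constructor is also exported so simple
#' reference polytopes (segments, boxes) can be sampled directly in tests
#' and examples.
#'
#' @param A equality constraint matrix (may have zero rows for a pure box).
#' @param b right-hand side, recycled scalar allowed.
#' @param lb,ub finite variable bounds.
#' @param reaction_ids variable names; default `v1..vn`.
#' @return a `flux_polytope`.
#' @export
flux_polytope <- function(A, b = 0, lb, ub, reaction_ids = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (length(lb) != n || length(ub) != n) stop("bounds must have length ncol(A)")
  if (any(lb > ub)) stop("lb > ub")
  b <- rep_len(b, nrow(A))
  if (is.null(reaction_ids)) reaction_ids <- paste0("v", seq_len(n))
  structure(list(A = A, b = as.numeric(b), lb = as.numeric(lb),
                 ub = as.numeric(ub), reaction_ids = reaction_ids),
            class = "flux_polytope")
}

#' Convert a metabolic model to its steady-state flux polytope
#'
#' @param model a `metabolic_model`.
#' @return a `flux_polytope` with `A` the stoichiometric matrix and `b = 0`.
#' @export
as_flux_polytope <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- stoichiometric_matrix(model)
  flux_polytope(S, 0, model$reactions$lower_bound,
                model$reactions$upper_bound,
                reaction_ids = model$reactions$id)
}

#' Fix the objective flux at (a fraction of) its optimum
#'
#' Solves FBA, then raises the objective reaction's lower bound to
#' `fraction` times the optimum. This is the "sampling at maximum growth"
#' construction: the remaining flux polytope contains only distributions
#' compatible with (near-)maximal growth. The default fraction 0.999 keeps
#' the polytope full-dimensional in the non-objective directions rather than
#' collapsing it onto the optimal face exactly.
#'
#' @param model a feasible `metabolic_model`.
#' @param fraction in (0, 1]; default 0.999.
#' @return a modified copy of the model.
#' @export
fix_objective_at_optimum <- function(model, fraction = 0.999) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  fba <- solve_fba(model)
  if (fba$status != "optimal")
    stop("model is infeasible; cannot fix the objective at its optimum")
  set_bounds(model, model$objective_reaction_id,
             lower = fraction * fba$objective_value)
}

#' Generate ACHR warm-up points
#'
#' Produces the warm-up matrix W whose columns are feasible flux vectors
#' spanning the polytope, obtained as optimal vertices of LPs with
#' randomized objectives (the first `2n` warm-ups minimize and maximize each
#' coordinate in turn; further ones use random Gaussian objectives). The
#' approximate centre s is the column mean of W and the walk starts there.
#'
#' @param x a `metabolic_model` or `flux_polytope`.
#' @param n_warmup number of warm-up points, at least 2; at least twice the
#'   number of reactions is recommended (and is the default).
#' @param seed integer RNG seed; the sampler is fully deterministic given
#'   the seed and settings.
#' @return a `sampler_state`: list with `polytope`, `warmup` (n x K matrix),
#'   `center`, `current`, `n_center` (points absorbed into the running
#'   centre) and `rng_seed`.
#' @export
generate_warmup <- function(x, n_warmup = NULL, seed = 1L) {
  poly <- if (inherits(x, "metabolic_model")) as_flux_polytope(x) else x
  stopifnot(inherits(poly, "flux_polytope"))
  n <- length(poly$lb)
  if (is.null(n_warmup)) n_warmup <- max(4L, 2L * n)
  if (n_warmup < 2) stop("n_warmup must be at least 2")
  set.seed(as.integer(seed))
  W <- matrix(NA_real_, nrow = n, ncol = n_warmup)
  k <- 0L
  # coordinate min/max sweeps first, then random objectives
  for (j in seq_len(n)) {
    for (sense in c("min", "max")) {
      if (k >= n_warmup) break
      obj <- numeric(n); obj[j] <- 1
      res <- solve_lp(obj, poly$A, poly$b, poly$lb, poly$ub, sense = sense)
      if (res$status != "optimal")
        stop("polytope is infeasible; cannot generate warm-up points")
      k <- k + 1L
      W[, k] <- res$solution
    }
  }
  while (k < n_warmup) {
    obj <- stats::rnorm(n)
    res <- solve_lp(obj, poly$A, poly$b, poly$lb, poly$ub, sense = "max")
    if (res$status != "optimal")
      stop("polytope is infeasible; cannot generate warm-up points")
    k <- k + 1L
    W[, k] <- res$solution
  }
  spread <- apply(W, 1, function(r) diff(range(r)))
  if (all(spread < 1e-9))
    warning("degenerate polytope: all warm-up points coincide; ",
            "sampling will return that single point repeatedly")
  center <- rowMeans(W)
  structure(
    list(polytope = poly, warmup = W, center = center, current = center,
         n_center = ncol(W), rng_seed = as.integer(seed)),
    class = "sampler_state"
  )
}

#' Sample the flux polytope by artificial-centering hit-and-run
#'
#' Runs the ACHR walk: at each iteration a random warm-up column y is drawn,
#' the direction is `d = y - s` (s the running centre), the feasible step
#' interval along d from the current point is computed from the bounds, a
#' uniform step is taken, the new point replaces a random column of W, and
#' the centre is updated as the running mean. Every `thinning`-th iterate is
#' stored. Directions are differences of feasible points and therefore
#' automatically satisfy the equality (mass-balance) constraints; slow
#' numerical drift is controlled by periodically re-projecting the iterate
#' onto the equality subspace.
#'
#' @param state a `sampler_state` from [generate_warmup()].
#' @param n_points number of stored samples; default 10000.
#' @param thinning iterations between stored samples; default 200.
#' @return a `flux_sample_set`: list with `points` (n_points x n matrix,
#'   columns named by reaction) and `settings` (n_points, thinning, seed).
#' @export
achr_sample <- function(state, n_points = 10000, thinning = 200) {
  stopifnot(inherits(state, "sampler_state"))
  if (n_points < 1) stop("n_points must be at least 1")
  if (thinning < 1) stop("thinning must be at least 1")
  poly <- state$polytope
  n <- length(poly$lb)
  W <- state$warmup
  K <- ncol(W)
  s <- state$center
  x <- state$current
  n_center <- state$n_center
  lb <- poly$lb; ub <- poly$ub
  eps_dir <- 1e-12
  has_eq <- nrow(poly$A) > 0
  if (has_eq) {
    # SVD of A, tolerant of row-rank deficiency (conserved moieties).
    # V spans the row space: I - V V' projects onto the null space, and the
    # pseudo-inverse gives the minimal-norm reprojection onto {A v = b}.
    # Directions are null-space-projected on every iteration — without
    # this, the constraint error of stored points re-enters through the
    # direction vectors scaled by the step size and compounds
    # geometrically.
    sv <- svd(poly$A)
    keep <- sv$d > max(dim(poly$A)) * max(sv$d[1], 1e-300) * 1e-12
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
    dinv <- 1 / sv$d[keep]
    reproject <- function(v) {
      resid <- as.numeric(poly$A %*% v - poly$b)
      as.numeric(v - V %*% (dinv * as.numeric(crossprod(U, resid))))
    }
    null_project <- function(d) {
      as.numeric(d - V %*% crossprod(V, d))
    }
  } else {
    reproject <- identity
    null_project <- identity
  }
  set.seed(state$rng_seed + 1L)
  pts <- matrix(NA_real_, nrow = n_points, ncol = n,
                dimnames = list(NULL, poly$reaction_ids))
  stored <- 0L
  iter <- 0L
  degenerate_tries <- 0L
  while (stored < n_points) {
    iter <- iter + 1L
    # direction from a random warm-up point through the centre
    repeat {
      jw <- sample.int(K, 1L)
      d <- W[, jw] - s
      if (sqrt(sum(d * d)) > eps_dir || degenerate_tries > 50L) break
      degenerate_tries <- degenerate_tries + 1L
    }
    d <- null_project(d)
    nd <- sqrt(sum(d * d))
    active <- which(abs(d) > eps_dir)
    if (nd <= eps_dir || !length(active)) {
      # fully determined polytope: the single point is the sample
      x_new <- x
    } else {
      l1 <- (lb[active] - x[active]) / d[active]
      l2 <- (ub[active] - x[active]) / d[active]
      lam_lo <- max(pmin(l1, l2))
      lam_hi <- min(pmax(l1, l2))
      if (lam_hi < lam_lo) {
        if (lam_hi < lam_lo - 1e-6)
          warning("empty step interval beyond tolerance; re-projecting")
        x <- pmin(pmax(x, lb), ub)
        x <- as.numeric(reproject(x))
        x_new <- x
      } else {
        lam <- stats::runif(1, lam_lo, lam_hi)
        x_new <- x + lam * d
      }
    }
    # replace a random warm-up column and update the running centre
    W[, sample.int(K, 1L)] <- x_new
    s <- (s * n_center + x_new) / (n_center + 1)
    n_center <- n_center + 1
    x <- x_new
    if (iter %% 1000L == 0L && has_eq) {
      x <- pmin(pmax(as.numeric(reproject(x)), lb), ub)
      s <- as.numeric(reproject(s))
    }
    if (iter %% thinning == 0L) {
      stored <- stored + 1L
      pts[stored, ] <- x
    }
  }
  structure(
    list(points = pts,
         settings = list(n_points = n_points, thinning = thinning,
                         seed = state$rng_seed)),
    class = "flux_sample_set"
  )
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("<flux_sample_set> ", nrow(x$points), " points x ", ncol(x$points),
      " reactions (thinning ", x$settings$thinning,
      ", seed ", x$settings$seed, ")\n", sep = "")
  invisible(x)
}

#' Per-reaction mean and standard deviation of sampled fluxes
#'
#' The mean +/- sd over the sampled steady-state points is the package's
#' flux prediction for a reaction (secretion rates, intracellular fluxes).
#'
#' @param samples a `flux_sample_set`.
#' @param reaction_ids reactions to summarize; default all.
#' @return a `flux_prediction` data.frame with columns `reaction`, `mean`,
#'   `sd`.
#' @export
summarize_samples <- function(samples, reaction_ids = NULL) {
  stopifnot(inherits(samples, "flux_sample_set"))
  all_ids <- colnames(samples$points)
  if (is.null(reaction_ids)) reaction_ids <- all_ids
  unknown <- setdiff(reaction_ids, all_ids)
  if (length(unknown))
    stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  m <- samples$points[, reaction_ids, drop = FALSE]
  out <- data.frame(
    reaction = reaction_ids,
    mean = apply(m, 2, mean),
    sd = apply(m, 2, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$sd[is.na(out$sd)] <- 0  # single-point sample sets
  class(out) <- c("flux_prediction", "data.frame")
  out
}

#' Count which of two prediction sets lies closer to measured fluxes
#'
#' For every measured reaction, compares the absolute deviation of each
#' prediction's mean flux from the measured value and counts wins for each
#' side and exact ties — the head-to-head comparison used to tabulate how
#' often one bound-setting scheme outpredicts another.
#'
#' @param pred_a,pred_b `flux_prediction` data.frames (or anything with
#'   `reaction` and `mean` columns).
#' @param measured named numeric vector, reaction id -> measured flux.
#' @return list with `count_a_closer`, `count_b_closer`, `ties` and a
#'   per-reaction `detail` data.frame.
#' @export
compare_to_measured <- function(pred_a, pred_b, measured) {
  if (!length(measured) || is.null(names(measured)))
    stop("measured must be a non-empty named vector")
  ids <- names(measured)
  ia <- match(ids, pred_a$reaction)
  ib <- match(ids, pred_b$reaction)
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("measured reaction(s) missing from predictions: ",
         paste(ids[is.na(ia) | is.na(ib)], collapse = ", "))
  dev_a <- abs(pred_a$mean[ia] - measured)
  dev_b <- abs(pred_b$mean[ib] - measured)
  list(
    count_a_closer = sum(dev_a < dev_b),
    count_b_closer = sum(dev_b < dev_a),
    ties = sum(dev_a == dev_b),
    detail = data.frame(reaction = ids, measured = unname(measured),
                        mean_a = pred_a$mean[ia], mean_b = pred_b$mean[ib],
                        dev_a = unname(dev_a), dev_b = unname(dev_b),
                        stringsAsFactors = FALSE, row.names = NULL)
  )
}
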