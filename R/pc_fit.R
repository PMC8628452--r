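# Growth at one PC value: scale -> GPR scores -> bounds -> FBA.
# `model` is expected to already carry any measured uptake constraints.
eflux_growth <- function(model, profile, delta,
                         constrain_exchanges = FALSE, missing_policy = "max") {
  scaled <- scale_expression(profile, delta)
  activity <- compute_reaction_scores(model, scaled,
                                      missing_policy = missing_policy)
  constrained <- suppressWarnings(
    apply_eflux_bounds(model, activity, constrain_exchanges = constrain_exchanges))
  fba <- solve_fba(constrained)
  list(status = fba$status,
       growth = if (fba$status == "optimal") fba$objective_value else NA_real_,
       model = constrained)
}

#' Scan predicted growth over a grid of proportionality constants
#'
#' For each PC value delta on the grid the full pipeline is run
#' (scale expression, evaluate GPRs, impose bounds, solve FBA) and the
#' predicted growth rate recorded. Growth is non-decreasing in delta because
#' every expression-derived bound scales linearly with it, and infeasible
#' entries (a PC too low to satisfy e.g. maintenance constraints) can only
#' occur as a prefix of the grid. The default grid is 61 points over
#' `[0, 600]`; the scan warns when the last two feasible growth values still
#' differ by more than `plateau_tol`, i.e. when the grid's upper limit has
#' not demonstrably reached the growth plateau.
#'
#' @param model a `metabolic_model`.
#' @param profile an `expression_profile`.
#' @param measured_uptakes optional named vector for
#'   [apply_uptake_constraints()].
#' @param grid strictly increasing non-negative PC values.
#' @param constrain_exchanges,missing_policy passed to the E-Flux step.
#' @param plateau_tol growth difference (h^-1) under which the curve is
#'   considered flat; default 1e-3.
#' @return a `pc_scan` data.frame with columns `delta`, `growth` (NA when
#'   infeasible) and `status`; attribute `plateau_reached` records the
#'   plateau check.
#' @export
scan_pc <- function(model, profile, measured_uptakes = NULL,
                    grid = seq(0, 600, by = 10),
                    constrain_exchanges = FALSE, missing_policy = "max",
                    plateau_tol = 1e-3) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(profile, "expression_profile"))
  if (!length(grid)) stop("PC grid must not be empty")
  if (any(diff(grid) <= 0)) stop("PC grid must be strictly increasing")
  if (any(grid < 0)) stop("PC values must be non-negative")
  if (length(measured_uptakes))
    model <- apply_uptake_constraints(model, measured_uptakes)
  growth <- rep(NA_real_, length(grid))
  status <- character(length(grid))
  for (k in seq_along(grid)) {
    res <- eflux_growth(model, profile, grid[k],
                        constrain_exchanges = constrain_exchanges,
                        missing_policy = missing_policy)
    growth[k] <- res$growth
    status[k] <- res$status
  }
  feas <- which(status == "optimal")
  plateau_reached <- NA
  if (length(feas) >= 2) {
    tail_g <- growth[utils::tail(feas, 2)]
    plateau_reached <- abs(diff(tail_g)) < plateau_tol
    if (!isTRUE(plateau_reached))
      warning("growth has not plateaued at the upper end of the PC grid ",
              "(last step changes growth by ", format(abs(diff(tail_g))), ")")
  }
  out <- data.frame(delta = grid, growth = growth, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("pc_scan", "data.frame")
  attr(out, "plateau_reached") <- plateau_reached
  out
}

#' Fit the proportionality constant against a measured growth rate
#'
#' Runs a coarse PC scan over `range` (step `coarse_step`), then refines by
#' bisection inside the bracketing interval until the delta interval is
#' narrower than `delta_tol`. The fitted PC is the smallest value whose
#' predicted growth reaches the measured growth rate — the left intersection
#' of the growth-versus-PC curve with the measurement, i.e. the most
#' constrained model consistent with the data. Because predicted growth is
#' non-decreasing and continuous in the PC, bisection on the predicate
#' "growth >= measured" converges to that point.
#'
#' @param model a `metabolic_model`.
#' @param profile an `expression_profile`.
#' @param measured_uptakes optional named uptake vector.
#' @param measured_growth the measured growth rate (h^-1), must be positive.
#' @param range PC search range, default `c(0, 600)`.
#' @param coarse_step coarse grid step, default 10 (61 grid points over the
#'   default range).
#' @param tolerance growth tolerance (h^-1) for declaring the fit achieved;
#'   default 1e-3, below the measurement precision of chemostat dilution
#'   rates.
#' @param delta_tol width of the final bisection interval on the PC;
#'   default 1e-3.
#' @param constrain_exchanges,missing_policy passed to the E-Flux step.
#' @return a `pc_fit_result`: list with `delta_fit`, `measured_growth`,
#'   `achieved_growth`, `plateau_growth`, `plateau_onset` (smallest PC whose
#'   growth is within `tolerance` of the plateau), `status` one of `"fit"`,
#'   `"at-plateau-unreachable"`, `"infeasible-everywhere"`, and `scan` (the
#'   coarse `pc_scan`).
#' @export
fit_pc <- function(model, profile, measured_uptakes = NULL, measured_growth,
                   range = c(0, 600), coarse_step = 10,
                   tolerance = 1e-3, delta_tol = 1e-3,
                   constrain_exchanges = FALSE, missing_policy = "max") {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(profile, "expression_profile"))
  if (!is.numeric(measured_growth) || length(measured_growth) != 1L ||
      measured_growth <= 0)
    stop("measured_growth must be a single positive growth rate")
  if (length(range) != 2L || range[1] < 0 || range[2] <= range[1])
    stop("range must be an increasing non-negative interval")
  grid <- seq(range[1], range[2], by = coarse_step)
  if (utils::tail(grid, 1) < range[2]) grid <- c(grid, range[2])
  if (length(measured_uptakes))
    model <- apply_uptake_constraints(model, measured_uptakes)

  scan <- scan_pc(model, profile, measured_uptakes = NULL, grid = grid,
                  constrain_exchanges = constrain_exchanges,
                  missing_policy = missing_policy, plateau_tol = tolerance)
  feas <- which(scan$status == "optimal")
  if (!length(feas)) {
    return(new_pc_fit_result(NA_real_, measured_growth, NA_real_, NA_real_,
                             NA_real_, "infeasible-everywhere", scan,
                             tolerance))
  }
  growth_at <- function(delta) {
    eflux_growth(model, profile, delta,
                 constrain_exchanges = constrain_exchanges,
                 missing_policy = missing_policy)$growth  # NA if infeasible
  }
  plateau_growth <- scan$growth[utils::tail(feas, 1)]

  # left edge of the plateau: smallest delta with growth within tolerance
  plateau_onset <- bisect_smallest_delta(
    scan, growth_at, target = plateau_growth - tolerance, delta_tol = delta_tol)

  if (measured_growth > plateau_growth + tolerance) {
    return(new_pc_fit_result(NA_real_, measured_growth, plateau_growth,
                             plateau_growth, plateau_onset,
                             "at-plateau-unreachable", scan, tolerance))
  }
  delta_fit <- bisect_smallest_delta(scan, growth_at,
                                     target = measured_growth,
                                     delta_tol = delta_tol,
                                     growth_tol = tolerance)
  achieved <- growth_at(delta_fit)
  status <- if (!is.na(achieved) &&
                abs(achieved - measured_growth) <= tolerance)
    "fit" else "at-plateau-unreachable"
  new_pc_fit_result(delta_fit, measured_growth, achieved, plateau_growth,
                    plateau_onset, status, scan, tolerance)
}

# Smallest delta with growth(delta) >= target, found by bisection between
# the bracketing coarse-grid points. Infeasible evaluations count as
# "below". Refines until the delta interval is narrower than delta_tol AND
# the upper endpoint's growth is within growth_tol of the target (growth is
# continuous, so both are attainable together), with a hard floor on the
# interval width to guarantee termination.
bisect_smallest_delta <- function(scan, growth_at, target, delta_tol,
                                  growth_tol = Inf) {
  ok <- !is.na(scan$growth) & scan$growth >= target
  if (!any(ok)) return(utils::tail(scan$delta, 1))
  hi_idx <- which(ok)[1]
  hi <- scan$delta[hi_idx]
  g_hi <- scan$growth[hi_idx]
  if (hi_idx == 1L) return(hi)
  lo <- scan$delta[hi_idx - 1L]
  while (hi - lo > 1e-9 &&
         (hi - lo > delta_tol || g_hi - target > growth_tol)) {
    mid <- (lo + hi) / 2
    g <- growth_at(mid)
    if (!is.na(g) && g >= target) { hi <- mid; g_hi <- g } else lo <- mid
  }
  hi
}

new_pc_fit_result <- function(delta_fit, measured_growth, achieved_growth,
                              plateau_growth, plateau_onset, status, scan,
                              tolerance) {
  structure(
    list(delta_fit = delta_fit, measured_growth = measured_growth,
         achieved_growth = achieved_growth, plateau_growth = plateau_growth,
         plateau_onset = plateau_onset, status = status, scan = scan,
         tolerance = tolerance),
    class = "pc_fit_result"
  )
}

#' @export
print.pc_fit_result <- function(x, ...) {
  cat("<pc_fit_result> status: ", x$status, "\n", sep = "")
  cat("  measured growth: ", format(x$measured_growth), " h^-1\n", sep = "")
  if (x$status == "fit") {
    cat("  fitted PC: ", format(x$delta_fit),
        "  (achieved growth ", format(x$achieved_growth), ")\n", sep = "")
  }
  if (!is.na(x$plateau_growth)) {
    cat("  plateau growth: ", format(x$plateau_growth),
        "  onset near PC ", format(x$plateau_onset), "\n", sep = "")
  }
  invisible(x)
}
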