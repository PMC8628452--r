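#' Set measured uptake (and secretion) limits on exchange reactions
#'
#' Exchange fluxes follow the standard sign convention: consumption is a
#' negative exchange flux, secretion positive. A measured uptake rate
#' `u > 0` therefore sets `lower_bound = -u` on that exchange (leaving the
#' upper bound untouched); an uptake of 0 makes the nutrient unavailable. A
#' measured secretion listed in `secretions` forbids uptake
#' (`lower_bound = 0`) while leaving secretion free up to the default upper
#' bound.
#'
#' @param model a `metabolic_model`.
#' @param uptakes named non-negative numeric vector, exchange reaction id ->
#'   measured uptake rate (mmol gDW^-1 h^-1).
#' @param secretions optional character vector (or named numeric, values
#'   ignored beyond the sign check) of exchange reactions measured as
#'   secreted.
#' @return a modified copy of the model.
#' @export
apply_uptake_constraints <- function(model, uptakes = NULL, secretions = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  exch_ids <- model$reactions$id[is_exchange_reaction(model)]
  check_keys <- function(ids, what) {
    bad <- setdiff(ids, exch_ids)
    if (length(bad))
      stop(what, " must name exchange reactions; not exchanges: ",
           paste(bad, collapse = ", "))
  }
  if (length(uptakes)) {
    if (is.null(names(uptakes)) || any(!nzchar(names(uptakes))))
      stop("uptakes must be a named vector")
    check_keys(names(uptakes), "uptakes")
    if (any(uptakes < 0))
      stop("uptake rates must be non-negative (magnitudes of consumption)")
    for (rid in names(uptakes)) {
      i <- match(rid, model$reactions$id)
      model$reactions$lower_bound[i] <- -uptakes[[rid]]
      if (model$reactions$upper_bound[i] < 0)
        model$reactions$upper_bound[i] <- 0
    }
  }
  if (length(secretions)) {
    ids <- if (is.null(names(secretions)) || !any(nzchar(names(secretions))))
      as.character(secretions) else names(secretions)
    check_keys(ids, "secretions")
    for (rid in ids) {
      i <- match(rid, model$reactions$id)
      model$reactions$lower_bound[i] <- max(0, model$reactions$lower_bound[i])
    }
  }
  model
}

#' Flux balance analysis
#'
#' Solves the FBA linear program: optimize the flux through one reaction
#' subject to steady-state mass balance `S v = 0` and the model's flux
#' bounds. Growth simulations maximize the biomass synthesis reaction.
#'
#' @param model a `metabolic_model`.
#' @param objective_reaction_id reaction to optimize; default the model's
#'   objective (biomass) reaction.
#' @param sense `"max"` (default) or `"min"`.
#' @param tol feasibility/optimality tolerance (default 1e-6), used when
#'   post-checking the returned flux vector.
#' @return an `fba_result`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `objective_value`, and `fluxes` (named vector, only
#'   when optimal). An over-constrained model (for instance a proportionality
#'   constant too low to sustain maintenance requirements) comes back
#'   `"infeasible"` with no fluxes.
#' @export
solve_fba <- function(model, objective_reaction_id = model$objective_reaction_id,
                      sense = c("max", "min"), tol = 1e-6) {
  sense <- match.arg(sense)
  stopifnot(inherits(model, "metabolic_model"))
  rxn_ids <- model$reactions$id
  j <- match(objective_reaction_id, rxn_ids)
  if (is.na(j)) stop("objective reaction '", objective_reaction_id,
                     "' is not in the model")
  S <- stoichiometric_matrix(model)
  obj <- numeric(length(rxn_ids)); obj[j] <- 1
  res <- solve_lp(obj, S, rep(0, nrow(S)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  sense = sense)
  if (res$status != "optimal") {
    return(structure(list(status = "infeasible", objective_value = NA_real_,
                          fluxes = NULL),
                     class = "fba_result"))
  }
  v <- res$solution
  names(v) <- rxn_ids
  resid <- max(abs(S %*% v))
  if (resid > tol)
    warning("FBA solution violates mass balance by ", format(resid))
  structure(list(status = "optimal", objective_value = res$objective,
                 fluxes = v),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status: ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective = ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' Export a flux vector as TSV
#'
#' @param result an optimal `fba_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(result, path) {
  stopifnot(inherits(result, "fba_result"))
  if (result$status != "optimal") stop("no fluxes: status is ", result$status)
  utils::write.table(
    data.frame(reaction = names(result$fluxes), flux = unname(result$fluxes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
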