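#' Reaction activity scores from a scaled expression profile
#'
#' Evaluates each reaction's GPR rule over the PC-scaled expression values
#' (OR = sum, AND = min; see [evaluate_gpr()]). Reactions without a GPR get
#' `NA` (absent): their bounds are never touched downstream.
#'
#' @param model a `metabolic_model`.
#' @param scaled a `scaled_profile` from [scale_expression()].
#' @param missing_policy handling of model genes absent from the profile,
#'   see [evaluate_gpr()].
#' @return a `reaction_activity`: list with `scores` (named numeric along
#'   reactions, `NA` = no GPR) and `delta` (the PC used).
#' @export
compute_reaction_scores <- function(model, scaled,
                                    missing_policy = c("max", "zero", "error")) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(scaled, "scaled_profile"))
  missing_policy <- match.arg(missing_policy)
  rxn_ids <- model$reactions$id
  scores <- rep(NA_real_, length(rxn_ids))
  names(scores) <- rxn_ids
  for (i in seq_along(rxn_ids)) {
    rule <- model$reactions$gpr[i]
    node <- tryCatch(parse_gpr(rule), error = function(e) {
      stop("reaction ", rxn_ids[i], ": ", conditionMessage(e), call. = FALSE)
    })
    if (is.null(node)) next
    scores[i] <- tryCatch(
      evaluate_gpr(node, scaled$values, missing_policy = missing_policy),
      error = function(e) {
        stop("reaction ", rxn_ids[i], ": ", conditionMessage(e), call. = FALSE)
      })
  }
  structure(list(scores = scores, delta = scaled$delta),
            class = "reaction_activity")
}

#' Impose expression-derived flux bounds (the E-Flux step)
#'
#' Replaces the bounds of every scored reaction by its activity score b:
#' irreversible reactions get `(0, b)`, reversible reactions get `(-b, +b)`.
#' Reactions without a GPR keep their original bounds. Exchange
#' pseudo-reactions are exempt by default (their bounds encode measured
#' uptake/secretion limits, and they carry no genes in standard models), as
#' is the objective (biomass) reaction. A score of zero blocks the reaction.
#'
#' If a score falls below a positive lower bound of an irreversible reaction
#' (e.g. an ATP maintenance requirement), the bounds are tightened to the
#' score with a warning; any resulting infeasibility is reported by the
#' solver, not here.
#'
#' @param model a `metabolic_model`.
#' @param activity a `reaction_activity` computed on the same model.
#' @param constrain_exchanges also apply scores to exchange reactions that
#'   happen to carry a GPR (non-standard models). Default `FALSE`.
#' @return a new `metabolic_model` with updated bounds; the input is not
#'   modified. The mapping is idempotent for fixed `activity`.
#' @export
apply_eflux_bounds <- function(model, activity, constrain_exchanges = FALSE) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(activity, "reaction_activity"))
  scores <- activity$scores[model$reactions$id]
  exch <- is_exchange_reaction(model)
  rev <- is_reversible_reaction(model)
  out <- model
  for (i in seq_along(scores)) {
    b <- scores[i]
    if (is.na(b)) next
    if (exch[i] && !constrain_exchanges) next
    if (model$reactions$id[i] == model$objective_reaction_id) next
    if (rev[i]) {
      out$reactions$lower_bound[i] <- -b
      out$reactions$upper_bound[i] <- b
    } else {
      lb <- model$reactions$lower_bound[i]
      if (lb > 0 && b < lb) {
        warning("reaction ", model$reactions$id[i], ": score ", format(b),
                " below positive lower bound ", format(lb),
                "; bounds tightened to the score")
        out$reactions$lower_bound[i] <- b
        out$reactions$upper_bound[i] <- b
      } else {
        out$reactions$lower_bound[i] <- max(0, min(lb, b))
        out$reactions$upper_bound[i] <- b
      }
    }
  }
  out
}

#' Per-reaction bound-change report
#'
#' @param model the original model.
#' @param constrained the model returned by [apply_eflux_bounds()].
#' @param activity the `reaction_activity` used.
#' @return data.frame with columns `reaction`, `old_lb`, `old_ub`, `new_lb`,
#'   `new_ub`, `score` (NA where no GPR), suitable for TSV export.
#' @export
bounds_report <- function(model, constrained, activity) {
  data.frame(
    reaction = model$reactions$id,
    old_lb = model$reactions$lower_bound,
    old_ub = model$reactions$upper_bound,
    new_lb = constrained$reactions$lower_bound,
    new_ub = constrained$reactions$upper_bound,
    score = unname(activity$scores[model$reactions$id]),
    stringsAsFactors = FALSE
  )
}
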