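#' Construct a genome-scale metabolic model
#'
#' The central container of the package: a stoichiometric reconstruction with
#' flux bounds, gene-protein-reaction (GPR) rule strings and a biomass
#' (objective) reaction. Models are usually obtained from
#' [load_sbml_model()], [load_json_model()] or [generate_toy_model()]; this
#' constructor is exported for programmatic model building.
#'
#' @param metabolites data.frame with columns `id` and `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`, `upper_bound`
#'   and `gpr` (the raw GPR rule string, `""` for none). Bounds are fluxes in
#'   mmol gDW^-1 h^-1 (the biomass flux is in h^-1).
#' @param stoich named list, one entry per reaction id, each a named numeric
#'   vector of stoichiometric coefficients (negative = consumed,
#'   positive = produced) keyed by metabolite id.
#' @param objective_reaction_id id of the reaction maximized by FBA,
#'   conventionally the biomass synthesis reaction.
#' @param id optional model identifier.
#'
#' @return An object of class `metabolic_model`: a list with elements
#'   `metabolites`, `reactions`, `stoich`, `genes` (the union of all GPR
#'   leaves, derived by parsing the rules), `objective_reaction_id` and `id`.
#' @seealso [validate_model()], [stoichiometric_matrix()]
#' @export
metabolic_model <- function(metabolites, reactions, stoich,
                            objective_reaction_id, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  if (is.null(genes)) genes <- character(0)
  model <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      stoich = stoich[reactions$id],
      genes = genes,
      objective_reaction_id = objective_reaction_id,
      id = id
    ),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks that metabolite and reaction ids are unique and non-empty, that
#' every bound pair satisfies `lower_bound <= upper_bound`, that every
#' stoichiometry entry references a declared metabolite, that the objective
#' reaction exists, and that the gene set equals the union of GPR leaves.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly; errors describe the first violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (any(!nzchar(met_ids)) || anyDuplicated(met_ids))
    stop("metabolite ids must be non-empty and unique")
  if (any(!nzchar(rxn_ids)) || anyDuplicated(rxn_ids))
    stop("reaction ids must be non-empty and unique")
  bad <- model$reactions$lower_bound > model$reactions$upper_bound
  if (any(bad))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rxn_ids[bad], collapse = ", "))
  if (!setequal(names(model$stoich), rxn_ids))
    stop("stoich entries must match reaction ids exactly")
  for (rid in rxn_ids) {
    st <- model$stoich[[rid]]
    if (length(st) == 0)
      stop("reaction ", rid, " has an empty stoichiometry")
    unknown <- setdiff(names(st), met_ids)
    if (length(unknown))
      stop("reaction ", rid, " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!model$objective_reaction_id %in% rxn_ids)
    stop("objective reaction '", model$objective_reaction_id,
         "' is not in the model")
  leaves <- sort(unique(unlist(lapply(model$reactions$gpr, gpr_genes))))
  if (is.null(leaves)) leaves <- character(0)
  if (!identical(model$genes, leaves))
    stop("model gene set does not equal the union of GPR leaves")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   genes: ", length(x$genes), "\n", sep = "")
  cat("  exchanges: ", sum(is_exchange_reaction(x)),
      "   objective: ", x$objective_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Identify exchange reactions
#'
#' An exchange (boundary) pseudo-reaction is detected structurally: it has
#' exactly one metabolite in its stoichiometry. Id prefixes such as `"EX_"`
#' are conventions, never the rule.
#'
#' @param model a `metabolic_model`.
#' @return logical vector along `model$reactions`.
#' @export
is_exchange_reaction <- function(model) {
  lengths(model$stoich) == 1L
}

#' Identify reversible reactions
#'
#' A reaction is reversible iff its bounds straddle zero
#' (`lower_bound < 0` and `upper_bound > 0`). Reactions whose bounds were
#' curated to `[0, ub]` are treated as irreversible regardless of any
#' reversibility flag in the source file.
#'
#' @param model a `metabolic_model`.
#' @return logical vector along `model$reactions`.
#' @export
is_reversible_reaction <- function(model) {
  model$reactions$lower_bound < 0 & model$reactions$upper_bound > 0
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix S (metabolites x reactions), `S[i, j]` the
#'   coefficient of metabolite i in reaction j, zero where absent. Row and
#'   column names are metabolite and reaction ids; column order follows
#'   `model$reactions`.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    st <- model$stoich[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Set reaction bounds
#'
#' @param model a `metabolic_model`.
#' @param reaction_id a reaction id.
#' @param lower,upper new bounds; `NA` keeps the current value.
#' @return a modified copy of the model.
#' @export
set_bounds <- function(model, reaction_id, lower = NA, upper = NA) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id)
  if (!is.na(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.na(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i])
    stop("lower_bound > upper_bound for ", reaction_id)
  model
}
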