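#' Generate a small analytically solvable toy metabolic model
#'
#' Builds a linear pathway `substrate_ext -> M1 -> ... -> biomass` with an
#' uptake exchange, optional secretion branches (overflow products such as
#' acetate), and GPR rules assigned per pattern. The default 2-step chain is
#' the 4-reaction model (exchange `EX_A`, transport `T_A`, conversion `R1`,
#' sink `BIOMASS`) used across the test-suite.
#'
#' For the plain chain the FBA optimum has a closed form: growth equals
#' `min(uptake_limit, min over chain reaction scores)`, since branches are
#' optional (zero lower bound) and every chain step must carry the full
#' flux. The chain reaction ids are attached as attribute
#' `chain_reactions` for oracle use.
#'
#' @param n_chain number of chain steps (reactions between the external
#'   substrate and biomass), at least 2.
#' @param branches optional list of `c(at, len)` pairs: a branch of `len`
#'   reactions leaving the chain at metabolite `at` (1-based, before
#'   biomass) ending in a secretion exchange.
#' @param reversible_fraction fraction of internal chain steps made
#'   reversible (lower bound -1000), drawn per seed.
#' @param uptake_limit substrate uptake bound (mmol gDW^-1 h^-1),
#'   default 10.
#' @param gpr_pattern GPR shape for internal chain steps: `"single"` one
#'   gene, `"and-pair"` a two-gene complex, `"or-pair"` two isozymes,
#'   `"mixed"` a random mix (per seed). The transport step always has the
#'   single gene `gT`.
#' @param maintenance_flux optional positive lower bound on a GPR-less
#'   maintenance reaction draining M1 (models non-growth ATP demand); with
#'   it, a PC of 0 makes the model infeasible. Default 0 (no maintenance
#'   reaction).
#' @param seed integer seed; generation is deterministic per seed.
#' @return a `metabolic_model` (validated, feasible at large PC).
#' @export
generate_toy_model <- function(n_chain = 2, branches = NULL,
                               reversible_fraction = 0, uptake_limit = 10,
                               gpr_pattern = c("single", "and-pair",
                                               "or-pair", "mixed"),
                               maintenance_flux = 0, seed = 1L) {
  gpr_pattern <- match.arg(gpr_pattern)
  if (n_chain < 2) stop("n_chain must be at least 2")
  if (reversible_fraction < 0 || reversible_fraction > 1)
    stop("reversible_fraction must be in [0, 1]")
  if (uptake_limit <= 0) stop("uptake_limit must be positive")
  set.seed(as.integer(seed))

  mets <- data.frame(id = c("A_ext", paste0("M", seq_len(n_chain))),
                     compartment = c("e", rep("c", n_chain)),
                     stringsAsFactors = FALSE)
  rxn <- list()
  st <- list()
  add <- function(id, stoich, lb, ub, gpr = "") {
    rxn[[length(rxn) + 1L]] <<- data.frame(
      id = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
      stringsAsFactors = FALSE)
    st[[id]] <<- stoich
  }
  pattern_for <- function(i) {
    p <- if (gpr_pattern == "mixed")
      sample(c("single", "and-pair", "or-pair"), 1L) else gpr_pattern
    switch(p,
      single = paste0("g", i),
      `and-pair` = paste0("g", i, "a and g", i, "b"),
      `or-pair` = paste0("g", i, "a or g", i, "b"))
  }

  add("EX_A", c(A_ext = -1), -uptake_limit, 1000)
  add("T_A", c(A_ext = -1, M1 = 1), 0, 1000, gpr = "gT")
  if (n_chain > 1) {
    for (i in seq_len(n_chain - 1)) {
      lb <- if (stats::runif(1) < reversible_fraction) -1000 else 0
      add(paste0("R", i),
          stats::setNames(c(-1, 1), paste0("M", c(i, i + 1))),
          lb, 1000, gpr = pattern_for(i))
    }
  }
  if (maintenance_flux > 0) {
    add("MAINT", c(M1 = -1), maintenance_flux, 1000)
  }
  if (length(branches)) {
    for (k in seq_along(branches)) {
      br <- branches[[k]]
      at <- br[[1]]; len <- br[[2]]
      if (at < 1 || at >= n_chain) stop("branch point must be in [1, n_chain)")
      if (len < 1) stop("branch length must be at least 1")
      prev <- paste0("M", at)
      for (j in seq_len(len)) {
        bm <- paste0("P", k, "_", j)
        mets <- rbind(mets, data.frame(id = bm, compartment = "c",
                                       stringsAsFactors = FALSE))
        add(paste0("B", k, "_", j),
            stats::setNames(c(-1, 1), c(prev, bm)),
            0, 1000, gpr = paste0("gb", k, "_", j))
        prev <- bm
      }
      add(paste0("EX_P", k), stats::setNames(-1, prev), 0, 1000)
    }
  }
  add("BIOMASS", stats::setNames(-1, paste0("M", n_chain)), 0, 1000)

  model <- metabolic_model(mets, do.call(rbind, rxn), st,
                           objective_reaction_id = "BIOMASS",
                           id = sprintf("toy_chain_n%d_seed%d", n_chain, seed))
  attr(model, "chain_reactions") <-
    c("T_A", if (n_chain > 1) paste0("R", seq_len(n_chain - 1)))
  attr(model, "uptake_limit") <- uptake_limit
  model
}

#' Generate a synthetic expression profile for a model
#'
#' Draws log-normal expression values for every model gene: a fraction
#' `active_fraction` of genes around a high mean (100 units) and the rest
#' around a low mean (1 unit), each with coefficient of variation
#' `noise_cv`. Log-normal is a generic positive-valued model for expression
#' levels; `noise_cv = 0` gives the two exact levels.
#'
#' @param model a `metabolic_model` with at least one gene.
#' @param active_fraction fraction of genes drawn from the high level,
#'   default 0.8.
#' @param noise_cv coefficient of variation of each level, default 0.2.
#' @param seed integer seed; deterministic per seed.
#' @param high_mean,low_mean expression means of the active and inactive
#'   groups (arbitrary platform units).
#' @return an `expression_profile` with all values positive.
#' @export
generate_synthetic_expression <- function(model, active_fraction = 0.8,
                                          noise_cv = 0.2, seed = 1L,
                                          high_mean = 100, low_mean = 1) {
  stopifnot(inherits(model, "metabolic_model"))
  genes <- model$genes
  if (!length(genes)) stop("model has no genes")
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must be in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  set.seed(as.integer(seed))
  n <- length(genes)
  n_active <- round(active_fraction * n)
  active <- rep(FALSE, n)
  if (n_active > 0) active[sample.int(n, n_active)] <- TRUE
  means <- ifelse(active, high_mean, low_mean)
  if (noise_cv == 0) {
    vals <- means
  } else {
    sdlog <- sqrt(log(1 + noise_cv^2))
    meanlog <- log(means) - sdlog^2 / 2
    vals <- stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
  }
  names(vals) <- genes
  expression_profile(vals, condition = sprintf("synthetic_seed%d", seed))
}

#' Write fixture files for a model and expression profile
#'
#' Emits the model in both SBML and COBRA-style JSON (so loader parity is
#' continuously exercised) plus the expression profile as a TSV with
#' columns `gene` and `value`.
#'
#' @param model a `metabolic_model`.
#' @param profile an `expression_profile`, or `NULL` to skip.
#' @param dir target directory (created if needed).
#' @param basename file stem, default the model id.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(model, profile = NULL, dir,
                           basename = model$id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    sbml = file.path(dir, paste0(basename, ".xml")),
    json = file.path(dir, paste0(basename, ".json"))
  )
  write_sbml_model(model, paths[["sbml"]])
  write_json_model(model, paths[["json"]])
  if (!is.null(profile)) {
    p <- file.path(dir, paste0(basename, "_expression.tsv"))
    utils::write.table(
      data.frame(gene = names(profile$values),
                 value = unname(profile$values)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, expression = p)
  }
  invisible(paths)
}
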