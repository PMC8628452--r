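#' Construct an expression profile
#'
#' One condition's gene expression measurements in arbitrary (but
#' consistently pre-processed) platform units. Platform-specific
#' normalization (RMA, TPM, library-size correction, ...) is assumed to have
#' happened upstream; this container only holds the resulting non-negative
#' levels and their per-condition maximum `g_max`.
#'
#' @param values named non-negative numeric vector, gene id -> expression
#'   level g_i.
#' @param condition condition label.
#' @return an `expression_profile`: list with `condition`, `values`, `g_max`.
#' @export
expression_profile <- function(values, condition = "condition") {
  if (!length(values) || is.null(names(values)) || any(!nzchar(names(values))))
    stop("values must be a non-empty named numeric vector")
  if (anyDuplicated(names(values)))
    stop("duplicate gene ids in expression values")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  g_max <- max(values)
  if (g_max <= 0)
    stop("all expression values are zero; g_max must be positive")
  structure(list(condition = condition, values = values, g_max = g_max),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> ", x$condition, ": ", length(x$values),
      " genes, g_max = ", format(x$g_max), "\n", sep = "")
  invisible(x)
}

#' Read a per-condition expression table
#'
#' Reads a delimited text table (TSV or CSV, chosen from the file extension
#' unless `sep` is given) with a header row into an [expression_profile()].
#' Rows with a duplicated gene id are collapsed by taking the maximum value
#' (the probe-set rule: the strongest signal stands for the gene), with a
#' message naming how many were collapsed.
#'
#' @param path file path.
#' @param gene_column,value_column column names holding gene ids and
#'   expression levels.
#' @param condition condition label, default the file name.
#' @param sep field separator; `NULL` picks `","` for `.csv`, tab otherwise.
#' @return an `expression_profile`.
#' @export
read_expression_table <- function(path, gene_column = "gene",
                                  value_column = "value",
                                  condition = basename(path), sep = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  for (col in c(gene_column, value_column)) {
    if (!col %in% names(tab))
      stop("column '", col, "' not found in ", path,
           " (columns: ", paste(names(tab), collapse = ", "), ")")
  }
  genes <- as.character(tab[[gene_column]])
  vals <- suppressWarnings(as.numeric(tab[[value_column]]))
  if (any(is.na(vals)))
    stop("non-numeric expression value at row(s) ",
         paste(utils::head(which(is.na(vals)), 5), collapse = ", "),
         " of ", path)
  neg <- which(vals < 0)
  if (length(neg))
    stop("negative expression value at row ", neg[1], " (gene ",
         genes[neg[1]], ") of ", path)
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    collapsed <- tapply(vals, genes, max)
    vals <- as.numeric(collapsed)
    names(vals) <- names(collapsed)
    message("collapsed ", n_dup, " duplicate gene row(s) by max in ", path)
  } else {
    names(vals) <- genes
  }
  expression_profile(vals, condition = condition)
}

#' Translate gene identifiers of a profile
#'
#' Applies a two-column identifier map (from-id, to-id; header optional via
#' `header`) so expression gene ids match the model's gene namespace.
#' Unmapped genes are kept under their original id; several source ids
#' mapping to one target are collapsed by max.
#'
#' @param profile an `expression_profile`.
#' @param map a data.frame with two columns, or a path to a two-column TSV.
#' @param header logical, whether a file `map` has a header row.
#' @return a remapped `expression_profile`.
#' @export
apply_gene_map <- function(profile, map, header = TRUE) {
  stopifnot(inherits(profile, "expression_profile"))
  if (is.character(map)) {
    map <- utils::read.table(map, header = header, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  if (ncol(map) < 2) stop("gene map needs two columns (from, to)")
  from <- as.character(map[[1]]); to <- as.character(map[[2]])
  ids <- names(profile$values)
  hit <- match(ids, from)
  new_ids <- ifelse(is.na(hit), ids, to[hit])
  collapsed <- tapply(profile$values, new_ids, max)
  vals <- as.numeric(collapsed); names(vals) <- names(collapsed)
  expression_profile(vals, condition = profile$condition)
}

#' Max-normalize an expression profile
#'
#' Divides every expression level by the per-condition maximum `g_max`, so
#' results lie in `[0, 1]` with at least one gene at exactly 1. With a unit
#' proportionality constant this is the whole of the classic E-Flux scaling.
#'
#' The maximum is taken over all genes in this profile (per condition), not
#' over a multi-condition dataset; see [scale_expression()]'s `g_max`
#' argument for a global-maximum mode.
#'
#' @param profile an `expression_profile`.
#' @return named numeric vector of normalized levels in `[0, 1]`.
#' @export
normalize_expression <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  if (profile$g_max <= 0) stop("g_max must be positive to normalize")
  profile$values / profile$g_max
}

#' Scale a normalized profile by the proportionality constant
#'
#' Computes `g_norm_i = (g_i / g_max) * delta` for every gene: the
#' max-normalized level multiplied by a single global proportionality
#' constant (PC) `delta`, shared by all genes. `delta = 1` reduces exactly to
#' plain E-Flux; `delta = 0` blocks every GPR-associated reaction.
#'
#' @param profile an `expression_profile`.
#' @param delta the proportionality constant, a non-negative scalar in flux
#'   units (mmol gDW^-1 h^-1 per unit normalized expression).
#' @param g_max optional override of the normalizing maximum (e.g. a global
#'   maximum over several conditions); default the profile's own `g_max`.
#' @return a `scaled_profile`: list with `condition`, `values`
#'   (gene id -> g_norm_i) and `delta`.
#' @export
scale_expression <- function(profile, delta, g_max = profile$g_max) {
  stopifnot(inherits(profile, "expression_profile"))
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("delta must be a single non-negative number")
  if (g_max <= 0) stop("g_max must be positive")
  structure(
    list(condition = profile$condition,
         values = profile$values / g_max * delta,
         delta = delta),
    class = "scaled_profile"
  )
}

#' @export
print.scaled_profile <- function(x, ...) {
  cat("<scaled_profile> ", x$condition, ": ", length(x$values),
      " genes, delta = ", format(x$delta), "\n", sep = "")
  invisible(x)
}
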