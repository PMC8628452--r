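#' Parse a gene-protein-reaction rule
#'
#' Parses a Boolean GPR string (genes combined with case-insensitive `and` /
#' `or`, parentheses allowed) into an AST. `and` binds tighter than `or`,
#' matching the usual COBRA convention, so `"g1 and g2 or g3"` parses as
#' `OR(AND(g1, g2), g3)`. Any token that is not a keyword or parenthesis is
#' taken as a gene identifier; no gene registry is consulted at parse time.
#'
#' @param rule the GPR string; `""`, `NA` or whitespace-only means
#'   "no rule" and returns `NULL`.
#' @return a `gpr_node` (see Details) or `NULL` for a blank rule.
#'
#' @details A `gpr_node` is a list with `kind` one of `"GENE"`, `"AND"`,
#'   `"OR"`; GENE nodes carry `gene_id`, AND/OR nodes carry `children`
#'   (at least two; same-kind children are flattened). Malformed input
#'   (unbalanced parentheses, dangling operators) raises an error reporting
#'   the 1-based character offset.
#' @examples
#' parse_gpr("b0001 and (b0002 or b0003)")
#' @export
parse_gpr <- function(rule) {
  if (length(rule) != 1L || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$paren_stack <- integer(0)
  node <- gpr_parse_or(st, rule)
  if (st$pos <= nrow(st$toks)) {
    stop("GPR parse error at offset ", st$toks$offset[st$pos],
         ": unexpected '", st$toks$text[st$pos], "' in rule \"", rule, "\"")
  }
  node
}

# Tokenizer: parentheses, keywords and gene identifiers, with 1-based offsets.
gpr_tokenize <- function(rule) {
  chars <- strsplit(rule, "", fixed = TRUE)[[1]]
  text <- character(0); type <- character(0); offset <- integer(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      text <- c(text, ch); type <- c(type, ch); offset <- c(offset, i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    type <- c(type, if (lw %in% c("and", "or")) lw else "gene")
    text <- c(text, word); offset <- c(offset, i)
    i <- j
  }
  data.frame(text = text, type = type, offset = offset,
             stringsAsFactors = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

# or-expression := and-expression ("or" and-expression)*
gpr_parse_or <- function(st, rule) {
  children <- list(gpr_parse_and(st, rule))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st, rule)))
  }
  gpr_combine("OR", children)
}

# and-expression := factor ("and" factor)*
gpr_parse_and <- function(st, rule) {
  children <- list(gpr_parse_factor(st, rule))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_factor(st, rule)))
  }
  gpr_combine("AND", children)
}

# factor := GENE | "(" or-expression ")"
gpr_parse_factor <- function(st, rule) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    if (length(st$paren_stack)) {
      stop("GPR parse error at offset ",
           st$paren_stack[length(st$paren_stack)],
           ": unclosed parenthesis in rule \"", rule, "\"")
    }
    stop("GPR parse error at offset ", nchar(rule) + 1L,
         ": unexpected end of rule \"", rule, "\"")
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(structure(list(kind = "GENE", gene_id = tk$text),
                     class = "gpr_node"))
  }
  if (tk$type == "(") {
    open_at <- tk$offset
    st$paren_stack <- c(st$paren_stack, open_at)
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st, rule)
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != ")") {
      stop("GPR parse error at offset ", open_at,
           ": unclosed parenthesis in rule \"", rule, "\"")
    }
    st$paren_stack <- st$paren_stack[-length(st$paren_stack)]
    st$pos <- st$pos + 1L
    return(node)
  }
  stop("GPR parse error at offset ", tk$offset, ": unexpected '", tk$text,
       "' in rule \"", rule, "\"")
}

# Collapse single-child wrappers, flatten nested nodes of the same kind.
gpr_combine <- function(kind, children) {
  if (length(children) == 1L) return(children[[1]])
  flat <- list()
  for (ch in children) {
    if (!inherits(ch, "gpr_node")) stop("internal GPR parser error")
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr_node")
}

#' Genes referenced by a GPR rule
#'
#' @param rule a GPR string or a parsed `gpr_node` (or `NULL`).
#' @return character vector of distinct gene ids (empty for a blank rule).
#' @export
gpr_genes <- function(rule) {
  node <- if (inherits(rule, "gpr_node")) rule else parse_gpr(rule)
  if (is.null(node)) return(character(0))
  walk <- function(nd) {
    if (nd$kind == "GENE") return(nd$gene_id)
    unlist(lapply(nd$children, walk))
  }
  unique(walk(node))
}

#' Evaluate a GPR rule over gene expression values
#'
#' Implements the E-Flux semantics: an `OR` (isozymes) sums the scores of its
#' children, an `AND` (complex formation) takes their minimum, a gene leaf
#' returns its expression value. Both operations are positively homogeneous,
#' which is the algebraic fact that lets a single global proportionality
#' constant act as one multiplier on every reaction score.
#'
#' @param node a `gpr_node` from [parse_gpr()] (or a rule string, parsed on
#'   the fly). `NULL` (blank rule) returns `NA_real_`.
#' @param values named non-negative numeric vector, gene id -> expression.
#' @param missing_policy what to do for a gene absent from `values`:
#'   `"max"` (default) substitutes the maximum of `values`, so an unmeasured
#'   gene never over-constrains its reaction; `"zero"` substitutes 0;
#'   `"error"` fails naming the gene.
#' @return a single non-negative number (or `NA_real_` for a blank rule).
#' @examples
#' evaluate_gpr(parse_gpr("g1 or g2"), c(g1 = 0.2, g2 = 0.3))   # 0.5
#' evaluate_gpr(parse_gpr("g1 and g2"), c(g1 = 0.2, g2 = 0.3))  # 0.2
#' @export
evaluate_gpr <- function(node, values,
                         missing_policy = c("max", "zero", "error")) {
  missing_policy <- match.arg(missing_policy)
  if (is.character(node)) node <- parse_gpr(node)
  if (is.null(node)) return(NA_real_)
  if (length(values) && any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  substitute_value <- switch(missing_policy,
    max = if (length(values)) max(values) else 0,
    zero = 0,
    error = NA_real_
  )
  walk <- function(nd) {
    if (nd$kind == "GENE") {
      v <- values[nd$gene_id]
      if (is.na(v) || is.null(names(v))) {
        if (missing_policy == "error")
          stop("gene '", nd$gene_id, "' has no expression value")
        return(unname(substitute_value))
      }
      return(unname(v))
    }
    scores <- vapply(nd$children, walk, numeric(1))
    if (nd$kind == "AND") min(scores) else sum(scores)
  }
  walk(node)
}

#' Render a GPR AST back to a rule string
#'
#' Produces a fully parenthesized infix string logically equivalent to the
#' parsed input; `gpr_to_string(parse_gpr(x))` re-parses to the same AST.
#'
#' @param node a `gpr_node` or `NULL`.
#' @return a string (`""` for `NULL`).
#' @export
gpr_to_string <- function(node) {
  if (is.null(node)) return("")
  if (node$kind == "GENE") return(node$gene_id)
  op <- if (node$kind == "AND") " and " else " or "
  parts <- vapply(node$children, function(ch) {
    s <- gpr_to_string(ch)
    if (ch$kind == "GENE") s else paste0("(", s, ")")
  }, character(1))
  paste(parts, collapse = op)
}

#' @export
print.gpr_node <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}
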