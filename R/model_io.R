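# Model readers/writers. SBML support targets the two dialects genome-scale
# reconstructions actually circulate in: Level 3 with the fbc package
# (flux bounds as parameter references, gene associations as nested
# fbc:and/fbc:or trees) and the older COBRA Level 2 dialect (bounds as
# kineticLaw parameters LOWER_BOUND/UPPER_BOUND, GPRs in a notes field
# "GENE_ASSOCIATION: ..."). XPath is namespace-agnostic (local-name()) so
# prefix variations across exporters do not matter.

DEFAULT_UB <- 1000
DEFAULT_LB_REV <- -1000

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# namespace-agnostic node search relative to `node`
xfind <- function(node, name, prefix = ".//") {
  xml2::xml_find_all(node, sprintf("%s*[local-name()='%s']", prefix, name))
}

# attribute lookup tolerant of namespace prefixes ("fbc:lowerFluxBound")
xattr <- function(node, name) {
  attrs <- xml2::xml_attrs(node)
  hit <- which(names(attrs) == name |
                 endsWith(names(attrs), paste0(":", name)))
  if (!length(hit)) NA_character_ else unname(attrs[hit[1]])
}

#' Load a genome-scale model from SBML
#'
#' Reads SBML Level 2 or 3. Flux bounds are taken from fbc
#' `lowerFluxBound`/`upperFluxBound` parameter references when present,
#' otherwise from COBRA-style kineticLaw parameters `LOWER_BOUND` /
#' `UPPER_BOUND`; reactions with no encoded bounds default to
#' `(0, 1000)` when irreversible and `(-1000, 1000)` when reversible (per
#' the SBML `reversible` attribute), with a warning. GPR strings come from
#' the fbc gene-product association tree or from a
#' `GENE_ASSOCIATION:` notes line and are stored verbatim for lazy parsing.
#' Boundary-condition species (the `_b` pool metabolites of older COBRA
#' exports) are dropped, which leaves exchange reactions with their single
#' internal metabolite.
#'
#' @param path SBML file path.
#' @return a validated `metabolic_model`.
#' @export
load_sbml_model <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  model_node <- xfind(doc, "model")
  if (!length(model_node)) stop("malformed SBML: no <model> element in ", path)
  model_node <- model_node[[1]]
  model_id <- xattr(model_node, "id")
  if (is.na(model_id)) model_id <- basename(path)

  species <- xfind(model_node, "species")
  sp_id <- vapply(species, function(s) xattr(s, "id"), character(1))
  sp_comp <- vapply(species, function(s) {
    cc <- xattr(s, "compartment"); if (is.na(cc)) "" else cc
  }, character(1))
  sp_boundary <- vapply(species, function(s) {
    identical(tolower(xattr(s, "boundaryCondition")), "true")
  }, logical(1))
  if (!length(sp_id)) stop("malformed SBML: no species in ", path)
  mets <- data.frame(id = sp_id[!sp_boundary],
                     compartment = sp_comp[!sp_boundary],
                     stringsAsFactors = FALSE)
  boundary_ids <- sp_id[sp_boundary]

  # global parameters (fbc bound values)
  params <- new.env(parent = emptyenv())
  for (p in xfind(model_node, "parameter")) {
    pid <- xattr(p, "id")
    pval <- suppressWarnings(as.numeric(xattr(p, "value")))
    if (!is.na(pid)) assign(pid, pval, envir = params)
  }
  # fbc gene products: sbml id -> label
  gene_label <- new.env(parent = emptyenv())
  for (g in xfind(model_node, "geneProduct")) {
    gid <- xattr(g, "id")
    lab <- xattr(g, "label")
    if (is.na(lab)) lab <- gid
    if (!is.na(gid)) assign(gid, lab, envir = gene_label)
  }

  rxn_nodes <- xfind(model_node, "reaction")
  if (!length(rxn_nodes)) stop("malformed SBML: no reactions in ", path)
  n <- length(rxn_nodes)
  ids <- character(n); lbs <- numeric(n); ubs <- numeric(n); gprs <- character(n)
  st <- list()
  obj_from_kinetic <- character(0)
  defaulted <- character(0)

  for (k in seq_len(n)) {
    r <- rxn_nodes[[k]]
    rid <- xattr(r, "id")
    if (is.na(rid)) stop("malformed SBML: reaction without id in ", path)
    ids[k] <- rid
    reversible <- !identical(tolower(xattr(r, "reversible")), "false")

    stoich <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      side_nodes <- xfind(r, side, prefix = "./")
      if (!length(side_nodes)) next
      sign <- if (side == "listOfReactants") -1 else 1
      for (sr in xfind(side_nodes[[1]], "speciesReference", prefix = "./")) {
        sp <- xattr(sr, "species")
        if (is.na(sp))
          stop("malformed SBML: speciesReference without species in reaction ", rid)
        if (sp %in% boundary_ids) next
        coef <- suppressWarnings(as.numeric(xattr(sr, "stoichiometry")))
        if (is.na(coef)) coef <- 1
        stoich[sp] <- (if (sp %in% names(stoich)) stoich[[sp]] else 0) + sign * coef
      }
    }
    stoich <- stoich[stoich != 0]
    if (!length(stoich))
      stop("malformed SBML: reaction ", rid,
           " has no (non-boundary) metabolites")
    st[[rid]] <- stoich

    # bounds: fbc parameter references, then kineticLaw, then defaults
    lb <- NA_real_; ub <- NA_real_
    lb_ref <- xattr(r, "lowerFluxBound")
    ub_ref <- xattr(r, "upperFluxBound")
    if (!is.na(lb_ref) && exists(lb_ref, envir = params))
      lb <- get(lb_ref, envir = params)
    if (!is.na(ub_ref) && exists(ub_ref, envir = params))
      ub <- get(ub_ref, envir = params)
    kl <- xfind(r, "kineticLaw", prefix = "./")
    if (length(kl)) {
      for (p in xfind(kl[[1]], "parameter")) {
        pid <- xattr(p, "id"); if (is.na(pid)) pid <- xattr(p, "name")
        pval <- suppressWarnings(as.numeric(xattr(p, "value")))
        if (identical(pid, "LOWER_BOUND") && is.na(lb)) lb <- pval
        if (identical(pid, "UPPER_BOUND") && is.na(ub)) ub <- pval
        if (identical(pid, "OBJECTIVE_COEFFICIENT") && !is.na(pval) && pval != 0)
          obj_from_kinetic <- c(obj_from_kinetic, rid)
      }
    }
    if (is.na(lb) || is.na(ub)) {
      defaulted <- c(defaulted, rid)
      if (is.na(lb)) lb <- if (reversible) DEFAULT_LB_REV else 0
      if (is.na(ub)) ub <- DEFAULT_UB
    }
    lbs[k] <- lb; ubs[k] <- ub

    # GPR: the verbatim notes GENE_ASSOCIATION line when present (so rule
    # strings survive round trips unchanged), else rendered from the fbc
    # association tree
    gpr <- ""
    notes <- xfind(r, "notes", prefix = "./")
    if (length(notes)) {
      txt <- xml2::xml_text(notes[[1]])
      m <- regmatches(txt, regexec("GENE[ _]ASSOCIATION:\\s*([^\n\r]*)", txt))[[1]]
      if (length(m) == 2) gpr <- trimws(m[2])
    }
    if (!nzchar(gpr)) {
      assoc <- xfind(r, "geneProductAssociation", prefix = "./")
      if (length(assoc)) {
        kids <- xml2::xml_children(assoc[[1]])
        if (length(kids))
          gpr <- fbc_assoc_to_string(kids[[1]], gene_label)
      }
    }
    gprs[k] <- gpr
  }
  if (length(defaulted))
    warning("no bounds encoded for ", length(defaulted),
            " reaction(s); defaults applied (e.g. ",
            paste(utils::head(defaulted, 3), collapse = ", "), ")")

  objective <- sbml_objective(model_node, obj_from_kinetic, path)
  metabolic_model(
    mets,
    data.frame(id = ids, lower_bound = lbs, upper_bound = ubs, gpr = gprs,
               stringsAsFactors = FALSE),
    st, objective_reaction_id = objective, id = model_id)
}

# fbc objective if present, else the kineticLaw OBJECTIVE_COEFFICIENT hit
sbml_objective <- function(model_node, obj_from_kinetic, path) {
  fo <- xfind(model_node, "fluxObjective")
  if (length(fo)) {
    rid <- xattr(fo[[1]], "reaction")
    if (!is.na(rid)) return(rid)
  }
  if (length(obj_from_kinetic)) return(obj_from_kinetic[1])
  stop("no objective reaction encoded in ", path,
       " (neither fbc objective nor OBJECTIVE_COEFFICIENT)")
}

# nested fbc:and / fbc:or / fbc:geneProductRef -> GPR rule string
fbc_assoc_to_string <- function(node, gene_label) {
  name <- xml2::xml_name(node)  # xml_name strips the namespace prefix
  if (name == "geneProductRef") {
    ref <- xattr(node, "geneProduct")
    if (is.na(ref)) stop("malformed SBML: geneProductRef without geneProduct")
    lab <- if (exists(ref, envir = gene_label)) get(ref, envir = gene_label) else ref
    return(lab)
  }
  if (name %in% c("and", "or")) {
    parts <- vapply(xml2::xml_children(node), fbc_assoc_to_string,
                    character(1), gene_label = gene_label)
    op <- if (name == "and") " and " else " or "
    return(paste0("(", paste(parts, collapse = op), ")"))
  }
  stop("malformed SBML: unexpected element '", name,
       "' in gene association")
}

#' Load a genome-scale model from COBRA-style JSON
#'
#' Reads the COBRA JSON dialect (top-level `metabolites`, `reactions`,
#' `genes` arrays; per reaction `metabolites` map, `lower_bound`,
#' `upper_bound`, `gene_reaction_rule`, `objective_coefficient`). Missing
#' bounds default as in [load_sbml_model()] with a warning; a stoichiometry
#' entry referencing an undeclared metabolite is a parse error naming the
#' reaction.
#'
#' @param path JSON file path.
#' @return a validated `metabolic_model`; [load_sbml_model()] and this
#'   loader produce equal models for equivalent encodings.
#' @export
load_json_model <- function(path) {
  if (!file.exists(path)) stop("JSON model file not found: ", path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) {
                   stop("malformed JSON in ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  for (field in c("metabolites", "reactions")) {
    if (is.null(js[[field]]))
      stop("malformed model JSON: missing '", field, "' array in ", path)
  }
  mets <- data.frame(
    id = vapply(js$metabolites, function(m) as.character(m$id), character(1)),
    compartment = vapply(js$metabolites, function(m) {
      cc <- m$compartment; if (is.null(cc)) "" else as.character(cc)
    }, character(1)),
    stringsAsFactors = FALSE)

  n <- length(js$reactions)
  if (!n) stop("malformed model JSON: empty 'reactions' in ", path)
  ids <- character(n); lbs <- numeric(n); ubs <- numeric(n); gprs <- character(n)
  st <- list()
  objective <- character(0)
  defaulted <- character(0)
  for (k in seq_len(n)) {
    r <- js$reactions[[k]]
    if (is.null(r$id))
      stop("malformed model JSON: reactions[", k, "] has no 'id'")
    rid <- as.character(r$id)
    ids[k] <- rid
    if (is.null(r$metabolites) || !length(r$metabolites))
      stop("malformed model JSON: reactions[", k, "] ('", rid,
           "') has no 'metabolites' map")
    stoich <- vapply(r$metabolites, as.numeric, numeric(1))
    unknown <- setdiff(names(stoich), mets$id)
    if (length(unknown))
      stop("malformed model JSON: reaction '", rid,
           "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    st[[rid]] <- stoich
    reversible <- isTRUE(r$reversible)
    lb <- if (is.null(r$lower_bound)) NA_real_ else as.numeric(r$lower_bound)
    ub <- if (is.null(r$upper_bound)) NA_real_ else as.numeric(r$upper_bound)
    if (is.na(lb) || is.na(ub)) {
      defaulted <- c(defaulted, rid)
      if (is.na(lb)) lb <- if (reversible) DEFAULT_LB_REV else 0
      if (is.na(ub)) ub <- DEFAULT_UB
    }
    lbs[k] <- lb; ubs[k] <- ub
    gprs[k] <- if (is.null(r$gene_reaction_rule)) "" else
      as.character(r$gene_reaction_rule)
    oc <- r$objective_coefficient
    if (!is.null(oc) && as.numeric(oc) != 0) objective <- c(objective, rid)
  }
  if (length(defaulted))
    warning("no bounds encoded for ", length(defaulted),
            " reaction(s); defaults applied (e.g. ",
            paste(utils::head(defaulted, 3), collapse = ", "), ")")
  if (!length(objective))
    stop("malformed model JSON: no reaction with a non-zero ",
         "objective_coefficient in ", path)
  model_id <- if (!is.null(js$id)) as.character(js$id) else basename(path)
  metabolic_model(
    mets,
    data.frame(id = ids, lower_bound = lbs, upper_bound = ubs, gpr = gprs,
               stringsAsFactors = FALSE),
    st, objective_reaction_id = objective[1], id = model_id)
}

#' Write a model as COBRA-style JSON
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- lapply(seq_len(nrow(model$reactions)), function(k) {
    r <- model$reactions[k, ]
    list(
      id = r$id,
      metabolites = as.list(model$stoich[[r$id]]),
      lower_bound = r$lower_bound,
      upper_bound = r$upper_bound,
      gene_reaction_rule = r$gpr,
      objective_coefficient =
        if (r$id == model$objective_reaction_id) 1 else 0
    )
  })
  js <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(k) {
      list(id = model$metabolites$id[k],
           compartment = model$metabolites$compartment[k])
    }),
    reactions = rxns,
    genes = lapply(model$genes, function(g) list(id = g))
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

sbml_gene_id <- function(gene) {
  paste0("G_", gsub("[^A-Za-z0-9_]", "_", gene))
}

# GPR AST -> nested fbc association XML
fbc_assoc_xml <- function(node, indent) {
  pad <- strrep(" ", indent)
  if (node$kind == "GENE") {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   pad, sbml_gene_id(node$gene_id)))
  }
  tag <- if (node$kind == "AND") "fbc:and" else "fbc:or"
  inner <- vapply(node$children, fbc_assoc_xml, character(1),
                  indent = indent + 2)
  paste0(pad, "<", tag, " sboTerm=\"SBO:0000173\">\n",
         paste(inner, collapse = "\n"), "\n", pad, "</", tag, ">")
}

#' Write a model as SBML Level 3 with fbc flux bounds
#'
#' Emits SBML L3V1 with the fbc extension: bounds as shared parameters
#' referenced from each reaction, gene products with labels, the gene
#' association both as an fbc tree and as a `GENE_ASSOCIATION:` notes line,
#' and the biomass objective as the active fbc objective.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  num <- function(x) sprintf("%.12g", x)
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)), num(bounds))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', xml_escape(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            unique(model$metabolites$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'),
            xml_escape(model$metabolites$id),
            xml_escape(model$metabolites$compartment)),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            unname(pid), names(pid)),
    '    </listOfParameters>'
  )
  if (length(model$genes)) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
               sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       sbml_gene_id(model$genes), xml_escape(model$genes)),
               '    </fbc:listOfGeneProducts>')
  }
  lines <- c(lines, '    <listOfReactions>')
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    st <- model$stoich[[r$id]]
    reactants <- st[st < 0]; products <- st[st > 0]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      xml_escape(r$id),
      if (r$lower_bound < 0) "true" else "false",
      pid[[num(r$lower_bound)]], pid[[num(r$upper_bound)]]))
    if (nzchar(r$gpr)) {
      lines <- c(lines,
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf('          <p>GENE_ASSOCIATION: %s</p>', xml_escape(r$gpr)),
        '        </body></notes>',
        '        <fbc:geneProductAssociation>',
        fbc_assoc_xml(parse_gpr(r$gpr), 10),
        '        </fbc:geneProductAssociation>')
    }
    if (length(reactants)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                xml_escape(names(reactants)), num(abs(reactants))),
        '        </listOfReactants>')
    }
    if (length(products)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                xml_escape(names(products)), num(products)),
        '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                   'fbc:coefficient="1"/>'),
            xml_escape(model$objective_reaction_id)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
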