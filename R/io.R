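# Model readers and writers.
#
# Two formats: a flat JSON dialect compatible with the community GEM
# JSON schema (metabolites/reactions/genes arrays, bounds and
# gene_reaction_rule per reaction, objective_coefficient marking the
# biomass reaction), and SBML Level 3 with the fbc flux-bound
# conventions (species charge/formula, parameter-backed reaction
# bounds, geneProductAssociation trees, subsystems in reaction notes).

#' Write a metabolic model to disk
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @param format `"json"` or `"sbml"`; `"auto"` (default) picks by file
#'   extension (`.json` vs `.xml`/`.sbml`).
#' @return `path`, invisibly.
#' @export
write_gem <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_path(path)
  validate_metabolic_model(model)
  switch(format,
         json = write_gem_json(model, path),
         sbml = write_gem_sbml(model, path))
  invisible(path)
}

#' Read a metabolic model from disk
#'
#' @param path Input file path.
#' @param format `"json"` or `"sbml"`; `"auto"` (default) picks by file
#'   extension.
#' @param extracellular Compartment tag of the extracellular space
#'   (default `"e"`).
#' @return A validated `metabolic_model`. Bounds absent from the file
#'   default to -1000/1000 mmol/gDW/h.
#' @export
read_gem <- function(path, format = c("auto", "json", "sbml"),
                     extracellular = "e") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- format_from_path(path)
  switch(format,
         json = read_gem_json(path, extracellular),
         sbml = read_gem_sbml(path, extracellular))
}

format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return("json")
  if (ext %in% c("xml", "sbml")) return("sbml")
  stop("cannot infer model format from extension '.", ext,
       "'; pass format explicitly", call. = FALSE)
}

# ---- JSON dialect -----------------------------------------------------

write_gem_json <- function(model, path) {
  st <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- st[[r$id]]
    list(id = r$id, name = r$name,
         metabolites = stats::setNames(as.list(s$coefficient), s$metabolite_id),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = r$gpr, subsystem = r$subsystem,
         objective_coefficient = if (r$id == model$objective_id) 1 else 0)
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment,
                formula = m$formula)
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  genes <- lapply(model$genes$id, function(g) list(id = g, name = g))
  comps <- unique(model$metabolites$compartment)
  obj <- list(id = model$name,
              compartments = stats::setNames(as.list(comps), comps),
              metabolites = mets, reactions = rxns, genes = genes,
              version = "1")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

read_gem_json <- function(path, extracellular) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("parse error in JSON model '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  for (field in c("metabolites", "reactions")) {
    if (is.null(obj[[field]])) {
      stop("parse error: JSON model lacks required element '", field, "'",
           call. = FALSE)
    }
  }
  mets <- dplyr::bind_rows(lapply(obj$metabolites, function(m) {
    tibble::tibble(id = m$id, name = m$name %||% m$id,
                   formula = m$formula %||% "",
                   charge = as.integer(m$charge %||% NA_integer_),
                   compartment = m$compartment %||%
                     stop("parse error: metabolite '", m$id,
                          "' lacks a compartment", call. = FALSE))
  }))
  rxns <- dplyr::bind_rows(lapply(obj$reactions, function(r) {
    tibble::tibble(id = r$id, name = r$name %||% r$id,
                   lower_bound = as.numeric(r$lower_bound %||% -DEFAULT_BOUND),
                   upper_bound = as.numeric(r$upper_bound %||% DEFAULT_BOUND),
                   subsystem = r$subsystem %||% "",
                   gpr = r$gene_reaction_rule %||% "")
  }))
  st <- dplyr::bind_rows(lapply(obj$reactions, function(r) {
    if (is.null(r$metabolites) || !length(r$metabolites)) {
      stop("parse error: reaction '", r$id, "' has empty stoichiometry",
           call. = FALSE)
    }
    tibble::tibble(reaction_id = r$id,
                   metabolite_id = names(r$metabolites),
                   coefficient = as.numeric(unlist(r$metabolites)))
  }))
  genes <- if (length(obj$genes)) {
    tibble::tibble(id = vapply(obj$genes, function(g) g$id, character(1)))
  } else NULL
  ocoef <- vapply(obj$reactions,
                  function(r) as.numeric(r$objective_coefficient %||% 0),
                  numeric(1))
  objective_id <- if (any(ocoef != 0)) rxns$id[which(ocoef != 0)[1]] else rxns$id[1]
  metabolic_model(mets, rxns, st, genes = genes, objective_id = objective_id,
                  name = obj$id %||% "model", extracellular = extracellular)
}

# ---- SBML Level 3 + fbc ----------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

write_gem_sbml <- function(model, path) {
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bid <- stats::setNames(paste0("bnd_", seq_along(bounds)),
                         vapply(bounds, sbml_num, character(1)))
  st <- split(model$stoichiometry, model$stoichiometry$reaction_id)

  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id(model$name),
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  }
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    node <- xml2::xml_add_child(sps, "species",
      id = paste0("M_", m$id), name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (nzchar(m$formula)) {
      xml2::xml_set_attr(node, "fbc:chemicalFormula", m$formula)
    }
    if (!is.na(m$charge)) {
      xml2::xml_set_attr(node, "fbc:charge", as.character(m$charge))
    }
  }
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(bounds)) {
    xml2::xml_add_child(pars, "parameter", id = bid[[k]],
                        value = sbml_num(bounds[k]), constant = "true")
  }
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    node <- xml2::xml_add_child(rxs, "reaction",
      id = paste0("R_", r$id), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid[[sbml_num(r$lower_bound)]],
      "fbc:upperFluxBound" = bid[[sbml_num(r$upper_bound)]])
    if (nzchar(r$subsystem)) {
      notes <- xml2::xml_add_child(node, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    s <- st[[r$id]]
    rea <- s[s$coefficient < 0, ]
    pro <- s[s$coefficient > 0, ]
    if (nrow(rea)) {
      lst <- xml2::xml_add_child(node, "listOfReactants")
      for (k in seq_len(nrow(rea))) {
        xml2::xml_add_child(lst, "speciesReference",
          species = paste0("M_", rea$metabolite_id[k]),
          stoichiometry = sbml_num(-rea$coefficient[k]), constant = "true")
      }
    }
    if (nrow(pro)) {
      lst <- xml2::xml_add_child(node, "listOfProducts")
      for (k in seq_len(nrow(pro))) {
        xml2::xml_add_child(lst, "speciesReference",
          species = paste0("M_", pro$metabolite_id[k]),
          stoichiometry = sbml_num(pro$coefficient[k]), constant = "true")
      }
    }
    tree <- parse_gpr(r$gpr)
    if (!is.null(tree)) {
      gpa <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      write_gpr_node(gpa, tree)
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  o <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                           "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(o, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model$objective_id),
                      "fbc:coefficient" = "1")
  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes$id) {
    xml2::xml_add_child(gps, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", sbml_id(g)),
                        "fbc:label" = g)
  }
  xml2::write_xml(doc, path)
}

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_gpr_node <- function(parent, tree) {
  if (tree$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sbml_id(tree$gene)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
    for (k in tree$children) write_gpr_node(node, k)
  }
}

read_gem_sbml <- function(path, extracellular) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("parse error in SBML file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop("parse error: no <model> element in '", path, "'", call. = FALSE)
  }
  att <- function(node, a) xml2::xml_attr(node, a)

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- dplyr::bind_rows(lapply(sp, function(node) {
    tibble::tibble(id = sub("^M_", "", att(node, "id")),
                   name = att(node, "name") %|na|% sub("^M_", "", att(node, "id")),
                   formula = att(node, "chemicalFormula") %|na|% "",
                   charge = as.integer(att(node, "charge")),
                   compartment = att(node, "compartment"))
  }))

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))

  # gene label lookup (fbc gene ids -> labels used as gene ids here)
  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- list(); st <- list()
  for (node in rx) {
    rid <- sub("^R_", "", att(node, "id"))
    lbp <- att(node, "lowerFluxBound")
    ubp <- att(node, "upperFluxBound")
    lbv <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else -DEFAULT_BOUND
    ubv <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else DEFAULT_BOUND
    notes <- xml2::xml_text(xml2::xml_find_all(node, ".//s:notes//*", ns))
    subsys <- ""
    hit <- grep("^\\s*SUBSYSTEM:", notes, value = TRUE)
    if (length(hit)) subsys <- trimws(sub("^\\s*SUBSYSTEM:\\s*", "", hit[1]))
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      gpr_to_string(read_gpr_node(gpa, glabel))
    }
    rxns[[rid]] <- tibble::tibble(id = rid,
                                  name = att(node, "name") %|na|% rid,
                                  lower_bound = lbv, upper_bound = ubv,
                                  subsystem = subsys, gpr = gpr)
    rea <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    pro <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    coef <- c(-as.numeric(xml2::xml_attr(rea, "stoichiometry")),
              as.numeric(xml2::xml_attr(pro, "stoichiometry")))
    mids <- sub("^M_", "", c(xml2::xml_attr(rea, "species"),
                             xml2::xml_attr(pro, "species")))
    if (!length(mids)) {
      stop("parse error: reaction '", rid, "' has empty stoichiometry",
           call. = FALSE)
    }
    agg <- tapply(coef, mids, sum)
    st[[rid]] <- tibble::tibble(reaction_id = rid, metabolite_id = names(agg),
                                coefficient = as.numeric(agg))
  }
  fobj <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  objective_id <- if (inherits(fobj, "xml_missing")) {
    names(rxns)[1]
  } else sub("^R_", "", xml2::xml_attr(fobj, "reaction"))
  genes <- if (length(glabel)) tibble::tibble(id = unname(glabel)) else NULL
  metabolic_model(mets, dplyr::bind_rows(rxns), dplyr::bind_rows(st),
                  genes = genes, objective_id = objective_id,
                  name = att(mdl, "id") %|na|% "model",
                  extracellular = extracellular)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

read_gpr_node <- function(node, glabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lab <- glabel[[gid]] %||% sub("^G_", "", gid)
    return(gpr_node("gene", gene = lab))
  }
  kids <- lapply(xml2::xml_children(node), read_gpr_node, glabel = glabel)
  gpr_node(if (nm == "and") "and" else "or", children = kids)
}
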