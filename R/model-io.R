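#' Read a metabolic model from a BiGG-style JSON file
#'
#' Reads the BiGG Models JSON dialect (the `metabolites`, `reactions`,
#' `genes` top-level arrays; each reaction carries `metabolites` (a
#' stoichiometry map), `lower_bound`, `upper_bound`, `gene_reaction_rule`
#' and `subsystem`). Bounds omitted by the file fall back to the COBRA
#' convention (0/1000 irreversible, -1000/1000 reversible).
#'
#' @param path Path to a BiGG-JSON model file.
#' @return A validated [metabolic_model()].
#' @seealso [write_model_json()], [read_model_sbml()]
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$reactions)) {
    abort(sprintf("malformed model file %s: missing 'reactions' array", path))
  }
  met_ids <- vapply(doc$metabolites %||% list(), function(m) {
    if (is.null(m$id)) abort(sprintf(
      "malformed model file %s: metabolite record without id", path))
    as.character(m$id)
  }, "")
  rxn_rows <- lapply(seq_along(doc$reactions), function(k) {
    r <- doc$reactions[[k]]
    if (is.null(r$id)) {
      abort(sprintf("malformed model file %s: reaction record %d without id",
                    path, k))
    }
    st <- r$metabolites %||% list()
    stoich <- setNames(vapply(st, as.numeric, 0), names(st))
    rev_default <- !is.null(r$lower_bound) && r$lower_bound < 0
    lb <- r$lower_bound %||% 0
    ub <- r$upper_bound %||% 1000
    if (is.null(r$lower_bound) && is.null(r$upper_bound) &&
        isTRUE(r$reversible)) {
      lb <- -1000
    }
    tibble(
      id = as.character(r$id),
      stoich = list(stoich),
      lower_bound = as.numeric(lb),
      upper_bound = as.numeric(ub),
      reversible = as.numeric(lb) < 0 || rev_default,
      subsystem = as.character(r$subsystem %||% ""),
      gpr = list(parse_gpr(r$gene_reaction_rule %||% ""))
    )
  })
  rxn <- dplyr::bind_rows(rxn_rows)
  dup <- rxn$id[duplicated(rxn$id)]
  if (length(dup) > 0) {
    abort(sprintf("model file %s: duplicate reaction id %s",
                  path, paste(unique(dup), collapse = ", ")))
  }
  mets <- if (length(met_ids) > 0) met_ids else NULL
  model <- metabolic_model(rxn, metabolites = mets,
                           id = as.character(doc$id %||% basename(path)),
                           check = FALSE)
  viol <- validate_model(model)
  if (length(viol) > 0) {
    abort(c(sprintf("model file %s failed validation:", path), viol))
  }
  model
}

#' Write a metabolic model as BiGG-style JSON
#'
#' Round-trip companion to [read_model_json()]: stoichiometries, bounds,
#' subsystems and GPR rule strings are preserved exactly.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxn <- model$reactions
  doc <- list(
    id = model$id,
    metabolites = lapply(model$metabolites, function(m) list(id = m)),
    reactions = lapply(seq_len(nrow(rxn)), function(i) {
      list(
        id = rxn$id[i],
        metabolites = as.list(rxn$stoich[[i]]),
        lower_bound = rxn$lower_bound[i],
        upper_bound = rxn$upper_bound[i],
        subsystem = rxn$subsystem[i],
        gene_reaction_rule = gpr_to_string(rxn$gpr[[i]])
      )
    }),
    genes = lapply(model$genes, function(g) list(id = g))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an SBML Level 3 (FBC) model
#'
#' Best-effort reader for the SBML subset produced by COBRA-style
#' exporters: species, reactions with `fbc:geneProductAssociation`, and
#' flux bounds either as `fbc:lowerFluxBound`/`fbc:upperFluxBound`
#' parameter references or via the `reversible` attribute. BiGG-JSON
#' ([read_model_json()]) is the primary dialect; use this for models only
#' available as SBML.
#'
#' @param path Path to an SBML file.
#' @return A validated [metabolic_model()].
#' @export
read_model_sbml <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  doc <- xml2::read_xml(path)
  ns_all <- xml2::xml_ns(doc)
  # parameters: id -> value (flux bound constants)
  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  met_ids <- xml2::xml_attr(species, "id")
  # gene products: fbc id -> label
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           xml2::xml_attr(gps, "id"), xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  rxn_rows <- lapply(rx_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    spref <- function(kind, sign) {
      refs <- xml2::xml_find_all(
        rx, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']",
                    kind))
      sp <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      setNames(sign * coef, sp)
    }
    st <- c(spref("listOfReactants", -1), spref("listOfProducts", +1))
    st <- tapply(st, names(st), sum)
    st <- setNames(as.numeric(st), names(st))
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else if (reversible) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]]
          else 1000
    gpa <- xml2::xml_find_first(
      rx, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) gpr_none() else {
      sbml_gpa_to_gpr(xml2::xml_children(gpa)[[1]], gp_label)
    }
    tibble(id = id, stoich = list(st), lower_bound = lb, upper_bound = ub,
           reversible = lb < 0, subsystem = "", gpr = list(gpr))
  })
  rxn <- dplyr::bind_rows(rxn_rows)
  model <- metabolic_model(rxn, metabolites = met_ids,
                           id = basename(path), check = FALSE)
  viol <- validate_model(model)
  if (length(viol) > 0) {
    abort(c(sprintf("SBML model %s failed validation:", path), viol))
  }
  model
}

sbml_gpa_to_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    gene <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(gpr_leaf(gene))
  }
  kids <- lapply(xml2::xml_children(node), sbml_gpa_to_gpr, gp_label = gp_label)
  if (nm == "and") gpr_node("all", kids)
  else if (nm == "or") gpr_node("any", kids)
  else abort(sprintf("unsupported SBML gene association node '%s'", nm))
}
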