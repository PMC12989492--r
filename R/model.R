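#' Construct a metabolic model
#'
#' A `metabolic_model` holds an ordered metabolite list, a reaction table
#' (stoichiometry, bounds, subsystem, GPR rule), and the gene universe
#' implied by the GPR rules. The stoichiometric matrix S (metabolites x
#' reactions) is materialized on demand by [stoich_matrix()].
#'
#' @param reactions A data frame / tibble with one row per reaction and
#'   columns `id` (unique character), `stoich` (list of named numeric
#'   vectors: metabolite id -> signed coefficient), and optionally
#'   `lower_bound`, `upper_bound`, `subsystem`, `gpr` (list of `gpr_rule`
#'   or rule strings). Missing bounds default to the COBRA convention:
#'   0/1000 when `reversible` is `FALSE` (the default), -1000/1000 when
#'   `TRUE`.
#' @param metabolites Optional character vector of metabolite ids; defaults
#'   to the union of stoichiometry keys, in order of first appearance.
#' @param id Optional model identifier string.
#' @param check If `TRUE` (default) run [validate_model()] and abort on
#'   violations.
#' @return A `metabolic_model` object.
#' @seealso [read_model_json()], [build_toy_model()], [validate_model()]
#' @export
metabolic_model <- function(reactions, metabolites = NULL, id = "model",
                            check = TRUE) {
  rxn <- as_tibble(reactions)
  if (!all(c("id", "stoich") %in% names(rxn))) {
    abort("`reactions` must have columns `id` and `stoich`")
  }
  if (!"reversible" %in% names(rxn)) rxn$reversible <- FALSE
  if (!"lower_bound" %in% names(rxn)) {
    rxn$lower_bound <- ifelse(rxn$reversible, -1000, 0)
  }
  if (!"upper_bound" %in% names(rxn)) rxn$upper_bound <- 1000
  if (!"subsystem" %in% names(rxn)) rxn$subsystem <- ""
  if (!"gpr" %in% names(rxn)) rxn$gpr <- list(gpr_none())
  rxn$gpr <- lapply(rxn$gpr, function(g) {
    if (inherits(g, "gpr_rule")) g else parse_gpr(g)
  })
  rxn$reversible <- rxn$lower_bound < 0
  rxn$subsystem[is.na(rxn$subsystem)] <- ""
  if (is.null(metabolites)) {
    metabolites <- unique(unlist(lapply(rxn$stoich, names)))
  }
  genes <- sort(unique(unlist(lapply(rxn$gpr, gpr_genes))))
  model <- structure(
    list(id = id,
         metabolites = as.character(metabolites),
         reactions = rxn[, c("id", "stoich", "lower_bound", "upper_bound",
                             "reversible", "subsystem", "gpr")],
         genes = genes),
    class = "metabolic_model")
  if (check) {
    viol <- validate_model(model)
    if (length(viol) > 0) {
      abort(c("invalid metabolic model:", viol))
    }
  }
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants of a [metabolic_model()]: unique
#' reaction ids, ordered bounds, stoichiometry keys declared in the
#' metabolite list, non-empty stoichiometries for non-exchange reactions,
#' and mass connectivity (every non-exchange reaction shares at least one
#' metabolite with another reaction). Violations are returned, not raised.
#'
#' @param model A `metabolic_model` (or a model-shaped list).
#' @return A character vector of violation messages; empty when the model
#'   is valid.
#' @export
validate_model <- function(model) {
  viol <- character()
  rxn <- model$reactions
  dup <- rxn$id[duplicated(rxn$id)]
  if (length(dup) > 0) {
    viol <- c(viol, sprintf("duplicate reaction id: %s",
                            paste(unique(dup), collapse = ", ")))
  }
  bad_bounds <- rxn$id[rxn$lower_bound > rxn$upper_bound]
  if (length(bad_bounds) > 0) {
    viol <- c(viol, sprintf("lower_bound > upper_bound for: %s",
                            paste(bad_bounds, collapse = ", ")))
  }
  mets <- model$metabolites
  if (anyDuplicated(mets)) {
    viol <- c(viol, "duplicate metabolite ids")
  }
  for (i in seq_len(nrow(rxn))) {
    st <- rxn$stoich[[i]]
    undecl <- setdiff(names(st), mets)
    if (length(undecl) > 0) {
      viol <- c(viol, sprintf("reaction %s cites undeclared metabolite(s): %s",
                              rxn$id[i], paste(undecl, collapse = ", ")))
    }
    if (length(st) == 0 && !is_exchange_id(rxn$id[i])) {
      viol <- c(viol, sprintf("reaction %s has empty stoichiometry", rxn$id[i]))
    }
  }
  gpr_gene_union <- unique(unlist(lapply(rxn$gpr, gpr_genes)))
  missing_genes <- setdiff(gpr_gene_union, model$genes)
  if (length(missing_genes) > 0) {
    viol <- c(viol, sprintf("GPR gene(s) missing from gene list: %s",
                            paste(missing_genes, collapse = ", ")))
  }
  # mass connectivity: a non-exchange reaction all of whose metabolites
  # appear in no other reaction is a disconnected stub
  if (nrow(rxn) > 1) {
    met_use <- table(unlist(lapply(rxn$stoich, names)))
    for (i in seq_len(nrow(rxn))) {
      st <- rxn$stoich[[i]]
      if (length(st) == 0 || is_exchange_id(rxn$id[i])) next
      shared <- any(met_use[names(st)] > 1)
      if (!shared) {
        viol <- c(viol, sprintf("reaction %s is not mass-connected", rxn$id[i]))
      }
    }
  }
  viol
}

# exchange stubs by convention: EX_/DM_/SRC_/sink_ prefixes or a
# single-metabolite stoichiometry
is_exchange_id <- function(id) {
  grepl("^(EX_|DM_|SRC_|sink_|SK_)", id)
}

is_exchange_reaction <- function(model, i) {
  is_exchange_id(model$reactions$id[i]) ||
    length(model$reactions$stoich[[i]]) <= 1L
}

#' Stoichiometric matrix of a model
#'
#' @param model A [metabolic_model()].
#' @return A sparse `dgCMatrix` (metabolites x reactions) with dimnames.
#' @export
stoich_matrix <- function(model) {
  rxn <- model$reactions
  mets <- model$metabolites
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_len(nrow(rxn))) {
    st <- rxn$stoich[[j]]
    if (length(st) == 0) next
    ii <- c(ii, match(names(st), mets))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), nrow(rxn)),
                       dimnames = list(mets, rxn$id))
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, %d genes>\n",
              x$id, length(x$metabolites), nrow(x$reactions), length(x$genes)))
  subs <- unique(x$reactions$subsystem)
  subs <- subs[nzchar(subs)]
  if (length(subs) > 0) {
    cat("  subsystems:", paste(head(subs, 6), collapse = "; "),
        if (length(subs) > 6) "..." else "", "\n")
  }
  invisible(x)
}

#' Tidy a metabolic model into its reaction table
#'
#' @param x A [metabolic_model()].
#' @param ... Unused.
#' @return A tibble with one row per reaction: `id`, `subsystem`,
#'   `lower_bound`, `upper_bound`, `reversible`, `gpr` (rule string),
#'   `n_metabolites`, `genes` (list column).
#' @method tidy metabolic_model
#' @export
tidy.metabolic_model <- function(x, ...) {
  rxn <- x$reactions
  tibble(
    id = rxn$id,
    subsystem = rxn$subsystem,
    lower_bound = rxn$lower_bound,
    upper_bound = rxn$upper_bound,
    reversible = rxn$reversible,
    gpr = vapply(rxn$gpr, gpr_to_string, ""),
    n_metabolites = vapply(rxn$stoich, length, 0L),
    genes = lapply(rxn$gpr, gpr_genes)
  )
}

#' @method glance metabolic_model
#' @export
glance.metabolic_model <- function(x, ...) {
  tibble(
    id = x$id,
    n_metabolites = length(x$metabolites),
    n_reactions = nrow(x$reactions),
    n_genes = length(x$genes),
    n_reversible = sum(x$reactions$reversible),
    n_subsystems = length(unique(x$reactions$subsystem[
      nzchar(x$reactions$subsystem)]))
  )
}
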