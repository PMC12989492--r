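#' Describe a synthetic paired two-group cohort
#'
#' A `synthetic_design` captures everything needed to simulate a paired
#' lesion/control RNA-seq cohort with planted per-gene effects: the gene
#' universe with per-gene baseline means and transcript lengths, the
#' number of patient pairs, the negative-binomial dispersion, a shared
#' per-patient lognormal factor that induces pairing, and a map of
#' planted fold changes applied to the lesion group.
#'
#' Transcript lengths (needed for TPM) are drawn log-uniformly in
#' \[500, 5000\] nt from the design seed and recorded in the design, so a
#' design is fully deterministic.
#'
#' @param genes Either an integer (number of genes, ids `gene_1`, ...) or
#'   a character vector of gene ids, or a data frame with columns `gene`
#'   and optionally `base_mean` and `length`.
#' @param n_pairs Number of patient pairs (>= 2); each patient contributes
#'   one lesion and one control sample.
#' @param nb_mean Baseline negative-binomial mean used for genes without
#'   their own `base_mean`.
#' @param nb_dispersion NB dispersion alpha (> 0), so that
#'   `var = mu + alpha * mu^2`. Values of 0 give Poisson counts.
#' @param planted_effects Named numeric vector: gene id -> fold change
#'   (> 0) multiplied into that gene's lesion-group mean.
#' @param patient_effect_sd Standard deviation (log scale) of the shared
#'   per-patient lognormal factor; 0 disables pairing noise.
#' @param seed Integer seed; all randomness in the design and in
#'   [generate_counts()] derives from it.
#' @return A `synthetic_design` object.
#' @seealso [generate_counts()], [toy_cohort_design()], [make_gold_standard()]
#' @export
synthetic_design <- function(genes = 200, n_pairs = 7, nb_mean = 100,
                             nb_dispersion = 0.1,
                             planted_effects = numeric(),
                             patient_effect_sd = 0.2, seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- tibble(gene = sprintf("gene_%03d", seq_len(genes)))
  } else if (is.character(genes)) {
    genes <- tibble(gene = genes)
  } else {
    genes <- as_tibble(genes)
  }
  if (!"gene" %in% names(genes)) abort("`genes` must have a `gene` column")
  if (anyDuplicated(genes$gene)) abort("duplicate gene ids in design")
  if (!"base_mean" %in% names(genes)) genes$base_mean <- nb_mean
  genes$base_mean[is.na(genes$base_mean)] <- nb_mean
  if (n_pairs < 2) abort("n_pairs must be >= 2")
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (patient_effect_sd < 0) abort("patient_effect_sd must be >= 0")
  if (length(planted_effects) > 0) {
    if (is.null(names(planted_effects)) || any(!nzchar(names(planted_effects)))) {
      abort("planted_effects must be a named vector (gene -> fold change)")
    }
    missing <- setdiff(names(planted_effects), genes$gene)
    if (length(missing) > 0) {
      abort(sprintf("planted gene(s) not in the gene universe: %s",
                    paste(missing, collapse = ", ")))
    }
    if (any(planted_effects <= 0)) abort("fold changes must be > 0")
  }
  if (!"length" %in% names(genes) || anyNA(genes$length)) {
    lens <- with_local_seed(seed + 1000L, {
      round(exp(runif(nrow(genes), log(500), log(5000))))
    })
    if (!"length" %in% names(genes)) genes$length <- lens
    genes$length[is.na(genes$length)] <- lens[is.na(genes$length)]
  }
  genes$planted_fc <- 1
  genes$planted_fc[match(names(planted_effects), genes$gene)] <-
    unname(planted_effects)
  structure(
    list(genes = genes, n_pairs = as.integer(n_pairs),
         nb_dispersion = nb_dispersion,
         patient_effect_sd = patient_effect_sd,
         planted_effects = planted_effects, seed = as.integer(seed)),
    class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "<synthetic_design: %d genes, %d pairs, dispersion %.3g, patient sd %.3g, %d planted effect(s), seed %d>\n",
    nrow(x$genes), x$n_pairs, x$nb_dispersion, x$patient_effect_sd,
    length(x$planted_effects), x$seed))
  invisible(x)
}

# run code under a temporary RNG state, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a paired two-group count cohort
#'
#' Draws a genes x (2 * n_pairs) integer count matrix under the design's
#' noise model: counts are negative-binomial with per-gene baseline mean,
#' multiplied by a per-patient lognormal factor shared by the lesion and
#' control sample of a pair, and by the planted fold change in lesion
#' samples. Output is deterministic for a fixed design seed.
#'
#' @param design A [synthetic_design()].
#' @return A `synthetic_cohort`: a list with `counts` (tibble, first
#'   column `gene`, then one column per sample), `samples` (tibble:
#'   `sample`, `patient`, `group` in lesion/control), and `lengths`
#'   (tibble: `gene`, `length` in nt).
#' @examples
#' d <- synthetic_design(genes = 20, n_pairs = 3, seed = 42)
#' cohort <- generate_counts(d)
#' head(cohort$counts)
#' @export
generate_counts <- function(design) {
  if (!inherits(design, "synthetic_design")) {
    abort("`design` must be a synthetic_design")
  }
  g <- design$genes
  n_pairs <- design$n_pairs
  samples <- tibble(
    sample = c(sprintf("lesion_p%02d", seq_len(n_pairs)),
               sprintf("control_p%02d", seq_len(n_pairs))),
    patient = rep(sprintf("p%02d", seq_len(n_pairs)), 2),
    group = rep(c("lesion", "control"), each = n_pairs)
  )
  counts <- with_local_seed(design$seed, {
    pf <- exp(rnorm(n_pairs, 0, design$patient_effect_sd))
    mat <- matrix(0L, nrow = nrow(g), ncol = nrow(samples),
                  dimnames = list(g$gene, samples$sample))
    for (j in seq_len(nrow(samples))) {
      p <- match(samples$patient[j], sprintf("p%02d", seq_len(n_pairs)))
      mu <- g$base_mean * pf[p]
      if (samples$group[j] == "lesion") mu <- mu * g$planted_fc
      mat[, j] <- if (design$nb_dispersion > 0) {
        rnbinom(nrow(g), mu = mu, size = 1 / design$nb_dispersion)
      } else {
        stats::rpois(nrow(g), mu)
      }
    }
    mat
  })
  structure(
    list(counts = dplyr::bind_cols(tibble(gene = g$gene),
                                   as_tibble(counts)),
         samples = samples,
         lengths = tibble(gene = g$gene, length = g$length),
         design = design),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d genes x %d samples (%d pairs)>\n",
              nrow(x$counts), nrow(x$samples), nrow(x$samples) / 2))
  invisible(x)
}

#' Tidy a synthetic cohort into long form
#'
#' @param x A `synthetic_cohort` from [generate_counts()].
#' @param ... Unused.
#' @return A long tibble: `gene`, `sample`, `patient`, `group`, `count`.
#' @method tidy synthetic_cohort
#' @export
tidy.synthetic_cohort <- function(x, ...) {
  tidyr::pivot_longer(x$counts, -"gene", names_to = "sample",
                      values_to = "count") |>
    dplyr::left_join(x$samples, by = "sample") |>
    dplyr::select("gene", "sample", "patient", "group", "count")
}

#' Build a toy-model cohort design with planted enzyme effects
#'
#' Convenience wrapper around [synthetic_design()] aligned with
#' [build_toy_model()]: the gene universe is the model's genes plus
#' filler genes, with high baseline expression for core energy-pathway
#' genes (so they anchor the per-sample activity percentile used by
#' [set_expression_bounds()]) and moderate baseline expression for
#' sentinel branch genes (so planted fold changes move their normalized
#' activities inside the unclipped range).
#'
#' @param model A [metabolic_model()] (typically [build_toy_model()]).
#' @param planted_effects Named numeric vector gene -> fold change; the
#'   default plants a 0.25x knockdown on the genes gating `DHCRD2` and
#'   `FAEL183` and a 4x upregulation on the gene gating `PSDm_hs`.
#' @param n_filler Number of filler (non-enzyme) genes.
#' @param core_mean,branch_mean Baseline NB means for core-energy genes
#'   and sentinel branch genes.
#' @param n_pairs,nb_dispersion,patient_effect_sd,seed Passed to
#'   [synthetic_design()].
#' @return A [synthetic_design()].
#' @export
toy_cohort_design <- function(model,
                              planted_effects = c(DEGS1_toy = 0.25,
                                                  ELOVL5_toy = 0.25,
                                                  PISD_toy = 4),
                              n_filler = 150, core_mean = 5000,
                              branch_mean = 50, n_pairs = 7,
                              nb_dispersion = 0.1, patient_effect_sd = 0.2,
                              seed = 1L) {
  energy <- energy_subsystems()
  rxn <- model$reactions
  core_genes <- unique(unlist(lapply(
    which(tolower(rxn$subsystem) %in% energy), function(i) gpr_genes(rxn$gpr[[i]]))))
  branch_genes <- setdiff(model$genes, core_genes)
  filler <- if (n_filler > 0) sprintf("filler_%03d", seq_len(n_filler))
            else character()
  genes <- tibble(
    gene = c(core_genes, branch_genes, filler),
    base_mean = c(rep(core_mean, length(core_genes)),
                  rep(branch_mean, length(branch_genes)),
                  rep(200, length(filler)))
  )
  synthetic_design(genes = genes, n_pairs = n_pairs,
                   nb_dispersion = nb_dispersion,
                   planted_effects = planted_effects,
                   patient_effect_sd = patient_effect_sd, seed = seed)
}

#' Gold-standard answer key for a planted design
#'
#' Derives, deterministically from the planted effects and the model's
#' GPR rules, what a correct analysis should recover: the true per-gene
#' log2 fold change, and the expected flux direction per reaction. A
#' reaction whose sole gating gene carries a planted effect is expected
#' to move in the direction of that effect. Reactions that are
#' stoichiometrically coupled to such a reaction (same connected branch
#' of the reaction graph, e.g. the source and demand steps of a linear
#' sentinel branch) carry identical flux and inherit the direction, with
#' `coupled = TRUE`. All other reactions are expected unchanged
#' (`"none"`).
#'
#' @param design A [synthetic_design()].
#' @param model A [metabolic_model()].
#' @return A `gold_standard`: list with `genes` (tibble: `gene`,
#'   `true_log2fc`) and `reactions` (tibble: `reaction`,
#'   `expected_direction` in up/down/none, `coupled`).
#' @export
make_gold_standard <- function(design, model) {
  genes <- tibble(
    gene = design$genes$gene,
    true_log2fc = log2(design$genes$planted_fc)
  )
  rxn <- model$reactions
  dir <- rep("none", nrow(rxn))
  coupled <- rep(FALSE, nrow(rxn))
  planted <- design$planted_effects
  for (i in seq_len(nrow(rxn))) {
    gg <- gpr_genes(rxn$gpr[[i]])
    if (length(gg) == 1 && gg %in% names(planted)) {
      dir[i] <- if (planted[[gg]] > 1) "up" else "down"
    }
  }
  # propagate along stoichiometrically coupled components
  comp <- reaction_components(model)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    dirs <- unique(dir[idx][dir[idx] != "none"])
    if (length(dirs) == 1) {
      inherit <- idx[dir[idx] == "none"]
      dir[inherit] <- dirs
      coupled[inherit] <- TRUE
    }
  }
  structure(
    list(genes = genes,
         reactions = tibble(reaction = rxn$id, expected_direction = dir,
                            coupled = coupled)),
    class = "gold_standard")
}

# connected components of the reaction graph (edges = shared metabolite)
reaction_components <- function(model) {
  rxn <- model$reactions
  met2rxn <- list()
  for (i in seq_len(nrow(rxn))) {
    for (m in names(rxn$stoich[[i]])) {
      met2rxn[[m]] <- c(met2rxn[[m]], i)
    }
  }
  edges <- do.call(rbind, lapply(met2rxn, function(rs) {
    if (length(rs) < 2) return(NULL)
    cbind(rs[1], rs[-1])
  }))
  g <- igraph::make_empty_graph(n = nrow(rxn), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' Simulate Gaussian fold-change profiles with planted clusters
#'
#' Generates per-gene profiles (e.g. per-pair log2 fold changes) with a
#' known cluster structure, for evaluating consensus clustering. Each
#' cluster is offset by `offset * noise_sd` (3 within-cluster standard
#' deviations by default) on its own disjoint block of `informative`
#' coordinates, so the cluster centers form an equidistant simplex and —
#' because only a minority of coordinates carry the offset — the planted
#' structure survives the per-gene median centering that
#' [consensus_cluster()] applies.
#'
#' @param n_genes Total number of genes (split as evenly as possible).
#' @param n_clusters Number of planted clusters.
#' @param n_dims Profile dimensionality; must be at least
#'   `n_clusters * informative`, and `informative` must stay below half
#'   of `n_dims` for median centering to leave the offsets intact.
#' @param informative Number of coordinates carrying each cluster's
#'   offset.
#' @param offset Center offset per informative coordinate, in units of
#'   `noise_sd`.
#' @param noise_sd Within-cluster standard deviation per coordinate.
#' @param seed Integer seed.
#' @return A list with `profiles` (tibble: `gene`, `V1`..`Vn`) and
#'   `clusters` (tibble: `gene`, `cluster`).
#' @export
simulate_cluster_profiles <- function(n_genes = 60, n_clusters = 3,
                                      n_dims = 10, informative = 3,
                                      offset = 3, noise_sd = 1, seed = 1L) {
  stopifnot(n_clusters >= 2, n_clusters * informative <= n_dims)
  sizes <- rep(n_genes %/% n_clusters, n_clusters)
  extra <- n_genes - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  cluster <- rep(seq_len(n_clusters), sizes)
  prof <- with_local_seed(seed, {
    m <- matrix(rnorm(n_genes * n_dims, 0, noise_sd), n_genes, n_dims)
    for (c_id in seq_len(n_clusters)) {
      rows <- which(cluster == c_id)
      cols <- (c_id - 1) * informative + seq_len(informative)
      m[rows, cols] <- m[rows, cols] + offset * noise_sd
    }
    m
  })
  colnames(prof) <- sprintf("V%d", seq_len(n_dims))
  gene <- sprintf("gene_%03d", seq_len(n_genes))
  list(profiles = dplyr::bind_cols(tibble(gene = gene), as_tibble(prof)),
       clusters = tibble(gene = gene, cluster = cluster))
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `counts.tsv` (genes x samples), `samples.tsv` (sample sheet),
#' `lengths.tsv`, and, when a gold standard is supplied,
#' `gold_standard_genes.tsv` and `gold_standard_reactions.tsv`.
#'
#' @param cohort A `synthetic_cohort` from [generate_counts()].
#' @param dir Output directory (created if missing).
#' @param gold Optional `gold_standard` from [make_gold_standard()].
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, gold = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(cohort$lengths, file.path(dir, "lengths.tsv"))
  if (!is.null(gold)) {
    readr::write_tsv(gold$genes, file.path(dir, "gold_standard_genes.tsv"))
    readr::write_tsv(gold$reactions,
                     file.path(dir, "gold_standard_reactions.tsv"))
  }
  invisible(dir)
}
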