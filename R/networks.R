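#' Consensus k-means clustering of fold-change profiles
#'
#' Repeatedly clusters random gene subsamples and records, for every
#' gene pair, how often the two genes land in the same cluster among the
#' repetitions where both were sampled. The resulting consensus matrix
#' is both a stability diagnostic (its entries concentrate near 0/1 when
#' k fits the data) and a co-expression similarity measure.
#'
#' Profiles are median-centered per gene first. Each repetition draws
#' `subsample_frac` of the genes without replacement and runs k-means
#' (Euclidean distance, k-means++ seeding, 10 restarts keeping the best
#' within-cluster sum of squares, at most 100 iterations). The final
#' assignment at each k cuts an average-linkage hierarchical tree of
#' `1 - M_k`; the preferred k is chosen by [select_k()].
#'
#' @param profiles A tibble whose first column is `gene` and remaining
#'   columns are the numeric profile (e.g. per-pair log2 fold changes
#'   from [log2fc_profiles()]), or a numeric matrix with gene rownames.
#' @param k_range Candidate cluster counts (default `2:10`).
#' @param reps Number of subsampling repetitions (default 30).
#' @param subsample_frac Fraction of genes drawn per repetition
#'   (default 0.8).
#' @param seed Integer seed; results are bit-for-bit reproducible.
#' @return A `consensus_result`: list with `consensus` (named list of
#'   gene x gene matrices, one per k), `assignments` (tibble: `gene`,
#'   one `k<j>` column per k), `cdf_area` and `delta_area` (per k),
#'   `chosen_k`, `never_cosampled` (pair count), and the call
#'   parameters.
#' @export
consensus_cluster <- function(profiles, k_range = 2:10, reps = 30,
                              subsample_frac = 0.8, seed = 1L) {
  if (is.data.frame(profiles)) {
    mat <- as.matrix(profiles[, -1, drop = FALSE])
    rownames(mat) <- profiles[[1]]
  } else {
    mat <- as.matrix(profiles)
    if (is.null(rownames(mat))) {
      rownames(mat) <- sprintf("gene_%03d", seq_len(nrow(mat)))
    }
  }
  n <- nrow(mat)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= n) abort("need more genes than the largest k")
  m_sub <- max(2L, floor(subsample_frac * n))
  if (m_sub <= max(k_range)) {
    abort("subsample too small for the largest k")
  }
  mat <- mat - apply(mat, 1, median)  # median-center each gene
  genes <- rownames(mat)
  cosampled <- matrix(0, n, n)
  coclust <- lapply(k_range, function(k) matrix(0, n, n))
  names(coclust) <- as.character(k_range)
  with_local_seed(seed, {
    for (rep_i in seq_len(reps)) {
      idx <- sort(sample.int(n, m_sub))
      cosampled[idx, idx] <- cosampled[idx, idx] + 1
      sub <- mat[idx, , drop = FALSE]
      for (k in k_range) {
        cl <- kmeans_pp(sub, k, restarts = 10, iter_max = 100)
        for (g in seq_len(k)) {
          members <- idx[cl == g]
          coclust[[as.character(k)]][members, members] <-
            coclust[[as.character(k)]][members, members] + 1
        }
      }
    }
  })
  never <- sum(cosampled[upper.tri(cosampled)] == 0)
  consensus <- lapply(coclust, function(cc) {
    M <- ifelse(cosampled > 0, cc / cosampled, 0)
    diag(M) <- 1
    dimnames(M) <- list(genes, genes)
    M
  })
  assignments <- tibble(gene = genes)
  for (k in k_range) {
    M <- consensus[[as.character(k)]]
    hc <- hclust(as.dist(1 - M), method = "average")
    assignments[[sprintf("k%d", k)]] <- unname(cutree(hc, k))
  }
  # area under the consensus CDF: for entries in [0, 1] the exact
  # integral of the empirical CDF is 1 - mean(entries)
  cdf_area <- vapply(consensus, function(M) {
    1 - mean(M[upper.tri(M)])
  }, 0)
  res <- structure(
    list(consensus = consensus, assignments = assignments,
         cdf_area = setNames(cdf_area, as.character(k_range)),
         k_range = k_range, reps = reps,
         subsample_frac = subsample_frac, seed = seed,
         never_cosampled = never),
    class = "consensus_result")
  res$delta_area <- delta_area(res)
  res$chosen_k <- select_k(res)
  res
}

# k-means with k-means++ seeding and multiple restarts
kmeans_pp <- function(x, k, restarts = 10, iter_max = 100) {
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = iter_max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1)
  centers[1, ] <- x[first, ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    pick <- sample.int(n, 1, prob = probs)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  # duplicated centers (possible under heavy ties) break kmeans; jitter
  if (anyDuplicated(centers)) {
    centers <- centers + rnorm(length(centers), 0, 1e-8)
  }
  centers
}

delta_area <- function(result) {
  a <- result$cdf_area
  k <- result$k_range
  d <- numeric(length(k))
  d[1] <- a[1]
  if (length(k) > 1) {
    for (i in 2:length(k)) d[i] <- (a[i] - a[i - 1]) / a[i - 1]
  }
  setNames(d, as.character(k))
}

#' Choose the number of clusters from a consensus result
#'
#' Two selection rules over the per-k consensus matrices:
#'
#' * `"pac"` (default): minimize the proportion of ambiguous clustering —
#'   the fraction of off-diagonal consensus entries strictly inside
#'   `(pac_lower, pac_upper)`. A k that fits the data drives consensus
#'   entries to 0 or 1, so its PAC is near zero; both merging and
#'   splitting real clusters leave intermediate entries behind. PAC is
#'   the standard refinement of the delta-area rule, whose first term
#'   (`A(k_min)` itself, an absolute area rather than a relative change)
#'   systematically favors the smallest k.
#' * `"delta-area"`: maximize the relative change in area under the
#'   consensus CDF, `(A(k) - A(k-1)) / A(k-1)` (and `A(k_min)` for the
#'   smallest k).
#'
#' Ties go to the smaller k under the delta-area rule. Under PAC they go
#' to the larger k: when a fine partition is perfectly stable, coarser
#' merges of it are stable too, so among equally unambiguous k the
#' finest one carries the information.
#'
#' @param result A `consensus_result` from [consensus_cluster()].
#' @param method `"pac"` or `"delta-area"`.
#' @param pac_lower,pac_upper Ambiguity window for PAC (defaults 0.1 and
#'   0.9).
#' @return The chosen k (integer).
#' @export
select_k <- function(result, method = c("pac", "delta-area"),
                     pac_lower = 0.1, pac_upper = 0.9) {
  method <- match.arg(method)
  if (method == "delta-area") {
    d <- result$delta_area %||% delta_area(result)
    return(result$k_range[which.max(d)])
  }
  pac <- vapply(result$consensus, function(M) {
    m <- M[upper.tri(M)]
    mean(m > pac_lower & m < pac_upper)
  }, 0)
  result$k_range[max(which(pac == min(pac)))]
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result: %d genes, k in {%s}, %d reps, chosen k = %d>\n",
    nrow(x$assignments), paste(range(x$k_range), collapse = ".."),
    x$reps, x$chosen_k))
  invisible(x)
}

#' Tidy a consensus result into gene assignments
#'
#' @param x A `consensus_result`.
#' @param k Which k to report (default the chosen k).
#' @param ... Unused.
#' @return Tibble: `gene`, `cluster`.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, k = x$chosen_k, ...) {
  tibble(gene = x$assignments$gene,
         cluster = x$assignments[[sprintf("k%d", k)]])
}

#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(chosen_k = x$chosen_k,
         reps = x$reps,
         subsample_frac = x$subsample_frac,
         never_cosampled_pairs = x$never_cosampled,
         max_delta_area = max(x$delta_area))
}

#' Co-expression network from a consensus matrix
#'
#' Thresholds the consensus matrix at the chosen k: gene pairs whose
#' consensus (co-clustering frequency) is at least `threshold` become
#' weighted undirected edges.
#'
#' @param result A `consensus_result`.
#' @param threshold Consensus threshold in (0, 1\] (default 0.5).
#' @param k Which k's matrix to use (default the chosen k).
#' @return A `gene_network`: list with `nodes` (tibble: `node`) and
#'   `edges` (tibble: `from`, `to`, `weight`).
#' @export
consensus_network <- function(result, threshold = 0.5, k = result$chosen_k) {
  M <- result$consensus[[as.character(k)]]
  idx <- which(upper.tri(M) & M >= threshold, arr.ind = TRUE)
  edges <- tibble(
    from = rownames(M)[idx[, 1]],
    to = colnames(M)[idx[, 2]],
    weight = M[idx]
  )
  gene_network(nodes = tibble(node = rownames(M)), edges = edges)
}

gene_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a gene network to an igraph graph
#'
#' @param net A `gene_network`.
#' @return An [igraph::graph] (undirected, weighted).
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Read a STRING-style protein interaction edge list
#'
#' Reads a tab- or space-separated file with columns `protein1`,
#' `protein2`, `combined_score` (STRING convention, scores 0-1000,
#' rescaled to \[0, 1\]), drops self-loops, collapses duplicate
#' (unordered) pairs keeping the maximum score, and filters by minimum
#' score. Duplicate and self-loop counts are reported via attributes
#' `dropped_duplicates` / `dropped_self_loops`.
#'
#' @param path Path to the edge-list file.
#' @param score_min Minimum rescaled score in \[0, 1\] (edges with
#'   `weight >= score_min` are kept; default 0.4, STRING's "medium
#'   confidence").
#' @return A `gene_network`.
#' @export
ppi_ingest <- function(path, score_min = 0.4) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(raw))) {
    abort(sprintf("edge list must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  edges <- tibble(
    from = as.character(raw$protein1),
    to = as.character(raw$protein2),
    weight = as.numeric(raw$combined_score) / 1000
  )
  n0 <- nrow(edges)
  edges <- dplyr::filter(edges, .data$from != .data$to)
  n_self <- n0 - nrow(edges)
  # canonical unordered pair
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  n1 <- nrow(edges)
  edges <- edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop")
  n_dup <- n1 - nrow(edges)
  edges <- dplyr::filter(edges, .data$weight >= score_min)
  nodes <- tibble(node = sort(unique(c(edges$from, edges$to))))
  net <- gene_network(nodes = nodes, edges = edges)
  attr(net, "dropped_duplicates") <- n_dup
  attr(net, "dropped_self_loops") <- n_self
  net
}

#' Network topology summaries
#'
#' Per-node degree and connected-component membership, plus whole-network
#' density (realized edges over possible edges among the listed nodes).
#'
#' @param net A `gene_network`.
#' @return A list: `nodes` (tibble: `node`, `degree`, `component`),
#'   `density`, `n_components`.
#' @export
network_topology <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  nodes <- tibble(
    node = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    component = as.integer(comp$membership)
  )
  n <- nrow(nodes)
  density <- if (n < 2) 0 else nrow(net$edges) / choose(n, 2)
  list(nodes = nodes, density = density, n_components = comp$no)
}

#' Write a gene network as GraphML
#'
#' @param net A `gene_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a gene network as an edge-list TSV
#'
#' @param net A `gene_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each GMT line is tab-separated: set name, description, then member
#' gene ids.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble: `set`, `description`, `genes` (list column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  tibble(
    set = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the selected genes overlap the set
#' more than expected under random draws from the universe: the p-value
#' is the upper hypergeometric tail `P(X >= overlap)` with universe size
#' `N`, set size `K` and selection size `n`. BH correction is applied
#' across sets. Set members outside the universe are ignored (and
#' counted in `outside_universe`).
#'
#' @param selected Character vector of selected gene ids (e.g. from
#'   [de_filter()]).
#' @param sets A named list of character vectors, or a GMT tibble from
#'   [read_gmt()].
#' @param universe Character vector of all eligible gene ids; defaults
#'   to the union of the sets and the selection.
#' @return A tibble: `set`, `set_size`, `overlap`, `p`, `fdr`,
#'   `outside_universe`, sorted by `p`.
#' @examples
#' hypergeom_ora(c("a", "b"), list(s1 = c("a", "b", "c")),
#'               universe = letters[1:10])
#' @export
hypergeom_ora <- function(selected, sets, universe = NULL) {
  if (is.data.frame(sets)) {
    sets <- setNames(sets$genes, sets$set)
  }
  if (is.null(universe)) {
    universe <- unique(c(unlist(sets), selected))
  }
  universe <- unique(universe)
  sel <- unique(intersect(selected, universe))
  n <- length(sel)
  N <- length(universe)
  rows <- purrr::imap(sets, function(members, name) {
    outside <- length(setdiff(unique(members), universe))
    members <- intersect(unique(members), universe)
    K <- length(members)
    k <- length(intersect(sel, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = name, set_size = K, overlap = k, p = p,
           outside_universe = outside)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_fdr(out$p)
  dplyr::arrange(out[, c("set", "set_size", "overlap", "p", "fdr",
                         "outside_universe")], .data$p)
}
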