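test_that("consensus matrices are valid, reproducible and block-perfect", {
  # two widely separated profile patterns (offsets on a minority of
  # coordinates, so median centering keeps them apart): consensus is
  # exactly 1 within and 0 between at k = 2
  mu1 <- c(50, 0, 0, 0, 0)
  mu2 <- c(0, 50, 0, 0, 0)
  prof <- rbind(
    matrix(rnorm(10 * 5, 0, 0.1), 10, 5) + rep(mu1, each = 10),
    matrix(rnorm(10 * 5, 0, 0.1), 10, 5) + rep(mu2, each = 10))
  rownames(prof) <- sprintf("g%02d", 1:20)
  cc <- consensus_cluster(prof, k_range = 2, reps = 20,
                          subsample_frac = 0.8, seed = 5)
  M <- cc$consensus[["2"]]
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, 20))
  expect_true(all(M >= 0 & M <= 1))
  blk <- rep(1:2, each = 10)
  expect_true(all(M[outer(blk, blk, "==")] == 1))
  expect_true(all(M[outer(blk, blk, "!=")] == 0))
  # bit-for-bit reproducible under a fixed seed
  cc2 <- consensus_cluster(prof, k_range = 2, reps = 20,
                           subsample_frac = 0.8, seed = 5)
  expect_identical(cc$consensus, cc2$consensus)
  # single rep without subsampling gives a hard partition
  cc1 <- consensus_cluster(prof, k_range = 2, reps = 1,
                           subsample_frac = 1, seed = 1)
  expect_true(all(cc1$consensus[["2"]] %in% c(0, 1)))
  expect_equal(cc1$never_cosampled, 0)
})

test_that("consensus clustering is invariant to per-gene constant shifts", {
  sim <- simulate_cluster_profiles(n_genes = 30, seed = 8)
  prof <- as.matrix(sim$profiles[, -1])
  rownames(prof) <- sim$profiles$gene
  shifted <- prof + runif(nrow(prof), -100, 100)  # removed by median centering
  cc_a <- consensus_cluster(prof, k_range = 2:4, reps = 10, seed = 3)
  cc_b <- consensus_cluster(shifted, k_range = 2:4, reps = 10, seed = 3)
  expect_identical(cc_a$consensus, cc_b$consensus)
})

test_that("consensus clustering validates its inputs", {
  prof <- matrix(rnorm(40), 10, 4)
  expect_error(consensus_cluster(prof, k_range = 2:10), "more genes")
  expect_error(consensus_cluster(prof, k_range = 2:8,
                                 subsample_frac = 0.8),
               "subsample too small")
})

test_that("select_k recovers a planted k and honors both methods", {
  ok <- 0
  for (s in 1:5) {
    sim <- simulate_cluster_profiles(seed = s)
    cc <- consensus_cluster(sim$profiles, k_range = 2:6, reps = 30,
                            subsample_frac = 0.8, seed = s + 50)
    ok <- ok + (cc$chosen_k == 3)
    expect_equal(select_k(cc), cc$chosen_k)
    expect_true(select_k(cc, method = "delta-area") %in% cc$k_range)
  }
  expect_gte(ok, 4)
})

test_that("consensus networks threshold the matrix exactly", {
  mu1 <- c(50, 0, 0, 0, 0)
  mu2 <- c(0, 50, 0, 0, 0)
  prof <- rbind(
    matrix(rnorm(6 * 5, 0, 0.1), 6, 5) + rep(mu1, each = 6),
    matrix(rnorm(6 * 5, 0, 0.1), 6, 5) + rep(mu2, each = 6))
  rownames(prof) <- sprintf("g%02d", 1:12)
  cc <- consensus_cluster(prof, k_range = 2, reps = 10,
                          subsample_frac = 0.9, seed = 2)
  net <- consensus_network(cc, threshold = 1.0, k = 2)
  # two 6-cliques
  expect_equal(nrow(net$edges), 2 * choose(6, 2))
  topo <- network_topology(net)
  expect_equal(topo$n_components, 2)
  expect_true(all(topo$nodes$degree == 5))
  # a threshold above 1 leaves no edges
  expect_equal(nrow(consensus_network(cc, threshold = 1.1, k = 2)$edges), 0)
  # edge count equals a brute-force scan of the matrix
  M <- cc$consensus[["2"]]
  for (thr in c(0.3, 0.5, 0.8)) {
    expect_equal(nrow(consensus_network(cc, threshold = thr, k = 2)$edges),
                 sum(M[upper.tri(M)] >= thr))
  }
})

test_that("ppi_ingest deduplicates, drops self-loops and filters", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t900",
               "B\tA\t700",     # duplicate (reversed), lower score
               "A\tA\t999",     # self-loop
               "B\tC\t500",
               "C\tD\t300"),    # below the 0.4 cutoff
             path)
  net <- ppi_ingest(path, score_min = 0.4)
  expect_equal(nrow(net$edges), 2)
  expect_equal(attr(net, "dropped_duplicates"), 1)
  expect_equal(attr(net, "dropped_self_loops"), 1)
  expect_equal(net$edges$weight[net$edges$from == "A"], 0.9)
  # hand count at a permissive threshold
  expect_equal(nrow(ppi_ingest(path, score_min = 0)$edges), 3)
})

test_that("network topology matches hand values and a union-find oracle", {
  tri <- fluxdiff:::gene_network(
    nodes = tibble::tibble(node = c("a", "b", "c")),
    edges = tibble::tibble(from = c("a", "a", "b"),
                           to = c("b", "c", "c"),
                           weight = 1))
  topo <- network_topology(tri)
  expect_equal(topo$nodes$degree, c(2, 2, 2))
  expect_equal(topo$density, 1)
  expect_equal(topo$n_components, 1)

  empty <- fluxdiff:::gene_network(
    nodes = tibble::tibble(node = c("a", "b")),
    edges = tibble::tibble(from = character(), to = character(),
                           weight = numeric()))
  expect_equal(network_topology(empty)$density, 0)

  # random graphs against a union-find oracle
  union_find_components <- function(n, edges) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (j in seq_len(nrow(edges))) {
      a <- find(edges[j, 1]); b <- find(edges[j, 2])
      if (a != b) parent[a] <- b
    }
    length(unique(vapply(seq_len(n), find, 0L)))
  }
  set.seed(71)
  for (rep_i in 1:5) {
    n <- 50
    m_edges <- 40
    ij <- cbind(sample.int(n, m_edges, replace = TRUE),
                sample.int(n, m_edges, replace = TRUE))
    ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    nodes <- sprintf("n%02d", 1:n)
    net <- fluxdiff:::gene_network(
      nodes = tibble::tibble(node = nodes),
      edges = tibble::tibble(from = nodes[ij[, 1]], to = nodes[ij[, 2]],
                             weight = 1))
    expect_equal(network_topology(net)$n_components,
                 union_find_components(n, ij))
  }
})

test_that("read_gmt parses sets and flags short lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst set\tg1\tg2\tg3",
               "setB\tsecond set\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_equal(sets$set, c("setA", "setB"))
  expect_equal(sets$genes[[1]], c("g1", "g2", "g3"))
  writeLines("broken\tonly-two-fields", path)
  expect_error(read_gmt(path), "fewer than 3")
})

test_that("hypergeometric ORA matches hand values and behaves sensibly", {
  universe <- sprintf("g%02d", 1:20)
  # all five selected genes inside a five-gene set: p = 1 / C(20, 5)
  res <- hypergeom_ora(universe[1:5], list(s = universe[1:5]),
                       universe = universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap: P(X >= 0) = 1
  res0 <- hypergeom_ora(universe[6:10], list(s = universe[1:5]),
                        universe = universe)
  expect_equal(res0$p, 1)
  # p decreases monotonically in the overlap for fixed N, K, n
  ps <- vapply(0:5, function(k) {
    sel <- c(universe[seq_len(k)], universe[10 + seq_len(5 - k)])
    hypergeom_ora(sel, list(s = universe[1:5]), universe = universe)$p
  }, 0)
  expect_true(all(diff(ps) < 0))
  # invariant to gene-id relabeling
  relabel <- setNames(sprintf("x%02d", 1:20), universe)
  res_rel <- hypergeom_ora(relabel[universe[1:4]],
                           list(s = relabel[universe[1:5]]),
                           universe = unname(relabel))
  res_orig <- hypergeom_ora(universe[1:4], list(s = universe[1:5]),
                            universe = universe)
  expect_equal(res_rel$p, res_orig$p, tolerance = 1e-12)
})

test_that("ORA p-values equal full enumeration for small universes", {
  set.seed(83)
  for (rep_i in 1:15) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    universe <- sprintf("u%02d", seq_len(N))
    members <- universe[seq_len(K)]
    sel <- sample(universe, n)
    k <- length(intersect(sel, members))
    p_pkg <- hypergeom_ora(sel, list(s = members), universe = universe)$p
    expect_equal(p_pkg, hyper_oracle_p(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("ORA reports members outside the declared universe", {
  res <- hypergeom_ora(c("a", "b"), list(s = c("a", "b", "zzz")),
                       universe = c("a", "b", "c", "d"))
  expect_equal(res$outside_universe, 1)
  expect_equal(res$set_size, 2)
})

test_that("network writers emit edge-list TSV and GraphML", {
  net <- fluxdiff:::gene_network(
    nodes = tibble::tibble(node = c("a", "b")),
    edges = tibble::tibble(from = "a", to = "b", weight = 0.7))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_tsv(net, tsv)
  expect_equal(readr::read_tsv(tsv, show_col_types = FALSE)$weight, 0.7)
  write_network_graphml(net, gml)
  expect_match(readLines(gml, n = 2), "graphml", all = FALSE)
})
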