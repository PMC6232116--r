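# Independent oracles and small fixture builders shared across tests.

# Brute-force clique percolation: enumerate every k-subset that is a clique,
# link two k-cliques when they share k-1 vertices, take connected components.
brute_force_cpm <- function(g, k) {
  n <- igraph::vcount(g)
  if (n < k) return(list())
  adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  diag(adj) <- TRUE
  combos <- utils::combn(n, k)
  is_clique <- apply(combos, 2L, function(v) all(adj[v, v]))
  kc <- combos[, is_clique, drop = FALSE]
  m <- ncol(kc)
  if (m == 0L) return(list())
  edges <- integer(0)
  if (m > 1L) {
    for (a in seq_len(m - 1L)) {
      for (b in seq(a + 1L, m)) {
        if (length(intersect(kc[, a], kc[, b])) >= k - 1L) {
          edges <- c(edges, a, b)
        }
      }
    }
  }
  cg <- igraph::make_graph(edges, n = m, directed = FALSE)
  comp <- igraph::components(cg)$membership
  name <- igraph::V(g)$name
  comms <- lapply(split(seq_len(m), comp), function(ix) {
    sort(unique(name[as.vector(kc[, ix])]))
  })
  unname(comms)
}

# canonical form of a community list for set comparison
comm_key <- function(communities) {
  unname(sort(vapply(communities, function(cm) paste(sort(cm), collapse = ","),
                     character(1L))))
}

# Exhaustive hypergeometric: success counts over all C(N, n) draws.
enum_hypergeom_hits <- function(N, K, n) {
  if (n == 0L) return(0L)
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  apply(draws, 2L, function(ix) sum(pop[ix]))
}

enum_hypergeom_upper <- function(N, K, n, k_obs) {
  if (n == 0L) return(as.numeric(k_obs <= 0))
  mean(enum_hypergeom_hits(N, K, n) >= k_obs)
}

# small labelled graph from an edge string like "A-B,B-C"
graph_from_edges <- function(edge_string, confidence = 1) {
  pairs <- strsplit(strsplit(edge_string, ",", fixed = TRUE)[[1L]], "-",
                    fixed = TRUE)
  a <- vapply(pairs, `[`, "", 1L)
  b <- vapply(pairs, `[`, "", 2L)
  make_network(a, b, rep_len(confidence, length(a)))
}

# consensus-table-shaped data frame from an ordered gene vector
toy_consensus <- function(genes) {
  n <- length(genes)
  data.frame(gene = toupper(genes),
             n_methods = rep(1L, n), mean_genen = rep(1, n),
             gene_score = (n - seq_len(n)) / (n - 1),
             rank = seq_len(n),
             consen_score = (n - seq_len(n)) / (n - 1),
             stringsAsFactors = FALSE)
}
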