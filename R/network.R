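#' Filter an interaction network by edge confidence
#'
#' Removes edges below the confidence cutoff and drops nodes left without
#' neighbors ("zero node addition": nothing is ever added). Node and edge
#' counts before and after are reported via `message()`.
#'
#' @param network An igraph with edge attribute `confidence`.
#' @param cutoff Minimum confidence retained, in \[0, 1\].
#' @return The filtered igraph.
#' @export
filter_network <- function(network, cutoff = 0.9) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  n0 <- igraph::vcount(network); e0 <- igraph::ecount(network)
  g <- igraph::delete_edges(
    network, igraph::E(network)[igraph::E(network)$confidence < cutoff])
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  message(sprintf("confidence filter %.2f: %d -> %d nodes, %d -> %d edges",
                  cutoff, n0, igraph::vcount(g), e0, igraph::ecount(g)))
  if (igraph::vcount(g) == 0L) {
    warning("no edge reaches the confidence cutoff; the network is empty")
  }
  g
}

#' k-clique percolation communities
#'
#' A community is the union of all k-cliques reachable from one another
#' through adjacent k-cliques, where two k-cliques are adjacent when they
#' share k-1 nodes. Implemented via exact maximal-clique enumeration: all
#' maximal cliques of size >= k are found, two maximal cliques are linked
#' when they share at least k-1 nodes (every k-clique within one maximal
#' clique is mutually reachable), and communities are the vertex unions of
#' the connected components of that clique graph. Output order is
#' deterministic: by decreasing size, then by the lexicographically
#' smallest member.
#'
#' @param network An igraph.
#' @param k Clique order, an integer >= 3.
#' @return An object of class `"community_set"`: a list with `k`,
#'   `communities` (list of sorted gene vectors), `sizes`,
#'   `n_communities` and `s_index` (see [s_index()]; `NA` when no
#'   community exists).
#' @export
k_clique_communities <- function(network, k) {
  if (length(k) != 1L || k < 3 || k != round(k)) {
    stop("k must be a single integer >= 3")
  }
  k <- as.integer(k)
  cliques <- igraph::max_cliques(network, min = k)
  if (length(cliques) == 0L) {
    return(structure(list(k = k, communities = list(), sizes = integer(),
                          n_communities = 0L, s_index = NA_real_),
                     class = "community_set"))
  }
  m <- length(cliques)
  vert <- unlist(lapply(cliques, as.integer), use.names = FALSE)
  lens <- lengths(cliques)
  inc <- Matrix::sparseMatrix(
    i = rep.int(seq_len(m), lens), j = vert, x = 1,
    dims = c(m, igraph::vcount(network)))
  ov <- Matrix::tcrossprod(inc)  # pairwise shared-vertex counts
  adj <- (ov >= (k - 1)) * 1    # k-1 >= 2, so the comparison stays sparse
  cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(cg)$membership
  name <- igraph::V(network)$name
  communities <- lapply(split(seq_len(m), comp), function(ix) {
    sort(unique(name[unlist(lapply(cliques[ix], as.integer),
                            use.names = FALSE)]))
  })
  ord <- order(-lengths(communities),
               vapply(communities, `[`, character(1L), 1L))
  communities <- unname(communities[ord])
  sizes <- lengths(communities)
  structure(list(k = k, communities = communities, sizes = sizes,
                 n_communities = length(communities),
                 s_index = s_index(sizes)),
            class = "community_set")
}

#' @export
print.community_set <- function(x, ...) {
  cat(sprintf("<community_set> k = %d: %d communities, sizes [%s], S = %s\n",
              x$k, x$n_communities,
              paste(head(x$sizes, 10L), collapse = ", "),
              format(x$s_index, digits = 4)))
  invisible(x)
}

#' Community size-balance index
#'
#' `S^k = |mean(sizes) - median(sizes)| / n_communities`. A small value
#' indicates a balanced distribution of genes across communities; both very
#' small and very large clique orders inflate it. The median of an
#' even-length list is the midpoint of the central pair.
#'
#' @param sizes Integer vector of community sizes.
#' @param n_communities Number of communities (defaults to
#'   `length(sizes)`).
#' @return The balance index, a non-negative number.
#' @export
s_index <- function(sizes, n_communities = length(sizes)) {
  if (length(sizes) == 0L || n_communities < 1L) {
    stop("the balance index is undefined without communities")
  }
  abs(mean(sizes) - stats::median(sizes)) / n_communities
}

#' Select the clique order k by the balance index
#'
#' Runs [k_clique_communities()] for every k in `k_range`, skips orders
#' that yield no community, and returns the k minimizing [s_index()]. Ties
#' are broken toward the larger k (fewer, tighter communities).
#'
#' @param network An igraph.
#' @param k_range Integer vector of candidate clique orders (all >= 3).
#' @return A list: `best_k`, `best` (the winning `community_set`), and
#'   `table` (data.frame `k`, `n_communities`, `s_index`, including the
#'   skipped orders with zero communities).
#' @export
select_k <- function(network, k_range = 3:12) {
  stopifnot(length(k_range) >= 1L)
  k_range <- sort(unique(as.integer(k_range)))
  sets <- lapply(k_range, function(k) k_clique_communities(network, k))
  tab <- data.frame(
    k = k_range,
    n_communities = vapply(sets, `[[`, integer(1L), "n_communities"),
    s_index = vapply(sets, `[[`, numeric(1L), "s_index"))
  ok <- which(tab$n_communities > 0L)
  if (length(ok) == 0L) stop("no k in k_range yields any community")
  # argmin of S; ties toward larger k
  best_ix <- ok[order(tab$s_index[ok], -tab$k[ok])][1L]
  list(best_k = tab$k[best_ix], best = sets[[best_ix]], table = tab)
}

#' Upper-tail hypergeometric probability
#'
#' Exact `P(X >= k_obs)` when drawing `n` items without replacement from a
#' population of `N` containing `K` successes. Terms are summed in log
#' space for numerical stability.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Sample size.
#' @param k_obs Observed successes in the sample.
#' @return The upper-tail p-value in (0, 1\].
#' @export
hypergeom_test <- function(N, K, n, k_obs) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N,
            k_obs >= 0, k_obs <= n)
  k_lo <- max(0, n + K - N)  # smallest attainable count
  if (k_obs <= k_lo) return(1)
  support <- k_obs:min(n, K)
  if (length(support) == 0L || k_obs > min(n, K)) return(0)
  lt <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Profile communities against the consensus and the network
#'
#' Per community: member genes, mean consensus score and rank, mean degree
#' in the full filtered network, pathogenic count and ratio, and an
#' upper-tail hypergeometric enrichment p-value with the network's node
#' set as population and the pathogenic genes present in the network as
#' successes.
#'
#' @param communities A `community_set` (or plain list of gene vectors).
#' @param consensus A consensus table from [consensus_table()].
#' @param network The filtered igraph the communities were detected in.
#' @param pathogenic A [pathogenic_gene_sets()] or character vector.
#' @return A `data.frame` with one row per community: `community`, `size`,
#'   `genes` (comma-separated), `mean_consen_score`, `mean_rank`,
#'   `mean_degree`, `n_pathogenic`, `pathogenic_ratio`, `hpt_p`.
#' @export
community_profiles <- function(communities, consensus, network, pathogenic) {
  comms <- if (inherits(communities, "community_set")) communities$communities
           else communities
  truth <- if (inherits(pathogenic, "pathogenic_sets")) pathogenic$union
           else unique(toupper(pathogenic))
  deg <- igraph::degree(network)
  nodes <- igraph::V(network)$name
  pop_n <- length(nodes)
  pop_k <- sum(nodes %in% truth)
  cons_score <- stats::setNames(consensus$consen_score, consensus$gene)
  cons_rank <- stats::setNames(consensus$rank, consensus$gene)
  rows <- lapply(seq_along(comms), function(i) {
    genes <- comms[[i]]
    in_cons <- genes[genes %in% names(cons_score)]
    if (length(in_cons) < length(genes)) {
      warning(sprintf(
        "community %d: %d gene(s) missing from the consensus table excluded from means",
        i, length(genes) - length(in_cons)))
    }
    n_path <- sum(genes %in% truth)
    data.frame(
      community = i, size = length(genes),
      genes = paste(genes, collapse = ","),
      mean_consen_score = if (length(in_cons)) mean(cons_score[in_cons]) else NA_real_,
      mean_rank = if (length(in_cons)) mean(cons_rank[in_cons]) else NA_real_,
      mean_degree = mean(deg[genes[genes %in% nodes]]),
      n_pathogenic = n_path,
      pathogenic_ratio = n_path / length(genes),
      hpt_p = hypergeom_test(pop_n, pop_k, sum(genes %in% nodes), n_path),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutation test of mean degree between a gene group and the rest
#'
#' Tests whether the group's mean degree exceeds the complement's by
#' permuting group labels over the network's nodes. One-sided p-value
#' `(1 + #{permuted diff >= observed}) / (n_perm + 1)`.
#'
#' @param network An igraph.
#' @param group Character vector of gene symbols (the putative high-degree
#'   group).
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed.
#' @return A list: `mean_in`, `mean_out`, `observed_diff`, `p`.
#' @export
degree_group_comparison <- function(network, group, n_perm = 999L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(.substream(seed, "permutation"))
  deg <- igraph::degree(network)
  in_group <- names(deg) %in% unique(toupper(group))
  if (!any(in_group)) stop("the group has no gene in the network")
  if (all(in_group)) stop("the group covers every network node")
  obs <- mean(deg[in_group]) - mean(deg[!in_group])
  n_in <- sum(in_group)
  perm <- vapply(seq_len(n_perm), function(i) {
    lab <- sample(deg, n_in)
    (sum(lab) / n_in) - ((sum(deg) - sum(lab)) / (length(deg) - n_in))
  }, numeric(1L))
  list(mean_in = mean(deg[in_group]),
       mean_out = mean(deg[!in_group]),
       observed_diff = obs,
       p = (1 + sum(perm >= obs)) / (n_perm + 1))
}
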