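test_that("confidence filtering removes weak edges and isolated nodes, never adds", {
  g <- make_network(c("A", "B"), c("B", "C"), c(0.95, 0.5))
  suppressMessages(f <- filter_network(g, 0.9))
  expect_setequal(igraph::V(f)$name, c("A", "B"))
  expect_equal(igraph::ecount(f), 1L)

  suppressMessages(id <- filter_network(g, 0))
  expect_equal(igraph::ecount(id), 2L)

  suppressMessages(expect_warning(empty <- filter_network(g, 0.99), "empty"))
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("clique percolation handles the canonical small cases", {
  k5 <- graph_from_edges(paste(apply(utils::combn(LETTERS[1:5], 2), 2,
                                     paste, collapse = "-"), collapse = ","))
  cpm <- k_clique_communities(k5, 3)
  expect_equal(cpm$n_communities, 1L)
  expect_setequal(cpm$communities[[1]], LETTERS[1:5])

  # two triangles sharing one node: separate communities
  shared_node <- graph_from_edges("A-B,B-C,C-A,C-D,D-E,E-C")
  cpm2 <- k_clique_communities(shared_node, 3)
  expect_equal(cpm2$n_communities, 2L)
  expect_identical(comm_key(cpm2$communities),
                   comm_key(list(c("A", "B", "C"), c("C", "D", "E"))))
  expect_identical(comm_key(cpm2$communities),
                   comm_key(brute_force_cpm(shared_node, 3)))

  # two triangles sharing an edge: one 4-node community
  shared_edge <- graph_from_edges("A-B,B-C,C-A,B-D,D-C")
  cpm3 <- k_clique_communities(shared_edge, 3)
  expect_equal(cpm3$n_communities, 1L)
  expect_setequal(cpm3$communities[[1]], c("A", "B", "C", "D"))
  expect_identical(comm_key(cpm3$communities),
                   comm_key(brute_force_cpm(shared_edge, 3)))

  expect_error(k_clique_communities(k5, 2), "k must be")
})

test_that("clique percolation equals brute force on random graphs", {
  set.seed(404)
  for (i in 1:30) {
    n <- sample(6:14, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.7))
    igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
    for (k in 3:5) {
      got <- k_clique_communities(g, k)
      expect_identical(comm_key(got$communities),
                       comm_key(brute_force_cpm(g, k)),
                       label = sprintf("graph %d, k = %d", i, k))
      expect_true(all(got$sizes >= k))
    }
  }
})

test_that("the balance index is |mean - median| over the community count", {
  expect_equal(s_index(c(4, 4, 4)), 0)
  expect_equal(s_index(c(3, 3, 9)), 2 / 3)
  expect_equal(s_index(c(2, 4, 6, 20)), abs(8 - 5) / 4)  # even-count median
  expect_equal(s_index(c(5, 7)), 0)                      # midpoint convention
  expect_error(s_index(integer()), "undefined")
})

test_that("k selection minimizes the balance index, ties toward larger k", {
  k6 <- graph_from_edges(paste(apply(utils::combn(LETTERS[1:6], 2), 2,
                                     paste, collapse = "-"), collapse = ","))
  sel <- select_k(k6, 3:6)
  expect_equal(sel$best_k, 6L)
  expect_true(all(sel$table$s_index[sel$table$n_communities > 0] == 0))

  # k values with zero communities are skipped, not selected
  tri <- graph_from_edges("A-B,B-C,C-A")
  sel2 <- select_k(tri, 3:5)
  expect_equal(sel2$best_k, 3L)
  expect_equal(sel2$table$n_communities, c(1L, 0L, 0L))
  expect_error(select_k(tri, 4:5), "no k")
})

test_that("the hypergeometric upper tail is exact", {
  expect_equal(hypergeom_test(10, 5, 4, 0), 1.0)
  expect_equal(hypergeom_test(10, 5, 4, 3), 55 / 210)
  # boundary: all draws are successes -> single term C(K,n)/C(N,n)
  expect_equal(hypergeom_test(10, 5, 4, 4), choose(5, 4) / choose(10, 4))
  expect_error(hypergeom_test(10, 11, 4, 2))
  expect_error(hypergeom_test(10, 5, 4, 5))
  # cross-check against the distribution function on larger parameters
  set.seed(99)
  for (i in 1:25) {
    N <- sample(50:500, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k_obs <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_test(N, K, n, k_obs),
                 stats::phyper(k_obs - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("community profiles report consensus, degree and enrichment per community", {
  g <- graph_from_edges("A-B,B-C,C-A,C-D,D-E,E-C")
  tab <- toy_consensus(c("A", "B", "C", "D", "E"))
  cpm <- k_clique_communities(g, 3)
  prof <- community_profiles(cpm, tab, g, pathogenic = c("A", "B"))
  expect_equal(nrow(prof), 2L)
  abc <- prof[grepl("A", prof$genes), ]
  expect_equal(abc$n_pathogenic, 2L)
  expect_equal(abc$mean_rank, 2)           # ranks 1, 2, 3
  expect_equal(abc$mean_degree, mean(c(2, 2, 4)))
  # enrichment p from the network background (5 nodes, 2 successes, draw 3)
  expect_equal(abc$hpt_p, enum_hypergeom_upper(5, 2, 3, 2))
  cde <- prof[grepl("E", prof$genes), ]
  expect_equal(cde$n_pathogenic, 0L)
  expect_equal(cde$hpt_p, 1.0)

  tab2 <- toy_consensus(c("A", "B", "C", "D"))  # E missing from consensus
  expect_warning(prof2 <- community_profiles(cpm, tab2, g, c("A", "B")),
                 "missing from the consensus")
  cde2 <- prof2[grepl("E", prof2$genes), ]
  expect_equal(cde2$mean_rank, mean(c(3, 4)))   # mean over C, D only
})

test_that("the degree permutation test behaves under the null and on a star", {
  set.seed(7)
  # two groups with identical degree distributions: p near 0.5
  g <- igraph::sample_gnp(60, 0.2)
  igraph::V(g)$name <- sprintf("V%02d", 1:60)
  res <- degree_group_comparison(g, sprintf("V%02d", sample(1:60, 30)),
                                 n_perm = 499, seed = 3)
  expect_gt(res$p, 0.1)
  expect_lt(res$p, 0.9)

  # star: the hub is the unique maximal-difference labeling
  star <- make_network(rep("HUB", 20), sprintf("L%02d", 1:20), rep(1, 20))
  res2 <- degree_group_comparison(star, "HUB", n_perm = 199, seed = 3)
  expect_equal(res2$mean_in, 20)
  expect_equal(res2$mean_out, 1)
  expect_lt(res2$p, 0.2)

  expect_error(degree_group_comparison(star, c("HUB", sprintf("L%02d", 1:20))),
               "every network node")
  expect_error(degree_group_comparison(star, "NOPE"), "no gene")
})
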