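#' Specification of a synthetic pipeline input
#'
#' Defines the statistical structure of the generated inputs: ranked lists
#' in which pathogenic genes are shifted toward the top with effect size
#' `signal`, an interaction network with planted overlapping cliques plus
#' background noise, pathway catalogs aligned with the planted communities,
#' and an RSA sensitivity matrix with a controllable essential-gene rate.
#'
#' Defaults mirror the study conditions this pipeline models: a universe of
#' 20,000 genes, 145 pathogenic genes, 8 prioritization methods, and a
#' clique order of 9.
#'
#' @param n_genes Size of the gene universe.
#' @param n_pathogenic Number of pathogenic (truth-set) genes.
#' @param n_methods Number of simulated prioritization methods.
#' @param signal Latent-score shift (in standard deviations) added to
#'   pathogenic genes in every method. 0 means no enrichment.
#' @param coverage Fraction of the universe each method reports, in (0, 1].
#' @param n_communities Number of planted clique communities.
#' @param clique_size Size of each planted clique; must be at least the
#'   clique order used downstream.
#' @param overlap Number of genes shared by adjacent planted communities;
#'   must be smaller than `clique_size`.
#' @param background_edge_p Erdos-Renyi probability of a background edge
#'   between gene pairs outside the planted cliques.
#' @param n_pathways Number of simulated pathway gene sets.
#' @param pathway_size Genes per pathway.
#' @param n_cell_lines Number of cell lines in the sensitivity screen.
#' @param essential_rate Fraction of genes simulated as essential.
#' @param seed Integer seed; all generators derive per-stage substreams
#'   from it deterministically.
#' @return A validated list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_genes = 20000L,
                            n_pathogenic = 145L,
                            n_methods = 8L,
                            signal = 2,
                            coverage = 0.8,
                            n_communities = 10L,
                            clique_size = 9L,
                            overlap = 2L,
                            background_edge_p = 0.002,
                            n_pathways = 20L,
                            pathway_size = 15L,
                            n_cell_lines = 25L,
                            essential_rate = 0.05,
                            seed = 1L) {
  stopifnot(
    n_genes >= 2, n_pathogenic >= 1, n_pathogenic < n_genes,
    n_methods >= 1, signal >= 0,
    coverage > 0, coverage <= 1,
    n_communities >= 1, clique_size >= 3,
    overlap >= 0, overlap < clique_size,
    background_edge_p >= 0, background_edge_p < 1,
    n_pathways >= 0, pathway_size >= 2,
    n_cell_lines >= 1, essential_rate >= 0, essential_rate <= 1,
    abs(seed) < 2^31
  )
  structure(
    list(n_genes = as.integer(n_genes),
         n_pathogenic = as.integer(n_pathogenic),
         n_methods = as.integer(n_methods),
         signal = signal, coverage = coverage,
         n_communities = as.integer(n_communities),
         clique_size = as.integer(clique_size),
         overlap = as.integer(overlap),
         background_edge_p = background_edge_p,
         n_pathways = as.integer(n_pathways),
         pathway_size = as.integer(pathway_size),
         n_cell_lines = as.integer(n_cell_lines),
         essential_rate = essential_rate,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Gene universe of a simulation
#'
#' @param spec A [simulation_spec()].
#' @return Character vector `G00001 ... G<n_genes>`.
#' @export
gene_universe <- function(spec) {
  sprintf("G%05d", seq_len(spec$n_genes))
}

#' Simulate per-method ranked gene lists and the pathogenic truth sets
#'
#' Each method draws a latent score `standard normal + signal * pathogenic`,
#' reports a random `coverage` fraction of the universe, and ranks by
#' descending latent score. The pathogenic set is split 40/60 into G1/G2
#' (the split only matters for stratified reporting).
#'
#' @param spec A [simulation_spec()].
#' @return A list with `rankings` (list of [method_ranking()]), `pathogenic`
#'   (a [pathogenic_gene_sets()]) and `universe`.
#' @export
simulate_method_rankings <- function(spec) {
  set.seed(.substream(spec$seed, "rankings"))
  universe <- gene_universe(spec)
  pathogenic <- sample(universe, spec$n_pathogenic)
  n_g1 <- max(1L, round(0.4 * spec$n_pathogenic))
  sets <- pathogenic_gene_sets(g1 = pathogenic[seq_len(n_g1)],
                               g2 = pathogenic[-seq_len(n_g1)])
  is_path <- universe %in% pathogenic
  n_report <- round(spec$coverage * spec$n_genes)
  if (n_report < 2L) stop("coverage so low that a method reports < 2 genes")
  rankings <- lapply(seq_len(spec$n_methods), function(j) {
    latent <- rnorm(spec$n_genes) + spec$signal * is_path
    keep <- sort(sample.int(spec$n_genes, n_report))
    ord <- keep[order(-latent[keep])]
    method_ranking(sprintf("method_%02d", j), universe[ord],
                   raw_score = latent[ord])
  })
  names(rankings) <- vapply(rankings, `[[`, "", "method_id")
  list(rankings = rankings, pathogenic = sets, universe = universe)
}

# map 1-based pair indices to 0-based (i, j) over the upper triangle of an
# n x n symmetric matrix, with a correction pass for sqrt rounding
.pair_from_index <- function(k, n) {
  k0 <- k - 1
  i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * k0)) / 2)
  off <- i * (2 * n - i - 1) / 2
  too_high <- off > k0
  i[too_high] <- i[too_high] - 1
  off <- i * (2 * n - i - 1) / 2
  too_low <- k0 - off >= n - 1 - i
  i[too_low] <- i[too_low] + 1
  off <- i * (2 * n - i - 1) / 2
  j <- k0 - off + i + 1
  cbind(i, j)
}

#' Simulate an interaction network with planted clique communities
#'
#' Plants `n_communities` cliques of `clique_size` genes arranged in a
#' chain, adjacent cliques sharing `overlap` genes. Planted edges receive
#' confidences in `[conf_min, 1]`; background edges appear between the
#' remaining pairs with probability `background_edge_p` and confidences
#' uniform in \[0.4, 1\].
#'
#' @param spec A [simulation_spec()].
#' @param genes Character vector of gene symbols to build the network over.
#' @param conf_min Lower confidence bound of planted edges (default 0.9, so
#'   planted structure survives the highest-confidence filter).
#' @return An igraph with edge attribute `confidence` and a
#'   `planted` attribute: the list of planted community gene sets.
#' @export
simulate_network <- function(spec, genes, conf_min = 0.9) {
  set.seed(.substream(spec$seed, "network"))
  genes <- unique(toupper(genes))
  n <- length(genes)
  cs <- spec$clique_size
  need <- cs * spec$n_communities - spec$overlap * (spec$n_communities - 1L)
  if (need > n) {
    stop(sprintf("planted layout needs %d distinct genes but only %d supplied",
                 need, n))
  }
  pool <- sample(genes)
  planted <- vector("list", spec$n_communities)
  used <- 0L
  for (i in seq_len(spec$n_communities)) {
    if (i == 1L) {
      planted[[i]] <- pool[seq_len(cs)]
      used <- cs
    } else {
      shared <- if (spec$overlap > 0L) {
        planted[[i - 1L]][seq(cs - spec$overlap + 1L, cs)]
      } else character()
      fresh <- pool[used + seq_len(cs - spec$overlap)]
      used <- used + cs - spec$overlap
      planted[[i]] <- c(shared, fresh)
    }
  }
  names(planted) <- sprintf("planted_%02d", seq_along(planted))

  idx <- stats::setNames(seq_len(n) - 1L, pool)  # 0-based positions
  edge_key <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    lo * n + hi
  }
  pa <- integer(0); pb <- integer(0)
  for (comm in planted) {
    pos <- idx[comm]
    pairs <- utils::combn(pos, 2L)
    pa <- c(pa, pairs[1L, ]); pb <- c(pb, pairs[2L, ])
  }
  planted_keys <- unique(edge_key(pa, pb))
  keep <- !duplicated(edge_key(pa, pb))
  pa <- pa[keep]; pb <- pb[keep]

  bg_a <- integer(0); bg_b <- integer(0)
  if (spec$background_edge_p > 0 && n >= 2) {
    n_pairs <- n * (n - 1) / 2
    m <- rbinom(1L, size = n_pairs, prob = spec$background_edge_p)
    if (m > 0L) {
      ij <- .pair_from_index(sample(n_pairs, m), n)
      not_planted <- !(edge_key(ij[, 1L], ij[, 2L]) %in% planted_keys)
      bg_a <- ij[not_planted, 1L]; bg_b <- ij[not_planted, 2L]
    }
  }
  conf <- c(runif(length(pa), conf_min, 1),
            runif(length(bg_a), 0.4, 1.0))
  g <- make_network(pool[c(pa, bg_a) + 1L], pool[c(pb, bg_b) + 1L], conf)
  attr(g, "planted") <- planted
  g
}

#' Simulate pathway gene sets aligned with planted communities
#'
#' Each pathway samples a majority (70%) of its members from one planted
#' community (cycling through them) and the remainder from the universe, so
#' pathway-community linkage is recoverable downstream.
#'
#' @param spec A [simulation_spec()].
#' @param communities List of gene sets (e.g. the `planted` attribute of
#'   [simulate_network()]).
#' @param universe Character vector of all gene symbols.
#' @return Named list of pathway member vectors (a GMT-style catalog).
#' @export
simulate_pathways <- function(spec, communities, universe) {
  set.seed(.substream(spec$seed, "pathways"))
  stopifnot(spec$pathway_size >= 2, length(communities) >= 1)
  lapply(stats::setNames(
    seq_len(spec$n_pathways),
    sprintf("PW%03d", seq_len(spec$n_pathways))
  ), function(i) {
    home <- communities[[(i - 1L) %% length(communities) + 1L]]
    n_core <- min(ceiling(0.7 * spec$pathway_size), length(home))
    core <- sample(home, n_core)
    n_rest <- spec$pathway_size - n_core
    rest <- sample(setdiff(universe, core), n_rest)
    unique(c(core, rest))
  })
}

#' Simulate a gene-by-cell-line RSA sensitivity matrix
#'
#' A fraction `essential_rate` of genes is essential: in a random majority
#' of cell lines (a subset of at least 60%, so comfortably above the >50%
#' essential bar even after noise) their RSA scores are drawn from
#' Normal(-5, 1); everywhere else scores are Normal(0, 1). At the
#' conventional threshold of -3 an essential gene is sensitive in each
#' affected line with probability ~0.977, while a non-essential gene
#' crosses it with probability ~0.0013.
#'
#' @param spec A [simulation_spec()].
#' @param genes Character vector of gene symbols to screen.
#' @return Numeric matrix (genes x cell lines) with an `essential`
#'   attribute naming the genes simulated as essential.
#' @export
simulate_sensitivity <- function(spec, genes) {
  set.seed(.substream(spec$seed, "sensitivity"))
  genes <- unique(toupper(genes))
  n <- length(genes); L <- spec$n_cell_lines
  mat <- matrix(rnorm(n * L), nrow = n,
                dimnames = list(genes, sprintf("CL%03d", seq_len(L))))
  n_ess <- round(spec$essential_rate * n)
  essential <- if (n_ess > 0L) sample(genes, n_ess) else character()
  lo <- max(floor(L / 2) + 1L, ceiling(0.6 * L))
  for (g in essential) {
    n_hit <- if (lo >= L) L else sample(seq(lo, L), 1L)
    hit <- sample.int(L, n_hit)
    mat[g, hit] <- rnorm(n_hit, mean = -5, sd = 1)
  }
  attr(mat, "essential") <- essential
  mat
}

#' Simulate the full input bundle
#'
#' Convenience wrapper producing all pipeline inputs from one spec:
#' rankings plus truth sets, a planted-community network, pathway sets and
#' a sensitivity matrix. When `network_genes` is `NULL` the network spans
#' the whole universe.
#'
#' @param spec A [simulation_spec()].
#' @param network_genes Optional gene subset to build the network over.
#' @param conf_min Lower confidence bound for planted edges.
#' @return A list with `rankings`, `pathogenic`, `universe`, `network`,
#'   `pathways` and `sensitivity`.
#' @export
simulate_inputs <- function(spec, network_genes = NULL, conf_min = 0.9) {
  sim <- simulate_method_rankings(spec)
  if (is.null(network_genes)) network_genes <- sim$universe
  network <- simulate_network(spec, network_genes, conf_min = conf_min)
  pathways <- simulate_pathways(spec, attr(network, "planted"), sim$universe)
  sensitivity <- simulate_sensitivity(spec, sim$universe)
  c(sim, list(network = network, pathways = pathways,
              sensitivity = sensitivity))
}
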