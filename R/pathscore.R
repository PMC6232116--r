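#' Consensus weight of a community
#'
#' `W_k` summarizes a community by the consensus scores of its genes. With
#' the default denominator (`"community_size"`) it is the community's
#' average consensus score, the reading consistent with per-community
#' score averages; `"n_communities"` divides the score sum by the total
#' number of communities instead (a literal alternative kept for
#' comparison).
#'
#' @param genes Character vector: the community's members.
#' @param consensus A consensus table from [consensus_table()].
#' @param denominator `"community_size"` or `"n_communities"`.
#' @param n_communities Required when `denominator = "n_communities"`.
#' @return The community weight.
#' @export
community_weight <- function(genes, consensus,
                             denominator = c("community_size", "n_communities"),
                             n_communities = NULL) {
  denominator <- match.arg(denominator)
  genes <- unique(toupper(genes))
  if (length(genes) == 0L) stop("a community must be non-empty")
  found <- consensus[consensus$gene %in% genes, "consen_score"]
  if (length(found) == 0L) {
    stop("no community gene is present in the consensus table")
  }
  den <- switch(denominator,
                community_size = length(genes),
                n_communities = {
                  if (is.null(n_communities)) {
                    stop("n_communities is required for this denominator")
                  }
                  n_communities
                })
  sum(found) / den
}

#' Community-rank weight of a pathway
#'
#' The mean of the community weights `W_k` over every community connected
#' with the pathway. A community counts as connected when it shares at
#' least `min_shared` genes (default 1) with the pathway. Pathways linked
#' to no community score 0 and are flagged via the `"linked"` attribute.
#'
#' @param pathway Character vector of the pathway's genes.
#' @param communities List of community gene vectors.
#' @param weights Numeric vector of `W_k`, aligned with `communities`.
#' @param min_shared Minimum shared genes for linkage.
#' @return The pathway's rank score, with attributes `linked` (indices of
#'   connected communities).
#' @export
path_rank_score <- function(pathway, communities, weights, min_shared = 1L) {
  stopifnot(length(communities) == length(weights))
  pathway <- unique(toupper(pathway))
  linked <- which(vapply(communities,
                         function(cm) sum(cm %in% pathway) >= min_shared,
                         logical(1L)))
  score <- if (length(linked)) mean(weights[linked]) else 0
  structure(score, linked = linked)
}

#' Gene-level weight of a pathway
#'
#' `PathGeneScore_m = sqrt( <ConsenScore^m> * n_m / N_m )`, where
#' `<ConsenScore^m>` is the mean consensus score over the pathway genes
#' found in the consensus table, `N_m` the pathway size and `n_m` the
#' number of pathway genes present in the interaction network. Pathways
#' absent from the network (or from the consensus) score 0.
#'
#' @param pathway Character vector of the pathway's genes.
#' @param consensus A consensus table from [consensus_table()].
#' @param network An igraph.
#' @return The gene score, with attributes `n_m`, `N_m`, `mean_consen`,
#'   `n_consensus` (pathway genes found in the consensus table).
#' @export
path_gene_score <- function(pathway, consensus, network) {
  pathway <- unique(toupper(pathway))
  N_m <- length(pathway)
  stopifnot(N_m >= 1L)
  found <- consensus[consensus$gene %in% pathway, "consen_score"]
  mean_consen <- if (length(found)) mean(found) else 0
  n_m <- sum(pathway %in% igraph::V(network)$name)
  structure(sqrt(mean_consen * n_m / N_m),
            n_m = n_m, N_m = N_m, mean_consen = mean_consen,
            n_consensus = length(found))
}

#' Final pathway score
#'
#' The geometric mean `sqrt(PathRankScore * PathGeneScore)`. The rank
#' score enters unscaled by default (`normalize = "identity"`), which is
#' the reading under which the two component scores recompose the final
#' score exactly; `normalize = "max"` divides all rank scores by their
#' maximum first (applied at table level).
#'
#' @param path_rank_score,path_gene_score Component scores in \[0, 1\].
#' @return The pathway score.
#' @export
path_score <- function(path_rank_score, path_gene_score) {
  if (any(path_rank_score < 0) || any(path_gene_score < 0)) {
    stop("pathway component scores must be non-negative")
  }
  sqrt(as.numeric(path_rank_score) * as.numeric(path_gene_score))
}

#' Pathway score table
#'
#' Computes, for every pathway in a catalog, the linked communities, the
#' community-rank score, the gene score and the final pathway score, and
#' returns them sorted by decreasing pathway score.
#'
#' @param pathways Named list of pathway gene vectors (e.g. from
#'   [read_gene_sets_gmt()] or [simulate_pathways()]).
#' @param communities A `community_set` or list of community gene vectors.
#' @param consensus A consensus table from [consensus_table()].
#' @param network The filtered igraph.
#' @param config A [run_config()] (supplies the `W_k` denominator).
#' @param normalize_rank `"identity"` (default) or `"max"`: how
#'   `PathRankScore` is normalized before entering the final geometric
#'   mean.
#' @return A `data.frame` with columns `pathway`, `path_rank_score`,
#'   `n_linked`, `linked_communities` (space-separated indices), `n_m`,
#'   `N_m`, `mean_consen_score`, `path_gene_score`, `path_score`.
#' @export
pathway_score_table <- function(pathways, communities, consensus, network,
                                config = run_config(),
                                normalize_rank = c("identity", "max")) {
  normalize_rank <- match.arg(normalize_rank)
  comms <- if (inherits(communities, "community_set")) communities$communities
           else communities
  W <- vapply(comms, community_weight, numeric(1L),
              consensus = consensus,
              denominator = config$w_k_denominator,
              n_communities = length(comms))
  rows <- lapply(names(pathways), function(m) {
    prs <- path_rank_score(pathways[[m]], comms, W)
    pgs <- path_gene_score(pathways[[m]], consensus, network)
    data.frame(
      pathway = m,
      path_rank_score = as.numeric(prs),
      n_linked = length(attr(prs, "linked")),
      linked_communities = paste(attr(prs, "linked"), collapse = " "),
      n_m = attr(pgs, "n_m"), N_m = attr(pgs, "N_m"),
      mean_consen_score = attr(pgs, "mean_consen"),
      path_gene_score = as.numeric(pgs),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rank_in <- tab$path_rank_score
  if (normalize_rank == "max" && any(rank_in > 0)) {
    rank_in <- rank_in / max(rank_in)
  }
  tab$path_score <- path_score(rank_in, tab$path_gene_score)
  tab[order(-tab$path_score, tab$pathway), , drop = FALSE]
}
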