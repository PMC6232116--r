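#' Community-level feature matrix for clustering
#'
#' One row per community with three features: the mean final pathway score
#' over the pathways linked to the community, the mean node degree of its
#' genes in the filtered network, and the mean consensus rank of its
#' genes. Communities linked to no pathway get a mean pathway score of 0
#' and are flagged.
#'
#' @param profiles Output of [community_profiles()].
#' @param pathway_scores Output of [pathway_score_table()].
#' @return A `data.frame` with columns `community`, `mean_path_score`,
#'   `mean_degree`, `mean_rank`, `no_pathway` (logical flag).
#' @export
build_community_features <- function(profiles, pathway_scores) {
  linked <- lapply(seq_len(nrow(pathway_scores)), function(i) {
    as.integer(strsplit(pathway_scores$linked_communities[i], " ")[[1L]])
  })
  feat <- lapply(profiles$community, function(cid) {
    in_path <- vapply(linked, function(l) cid %in% l, logical(1L))
    mps <- if (any(in_path)) mean(pathway_scores$path_score[in_path]) else 0
    data.frame(community = cid,
               mean_path_score = mps,
               mean_degree = profiles$mean_degree[profiles$community == cid],
               mean_rank = profiles$mean_rank[profiles$community == cid],
               no_pathway = !any(in_path))
  })
  do.call(rbind, feat)
}

#' k-means clustering of communities
#'
#' Clusters the community feature matrix with Euclidean k-means after
#' per-column z-scoring (the three features live on incommensurate
#' scales). Constant columns are mapped to 0 instead of NaN. Multiple
#' random restarts are used and the run is deterministic under `seed`.
#'
#' @param features Output of [build_community_features()].
#' @param n_clusters Number of clusters.
#' @param seed Optional integer seed.
#' @param n_restarts Random restarts passed to [stats::kmeans()] `nstart`.
#' @return A list: `labels` (named by community id), `centers` (on the
#'   z-scored scale), `withinss`, `scaled` (the z-scored matrix).
#' @export
cluster_communities <- function(features, n_clusters = 3, seed = NULL,
                                n_restarts = 25L) {
  x <- as.matrix(features[c("mean_path_score", "mean_degree", "mean_rank")])
  if (nrow(x) < n_clusters) {
    stop(sprintf("%d communities cannot form %d clusters", nrow(x), n_clusters))
  }
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0  # constant feature carries no signal
  if (!is.null(seed)) set.seed(.substream(seed, "kmeans"))
  km <- stats::kmeans(z, centers = n_clusters, nstart = n_restarts,
                      iter.max = 100L)
  list(labels = stats::setNames(km$cluster, features$community),
       centers = km$centers,
       withinss = km$tot.withinss,
       scaled = z)
}

#' Select the most disease-relevant cluster
#'
#' Orders clusters lexicographically by (mean pathway score, decreasing),
#' then (mean degree, decreasing), then (mean consensus rank, increasing)
#' and returns the top cluster: the communities with high pathway
#' involvement, high connectivity and low (good) consensus ranks.
#'
#' @param labels Named cluster labels from [cluster_communities()].
#' @param features The feature matrix the labels were computed from.
#' @return A list: `cluster` (winning label), `communities` (member
#'   community ids), `summary` (per-cluster feature means, ordered best
#'   first).
#' @export
select_relevant_cluster <- function(labels, features) {
  stopifnot(length(labels) == nrow(features))
  agg <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    rows <- features[labels == cl, , drop = FALSE]
    data.frame(cluster = cl,
               n_communities = nrow(rows),
               mean_path_score = mean(rows$mean_path_score),
               mean_degree = mean(rows$mean_degree),
               mean_rank = mean(rows$mean_rank))
  }))
  agg <- agg[order(-agg$mean_path_score, -agg$mean_degree, agg$mean_rank), ,
             drop = FALSE]
  best <- agg$cluster[1L]
  list(cluster = best,
       communities = as.integer(names(labels)[labels == best]),
       summary = agg)
}
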