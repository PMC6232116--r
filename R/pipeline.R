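#' Run the full pipeline on synthetic inputs
#'
#' Exercises every stage end to end on data from the synthetic generator:
#' consensus scoring and ranking, cutoff selection, early-recognition
#' benchmarking of the consensus against each single method, network
#' construction over the selected genes, clique-order selection and
#' community detection, community profiling and enrichment, pathway
#' scoring, community clustering and relevant-cluster selection,
#' sensitivity classification with group summaries, the overlap funnel and
#' the combined consensus-by-sensitivity list.
#'
#' @param spec A [simulation_spec()].
#' @param config A [run_config()]. Its `seed` is ignored in favor of the
#'   spec's seed, which drives all generators.
#' @param network_size Maximum number of top-ranked genes carried into the
#'   interaction network (default 1500).
#' @return A named list with the intermediate and final results of every
#'   stage (see the worked example in the package README).
#' @export
run_pipeline <- function(spec = simulation_spec(),
                         config = run_config(seed = spec$seed),
                         network_size = 1500L) {
  sim <- simulate_method_rankings(spec)

  tab <- consensus_table(sim$rankings, m_total = config$m_total)
  cut <- cutoff_curve(tab, sim$pathogenic, mode = config$tp_fp_mode)
  selected <- tab$gene[seq_len(cut$best_rank)]

  recog <- list(
    consensus = early_recognition(tab$gene, sim$pathogenic,
                                  fractions = config$fractions),
    per_method = lapply(sim$rankings, function(r) {
      early_recognition(r$genes, sim$pathogenic,
                        fractions = config$fractions)
    })
  )

  net_genes <- head(selected, network_size)
  network <- simulate_network(spec, net_genes,
                              conf_min = config$confidence_cutoff)
  filtered <- filter_network(network, config$confidence_cutoff)
  attr(filtered, "planted") <- attr(network, "planted")

  ksel <- select_k(filtered, config$k_range)
  profiles <- community_profiles(ksel$best, tab, filtered, sim$pathogenic)

  pathways <- simulate_pathways(spec, attr(network, "planted"), sim$universe)
  pscores <- pathway_score_table(pathways, ksel$best, tab, filtered, config)

  features <- build_community_features(profiles, pscores)
  clustering <- NULL
  relevant <- NULL
  if (nrow(features) >= config$n_clusters) {
    clustering <- cluster_communities(features, config$n_clusters,
                                      seed = spec$seed)
    relevant <- select_relevant_cluster(clustering$labels, features)
  }
  relevant_genes <- if (!is.null(relevant)) {
    sort(unique(unlist(
      ksel$best$communities[relevant$communities], use.names = FALSE)))
  } else character()

  sens <- simulate_sensitivity(spec, sim$universe)
  classification <- classify_sensitivity(
    sens, threshold = config$rsa_threshold,
    essential_fraction = config$essential_fraction,
    universe = sim$universe)
  community_genes <- sort(unique(unlist(ksel$best$communities,
                                        use.names = FALSE)))
  groups <- list(consensus = selected,
                 network = igraph::V(filtered)$name,
                 communities = community_genes,
                 relevant_communities = relevant_genes,
                 pathogenic = sim$pathogenic$union)
  sens_summary <- sensitivity_summary(
    classification, groups, essential_fraction = config$essential_fraction)

  overlap <- overlap_report(
    c(groups["pathogenic"],
      list(consensus = selected, network = igraph::V(filtered)$name,
           communities = community_genes,
           relevant_communities = relevant_genes)),
    reference = "pathogenic")

  frac <- stats::setNames(classification$fraction_sensitive,
                          classification$gene)
  combined <- combined_priority(tab, frac[!is.na(frac)])

  list(spec = spec, config = config,
       pathogenic = sim$pathogenic,
       consensus = tab, cutoff = cut, selected = selected,
       recognition = recog,
       network = filtered, k_selection = ksel,
       profiles = profiles, pathway_scores = pscores,
       features = features, clustering = clustering, relevant = relevant,
       sensitivity = classification, sensitivity_summary = sens_summary,
       overlap = overlap, combined = combined)
}

#' Write a JSON summary of a pipeline run
#'
#' Persists the headline quantities of a [run_pipeline()] result (cutoff,
#' early recognition of the consensus, selected clique order, community
#' counts, relevant cluster, sensitivity summary, funnel ratios) as a
#' JSON file.
#'
#' @param result Output of [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(result, path) {
  consensus_recog <- result$recognition$consensus
  top1 <- consensus_recog[consensus_recog$set == "G1+G2" &
                            consensus_recog$fraction ==
                            min(consensus_recog$fraction), , drop = FALSE]
  summary <- list(
    n_genes = nrow(result$consensus),
    cutoff_rank = result$cutoff$best_rank,
    cutoff_i = result$cutoff$best_i,
    recognition_top_fraction_pct = top1$identified_pct[1L],
    best_k = result$k_selection$best_k,
    n_communities = result$k_selection$best$n_communities,
    s_index = result$k_selection$best$s_index,
    relevant_cluster = if (!is.null(result$relevant)) {
      result$relevant$communities
    },
    sensitivity_summary = result$sensitivity_summary,
    funnel = result$overlap$funnel
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
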