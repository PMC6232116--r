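#' Rank-normalize the scores of one method
#'
#' Maps rank r of N to `(N - r) / (N - 1)`: the top gene gets 1, the bottom
#' gene 0. Genes a method does not report simply have no normalized score
#' (they are not zero-filled), so absence and a bottom rank stay distinct.
#'
#' @param ranking A [method_ranking()].
#' @return Named numeric vector of normalized scores in \[0, 1\].
#' @export
normalize_method_scores <- function(ranking) {
  stopifnot(inherits(ranking, "method_ranking"))
  n <- length(ranking$genes)
  if (n < 2L) stop(sprintf("method '%s' has fewer than 2 genes", ranking$method_id))
  stats::setNames((n - seq_len(n)) / (n - 1), ranking$genes)
}

#' Consensus score of one gene
#'
#' `Gene_i = sqrt( (n_i - 1)/(m_total - 1) * mean_j GeneN_ij )`: the
#' geometric mean of the average normalized score across the methods that
#' predict the gene and the (normalized) number of predicting methods. A
#' gene predicted by a single method scores 0 regardless of its rank, so
#' cross-method agreement is required for a high score.
#'
#' @param genen Numeric vector of the gene's normalized scores, one per
#'   predicting method.
#' @param m_total Normalizing constant: the maximum method count.
#' @return The consensus score in \[0, 1\].
#' @export
consensus_score <- function(genen, m_total = 12) {
  n_i <- length(genen)
  if (n_i < 1L) stop("a gene must be predicted by at least one method")
  if (n_i > m_total) {
    stop(sprintf("gene predicted by %d methods but m_total is %d", n_i, m_total))
  }
  sqrt((n_i - 1) / (m_total - 1) * mean(genen))
}

#' Build the consensus table from per-method rankings
#'
#' Normalizes every method with [normalize_method_scores()], computes the
#' per-gene consensus score, ranks genes by descending score (ties broken
#' by higher method count, then alphabetically) and rank-normalizes the
#' result into `consen_score = (N - rank)/(N - 1)`. The gene universe is
#' the union of genes reported by at least one method.
#'
#' @param rankings List of [method_ranking()] objects.
#' @param m_total Normalizing constant of [consensus_score()].
#' @return A `data.frame` with one row per gene, ordered by rank, columns
#'   `gene`, `n_methods`, `mean_genen`, `gene_score`, `rank`,
#'   `consen_score`.
#' @export
consensus_table <- function(rankings, m_total = 12) {
  stopifnot(length(rankings) >= 1L)
  if (length(rankings) > m_total) {
    stop(sprintf("%d methods supplied but m_total is %d", length(rankings), m_total))
  }
  genen <- lapply(rankings, normalize_method_scores)
  gene <- unlist(lapply(genen, names), use.names = FALSE)
  score <- unlist(genen, use.names = FALSE)
  f <- factor(gene)
  n_methods <- as.integer(tabulate(f, nbins = nlevels(f)))
  sums <- as.vector(rowsum(score, f))
  mean_genen <- sums / n_methods
  gene_score <- sqrt((n_methods - 1) / (m_total - 1) * mean_genen)
  tab <- data.frame(gene = levels(f), n_methods = n_methods,
                    mean_genen = mean_genen, gene_score = gene_score,
                    stringsAsFactors = FALSE)
  if (nrow(tab) < 2L) stop("consensus needs at least 2 distinct genes")
  ord <- order(-tab$gene_score, -tab$n_methods, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  n <- nrow(tab)
  tab$rank <- seq_len(n)
  tab$consen_score <- (n - tab$rank) / (n - 1)
  rownames(tab) <- NULL
  tab
}

#' Cutoff index over the consensus ranking
#'
#' At each rank i the index `I_i = TP_i / (FP_i + 1) * ConsenScore_i`
#' weighs the cumulative recovery of pathogenic genes against the
#' accumulation of non-pathogenic ones, damped by the rank-normalized
#' consensus score. With `mode = "rates"` (the default) TP and FP are the
#' cumulative counts divided by the total number of pathogenic and
#' non-pathogenic genes in the universe; with `mode = "counts"` they are
#' the raw cumulative counts. The selected cutoff is the first rank
#' attaining the maximum of the curve.
#'
#' @param table A consensus table from [consensus_table()].
#' @param pathogenic A [pathogenic_gene_sets()] (or character vector).
#' @param mode `"rates"` or `"counts"`.
#' @return A list: `curve` (data.frame `rank`, `gene`, `tp`, `fp`,
#'   `i_score`), `best_rank`, `best_i`.
#' @export
cutoff_curve <- function(table, pathogenic, mode = c("rates", "counts")) {
  mode <- match.arg(mode)
  truth <- if (inherits(pathogenic, "pathogenic_sets")) pathogenic$union
           else unique(toupper(pathogenic))
  is_path <- table$gene %in% truth
  if (!any(is_path)) {
    stop("no pathogenic gene is present in the consensus universe")
  }
  tp <- cumsum(is_path)
  fp <- cumsum(!is_path)
  if (mode == "rates") {
    tp_v <- tp / sum(is_path)
    fp_v <- fp / max(1L, sum(!is_path))
  } else {
    tp_v <- tp
    fp_v <- fp
  }
  i_score <- tp_v / (fp_v + 1) * table$consen_score
  best <- which.max(i_score)  # first maximum on ties
  list(curve = data.frame(rank = table$rank, gene = table$gene,
                          tp = tp_v, fp = fp_v, i_score = i_score,
                          stringsAsFactors = FALSE),
       best_rank = table$rank[best],
       best_i = i_score[best])
}

#' Early-recognition report over a ranked gene list
#'
#' For every gene set and fraction f, counts how many set members fall in
#' the top `floor(f * N)` of the ranking (as a percentage of the full set,
#' so members absent from the ranking count as never identified) and the
#' mean rank of the identified members.
#'
#' @param ranked_genes Character vector of genes, best first.
#' @param sets Named list of gene sets, or a [pathogenic_gene_sets()]
#'   (expanded to G1, G2 and G1+G2).
#' @param fractions Numeric fractions in (0, 1\].
#' @return A `data.frame` with columns `set`, `fraction`, `window`,
#'   `n_identified`, `identified_pct`, `mean_rank` (`NA` when nothing is
#'   identified).
#' @export
early_recognition <- function(ranked_genes, sets,
                              fractions = c(0.01, 0.05, 0.10, 0.20, 0.50)) {
  if (inherits(sets, "pathogenic_sets")) {
    sets <- list(G1 = sets$g1, G2 = sets$g2, `G1+G2` = sets$union)
  }
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  n <- length(ranked_genes)
  pos <- stats::setNames(seq_len(n), ranked_genes)
  rows <- list()
  for (s in names(sets)) {
    members <- unique(toupper(sets[[s]]))
    hit_pos <- pos[members]
    for (f in fractions) {
      w <- floor(f * n)
      if (w < 1L) stop(sprintf("fraction %.3g gives an empty window", f))
      inside <- hit_pos[!is.na(hit_pos) & hit_pos <= w]
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, fraction = f, window = w,
        n_identified = length(inside),
        identified_pct = 100 * length(inside) / length(members),
        mean_rank = if (length(inside)) mean(inside) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rank summary of a gene group inside the consensus table
#'
#' @param table A consensus table from [consensus_table()].
#' @param group Character vector of gene symbols.
#' @return A list: `n_found`, `n_missing`, `mean_rank`,
#'   `mean_consen_score` (means are `NA` when nothing is found).
#' @export
group_rank_summary <- function(table, group) {
  group <- unique(toupper(group))
  hit <- table[table$gene %in% group, , drop = FALSE]
  list(n_found = nrow(hit),
       n_missing = length(group) - nrow(hit),
       mean_rank = if (nrow(hit)) mean(hit$rank) else NA_real_,
       mean_consen_score = if (nrow(hit)) mean(hit$consen_score) else NA_real_)
}
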