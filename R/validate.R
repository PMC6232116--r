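#' Spearman correlation of degree centrality between two networks
#'
#' Over the genes shared by both networks, correlates the two degree
#' sequences by Spearman rank correlation. `r_squared` is the square of
#' rho, reported alongside it as the customary effect-size companion.
#'
#' @param network_a,network_b igraph objects with named vertices.
#' @return A list: `n_shared`, `rho`, `r_squared`, `p` (two-sided).
#' @export
degree_spearman <- function(network_a, network_b) {
  shared <- intersect(igraph::V(network_a)$name, igraph::V(network_b)$name)
  if (length(shared) < 3L) {
    stop("degree correlation needs at least 3 shared genes")
  }
  da <- igraph::degree(network_a)[shared]
  db <- igraph::degree(network_b)[shared]
  ct <- suppressWarnings(
    stats::cor.test(da, db, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  list(n_shared = length(shared), rho = rho, r_squared = rho^2,
       p = ct$p.value)
}

#' Classify genes by RSA sensitivity across cell lines
#'
#' A gene is *sensitive* in a cell line when its RSA score is at or below
#' `threshold`. Genes sensitive in more than `essential_fraction` of
#' lines are *essential*; genes sensitive in no line are *inert*; the
#' rest are *active*. The exact boundary (`fraction == essential_fraction`)
#' is assigned to *active*, keeping "essential" strict. Genes of
#' `universe` absent from the screen are labeled *undetected* rather than
#' dropped, so downstream denominators stay auditable.
#'
#' @param mat Numeric gene-by-cell-line matrix of RSA scores.
#' @param threshold RSA sensitivity threshold (default -3).
#' @param essential_fraction Strict lower bound of the essential class
#'   (default 0.5).
#' @param universe Optional character vector of genes that should appear
#'   in the output even when undetected.
#' @return A `data.frame` with columns `gene`, `fraction_sensitive`
#'   (`NA` for undetected), `class` (factor: essential/active/inert/
#'   undetected).
#' @export
classify_sensitivity <- function(mat, threshold = -3,
                                 essential_fraction = 0.5,
                                 universe = NULL) {
  if (is.null(dim(mat)) || nrow(mat) == 0L || ncol(mat) == 0L) {
    stop("the sensitivity matrix must have at least one gene and one cell line")
  }
  frac <- rowMeans(mat <= threshold)
  cls <- ifelse(frac > essential_fraction, "essential",
                ifelse(frac == 0, "inert", "active"))
  out <- data.frame(gene = rownames(mat), fraction_sensitive = unname(frac),
                    class = unname(cls), stringsAsFactors = FALSE)
  if (!is.null(universe)) {
    missing <- setdiff(unique(toupper(universe)), out$gene)
    if (length(missing)) {
      out <- rbind(out, data.frame(gene = missing,
                                   fraction_sensitive = NA_real_,
                                   class = "undetected",
                                   stringsAsFactors = FALSE))
    }
  }
  out$class <- factor(out$class,
                      levels = c("essential", "active", "inert", "undetected"))
  out
}

#' Sensitivity-class summary per gene group
#'
#' For each named gene group: how many members the screen detected, the
#' detection percentage (over the group size), and the percentage of
#' essential genes and of genes with `fraction_sensitive` above the
#' essential bar among the detected members.
#'
#' @param classification Output of [classify_sensitivity()].
#' @param groups Named list of gene sets.
#' @param essential_fraction The bar used for the `pct_above_bar` column.
#' @return A `data.frame` with one row per group: `group`, `n_group`,
#'   `n_detected`, `detected_pct`, `essential_pct`, `active_pct`,
#'   `inert_pct`, `pct_above_bar`.
#' @export
sensitivity_summary <- function(classification, groups,
                                essential_fraction = 0.5) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  rows <- lapply(names(groups), function(gname) {
    members <- unique(toupper(groups[[gname]]))
    sub <- classification[classification$gene %in% members, , drop = FALSE]
    det <- sub[sub$class != "undetected", , drop = FALSE]
    pct <- function(x) if (nrow(det)) 100 * x / nrow(det) else NA_real_
    data.frame(
      group = gname,
      n_group = length(members),
      n_detected = nrow(det),
      detected_pct = 100 * nrow(det) / length(members),
      essential_pct = pct(sum(det$class == "essential")),
      active_pct = pct(sum(det$class == "active")),
      inert_pct = pct(sum(det$class == "inert")),
      pct_above_bar = pct(sum(det$fraction_sensitive > essential_fraction)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Set-overlap report with enrichment funnel ratios
#'
#' Computes all pairwise intersection counts between the named sets and,
#' when a `reference` set is named, the funnel ratios
#' `|reference intersect stage| / |stage|` for every other stage (rounded
#' to 3 decimals), mirroring the successive enrichment of a truth set
#' through pipeline stages.
#'
#' @param sets Named list of gene sets (at least 2).
#' @param reference Optional name of the set whose enrichment is tracked.
#' @return A list: `sizes`, `pairwise` (intersection count matrix),
#'   `funnel` (data.frame `stage`, `n_stage`, `n_overlap`, `ratio`;
#'   `NULL` without a reference).
#' @export
overlap_report <- function(sets, reference = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(toupper(s)))
  nm <- names(sets)
  pairwise <- outer(nm, nm, Vectorize(function(a, b) {
    length(intersect(sets[[a]], sets[[b]]))
  }))
  dimnames(pairwise) <- list(nm, nm)
  funnel <- NULL
  if (!is.null(reference)) {
    stopifnot(reference %in% nm)
    stages <- setdiff(nm, reference)
    funnel <- data.frame(
      stage = stages,
      n_stage = vapply(stages, function(s) length(sets[[s]]), integer(1L)),
      n_overlap = vapply(stages, function(s) {
        length(intersect(sets[[reference]], sets[[s]]))
      }, integer(1L)),
      stringsAsFactors = FALSE)
    funnel$ratio <- round(funnel$n_overlap / funnel$n_stage, 3L)
    rownames(funnel) <- NULL
  }
  list(sizes = lengths(sets), pairwise = pairwise, funnel = funnel)
}

#' Combine consensus score and screen sensitivity into one priority list
#'
#' Re-scores genes as `sqrt(ConsenScore * fraction_sensitive)` (the
#' geometric-mean idiom used throughout the pipeline; any other combiner
#' can be plugged in). Genes undetected in the screen are ranked after all
#' detected genes, ordered by consensus score among themselves.
#'
#' @param consensus A consensus table from [consensus_table()].
#' @param fraction_sensitive Named numeric vector: per-gene share of cell
#'   lines with a sensitive RSA score.
#' @param combiner Function of (consen_score, fraction_sensitive).
#' @return A `data.frame` ordered by the combined score: `gene`,
#'   `consen_score`, `fraction_sensitive`, `combined`, `rank`.
#' @export
combined_priority <- function(consensus, fraction_sensitive,
                              combiner = function(c, f) sqrt(c * f)) {
  common <- intersect(consensus$gene, names(fraction_sensitive))
  if (length(common) == 0L) {
    stop("the consensus table and the screen share no gene")
  }
  tab <- consensus[c("gene", "consen_score")]
  tab$fraction_sensitive <- unname(fraction_sensitive[tab$gene])
  detected <- !is.na(tab$fraction_sensitive)
  tab$combined <- NA_real_
  tab$combined[detected] <- combiner(tab$consen_score[detected],
                                     tab$fraction_sensitive[detected])
  ord <- order(!detected,                      # detected first
               -ifelse(detected, tab$combined, tab$consen_score))
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
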