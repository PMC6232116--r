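#' Pipeline run configuration
#'
#' Collects the tunable constants of the pipeline in one validated object.
#' Defaults follow the published analysis this pipeline models: a consensus
#' normalizing constant of 12 methods, a STRING "highest confidence" edge
#' cutoff of 0.9, early-recognition fractions of 1/5/10/20/50%, an RSA
#' sensitivity threshold of -3 with an essential-gene bar at >50% of cell
#' lines, and 3 community clusters.
#'
#' @param m_total Normalizing constant of the consensus score: the maximum
#'   number of methods a gene can be predicted by. Default 12.
#' @param confidence_cutoff Minimum interaction confidence kept when
#'   filtering the network, on the unit scale. Default 0.9.
#' @param fractions Top-list fractions at which early recognition is
#'   evaluated. Default `c(0.01, 0.05, 0.10, 0.20, 0.50)`.
#' @param k_range Candidate clique orders for community detection.
#'   Default `3:12`.
#' @param rsa_threshold RSA score at or below which a gene is called
#'   sensitive in a cell line. Default -3.
#' @param essential_fraction Fraction of cell lines above which a sensitive
#'   gene is deemed essential (strict inequality). Default 0.5.
#' @param n_clusters Number of k-means clusters of communities. Default 3.
#' @param seed Integer seed used by every stochastic stage.
#' @param tp_fp_mode How the cutoff index counts true/false positives:
#'   `"rates"` (cumulative counts divided by class totals, the default) or
#'   `"counts"` (raw cumulative counts).
#' @param w_k_denominator Denominator of the community weight `W_k`:
#'   `"community_size"` (the community average, the default) or
#'   `"n_communities"` (divide by the total number of communities).
#'
#' @return A list of class `"run_config"`.
#' @examples
#' cfg <- run_config(seed = 7)
#' cfg$m_total
#' @export
run_config <- function(m_total = 12,
                       confidence_cutoff = 0.9,
                       fractions = c(0.01, 0.05, 0.10, 0.20, 0.50),
                       k_range = 3:12,
                       rsa_threshold = -3,
                       essential_fraction = 0.5,
                       n_clusters = 3,
                       seed = 1L,
                       tp_fp_mode = c("rates", "counts"),
                       w_k_denominator = c("community_size", "n_communities")) {
  tp_fp_mode <- match.arg(tp_fp_mode)
  w_k_denominator <- match.arg(w_k_denominator)
  stopifnot(
    is.numeric(m_total), length(m_total) == 1L, m_total >= 2,
    is.numeric(confidence_cutoff), confidence_cutoff >= 0, confidence_cutoff <= 1,
    is.numeric(fractions), all(fractions > 0), all(fractions <= 1),
    is.numeric(k_range), length(k_range) >= 1L, all(k_range >= 3),
    is.numeric(rsa_threshold), length(rsa_threshold) == 1L,
    is.numeric(essential_fraction), essential_fraction >= 0, essential_fraction <= 1,
    is.numeric(n_clusters), n_clusters >= 1,
    is.numeric(seed), length(seed) == 1L, abs(seed) < 2^31
  )
  structure(
    list(
      m_total = as.integer(m_total),
      confidence_cutoff = confidence_cutoff,
      fractions = fractions,
      k_range = as.integer(k_range),
      rsa_threshold = rsa_threshold,
      essential_fraction = essential_fraction,
      n_clusters = as.integer(n_clusters),
      seed = as.integer(seed),
      tp_fp_mode = tp_fp_mode,
      w_k_denominator = w_k_denominator
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# Deterministic per-stage substreams derived from one global seed, so stages
# can be re-run independently without sharing RNG state.
.substream <- function(seed, stage) {
  offsets <- c(rankings = 101L, network = 211L, pathways = 307L,
               sensitivity = 401L, kmeans = 503L, permutation = 601L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) + off) %% 2147483647)
}
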