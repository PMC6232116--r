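#' Construct a per-method gene ranking
#'
#' A `method_ranking` holds the ordered gene list produced by one
#' prioritization method; the position in the list defines rank 1..N.
#'
#' @param method_id Single label identifying the method.
#' @param genes Character vector of gene symbols, best first. Symbols are
#'   uppercased; duplicates are an error.
#' @param raw_score Optional numeric vector of raw method scores aligned
#'   with `genes` (descending).
#' @return An object of class `"method_ranking"` with elements `method_id`,
#'   `genes` and `raw_score`.
#' @export
method_ranking <- function(method_id, genes, raw_score = NULL) {
  stopifnot(length(method_id) == 1L, is.character(genes))
  genes <- toupper(genes)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop(sprintf("method '%s' lists duplicated gene(s): %s",
                 method_id, paste(dup, collapse = ", ")))
  }
  if (!is.null(raw_score)) stopifnot(length(raw_score) == length(genes))
  structure(list(method_id = as.character(method_id),
                 genes = genes, raw_score = raw_score),
            class = "method_ranking")
}

#' @export
print.method_ranking <- function(x, ...) {
  cat(sprintf("<method_ranking> %s: %d genes (top: %s)\n",
              x$method_id, length(x$genes),
              paste(head(x$genes, 3L), collapse = ", ")))
  invisible(x)
}

#' Construct the curated pathogenic gene sets
#'
#' Two curated truth sets are carried through the pipeline: genes whose
#' perturbation in model organisms produces a disease-like phenotype (G1)
#' and genes with at least one disease-associated polymorphism in
#' meta-analyses (G2). Their union is the validation set for
#' early-recognition benchmarking and enrichment tests.
#'
#' @param g1,g2 Character vectors of gene symbols (uppercased on input).
#' @return An object of class `"pathogenic_sets"` with elements `g1`, `g2`
#'   and the derived `union`.
#' @export
pathogenic_gene_sets <- function(g1, g2 = character()) {
  g1 <- unique(toupper(g1))
  g2 <- unique(toupper(g2))
  u <- union(g1, g2)
  if (length(u) == 0L) stop("the union of G1 and G2 must be non-empty")
  structure(list(g1 = g1, g2 = g2, union = u), class = "pathogenic_sets")
}

#' @export
print.pathogenic_sets <- function(x, ...) {
  cat(sprintf("<pathogenic_sets> G1: %d, G2: %d, union: %d genes\n",
              length(x$g1), length(x$g2), length(x$union)))
  invisible(x)
}

#' Read per-method ranked gene lists from a TSV file
#'
#' The file needs columns `method`, `gene` and at least one of `score` /
#' `rank`. When both are present, `score` wins and ranks are recomputed;
#' ties in raw score are broken by input order.
#'
#' @param path Path to a tab-separated file.
#' @return A named list of [method_ranking()] objects, one per distinct
#'   method.
#' @export
read_method_rankings <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("method", "gene")) {
    if (!col %in% names(df)) {
      stop(sprintf("rankings file '%s' is missing required column '%s'", path, col))
    }
  }
  has_score <- "score" %in% names(df)
  has_rank <- "rank" %in% names(df)
  if (!has_score && !has_rank) {
    stop(sprintf("rankings file '%s' needs a 'score' or a 'rank' column", path))
  }
  df$gene <- toupper(df$gene)
  dup <- df[duplicated(df[c("method", "gene")]), , drop = FALSE]
  if (nrow(dup) > 0L) {
    stop(sprintf(
      "duplicated (method, gene) rows: %s",
      paste(sprintf("%s/%s", dup$method, dup$gene), collapse = ", ")))
  }
  out <- lapply(split(df, df$method), function(d) {
    if (has_score && !all(is.na(d$score))) {
      ord <- order(-d$score)  # stable: input order breaks ties
      method_ranking(d$method[1L], d$gene[ord], raw_score = d$score[ord])
    } else {
      ord <- order(d$rank)
      method_ranking(d$method[1L], d$gene[ord])
    }
  })
  out[order(names(out))]
}

#' Write method rankings to a TSV file
#'
#' Inverse of [read_method_rankings()]; round-trips exactly.
#'
#' @param rankings A list of [method_ranking()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_method_rankings <- function(rankings, path) {
  rows <- do.call(rbind, lapply(rankings, function(r) {
    data.frame(method = r$method_id, gene = r$genes,
               score = if (is.null(r$raw_score)) {
                 # rank-derived pseudo-score keeps the order on re-read
                 rev(seq_along(r$genes))
               } else r$raw_score,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style weighted edge list
#'
#' Expects columns `geneA`, `geneB`, `score`. Scores may be on the unit
#' scale or the STRING `combined_score` 0-1000 scale; with `scale = "auto"`
#' the file is divided by 1000 whenever any score exceeds 1. Self-loops are
#' dropped (with a warning) and parallel edges keep the maximum confidence.
#'
#' @param path Path to a tab-separated edge list.
#' @param scale One of `"auto"`, `"unit"`, `"string1000"`.
#' @return An undirected simple [igraph::graph] with an edge attribute
#'   `confidence` in \[0, 1\].
#' @export
read_network_tsv <- function(path, scale = c("auto", "unit", "string1000")) {
  scale <- match.arg(scale)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("geneA", "geneB", "score")) {
    if (!col %in% names(df)) {
      stop(sprintf("network file '%s' is missing required column '%s'", path, col))
    }
  }
  if (any(df$score < 0) || any(df$score > 1000)) {
    stop("edge scores must lie in [0, 1] or in the STRING scale [0, 1000]")
  }
  conf <- switch(scale,
    unit = df$score,
    string1000 = df$score / 1000,
    auto = if (any(df$score > 1)) df$score / 1000 else df$score
  )
  make_network(toupper(df$geneA), toupper(df$geneB), conf)
}

#' Build an interaction network from edge vectors
#'
#' @param gene_a,gene_b Character vectors of endpoint symbols.
#' @param confidence Numeric vector of per-edge confidences in \[0, 1\].
#' @return An undirected simple igraph with edge attribute `confidence`.
#' @export
make_network <- function(gene_a, gene_b, confidence) {
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(confidence),
            all(confidence >= 0), all(confidence <= 1))
  self <- gene_a == gene_b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop(s): %s", sum(self),
                    paste(unique(gene_a[self]), collapse = ", ")))
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]
    confidence <- confidence[!self]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = gene_a, to = gene_b, confidence = confidence,
               stringsAsFactors = FALSE),
    directed = FALSE)
  # parallel edges keep the maximum confidence
  igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
}

#' Write an interaction network as a TSV edge list
#'
#' @param network An igraph with edge attribute `confidence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  names(el)[1:2] <- c("geneA", "geneB")
  write.table(el[c("geneA", "geneB", "confidence")] |>
                stats::setNames(c("geneA", "geneB", "score")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description, and one or more member
#' symbols, tab-separated. Members are deduplicated (with a warning);
#' duplicated set names and empty member lists are errors.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of uppercased symbols.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    name <- fields[[1L]]
    members <- toupper(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop(sprintf("GMT line %d ('%s') has an empty member list", i, name))
    }
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': duplicated members removed", name))
      members <- unique(members)
    }
    if (name %in% names(out)) {
      stop(sprintf("duplicated gene-set name in GMT: '%s'", name))
    }
    out[[name]] <- members
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-cell-line sensitivity matrix from CSV
#'
#' First column: gene symbols; remaining columns: per-cell-line RSA scores,
#' with a header row of cell-line identifiers.
#'
#' @param path Path to a CSV file.
#' @return A numeric matrix with gene-symbol row names.
#' @export
read_sensitivity_csv <- function(path) {
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE, check.names = FALSE)
  genes <- toupper(df[[1L]])
  mat <- as.matrix(df[-1L])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  mat
}

#' Write a sensitivity matrix to CSV
#'
#' @param mat Numeric matrix with gene row names and cell-line column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene-symbol list
#'
#' One symbol per line; blank lines and `#` comments are skipped.
#'
#' @param path Path to a text file.
#' @return Character vector of unique uppercased symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}
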