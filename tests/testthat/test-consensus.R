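test_that("rank normalization maps top to 1, bottom to 0, and interior ranks linearly", {
  rk <- method_ranking("m", sprintf("G%03d", 1:100))
  gn <- normalize_method_scores(rk)
  expect_equal(unname(gn[1]), 1.0)
  expect_equal(unname(gn[100]), 0.0)
  expect_equal(unname(gn[50]), 50 / 99)
  expect_error(normalize_method_scores(method_ranking("m", "A")), "fewer than 2")
})

test_that("the consensus score rewards cross-method agreement", {
  expect_equal(consensus_score(0.99, m_total = 12), 0)            # n_i = 1
  expect_equal(consensus_score(rep(1, 12), m_total = 12), 1)      # full house
  expect_equal(consensus_score(rep(1, 8), m_total = 12), sqrt(7 / 11))
  expect_error(consensus_score(rep(0.5, 13), m_total = 12), "m_total")
  # strictly increasing in the method count at a fixed mean score
  scores <- vapply(1:12, function(n) consensus_score(rep(0.6, n), 12), 0)
  expect_true(all(diff(scores) > 0))
  # bounded by the square root of the mean normalized score
  expect_true(all(scores <= sqrt(0.6) + 1e-12))
})

test_that("the consensus table ranks by score with the n-methods tie rule and rank-normalizes", {
  rk <- list(
    m1 = method_ranking("m1", c("A", "B", "C", "D")),
    m2 = method_ranking("m2", c("A", "C", "B", "D")),
    m3 = method_ranking("m3", c("B", "A"))
  )
  tab <- consensus_table(rk, m_total = 12)
  expect_equal(tab$gene[tab$rank == 1], "A")
  expect_equal(tab$consen_score[1], 1.0)
  expect_equal(tab$consen_score[nrow(tab)], 0.0)
  expect_true(all(diff(tab$consen_score) <= 0))
  expect_true(all(tab$gene_score >= 0 & tab$gene_score <= 1))

  # equal gene scores: the gene seen by more methods ranks first.
  # U: 3 methods at mid rank (mean 0.5) and V: 2 methods at top rank both
  # give sqrt(1/11), an exact tie in the consensus score.
  rk2 <- list(
    m1 = method_ranking("m1", c("V", "U", "F1")),
    m2 = method_ranking("m2", c("V", "U", "F2")),
    m3 = method_ranking("m3", c("F3", "U", "F4"))
  )
  tab2 <- consensus_table(rk2, m_total = 12)
  expect_equal(tab2$gene_score[tab2$gene == "U"],
               tab2$gene_score[tab2$gene == "V"])
  expect_lt(tab2$rank[tab2$gene == "U"], tab2$rank[tab2$gene == "V"])
})

test_that("the cutoff index curve matches hand enumeration in counts mode", {
  tab <- toy_consensus(c("P1", "N1", "P2", "N2"))
  tab$consen_score <- c(1.0, 0.75, 0.5, 0.25)
  cut <- cutoff_curve(tab, c("P1", "P2"), mode = "counts")
  expect_equal(cut$curve$i_score, c(1.0, 0.375, 0.5, 1 / 6))
  expect_equal(cut$best_rank, 1L)
  expect_equal(cut$best_i, 1.0)
})

test_that("rate-based TP/FP divides the cumulative counts by the class totals", {
  tab <- toy_consensus(c("P1", "N1", "P2", "N2", "N3"))
  cut <- cutoff_curve(tab, c("P1", "P2"), mode = "rates")
  # independent arithmetic: tp = c(1,1,2,2,2)/2, fp = c(0,1,1,2,3)/3
  tp <- c(1, 1, 2, 2, 2) / 2
  fp <- c(0, 1, 1, 2, 3) / 3
  expect_equal(cut$curve$tp, tp)
  expect_equal(cut$curve$fp, fp)
  expect_equal(cut$curve$i_score, tp / (fp + 1) * tab$consen_score)
  expect_error(cutoff_curve(tab, c("ZZZ")), "no pathogenic gene")
})

test_that("ties in the cutoff index resolve to the first maximum", {
  tab <- toy_consensus(c("P1", "P2", "N1", "N2"))
  tab$consen_score <- c(0.5, 1.0, 0.1, 0.0)
  cut <- cutoff_curve(tab, c("P1", "P2"), mode = "counts")
  # i = c(0.5, 2.0, 1.0, 2/3*0) -> unique max; force a tie instead
  tab$consen_score <- c(1.0, 0.5, 0.1, 0.0)
  cut2 <- cutoff_curve(tab, c("P1", "P2"), mode = "counts")
  expect_equal(cut2$curve$i_score[1], cut2$curve$i_score[2])
  expect_equal(cut2$best_rank, 1L)
})

test_that("early recognition reports window hits and mean ranks per set and fraction", {
  genes <- sprintf("G%03d", 1:100)
  path <- genes[1:10]
  er <- early_recognition(genes, list(p = path), fractions = 0.10)
  expect_equal(er$window, 10L)
  expect_equal(er$identified_pct, 100)
  expect_equal(er$mean_rank, 5.5)

  er2 <- early_recognition(genes, list(p = c("X1", "X2")),
                           fractions = c(0.10, 0.50))
  expect_equal(er2$identified_pct, c(0, 0))
  expect_true(all(is.na(er2$mean_rank)))

  # identified % is non-decreasing in the fraction, mean rank <= window
  er3 <- early_recognition(genes, list(p = genes[c(3, 30, 80)]),
                           fractions = c(0.05, 0.10, 0.50, 1.0))
  expect_true(all(diff(er3$identified_pct) >= 0))
  expect_true(all(er3$mean_rank <= er3$window, na.rm = TRUE))
})

test_that("pathogenic_sets inputs expand to G1, G2 and their union", {
  genes <- sprintf("G%03d", 1:50)
  ps <- pathogenic_gene_sets(genes[1:4], genes[3:8])
  er <- early_recognition(genes, ps, fractions = 0.2)
  expect_setequal(er$set, c("G1", "G2", "G1+G2"))
  expect_equal(er$n_identified[er$set == "G1+G2"], 8L)
})

test_that("group rank summaries average over the genes found in the universe", {
  tab <- toy_consensus(sprintf("G%03d", 1:300))
  s <- group_rank_summary(tab, sprintf("G%03d", 1:3))
  expect_equal(s$mean_rank, 2.0)
  s2 <- group_rank_summary(tab, c("G100", "G200", "G300"))
  expect_equal(s2$mean_rank, 200.0)
  s3 <- group_rank_summary(tab, c("NOPE"))
  expect_equal(s3$n_found, 0L)
  expect_true(is.na(s3$mean_rank))
  s4 <- group_rank_summary(tab, c("G001", "MISSING"))
  expect_equal(s4$n_missing, 1L)
})

test_that("with signal and partial coverage the consensus beats the best single method early", {
  recog_at_1pct <- function(genes, truth) {
    early_recognition(genes, list(p = truth), fractions = 0.01)$identified_pct
  }
  cons <- numeric(20); best <- numeric(20)
  per_method <- matrix(NA_real_, nrow = 20, ncol = 6)
  for (s in 1:20) {
    spec <- simulation_spec(n_genes = 1000, n_pathogenic = 50, n_methods = 6,
                            signal = 1.5, coverage = 0.7, seed = 9000 + s)
    sim <- simulate_method_rankings(spec)
    tab <- consensus_table(sim$rankings, m_total = 12)
    cons[s] <- recog_at_1pct(tab$gene, sim$pathogenic$union)
    per_method[s, ] <- vapply(sim$rankings, function(r) {
      recog_at_1pct(r$genes, sim$pathogenic$union)
    }, numeric(1L))
  }
  expect_gte(mean(cons), max(colMeans(per_method)))
})
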