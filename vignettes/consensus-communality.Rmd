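---
title: "Consensus gene prioritization and network communality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus gene prioritization and network communality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priocomm)
```

## The problem

Disease-gene prioritization tools rank the genome by predicted relevance to
a disease, but individual tools disagree widely: each has its own evidence
sources, coverage and biases. `priocomm` implements a consensus strategy
that aggregates the ranked outputs of several such tools into one score,
selects a rational cutoff for how many top genes to keep, and then carries
the selected genes through a network-biology workflow: community detection
in a confidence-filtered protein–protein interaction (PPI) network,
consensus-weighted pathway scoring, clustering of communities to nominate
the most disease-relevant ones, and validation against an external
interaction network and a pooled shRNA viability screen.

## The consensus model

Each method $j$ contributes a ranked list of $N_j$ genes. Raw scores from
heterogeneous tools are not comparable, so each list is rank-normalized:

$$GeneN_{i,j} = \frac{N_j - r_{i,j}}{N_j - 1},$$

so the top gene of a method scores 1 and the bottom gene 0. Genes a method
does not report have *no* normalized score — absence is not a zero, which
keeps partial coverage from silently dragging scores down.

The consensus score of gene $i$ combines the average normalized score with
the number of methods $n_i$ that predict the gene at all:

$$Gene_i = \sqrt{\frac{n_i - 1}{m_{\mathrm{total}} - 1}\cdot
  \frac{1}{n_i}\sum_j GeneN_{i,j}},$$

a geometric mean of rank quality and cross-method agreement. A gene
predicted by a single method scores exactly 0 however well it ranks: the
consensus deliberately requires corroboration. The normalizing constant
$m_{\mathrm{total}}$ defaults to 12 and is configurable via
`run_config(m_total = )`; it is the ceiling on the number of methods, and
can exceed the number actually supplied (scores then simply cannot reach
1). Genes are sorted by $Gene_i$ (ties: more predicting methods first, then
alphabetically — a documented, deterministic rule) and the resulting rank
is normalized once more into $ConsenScore_i = (N - \mathrm{rank}_i)/(N-1)$.

### Rational cutoff

How many top genes to carry forward is decided with a curated truth set
(genes with perturbation-phenotype evidence, G1, and polymorphism
meta-analysis evidence, G2). At every rank $i$,

$$I_i = \frac{TP_i}{FP_i + 1}\, ConsenScore_i,$$

where $TP_i$ and $FP_i$ are the cumulative truth-set and
non-truth-set tallies down to rank $i$. Two readings are implemented
(`run_config(tp_fp_mode = )`): `"rates"` (the default) divides the
cumulative counts by the class totals in the universe; `"counts"` uses the
raw tallies. The rate reading is the default because only it produces a
maximal $I$ of the magnitude reported in the analysis this package models
(raw counts push the index far below it when the truth set is small
relative to the list). The first rank attaining the maximum is the cutoff.

Early-recognition benchmarking (`early_recognition()`) evaluates any
ranking at top-list fractions $f$ with window $\lfloor f N\rfloor$,
reporting the percentage of the truth set identified (absent genes count
as never identified) and the mean rank of the identified members.

## Network communality

The PPI network is read as a STRING-style weighted edge list (scores on
either the unit or the 0–1000 scale, auto-detected) and filtered at the
"highest confidence" cutoff of 0.9 with zero node addition: edges below the
cutoff are removed and isolated nodes dropped, nothing is ever added.

Overlapping communities are found by the clique percolation method (CPM):
a community is a maximal union of $k$-cliques chained through
($k{-}1$)-node overlaps. The implementation enumerates maximal cliques
exactly (Bron–Kerbosch with pivoting, via igraph), links two maximal
cliques of size $\ge k$ when they share at least $k-1$ vertices — every
$k$-clique inside one maximal clique is mutually reachable, so this is
equivalent to percolating the $k$-cliques themselves — and takes the
vertex unions of the connected components. The equivalence is not taken on
faith: the test suite compares the output against a brute-force oracle
that enumerates all $k$-subsets on random graphs.

The clique order $k$ trades community count against community size. It is
selected with the size-balance index

$$S^k = \frac{|\,\mathrm{mean}(N^k_g) - \mathrm{median}(N^k_g)\,|}{N^k_c},$$

over the community sizes $N^k_g$ and count $N^k_c$: both very small and
very large $k$ skew the size distribution. `select_k()` takes the $k$
minimizing $S^k$, skipping orders with no community; ties resolve toward
the larger $k$ (fewer, tighter communities), since the index describes
imbalance and a tie leaves no reason to keep looser communities. The
even-length median is the midpoint of the central pair.

Communities are profiled (`community_profiles()`) by mean consensus score,
mean consensus rank, mean degree *in the full filtered network* (not the
community subgraph — community membership should not hide a hub's global
connectivity), truth-set count, and an upper-tail hypergeometric
enrichment p-value. The hypergeometric tail is computed by exact
summation in log space; the background population is the filtered
network's node set with the truth-set genes present in the network as
successes. The degree contrast between truth-set and other genes is
assessed with a one-sided label-permutation test
(`degree_group_comparison()`), since the underlying claim is about mean
degree under an exchangeable null.

## Pathway weighting

Pathway catalogs (GMT) are scored in four steps. Each community $k$ gets a
weight $W_k$, its mean $ConsenScore$; each pathway $m$ gets
$PathRankScore_m$, the mean $W_k$ over the communities sharing at least
one gene with it; $PathGeneScore_m = \sqrt{\langle ConsenScore^m\rangle\,
n_m/N_m}$ combines the mean consensus score of the pathway's genes with
its network coverage ($n_m$ of $N_m$ genes present in the PPI network);
and $PathScore_m = \sqrt{PathRankScore_m \cdot PathGeneScore_m}$.

Two ambiguities in the formulation this package models were resolved as
follows, with the literal alternatives kept as options:

* the $W_k$ denominator is the **community size** (making $W_k$ a
  community average, consistent with per-community score averages being
  reported elsewhere); dividing by the number of communities is available
  via `run_config(w_k_denominator = "n_communities")`;
* the "normalized" $PathRankScore$ entering the final geometric mean is
  the **identity** by default — under this reading the two printed
  component columns of the reference table recompose the printed final
  column to ~7 decimals, which the acceptance checks verify — with
  max-normalization available via `pathway_score_table(normalize_rank =
  "max")`;
* $\langle ConsenScore^m\rangle$ averages over the pathway genes **found**
  in the consensus table (coverage is reported separately) rather than
  zero-filling absent genes.

## Community clustering

Communities are clustered on three features: mean $PathScore$ of linked
pathways, mean degree, and mean consensus rank. The features live on
incommensurate scales (unit scores vs. degrees vs. ranks in the hundreds),
so each column is z-scored before Euclidean k-means; a constant column is
mapped to zero rather than NaN. `stats::kmeans` (Hartigan–Wong) is used
with 25 random restarts and a fixed seed — the standard, well-tested R
implementation; with three features and tens of communities the restart
count, not the update rule, determines solution quality. The default of 3
clusters is configurable. The "most relevant" cluster is chosen by a
lexicographic total order: highest mean pathway score, then highest mean
degree, then lowest (best) mean consensus rank.

## Oncogenomic validation

`degree_spearman()` correlates degree centrality over the genes shared by
two networks (Spearman, two-sided, tie-tolerant); $r^2 = \rho^2$ is
reported alongside $\rho$ as the customary effect-size companion.

RSA scores from pooled shRNA screens are classified per gene
(`classify_sensitivity()`): *sensitive* in a cell line means RSA $\le -3$;
*essential* means sensitive in more than 50% of lines, *inert* in none,
*active* otherwise. The exact-50% boundary is assigned to *active*,
keeping "essential" strict. Genes absent from the screen are an explicit
fourth class, *undetected*, so every percentage's denominator is
auditable. `overlap_report()` produces pairwise intersection counts and
truth-set funnel ratios (rounded to 3 decimals), and
`combined_priority()` merges consensus and screen evidence as
$\sqrt{ConsenScore_i \cdot \mathrm{fraction~sensitive}_i}$ — the same
geometric-mean idiom as the rest of the pipeline; the combiner is
pluggable, and undetected genes rank after all detected ones.

## The synthetic-data generator

`simulation_spec()` defines inputs with known ground truth:

* **Rankings** — each method draws a latent score $\mathcal N(0,1) +
  \mathrm{signal}\cdot\mathbb 1[\text{pathogenic}]$, reports a random
  `coverage` fraction of the universe and ranks by the latent score.
  Normal noise is chosen for its analytic tails; any continuous
  distribution would do. The defaults (20,000 genes, 145 pathogenic split
  40/60 into G1/G2, 8 methods, signal 2, coverage 0.8) mirror the scale
  of the study this package models; signal 2 yields consensus early
  recognition near 55–60% at the 1% window, the regime where aggregation
  visibly beats single methods.
* **Network** — `n_communities` cliques of `clique_size` genes planted in
  a chain, adjacent cliques sharing `overlap` genes; planted edges get
  confidences $\ge 0.9$ so they survive filtering; background
  Erdős–Rényi edges (probability `background_edge_p`) get confidences
  uniform on $[0.4, 1]$, so roughly a sixth of them also survive — the
  noise CPM must tolerate.
* **Pathways** — 70% of each pathway's members from one planted
  community, the rest from the universe, so pathway–community linkage is
  recoverable.
* **Sensitivity** — essential genes receive $\mathcal N(-5,1)$ RSA scores
  in a random subset of at least 60% of cell lines and $\mathcal N(0,1)$
  elsewhere. The subset floor is 60% rather than a bare majority: at
  $-5 \pm 1$ a hit line is sensitive with probability $\approx 0.977$, so
  a 52%-of-lines subset would leave a noticeable fraction of essential
  genes below the strict >50% bar, while at 60% recovery exceeds 99% —
  the designed detectability of the class.

One global seed drives everything through deterministic per-stage
substreams, so stages can be re-run independently.

What the generator does **not** emulate: realistic PPI degree
distributions (hubs, scale-free tails), correlated errors between methods
(literature bias makes real tools agree on famous genes), gene-length or
expression confounders in screens, and pathway catalogs with hierarchical
overlap. Passing tests therefore demonstrate algorithmic correctness and
parameter recovery under the stated statistical model, not performance on
any real cohort.

## Numerical choices and degenerate inputs

* Score ties within a method are broken by input order (stable sort);
  consensus ties by method count, then symbol — all deterministic.
* The hypergeometric tail sums in log space with max-subtraction;
  `k_obs` at or below the support minimum returns exactly 1.
* `s_index` errors on an empty community list rather than returning NaN;
  `select_k` skips empty orders and errors only when no $k$ yields any
  community.
* Empty filtered networks warn rather than error (a cutoff sweep should
  not abort); readers reject malformed files with the offending
  column/line named.
* Gene symbols are matched case-insensitively and stored uppercase
  throughout.

## Problem sizes used by the tests

The package's own test runs use a 1,000–2,000-gene universe with 50–60
truth genes and 5–6 methods for statistical properties (20-seed
averages), graphs of at most 14 nodes for the brute-force CPM comparison
(100 random graphs, $k \in \{3,4,5\}$), full enumeration of the
hypergeometric distribution for all populations up to 12, and one
full-scale run (20,000 genes, 8 methods, network over the selected genes
capped at 1,500) exercised in the acceptance suite and script. At default
settings the synthetic cutoff selects on the order of 800–2,300 genes
depending on the seed, so the simulated network universe is that selected
list.

## Known limitations

* The cutoff index depends on the truth set; with a tiny or
  unrepresentative truth set the selected rank is unstable.
* CPM cost is driven by maximal-clique enumeration; dense networks at low
  confidence cutoffs can blow up combinatorially. The intended regime —
  high-confidence filtering first — keeps the graph sparse.
* The balance index $S^k$ is a heuristic for choosing $k$; it says
  nothing about biological validity of the communities, only about size
  balance.
* The pathway scores are descriptive weights, not calibrated enrichment
  statistics; no multiplicity correction applies to them.
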