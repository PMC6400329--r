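---
title: "Multiscale content clustering of free text with Markov Stability"
author: "mstopics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale content clustering of free text with Markov Stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstopics)
```

## The problem and the model

Large collections of short free-text records (incident reports, case
notes, service feedback) carry structure at several granularities at
once: a report about a mislabelled blood sample is simultaneously about
*samples*, about *documentation*, and about *clinical process*. Methods
that fit a single flat set of topics force one resolution on the data.
`mstopics` instead embeds documents as vectors, builds a sparse geometric
similarity graph over them, and studies a continuous-time random walk on
that graph: groups of documents that transiently trap the diffusing
probability are content clusters, and the diffusion time acts as a
resolution dial. Clusters are *found at every scale in one sweep*, and
robust scales are selected afterwards from stability diagnostics.

### The diffusion and its quality function

For a weighted, undirected, connected graph with adjacency $A$, degree
matrix $D$ and degree vector $d$, the random-walk Laplacian is
$L_{\mathrm{RW}} = I - D^{-1}A$, the kernel of the associated
continuous-time Markov process is $P(t) = e^{-t L_{\mathrm{RW}}}$, and
the stationary distribution is $\pi = d / \sum_i d_i$. For a partition
with binary indicator matrix $H_{N\times C}$, the clustered
autocovariance is

$$R(t, H) = H^\top\!\left[\Pi P(t) - \pi\pi^\top\right] H,
  \qquad \Pi = \mathrm{diag}(\pi),$$

whose entry $(\alpha,\beta)$ is the probability that a walker starting
in community $\alpha$ under stationarity is found in community $\beta$
at time $t$, minus the probability of that event by chance. The quality
of the partition at time $t$ is its **Markov Stability**
$r(t,H) = \mathrm{trace}\, R(t,H)$. Two exact identities anchor the
implementation and its tests: the one-community partition always scores
$0$, and at $t = 0$ the all-singletons partition attains the maximum
$1 - \sum_i \pi_i^2$. All entries of $R$ sum to zero for every $H$ and
$t$ (conservation of probability).

Because the walk is reversible, $\Pi P(t)$ is symmetric. The package
computes $P(t)$ from a single eigendecomposition of the symmetric
normalised Laplacian
$L_{\mathrm{sym}} = D^{1/2} L_{\mathrm{RW}} D^{-1/2}$, which makes the
scan over hundreds of Markov times cheap (one decomposition, then one
matrix reconstruction per time) and keeps
$B(t) = \Pi P(t) - \pi\pi^\top$ symmetric to machine precision. The
dense matrix exponential (`Matrix::expm`) is used as an independent
cross-check in the test suite, never in the scan itself. The
implementation is dense and intended for analysis sets up to a few
thousand documents; sparsity of $A$ does not persist in $P(t)$, so
nothing is gained from sparse kernels at these sizes.

### Optimisation

$B(t)$ has negative entries by construction, so the usual
degree-product shortcuts of modularity optimisers do not apply. The
package's Louvain variant (compiled) computes all merge and move gains
directly from aggregated entries of $B(t)$: local moves from a singleton
start, visiting nodes in a shuffled order, followed by graph aggregation
and repetition until no gain remains. The node order is the only source
of randomness; per-run orders are derived from a master seed by a
counter, so the whole ensemble is reproducible. At each time the best of
`n_runs` runs (default 500, as in the method's standard operating
point) is kept together with the `n_top` best (default 50). After the
per-time scan, every stored optimum is re-scored at every other time in
one sweep and replaces the incumbent where it scores higher — the
optimisation is NP-hard, and a partition found at one resolution is
often the better optimum at a neighbouring one. A single sweep (rather
than iterating to convergence) is used: in practice the sweep only
propagates partitions into adjacent plateaus, and a second sweep changes
nothing on any fixture we generate.

On every fixture graph with $N \le 8$ nodes the ensemble optimum is
verified against exhaustive enumeration over all set partitions (4140
at $N = 8$) at $t \in \{0.1, 1, 10\}$.

### Scale selection

Two diagnostics identify resolutions worth reporting. The ensemble
variation of information $VI(t)$ — the mean pairwise VI among the top
`n_top` partitions at $t$ — measures reproducibility of the
optimisation; a dip means different starting points agree. The
cross-time matrix $VI(t, t')$ between optimal partitions measures
persistence; a plateau means the same partition is optimal over an
extended range of resolutions. `select_scales()` returns times that are
local minima of $VI(t)$ at or below its `dip_quantile` quantile
(default 0.25) and sit inside a contiguous block where
$VI(t, t') < $ `plateau_eps` (default 0.05 nats) of length at least
`min_plateau` grid points (default 3), merging candidates that carry
the same partition and ranking by plateau length.

Two policies here were genuinely open design choices:

* **Trivial endpoints.** The all-singletons partition is optimal as
  $t \to 0$ and the one-community partition as $t \to \infty$; both are
  maximally robust and carry no cluster structure. They are excluded by
  default, and the exclusion is applied *at the same VI resolution that
  defines a plateau*: a candidate within `plateau_eps` of either
  endpoint (for example a partition separating 31 of 32 nodes) is
  treated as that endpoint. Without this, the near-singleton fringe of
  the sweep chains into an apparently long plateau and is reported as a
  scale.
* **The time grid.** The default grid is geometric with 200 points on
  $[10^{-2}, 10^{2}]$, matching the span commonly used for document
  graphs of a few thousand nodes (and 50 times cheaper than a linear
  0.01-step grid, while placing points evenly in the log-time domain
  where plateaus live). A fixed upper limit, however, can stop short of
  the coarsest structure: the slowest community merge resolves at times
  comparable to the relaxation time $1/\lambda_2$ of the diffusion's
  slowest mode, and on a 100-document MST-kNN graph with $k = 5$ we
  measure $1/\lambda_2 \approx 10^3$. `auto_time_grid()` therefore sets
  the upper limit to $4/\lambda_2$ (the slowest mode decayed to
  $e^{-4} \approx 2\%$), and the end-to-end corpus analyses use it.

## From text to graph

**Tokens.** `normalize_tokens()` lowercases, tokenises into
alphanumeric word tokens, drops punctuation and digit-only tokens, stems
with the Porter algorithm (implemented in the package from the published
rule tables, with canonical outputs frozen as test fixtures) and removes
stop words. Stop words are matched against both raw and stemmed forms by
default — the stemmer maps e.g. "wills" onto the stop word "will", and
matching only raw forms would let such variants leak through; a flag
restores raw-only or stemmed-only matching. A parallel path for
human-readable summaries (`summary_tokens()`) keeps content words
(adjectives, nouns, verbs) using a rule-based filter — closed-class
function words, *be/have/do* inflections and `-ly` adverbs removed —
and lemmatises survivors with suffix rules mirroring Porter's
undouble-or-restore-e logic. This rule-based tagger is deliberately
simple; it is not a statistical POS tagger, and words whose surface form
is ambiguous (e.g. nominal uses of verbs) are kept rather than
disambiguated.

**Vectors.** Two routes produce document vectors. The TF-iDF baseline
uses raw term counts weighted by the smoothed inverse document frequency
$\log\frac{1+N}{1+\mathrm{df}} + 1$ (the unsmoothed $\log(N/\mathrm{df})$
convention is available and used in tests of the boundary case where a
word occurs in every document). The paragraph-vector route (PV-DBOW)
trains document vectors to predict their own sampled words by negative
sampling; the trainer is single-threaded with its own deterministic RNG,
so training is bit-reproducible — the usual multi-worker
order-nonreproducibility is deliberately traded away for testability.
Inference for a document seeds its RNG from the inference seed and a
hash of the document's in-vocabulary token sequence, so identical
documents always receive identical vectors. Defaults (d = 300, 10
epochs, window 15, min count 5, 5 negative samples, subsampling 1e-3)
are the method's standard operating point for large clinical corpora;
the synthetic-corpus tests use d = 32 and more epochs, appropriate for
a 100-document corpus where each document must be visited many more
times for the SGD to converge.

**Graph.** Cosine similarities are converted to distances, rescaled by
the *maximum off-diagonal* distance (the diagonal is identically zero
and uninformative), and flipped back to similarities
$\hat S \in [0, 1]$, so the most dissimilar pair sits exactly at 0. If
every pairwise distance is zero the geometry is degenerate; $\hat S$ is
defined as all ones and a warning raised. The MST-kNN sparsifier keeps
the union of the Kruskal minimum spanning tree of $\hat D$ (ties broken
by sorting on distance, then smaller node index, then larger — the MST
is bit-reproducible under ties) and each node's $k$ nearest neighbours
(directed neighbourhoods, symmetrised; ties at the $k$-th distance all
included, so the result is order-independent). Default $k = 13$;
nearest neighbours are computed on distances, which gives the same
ranking as similarities. Edge weights are the $\hat S$ entries.

## Scoring partitions

**Aggregate PMI** is an intrinsic coherence score needing no labels.
Word probabilities are document frequencies over the analysis set (the
co-occurrence unit is the whole document); for each cluster the `top_n`
(default 10) most frequent words by within-cluster document frequency
are taken (ties lexicographic), the median pairwise
$\mathrm{PMI} = \log\frac{P(w_1 w_2)}{P(w_1)P(w_2)}$ over those words is
computed, and cluster medians are averaged weighted by cluster size.
Pairs that never co-occur have $\mathrm{PMI} = -\infty$; a configurable
floor, default $-\log N_{\mathrm{docs}}$ (the largest magnitude any
observed pair can attain), keeps medians defined. Top words are
*within-cluster* frequent, not globally frequent words restricted to
the cluster: the score should reward what the cluster is about, not
what the corpus is about.

**NMI** uses the geometric-mean normalisation
$I(C,D)/\sqrt{H(C)H(D)}$ (note other libraries default to the
arithmetic-mean variant; tests therefore cross-check the components
against `igraph::compare`'s VI rather than its NMI). **Contingency
z-scores** standardise cluster-by-category counts against the
fixed-margin hypergeometric null, $E = n_c n_k / N$ and
$\mathrm{Var} = n_c n_k (N-n_c)(N-n_k) / (N^2 (N-1))$; cells whose null
variance is zero get $z = 0$.

## The synthetic generators, and what passing tests show

`generate_corpus()` plants a two-level hierarchy: sub-topics with
disjoint keyword sets nested in super-topics with shared keyword sets,
over a common background vocabulary. Defaults: 2 super-topics × 2
sub-topics × 25 documents of 50 tokens; 70% of tokens are on-topic,
split evenly between the sub-topic signature and the super-topic theme
(10 + 10 keywords) over a 200-word background. The even split matters:
the super-level is only geometrically recoverable when the shared theme
carries weight comparable to the sub-signature — with a much weaker
theme the coarse cut exists in the graph spectrum but never dominates
the stability objective. Keywords are alphanumeric pseudo-words
(`t01s02kw03`) that pass through stemming and stop-word removal
unchanged, so integration tests exercise clustering behaviour, not
linguistic preprocessing. `generate_multiscale_graph()` plants the
analogous structure directly as a graph: 4 cliques of 8 nodes paired
into 2 groups, with weight tiers 1 / 0.4 / 0.05 and connection
probabilities 0.3 / 0.15, i.e. per-node interaction strengths of about
7 : 1 : 0.1 across the three levels — three well-separated scales.

What the passing tests do show: the full pipeline — tokens, vectors
(both routes), normalised similarities, MST-kNN, the stability scan,
scale selection — recovers exactly the planted partitions at both
levels (NMI = 1) from data it has never seen labelled, and the
optimiser attains provable optima on all exhaustively checkable graphs.
What they do not show: performance on real clinical language. The
generator produces no misspellings, no abbreviations, no class
imbalance, no semantic overlap between topics — the hard parts of real
free text. Scores on real corpora will be far from 1, and the paragraph
-vector route's advantage over bag-of-words (which on the clean
synthetic corpus is a tie at ceiling, asserted as a non-strict
inequality) only materialises where semantics, not vocabulary overlap,
separate topics.

## Numerical choices and limitations

* Eigenvalues of $L_{\mathrm{sym}}$ are clipped at zero (they are
  nonnegative analytically); kernels are exact to ~1e-13 against the
  dense exponential, and `P(0)` returns the exact identity.
* Louvain accepts a move only for a gain above $10^{-12}$, with ties
  broken toward the smaller community label; best-of-ensemble ties keep
  the lowest run index. Equal-stability partitions are therefore
  selected deterministically.
* VI is computed in natural-log units and clamped at 0; partitions are
  compared for equality at VI $< 10^{-9}$.
* The test-suite and acceptance problem sizes (32-node benchmark
  graphs, 100-document corpora, 40–48 point time grids, 50–100 Louvain
  runs) are chosen so the planted structure is unambiguous while the
  full suite runs in minutes; all of them are configuration, not code,
  and scale up unchanged.
* Degenerate inputs: empty corpora, all-stop-word documents,
  out-of-vocabulary documents, zero-norm vectors, isolated nodes,
  disconnected generated graphs and zero-entropy partitions all have
  defined behaviour (empty outputs, warnings, or errors naming the
  offending item) covered by tests.
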