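# mstopics

Unsupervised, multi-resolution discovery of content-based clusters in
collections of free-text records — short incident reports, case notes,
feedback forms — where useful groupings are not known in advance and a
single "number of topics" is the wrong question.

The package implements a full pipeline:

1. **Preprocess**: lowercase word tokenisation, removal of punctuation and
   digit-only tokens, Porter stemming, stop-word removal; a parallel
   content-word path (rule-based adjective/noun/verb filtering plus
   lemmatisation) produces readable tokens for summaries.
2. **Embed**: each document becomes a fixed-dimension vector, either by a
   PV-DBOW paragraph-vector model (deterministic single-threaded
   negative-sampling SGD, compiled) or by a TF-iDF bag-of-words baseline.
3. **Graph**: pairwise cosine similarities are rescaled by the maximum
   off-diagonal cosine distance, `S_hat = 1 - D_cos / max(D_cos)`, and
   sparsified to the **MST-kNN** graph: the union of the minimum spanning
   tree of the distance matrix (global connectivity) and each node's *k*
   nearest neighbours (local geometry), with kept edges weighted by
   `S_hat`.
4. **Partition across scales with Markov Stability.** For the random-walk
   Laplacian `L_RW = I - D^{-1}A`, kernel `P(t) = expm(-t L_RW)` and
   stationary distribution `pi`, the clustered autocovariance of a
   partition with indicator matrix `H` is

   ```
   R(t, H) = H' [ Pi P(t) - pi pi' ] H,      r(t, H) = trace R(t, H)
   ```

   `r(t, H)` measures how much diffusing probability stays trapped inside
   communities over Markov time `t`, beyond chance. Small `t` resolves
   fine partitions, large `t` coarse ones; `t` is the resolution knob. At
   each time on a (log-spaced) grid, `r` is maximised by an ensemble of
   Louvain runs on the signed matrix `B(t) = Pi P(t) - pi pi'`.
5. **Select robust scales** where the ensemble variation of information
   `VI(t)` dips (the optimisation is reproducible) and the cross-time
   `VI(t, t')` shows an extended plateau (the partition persists across
   resolution).
6. **Evaluate**: intrinsic topic coherence by aggregate pointwise mutual
   information (size-weighted median PMI over each cluster's top words),
   agreement with reference labels by normalised mutual information
   `NMI = I / sqrt(H H')`, and cluster-by-category contingency tables
   standardised against the hypergeometric (fixed-margin) null.

A synthetic-data module generates corpora and graphs with planted
two-level (sub-topic within super-topic) structure so the whole pipeline
is testable end to end without any external data.

## Worked example

```r
library(mstopics)

# a synthetic corpus: 2 super-topics x 2 sub-topics x 25 documents
gen  <- generate_corpus(topic_spec(seed = 1))
corp <- preprocess_corpus(gen$corpus)

# TF-iDF vectors -> normalised similarities -> MST-kNN graph (k = 5)
vec <- tfidf_vectors(corp)
G   <- mst_knn(similarity_matrix(vec), k = 5)

# Markov Stability scan over a grid reaching the slowest diffusion scale
res <- ms_scan(G, auto_time_grid(G, n = 48), n_runs = 60, n_top = 20,
               seed = 2)
sel <- select_scales(res)
print(sel)
#> ms_scales: 2 selected scale(s)
#>    time n_comms plateau_len
#> 1   1.1       4          17
#> 2 159.5       2          13

# agreement with the planted labels at each selected scale
nmi(sel$memberships[[which(sel$n_comms == 4)]], gen$sub_labels[G$ids])
#> [1] 1
nmi(sel$memberships[[which(sel$n_comms == 2)]], gen$super_labels[G$ids])
#> [1] 1

# intrinsic topic coherence of the fine partition
aggregate_pmi(sel$memberships[[which(sel$n_comms == 4)]], corp)
#> [1] 0.7977176
```

The selector found exactly the two planted resolutions: a fine 4-way
partition matching the sub-topics and a coarse 2-way partition matching
the super-topics, both in perfect agreement with the planted labels
(NMI = 1). The aggregate PMI (about 0.80) says the fine clusters' top
words co-occur in documents far more than chance.

The same analysis runs from the shell via the bundled CLI
(`inst/cli/mstopics`): `mstopics synth`, `preprocess`, `embed`, `graph`,
`scan`, `select`, `evaluate`, `report`, each writing its artifacts into a
working directory.

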