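# Partition scoring: intrinsic topic coherence via aggregate pointwise
# mutual information over each cluster's top words, agreement with
# reference labels via normalised mutual information, and cluster-by-
# category contingency tables standardised against the fixed-margin
# (hypergeometric) independence null.

#' Document co-occurrence statistics for PMI
#'
#' Builds an inverted index of word -> documents containing it. The
#' co-occurrence unit is the whole document: a word pair co-occurs when
#' both words appear anywhere in the same document.
#'
#' @param corpus an `ms_corpus` with tokens, or a list of token vectors.
#' @return a `word_stats` object with `index` (word -> sorted doc indices)
#'   and `n_docs`.
#' @export
word_stats <- function(corpus) {
  toks <- .as_token_list(corpus, "tokens")
  n <- length(toks)
  uniq <- lapply(toks, unique)
  words <- unlist(uniq, use.names = FALSE)
  docs <- rep(seq_len(n), lengths(uniq))
  index <- split(docs, words)
  structure(list(index = index, n_docs = n), class = "word_stats")
}

#' @export
print.word_stats <- function(x, ...) {
  cat("word_stats:", length(x$index), "words over", x$n_docs, "documents\n")
  invisible(x)
}

#' Pointwise mutual information of a word pair
#'
#' `PMI(w1, w2) = log( P(w1 w2) / (P(w1) P(w2)) )` (natural log), with
#' probabilities estimated as document frequencies over the corpus. A
#' pair that never co-occurs has PMI of minus infinity; the configurable
#' `floor` (default `-log(n_docs)`, the natural magnitude scale of the
#' corpus) is returned instead so that medians stay defined.
#'
#' @param stats a [word_stats()] object.
#' @param w1,w2 words; both must occur in the corpus.
#' @param floor value returned for zero co-occurrence.
#' @return scalar PMI.
#' @export
pmi <- function(stats, w1, w2, floor = -log(stats$n_docs)) {
  stopifnot(inherits(stats, "word_stats"))
  d1 <- stats$index[[w1]]
  d2 <- stats$index[[w2]]
  if (is.null(d1)) stop("word not in corpus: ", w1)
  if (is.null(d2)) stop("word not in corpus: ", w2)
  N <- stats$n_docs
  co <- length(intersect(d1, d2))
  if (co == 0L) return(floor)
  log((co / N) / ((length(d1) / N) * (length(d2) / N)))
}

#' Aggregate PMI topic coherence of a partition
#'
#' For each cluster, takes its `top_n` most frequent words (by
#' within-cluster document frequency, ties broken lexicographically),
#' computes the median PMI over all unordered pairs of those words, and
#' returns the cluster-size-weighted average of the medians:
#' `sum_i (n_i / N) * median_i`. A cluster with fewer than two distinct
#' words contributes the PMI floor (with a warning).
#'
#' @param partition membership vector, one entry per document.
#' @param corpus an `ms_corpus` with tokens, or a list of token vectors
#'   (same order as `partition`).
#' @param stats optional precomputed [word_stats()]; computed from
#'   `corpus` when missing. PMI statistics are always corpus-wide, not
#'   per-cluster.
#' @param top_n number of top words per cluster (default 10).
#' @param floor PMI floor for zero co-occurrence.
#' @return scalar aggregate PMI.
#' @export
aggregate_pmi <- function(partition, corpus, stats = NULL, top_n = 10L,
                          floor = NULL) {
  stopifnot(top_n >= 2L)
  toks <- .as_token_list(corpus, "tokens")
  memb <- as_partition(partition)
  if (length(memb) != length(toks))
    stop("partition length must equal document count")
  if (is.null(stats)) stats <- word_stats(corpus)
  if (is.null(floor)) floor <- -log(stats$n_docs)
  N <- length(toks)
  out <- 0
  for (cl in seq_len(max(memb))) {
    in_cl <- which(memb == cl)
    dfreq <- table(unlist(lapply(toks[in_cl], unique), use.names = FALSE))
    if (length(dfreq) < 2L) {
      warning("cluster ", cl, " has fewer than 2 distinct words; ",
              "contributes the PMI floor")
      out <- out + (length(in_cl) / N) * floor
      next
    }
    wt <- names(dfreq)[order(-as.numeric(dfreq), names(dfreq))]
    S <- utils::head(wt, top_n)
    prs <- utils::combn(S, 2L)
    vals <- vapply(seq_len(ncol(prs)), function(j)
      pmi(stats, prs[1, j], prs[2, j], floor = floor), numeric(1))
    out <- out + (length(in_cl) / N) * stats::median(vals)
  }
  out
}

#' Normalised mutual information between two partitions
#'
#' `NMI(C, D) = I(C, D) / sqrt(H(C) H(D))` with natural-log entropies:
#' bounded in `[0, 1]`, equal to 1 iff the partitions coincide up to
#' relabelling. Undefined (error) when either partition has zero entropy.
#'
#' @param c1,c2 membership vectors over the same node set.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(c1, c2) {
  if (length(c1) != length(c2)) stop("partitions are over different node sets")
  .nmi_from_counts(table(c1, c2))
}

.nmi_from_counts <- function(counts) {
  p <- counts / sum(counts)
  pc <- rowSums(p)
  pd <- colSums(p)
  Hc <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  Hd <- -sum(pd[pd > 0] * log(pd[pd > 0]))
  if (Hc <= 0 || Hd <= 0) stop("NMI undefined for trivial partition")
  nz <- p > 0
  I <- sum(p[nz] * log(p[nz] / (pc[row(p)[nz]] * pd[col(p)[nz]])))
  min(max(I / sqrt(Hc * Hd), 0), 1)
}

#' Cluster-by-category contingency table with hypergeometric z-scores
#'
#' Cross-tabulates cluster memberships against reference labels and
#' standardises each cell against the fixed-margin independence null:
#' under the hypergeometric null the cell count has mean
#' `n_c n_k / N` and variance
#' `n_c n_k (N - n_c)(N - n_k) / (N^2 (N - 1))`. Cells whose null
#' variance is zero (an empty or exhaustive margin) get z = 0. The NMI
#' between partition and labels is included.
#'
#' @param partition membership vector.
#' @param labels reference label vector, same length and order.
#' @return a `contingency_report`: `counts` (C x K), `zscores` (C x K),
#'   `nmi`.
#' @export
contingency_zscores <- function(partition, labels) {
  if (length(partition) != length(labels))
    stop("every node must be labelled")
  memb <- as_partition(partition)
  counts <- table(cluster = memb, category = as.character(labels))
  N <- sum(counts)
  nc <- rowSums(counts)
  nk <- colSums(counts)
  E <- outer(nc, nk) / N
  V <- outer(nc * (N - nc), nk * (N - nk)) / (N^2 * (N - 1))
  Z <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  pos <- V > 0
  Z[pos] <- (counts[pos] - E[pos]) / sqrt(V[pos])
  structure(list(counts = unclass(counts), zscores = Z,
                 nmi = .nmi_from_counts(counts)),
            class = "contingency_report")
}

#' @export
print.contingency_report <- function(x, ...) {
  cat("contingency_report:", nrow(x$counts), "clusters x",
      ncol(x$counts), "categories; NMI =", round(x$nmi, 4), "\n")
  invisible(x)
}

#' Per-cluster n-gram content summaries
#'
#' For each cluster, pools the `summary_tokens` of its documents and
#' returns the `n_top` most frequent 1-, 2- and 3-grams, as input for
#' word-cloud rendering.
#'
#' @param partition membership vector, one entry per document.
#' @param corpus an `ms_corpus` with `summary_tokens`, or a list of
#'   summary-token vectors.
#' @param n_top number of n-grams kept per cluster (default 20).
#' @return named list (one element per cluster) of named count vectors.
#' @export
cluster_summaries <- function(partition, corpus, n_top = 20L) {
  toks <- .as_token_list(corpus, "summary_tokens")
  memb <- as_partition(partition)
  if (length(memb) != length(toks))
    stop("partition length must equal document count")
  out <- vector("list", max(memb))
  names(out) <- paste0("cluster_", seq_len(max(memb)))
  for (cl in seq_len(max(memb))) {
    freqs <- ngram_frequencies(toks[memb == cl], n_range = c(1L, 3L))
    out[[cl]] <- utils::head(freqs, n_top)
  }
  out
}

#' Sankey links between a partition and reference labels
#'
#' Flattens the contingency counts into (source, target, value) triples
#' for external Sankey plotting.
#'
#' @param partition membership vector.
#' @param labels reference label vector.
#' @return data.frame with columns `source`, `target`, `value`
#'   (nonzero cells only).
#' @export
sankey_links <- function(partition, labels) {
  counts <- table(as_partition(partition), as.character(labels))
  idx <- which(counts > 0, arr.ind = TRUE)
  data.frame(source = paste0("cluster_", rownames(counts)[idx[, 1]]),
             target = colnames(counts)[idx[, 2]],
             value = as.integer(counts[idx]),
             stringsAsFactors = FALSE)
}
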