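# Synthetic corpora and graphs with planted quasi-hierarchical structure:
# sub-topics nested in super-topics for the text pipeline, and cliques
# nested in groups for the partitioning core. Vocabulary items are
# pronounceable alphanumeric pseudo-words so that stemming and stop-word
# removal pass them through unchanged, isolating clustering behaviour from
# linguistic preprocessing.

#' Specification of a planted-topic synthetic corpus
#'
#' Documents are short token sequences: each token comes from the
#' document's own sub-topic keyword set united with its super-topic's
#' shared keyword set (with probability `keyword_rate`), otherwise from a
#' common background vocabulary. Sub-topic keyword sets are pairwise
#' disjoint. The defaults emulate a small corpus of short, noisy reports
#' drawn from a two-level topic hierarchy: 2 super-topics x 2 sub-topics
#' x 25 documents of 50 tokens, with 70% on-topic tokens split evenly
#' between the sub-topic signature and the super-topic theme (10 + 10
#' keywords), over a 200-word background vocabulary. Equal sub/shared
#' keyword mass puts the corpus in the regime where both hierarchy
#' levels are geometrically recoverable.
#'
#' @param n_super number of super-topics.
#' @param subs_per_super sub-topics per super-topic.
#' @param docs_per_sub documents per sub-topic.
#' @param keywords_per_sub keywords exclusive to each sub-topic.
#' @param shared_super_keywords keywords shared within a super-topic.
#' @param background_vocab size of the background vocabulary.
#' @param doc_length tokens per document.
#' @param keyword_rate probability a token is drawn from the topic
#'   keywords rather than the background, in (0, 1].
#' @param seed RNG seed.
#' @return a `topic_spec` list.
#' @export
topic_spec <- function(n_super = 2L, subs_per_super = 2L, docs_per_sub = 25L,
                       keywords_per_sub = 10L, shared_super_keywords = 10L,
                       background_vocab = 200L, doc_length = 50L,
                       keyword_rate = 0.7, seed = 1L) {
  stopifnot(n_super >= 1, subs_per_super >= 1, docs_per_sub >= 1,
            keywords_per_sub >= 1, shared_super_keywords >= 0,
            background_vocab >= 1, doc_length >= 1,
            keyword_rate > 0, keyword_rate <= 1)
  structure(list(n_super = as.integer(n_super),
                 subs_per_super = as.integer(subs_per_super),
                 docs_per_sub = as.integer(docs_per_sub),
                 keywords_per_sub = as.integer(keywords_per_sub),
                 shared_super_keywords = as.integer(shared_super_keywords),
                 background_vocab = as.integer(background_vocab),
                 doc_length = as.integer(doc_length),
                 keyword_rate = keyword_rate, seed = as.integer(seed)),
            class = "topic_spec")
}

#' Generate a synthetic corpus with planted two-level topics
#'
#' @param spec a [topic_spec()].
#' @return list with `corpus` (an `ms_corpus`; `category` holds the
#'   super-topic label), `sub_labels` and `super_labels` (character
#'   vectors, one entry per document). Fully reproducible from
#'   `spec$seed`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "topic_spec"))
  .with_seed(spec$seed, function() {
    n_sub_total <- spec$n_super * spec$subs_per_super
    n_docs <- n_sub_total * spec$docs_per_sub
    sub_kw <- lapply(seq_len(n_sub_total), function(s) {
      sup <- (s - 1L) %/% spec$subs_per_super + 1L
      sprintf("t%02ds%02dkw%02d", sup, s, seq_len(spec$keywords_per_sub))
    })
    super_kw <- lapply(seq_len(spec$n_super), function(g)
      if (spec$shared_super_keywords > 0)
        sprintf("t%02dshared%02d", g, seq_len(spec$shared_super_keywords))
      else character(0))
    background <- sprintf("bg%04d", seq_len(spec$background_vocab))
    ids <- sprintf("doc%04d", seq_len(n_docs))
    sub_lab <- character(n_docs)
    super_lab <- character(n_docs)
    text <- character(n_docs)
    i <- 0L
    for (s in seq_len(n_sub_total)) {
      sup <- (s - 1L) %/% spec$subs_per_super + 1L
      pool <- c(sub_kw[[s]], super_kw[[sup]])
      for (d in seq_len(spec$docs_per_sub)) {
        i <- i + 1L
        from_kw <- runif(spec$doc_length) < spec$keyword_rate
        toks <- ifelse(from_kw,
                       sample(pool, spec$doc_length, replace = TRUE),
                       sample(background, spec$doc_length, replace = TRUE))
        text[i] <- paste(toks, collapse = " ")
        sub_lab[i] <- sprintf("sub%02d", s)
        super_lab[i] <- sprintf("super%02d", sup)
      }
    }
    list(corpus = ms_corpus(ids, text, category = super_lab),
         sub_labels = stats::setNames(sub_lab, ids),
         super_labels = stats::setNames(super_lab, ids))
  })
}

#' Generate a weighted graph with planted two-level community structure
#'
#' Builds `n_cliques` cliques of `clique_size` nodes, assigned
#' contiguously to `n_groups` groups. Within-clique edges always exist
#' with weight `w_in`; node pairs in different cliques of the same group
#' are joined with probability `p_in` at weight `w_mid`; pairs across
#' groups with probability `p_between` at weight `w_out` (skipped when
#' `w_out = 0`). If the realised graph is disconnected, a minimal set of
#' repair edges with weight `max(w_out, 1e-6)` is added between
#' components and a warning is emitted.
#'
#' The defaults give three well-separated interaction scales (expected
#' per-node strength about 7 within a clique, about 1 to the partner
#' clique, about 0.1 across groups), so that both the clique level and
#' the group level are recoverable.
#'
#' @param n_cliques number of cliques (fine-level communities).
#' @param clique_size nodes per clique.
#' @param n_groups number of groups (coarse-level communities);
#'   must divide `n_cliques`.
#' @param p_in edge probability between cliques of the same group.
#' @param p_between edge probability across groups.
#' @param w_in,w_mid,w_out edge weights, `w_in > w_mid > w_out >= 0`.
#' @param seed RNG seed.
#' @return list with `graph` (an `ms_graph`), `clique_labels` and
#'   `group_labels` (integer vectors).
#' @export
generate_multiscale_graph <- function(n_cliques = 4L, clique_size = 8L,
                                      n_groups = 2L, p_in = 0.3,
                                      p_between = 0.15, w_in = 1,
                                      w_mid = 0.4, w_out = 0.05,
                                      seed = 1L) {
  stopifnot(n_cliques >= 1, clique_size >= 2, n_groups >= 1,
            n_cliques %% n_groups == 0,
            w_in > w_mid, w_mid > w_out, w_out >= 0,
            p_in >= 0, p_in <= 1, p_between >= 0, p_between <= 1)
  .with_seed(seed, function() {
    N <- n_cliques * clique_size
    clique <- rep(seq_len(n_cliques), each = clique_size)
    per_group <- n_cliques %/% n_groups
    group <- (clique - 1L) %/% per_group + 1L
    A <- matrix(0, N, N)
    for (i in seq_len(N - 1L)) for (j in seq(i + 1L, N)) {
      w <- if (clique[i] == clique[j]) w_in
      else if (group[i] == group[j]) {
        if (runif(1) < p_in) w_mid else 0
      } else {
        if (w_out > 0 && runif(1) < p_between) w_out else 0
      }
      A[i, j] <- A[j, i] <- w
    }
    G <- ms_graph(A)
    comp <- igraph::components(.as_igraph_allow_isolated(G))
    if (comp$no > 1L) {
      warning("generated graph disconnected; adding ", comp$no - 1L,
              " repair edge(s)")
      reps <- vapply(seq_len(comp$no),
                     function(cmp) which(comp$membership == cmp)[1],
                     integer(1))
      eps <- max(w_out, 1e-6)
      for (cmp in seq_len(comp$no - 1L)) {
        A[reps[cmp], reps[cmp + 1L]] <- eps
        A[reps[cmp + 1L], reps[cmp]] <- eps
      }
      G <- ms_graph(A)
    }
    list(graph = G, clique_labels = clique, group_labels = group)
  })
}

.as_igraph_allow_isolated <- function(G) {
  igraph::graph_from_adjacency_matrix(G$A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
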