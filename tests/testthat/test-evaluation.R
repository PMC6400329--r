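# PMI topic coherence, NMI, contingency z-scores, cluster summaries.

test_that("pmi matches hand-counted document co-occurrence fixtures", {
  # perfect co-occurrence: both words in the same half of the docs
  toks <- list(c("a", "b"), c("a", "b"), "z", "z")
  st <- word_stats(toks)
  expect_equal(pmi(st, "a", "b"), -log(1 / 2), tolerance = 1e-12)
  # hand count: N = 4, w1 in {1,2}, w2 in {2,3}: log((1/4)/((1/2)(1/2))) = 0
  toks2 <- list("w1", c("w1", "w2"), "w2", "x")
  expect_equal(pmi(word_stats(toks2), "w1", "w2"), 0)
  # exact independence constructed on N = 8
  toks3 <- list(c("u", "v"), c("u", "v"), "u", "u", "v", "v", "x", "x")
  expect_equal(pmi(word_stats(toks3), "u", "v"), 0)
  # unseen words are errors naming the word
  expect_error(pmi(st, "a", "nope"), "nope")
  # zero co-occurrence hits the floor
  expect_equal(pmi(st, "a", "z"), -log(4))
  expect_equal(pmi(st, "a", "z", floor = -99), -99)
})

test_that("aggregate_pmi reproduces closed-form constructions", {
  # single cluster, two words present in every document: PMI = -log 1 = 0
  toks <- list(c("a", "b"), c("a", "b"))
  expect_equal(aggregate_pmi(rep(1, 2), toks), 0)
  # two equal clusters with exclusive perfectly co-occurring vocabularies,
  # each word in half the docs: aggregate = ln 2
  toks2 <- list(c("a", "b"), c("a", "b"), c("c", "d"), c("c", "d"))
  expect_equal(aggregate_pmi(c(1, 1, 2, 2), toks2), log(2),
               tolerance = 1e-12)
  # invariant to cluster relabelling and document order
  expect_equal(aggregate_pmi(c(2, 2, 1, 1), toks2), log(2),
               tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(aggregate_pmi(c(2, 1, 2, 1), toks2[perm]), log(2),
               tolerance = 1e-12)
  # degenerate cluster contributes the floor, with a warning; the other
  # cluster's pair co-occurs perfectly (each word in 1 of 2 docs): +log 2
  expect_warning(v <- aggregate_pmi(c(1, 2), list(c("a", "b"), "c")),
                 "fewer than 2 distinct words")
  expect_equal(v, 0.5 * log(2) + 0.5 * (-log(2)), tolerance = 1e-12)
})

test_that("planted partitions are more coherent than random ones", {
  wins <- 0L
  for (seed in 1:20) {
    gen <- generate_corpus(topic_spec(docs_per_sub = 10L, doc_length = 20L,
                                      seed = seed))
    corp <- preprocess_corpus(gen$corpus)
    planted <- as_partition(gen$sub_labels[corp$id])
    set.seed(1000 + seed)
    rand <- sample(planted)
    st <- word_stats(corp)
    if (aggregate_pmi(planted, corp, stats = st) >
        aggregate_pmi(rand, corp, stats = st)) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("nmi matches its defining formula and boundary cases", {
  expect_equal(nmi(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  # product-independent partitions on a 4 x 4 grid: I = 0
  rows <- rep(1:4, each = 4)
  cols <- rep(1:4, times = 4)
  expect_equal(nmi(rows, cols), 0)
  # frozen fixture: counts [[2,0],[1,1]] on N = 4, computed independently
  # from the mutual-information/entropy definition
  c1 <- c(1, 1, 2, 2)
  c2 <- c(1, 1, 1, 2)
  expect_equal(nmi(c1, c2), 0.345592029944, tolerance = 1e-10)
  expect_error(nmi(rep(1, 4), c(1, 2, 1, 2)), "trivial")
  expect_error(nmi(1:3, 1:4), "different node sets")
})

test_that("nmi is symmetric and bounded on random partition pairs", {
  set.seed(31)
  for (i in 1:200) {
    a <- random_partition(30, 5)
    b <- random_partition(30, 5)
    if (max(a) == 1L || max(b) == 1L) next
    v <- nmi(a, b)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, nmi(b, a), tolerance = 1e-12)
  }
})

test_that("contingency z-scores follow the hypergeometric null", {
  # perfectly aligned diagonal: positive diagonal, negative off-diagonal
  rep1 <- contingency_zscores(c(1, 1, 2, 2), c("x", "x", "y", "y"))
  expect_true(all(diag(rep1$zscores) > 0))
  expect_true(all(rep1$zscores[row(rep1$zscores) != col(rep1$zscores)] < 0))
  # uniform table matching expectation exactly: all z = 0
  rep2 <- contingency_zscores(rep(1:2, each = 4),
                              rep(c("x", "y"), times = 4))
  expect_equal(unname(rep2$zscores), matrix(0, 2, 2))
  # frozen oracle: counts [[8,2],[2,8]]; z computed independently from the
  # moments of the hypergeometric distribution (dhyper)
  part <- rep(1:2, each = 10)
  lab <- c(rep("x", 8), rep("y", 2), rep("x", 2), rep("y", 8))
  rep3 <- contingency_zscores(part, lab)
  expect_equal(unname(rep3$counts), matrix(c(8, 2, 2, 8), 2, 2))
  expect_equal(rep3$zscores[1, 1], 2.615339366124, tolerance = 1e-10)
  expect_equal(rep3$zscores[1, 2], -2.615339366124, tolerance = 1e-10)
  # margins
  expect_equal(unname(rowSums(rep3$counts)), c(10, 10))
  expect_equal(unname(colSums(rep3$counts)), c(10, 10))
  # NMI from the table equals NMI from memberships
  expect_equal(rep3$nmi, nmi(part, lab), tolerance = 1e-12)
})

test_that("cluster_summaries surfaces the planted content words", {
  # one document cluster
  out <- cluster_summaries(1L, list(c("pressure", "ulcer")))
  expect_equal(out$cluster_1[["pressure ulcer"]], 1L)
  # disjoint vocabularies never share n-grams
  out2 <- cluster_summaries(c(1, 2),
                            list(c("a", "b", "a"), c("c", "d", "c")))
  expect_length(intersect(names(out2$cluster_1), names(out2$cluster_2)), 0)
  # planted-topic corpora: each cluster's top unigram is a planted keyword
  for (seed in 1:10) {
    gen <- generate_corpus(topic_spec(docs_per_sub = 8L, doc_length = 30L,
                                      keyword_rate = 0.9, seed = seed))
    corp <- preprocess_corpus(gen$corpus)
    planted <- as_partition(gen$sub_labels[corp$id])
    sums <- cluster_summaries(planted, corp, n_top = 5L)
    for (cl in seq_along(sums)) {
      grams <- names(sums[[cl]])
      unigrams <- grams[!grepl(" ", grams)]
      expect_match(unigrams[1], "^(t[0-9]+s[0-9]+kw|t[0-9]+shared)")
    }
  }
})

test_that("sankey_links flattens the contingency structure", {
  links <- sankey_links(c(1, 1, 2), c("x", "y", "y"))
  expect_equal(nrow(links), 3L)
  expect_equal(sum(links$value), 3L)
})
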