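# Paragraph-vector training/inference contracts, TF-iDF conventions, and
# the centroid retrieval benchmark.

two_topic_corpus <- function(seed = 3) {
  gen <- generate_corpus(topic_spec(n_super = 2L, subs_per_super = 1L,
                                    docs_per_sub = 50L,
                                    keywords_per_sub = 15L,
                                    shared_super_keywords = 0L,
                                    seed = seed))
  list(corpus = preprocess_corpus(gen$corpus), labels = gen$super_labels)
}

test_that("train_embedding produces vectors of the configured dimension", {
  tc <- two_topic_corpus()
  cfg <- embedding_config(dim = 8L, epochs = 2L, min_count = 2L, seed = 1L)
  model <- train_embedding(tc$corpus, cfg)
  vec <- infer_vectors(model, tc$corpus, epochs = 5L, seed = 1L)
  expect_equal(ncol(vec$vectors), 8L)
  expect_equal(nrow(vec$vectors), 100L)
  expect_false(anyNA(vec$vectors))
})

test_that("training and inference are deterministic given a seed", {
  tc <- two_topic_corpus()
  cfg <- embedding_config(dim = 8L, epochs = 3L, min_count = 2L, seed = 5L)
  v1 <- infer_vectors(train_embedding(tc$corpus, cfg), tc$corpus,
                      epochs = 10L, seed = 2L)
  v2 <- infer_vectors(train_embedding(tc$corpus, cfg), tc$corpus,
                      epochs = 10L, seed = 2L)
  expect_identical(v1$vectors, v2$vectors)
})

test_that("identical documents receive identical inferred vectors", {
  tc <- two_topic_corpus()
  model <- train_embedding(tc$corpus,
                           embedding_config(dim = 8L, epochs = 3L,
                                            min_count = 2L, seed = 1L))
  toks <- list(a = c("t01s01kw01", "t01s01kw02"),
               b = c("t01s01kw01", "t01s01kw02"))
  v <- infer_vectors(model, toks, epochs = 10L, seed = 4L)
  expect_identical(v$vectors[1, ], v$vectors[2, ])
})

test_that("empty inputs are handled per contract", {
  expect_error(train_embedding(list(), embedding_config(dim = 4L)),
               "empty training corpus")
  tc <- two_topic_corpus()
  model <- train_embedding(tc$corpus,
                           embedding_config(dim = 4L, epochs = 2L,
                                            min_count = 2L, seed = 1L))
  v <- infer_vectors(model, list(), seed = 1L)
  expect_equal(nrow(v$vectors), 0L)
  expect_warning(infer_vectors(model, list(z = c("zzz", "qqq")), seed = 1L),
                 "no in-vocabulary tokens")
})

test_that("trained vectors separate disjoint-vocabulary topics", {
  tc <- two_topic_corpus(seed = 11)
  model <- train_embedding(tc$corpus,
                           embedding_config(dim = 16L, epochs = 40L,
                                            min_count = 2L, seed = 7L))
  vec <- infer_vectors(model, tc$corpus, epochs = 40L, seed = 7L)
  X <- vec$vectors / sqrt(rowSums(vec$vectors^2))
  S <- tcrossprod(X)
  lab <- tc$labels[vec$ids]
  same <- outer(lab, lab, "==") & upper.tri(S)
  diff <- (!outer(lab, lab, "==")) & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})

test_that("tfidf_vectors follows the documented weighting conventions", {
  # single doc, single token
  v <- tfidf_vectors(list(d1 = "a"))
  expect_equal(ncol(v$vectors), 1L)
  expect_gt(v$vectors[1, "a"], 0)
  # unsmoothed convention: a token in every document has idf = log(N/N) = 0
  v2 <- tfidf_vectors(list(d1 = c("a", "b"), d2 = c("a", "c")),
                      smooth = FALSE)
  expect_equal(unname(v2$vectors[, "a"]), c(0, 0))
  # hand-computed smoothed fixture: docs {a, b} and {a}; N = 2
  # idf(a) = log(3/3) + 1 = 1; idf(b) = log(3/2) + 1
  v3 <- tfidf_vectors(list(d1 = c("a", "b"), d2 = "a"))
  expect_equal(unname(v3$vectors[1, c("a", "b")]),
               c(1, 1.405465108108), tolerance = 1e-10)
  expect_equal(unname(v3$vectors[2, c("a", "b")]), c(1, 0))
  # nonnegativity
  expect_true(all(v3$vectors >= 0))
})

test_that("centroid_benchmark is exact on separable clusters", {
  set.seed(1)
  X <- rbind(matrix(rnorm(50 * 4, mean = 5), 50, 4),
             matrix(rnorm(50 * 4, mean = -5), 50, 4))
  ids <- sprintf("d%03d", 1:100)
  labels <- stats::setNames(rep(c("x", "y"), each = 50), ids)
  vec <- doc_vectors(ids, X)
  expect_equal(centroid_benchmark(vec, labels, per_centroid = 50L), 100L)
  # scale invariance of cosine ranking
  vec2 <- doc_vectors(ids, 7.3 * X)
  expect_equal(centroid_benchmark(vec2, labels, per_centroid = 50L), 100L)
})

test_that("centroid_benchmark is at chance under permuted labels", {
  set.seed(2)
  X <- matrix(rnorm(100 * 4), 100, 4)
  ids <- sprintf("d%03d", 1:100)
  vec <- doc_vectors(ids, X)
  counts <- vapply(1:20, function(i) {
    set.seed(100 + i)
    perm <- stats::setNames(sample(rep(c("x", "y"), each = 50)), ids)
    centroid_benchmark(vec, perm, per_centroid = 50L)
  }, numeric(1))
  # chance level: 50 x (1/2) per class, 50 total; binomial tolerance
  expect_gt(mean(counts), 40)
  expect_lt(mean(counts), 60)
})

test_that("centroid_benchmark handles exact-duplicate classes and errors", {
  X <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(-1, 0), c(-1, 0))
  ids <- letters[1:6]
  labels <- stats::setNames(rep(c("p", "q", "r"), each = 2), ids)
  vec <- doc_vectors(ids, X)
  # each class is two copies of its own centroid
  expect_equal(centroid_benchmark(vec, labels, per_centroid = 1L), 3L)
  expect_error(centroid_benchmark(vec, labels, per_centroid = 3L),
               "per_centroid")
})

test_that("trained embeddings beat a random-label centroid baseline", {
  tc <- two_topic_corpus(seed = 21)
  model <- train_embedding(tc$corpus,
                           embedding_config(dim = 16L, epochs = 40L,
                                            min_count = 2L, seed = 3L))
  vec <- infer_vectors(model, tc$corpus, epochs = 40L, seed = 3L)
  true_count <- centroid_benchmark(vec, tc$labels, per_centroid = 30L)
  set.seed(9)
  perm <- stats::setNames(sample(unname(tc$labels)), names(tc$labels))
  rand_count <- centroid_benchmark(vec, perm, per_centroid = 30L)
  expect_gt(true_count, rand_count)
})

test_that("vector CSV round-trip preserves ids and values", {
  vec <- doc_vectors(c("a", "b"), matrix(c(1.5, -2, 0, 3), 2, 2))
  tmp <- tempfile(fileext = ".csv")
  write_vectors_csv(vec, tmp)
  back <- read_vectors_csv(tmp)
  expect_identical(back$ids, vec$ids)
  expect_equal(unname(back$vectors), unname(vec$vectors))
})
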