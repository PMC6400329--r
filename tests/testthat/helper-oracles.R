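# Independent oracles and fixture builders shared across tests.

# enumerate every set partition of n elements (restricted growth strings);
# 4140 partitions at n = 8
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, k, i) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a
      return(invisible(NULL))
    }
    for (c in seq_len(k + 1L)) {
      a[i] <- c
      rec(a, max(k, c), i + 1L)
    }
  }
  rec(integer(n), 0L, 1L)
  out
}

# exhaustive maximum of Markov Stability over all partitions (brute force)
exhaustive_max_r <- function(op, P_t, partitions) {
  max(vapply(partitions, function(p) stability(op, P_t, p), numeric(1)))
}

# small named fixture graphs (adjacency matrices), all with N <= 8
fixture_graphs <- function() {
  barbell <- matrix(0, 8, 8)
  barbell[1:4, 1:4] <- 1
  barbell[5:8, 5:8] <- 1
  diag(barbell) <- 0
  barbell[4, 5] <- barbell[5, 4] <- 1

  two_triangles <- matrix(0, 6, 6)
  two_triangles[1:3, 1:3] <- 1
  two_triangles[4:6, 4:6] <- 1
  diag(two_triangles) <- 0

  K4 <- matrix(1, 4, 4)
  diag(K4) <- 0

  path5 <- matrix(0, 5, 5)
  for (i in 1:4) path5[i, i + 1] <- path5[i + 1, i] <- 1

  cycle6 <- matrix(0, 6, 6)
  for (i in 1:5) cycle6[i, i + 1] <- cycle6[i + 1, i] <- 1
  cycle6[1, 6] <- cycle6[6, 1] <- 1

  star4 <- matrix(0, 4, 4)
  star4[1, 2:4] <- star4[2:4, 1] <- 1

  list(barbell = barbell, two_triangles = two_triangles, K4 = K4,
       path5 = path5, cycle6 = cycle6, star4 = star4)
}

# random connected MST-kNN graph from Gaussian document vectors
random_vector_graph <- function(n = 20, d = 5, k = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  mst_knn(similarity_matrix(doc_vectors(sprintf("d%03d", seq_len(n)), X)),
          k = k)
}

# random partition of n nodes into at most c_max parts
random_partition <- function(n, c_max = 5) {
  as_partition(sample.int(c_max, n, replace = TRUE))
}
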