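# Diffusion operator, transition kernel, clustered autocovariance,
# stability optimisation and VI diagnostics.

test_that("diffusion_operator gives degree-proportional stationarity", {
  # cycle: uniform
  A <- fixture_graphs()$cycle6
  op <- diffusion_operator(ms_graph(A))
  expect_equal(op$pi, rep(1 / 6, 6))
  # star with 3 leaves: degrees (3, 1, 1, 1)
  op2 <- diffusion_operator(ms_graph(fixture_graphs()$star4))
  expect_equal(op2$pi, c(1 / 2, 1 / 6, 1 / 6, 1 / 6))
  # two nodes, any weight
  op3 <- diffusion_operator(ms_graph(matrix(c(0, 2.7, 2.7, 0), 2, 2)))
  expect_equal(op3$pi, c(1 / 2, 1 / 2))
  # rows of L_RW sum to zero
  expect_equal(rowSums(op$L_rw), rep(0, 6))
  # isolated node rejected
  A_iso <- matrix(0, 3, 3)
  A_iso[1, 2] <- A_iso[2, 1] <- 1
  expect_error(diffusion_operator(ms_graph(A_iso)), "isolated")
})

test_that("transition_kernel matches closed forms and limits", {
  op2 <- diffusion_operator(ms_graph(matrix(c(0, 1, 1, 0), 2, 2)))
  expect_equal(transition_kernel(op2, 0), diag(2))
  for (t in c(0.3, 1, 2.5)) {
    P <- transition_kernel(op2, t)
    closed <- matrix(c((1 + exp(-2 * t)) / 2, (1 - exp(-2 * t)) / 2,
                       (1 - exp(-2 * t)) / 2, (1 + exp(-2 * t)) / 2), 2, 2)
    expect_equal(P, closed, tolerance = 1e-12)
  }
  expect_error(transition_kernel(op2, -1), "nonnegative")
  # ergodic limit: every row approaches pi
  G <- random_vector_graph(n = 15, k = 3, seed = 5)
  op <- diffusion_operator(G)
  P <- transition_kernel(op, 1000)
  expect_lt(max(abs(sweep(P, 2, op$pi))), 1e-6)
})

test_that("the eigendecomposition kernel agrees with a dense matrix
           exponential", {
  G <- random_vector_graph(n = 20, k = 3, seed = 6)
  op <- diffusion_operator(G)
  for (t in c(0.1, 1, 10)) {
    P1 <- transition_kernel(op, t)
    P2 <- as.matrix(Matrix::expm(-t * op$L_rw))
    expect_lt(max(abs(P1 - P2)), 1e-12)
    expect_equal(rowSums(P1), rep(1, 20), tolerance = 1e-12)
    expect_gt(min(P1), -1e-12)
  }
})

test_that("pi is stationary under P(t) on random graphs", {
  for (seed in 1:5) {
    op <- diffusion_operator(random_vector_graph(n = 15, k = 3, seed = seed))
    for (t in c(0.5, 5)) {
      P <- transition_kernel(op, t)
      expect_lt(max(abs(crossprod(P, op$pi) - op$pi)), 1e-10)
    }
  }
})

test_that("clustered autocovariance satisfies its analytic identities", {
  G <- random_vector_graph(n = 12, k = 3, seed = 3)
  op <- diffusion_operator(G)
  P1 <- transition_kernel(op, 1)
  # single community: R = [[0]]
  R1 <- clustered_autocovariance(op, P1, rep(1, 12))
  expect_equal(dim(R1), c(1L, 1L))
  expect_lt(abs(R1[1, 1]), 1e-12)
  # t = 0, singletons: R = diag(pi) - pi pi'
  R0 <- clustered_autocovariance(op, diag(12), 1:12)
  expect_equal(unname(R0), diag(op$pi) - op$pi %o% op$pi, tolerance = 1e-12)
  # conservation: all entries sum to zero for random partitions and times
  set.seed(42)
  for (rep_i in 1:10) {
    part <- random_partition(12, 4)
    t <- runif(1, 0.01, 20)
    R <- clustered_autocovariance(op, transition_kernel(op, t), part)
    expect_lt(abs(sum(R)), 1e-10)
  }
  expect_error(clustered_autocovariance(op, P1, rep(1, 5)), "length")
})

test_that("no probability flows between disconnected components", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  diag(A) <- 0
  op <- diffusion_operator(ms_graph(A))
  R <- clustered_autocovariance(op, transition_kernel(op, 1),
                                c(1, 1, 1, 2, 2, 2))
  # the transition term contributes nothing across components, so the
  # off-diagonal blocks reduce exactly to the stationary correction
  # -pi_a * pi_b, and the diagonal keeps the full trapped mass
  expect_equal(R[1, 2], -1 / 4, tolerance = 1e-14)
  expect_equal(R[2, 1], -1 / 4, tolerance = 1e-14)
  expect_equal(R[1, 1], 1 / 4, tolerance = 1e-12)
  expect_lt(abs(sum(R)), 1e-12)
})

test_that("stability is invariant to community relabelling", {
  G <- random_vector_graph(n = 12, k = 3, seed = 9)
  op <- diffusion_operator(G)
  P <- transition_kernel(op, 2)
  part <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3)
  relab <- c(3, 1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2)
  expect_equal(stability(op, P, part), stability(op, P, relab),
               tolerance = 1e-14)
})

test_that("optimise_partition is deterministic and finds planted cliques", {
  A <- fixture_graphs()$two_triangles
  op <- diffusion_operator(ms_graph(A))
  r1 <- optimise_partition(op, 1, n_runs = 1L, n_top = 1L, seed = 7L)
  r2 <- optimise_partition(op, 1, n_runs = 1L, n_top = 1L, seed = 7L)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$r, r2$r)
  res <- optimise_partition(op, 1, n_runs = 50L, n_top = 10L, seed = 1L)
  expect_equal(as_partition(res$best), as_partition(rep(1:2, each = 3)))
  # matches the exhaustive oracle
  parts <- all_partitions(6)
  expect_equal(res$r,
               exhaustive_max_r(op, transition_kernel(op, 1), parts),
               tolerance = 1e-12)
})

test_that("variation_of_information is a metric on partitions", {
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  expect_equal(variation_of_information(rep(1, 4), 1:4), log(4))
  expect_error(variation_of_information(1:4, 1:5), "different node sets")
  set.seed(13)
  for (i in 1:100) {
    a <- random_partition(50, 6)
    b <- random_partition(50, 6)
    c_ <- random_partition(50, 6)
    vab <- variation_of_information(a, b)
    expect_equal(vab, variation_of_information(b, a), tolerance = 1e-12)
    expect_gte(vab, 0)
    expect_lte(vab, variation_of_information(a, c_) +
                 variation_of_information(c_, b) + 1e-12)
    if (i <= 10) # independent implementation agrees (natural-log units)
      expect_equal(vab, igraph::compare(a, b, method = "vi"),
                   tolerance = 1e-12)
  }
})

test_that("ms_scan handles single times and disconnected cliques", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  diag(A) <- 0
  G <- ms_graph(A)
  res <- ms_scan(G, times = 1, n_runs = 20L, n_top = 5L, seed = 1L)
  expect_equal(res$n_comms, 2L)
  expect_equal(res$vi_cross, matrix(0, 1, 1))
  expect_error(ms_scan(G, times = numeric(0)), "empty")
  # vi_cross diagonal is zero on a longer grid
  res2 <- ms_scan(G, times = c(0.5, 1, 2), n_runs = 10L, n_top = 3L,
                  seed = 1L)
  expect_equal(diag(res2$vi_cross), rep(0, 3))
  sel <- select_scales(res2, min_plateau = 1L)
  expect_equal(length(sel$time), 1L)
  expect_equal(sel$n_comms, 2L)
})

test_that("a uniform noise graph yields no fine-scale structure", {
  set.seed(77)
  N <- 24
  A <- matrix(runif(N * N, 0.5, 1), N, N)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  G <- ms_graph(A)
  res <- ms_scan(G, ms_time_grid(0.01, 100, 24), n_runs = 40L,
                 n_top = 10L, seed = 2L)
  sel <- select_scales(res)
  expect_true(all(sel$n_comms <= 4))
})

test_that("the cross-time sweep can only improve stored stabilities", {
  gen <- generate_multiscale_graph(seed = 2)
  op <- diffusion_operator(gen$graph)
  times <- ms_time_grid(0.05, 50, 8)
  res <- ms_scan(gen$graph, times, n_runs = 15L, n_top = 5L, seed = 3L)
  for (i in seq_along(times)) {
    P <- transition_kernel(op, times[i])
    direct <- optimise_partition(op, times[i], n_runs = 15L, n_top = 5L,
                                 seed = res$seed + (i - 1L) * res$n_runs)
    expect_gte(res$r_best[i] + 1e-12, direct$r)
    expect_equal(res$r_best[i], stability(op, P, res$memberships[[i]]),
                 tolerance = 1e-10)
  }
})

test_that("auto_time_grid covers the slowest relaxation time", {
  G <- generate_multiscale_graph(seed = 1)$graph
  op <- diffusion_operator(G)
  tg <- auto_time_grid(G, n = 10)
  lam2 <- sort(op$lambda)[2]
  expect_equal(max(tg), 4 / lam2, tolerance = 1e-9)
  expect_equal(min(tg), 0.01)
})
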