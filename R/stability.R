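# Markov Stability: continuous-time diffusion on the document graph,
# clustered autocovariance, Louvain-ensemble optimisation across Markov
# times, and variation-of-information diagnostics for scale selection.
#
# The random-walk Laplacian L_RW = I - D^{-1} A is similar to the symmetric
# normalised Laplacian L_sym = I - D^{-1/2} A D^{-1/2}; the kernel
# P(t) = expm(-t L_RW) is therefore computed from a single symmetric
# eigendecomposition, P(t) = D^{-1/2} V exp(-t Lambda) V' D^{1/2}, which
# makes scans over many Markov times cheap and keeps Pi P(t) exactly
# symmetric (the walk is reversible).

#' Diffusion operator of a weighted graph
#'
#' Computes the random-walk Laplacian `L_RW = I - D^{-1} A`, the
#' degree-proportional stationary distribution `pi = d / sum(d)`, and the
#' eigendecomposition of the symmetric normalised Laplacian used to
#' evaluate the diffusion kernel at any Markov time.
#'
#' @param G an `ms_graph` with no isolated (zero-degree) nodes.
#' @return a `diffusion_operator` object.
#' @export
diffusion_operator <- function(G) {
  stopifnot(inherits(G, "ms_graph"))
  A <- unname(G$A)
  d <- rowSums(A)
  if (any(d == 0))
    stop("isolated node(s): ", paste(G$ids[d == 0], collapse = ", "))
  N <- nrow(A)
  pi <- d / sum(d)
  L_rw <- diag(N) - A / d
  dsq <- sqrt(d)
  L_sym <- diag(N) - A / (dsq %o% dsq)
  L_sym <- (L_sym + t(L_sym)) / 2
  eig <- eigen(L_sym, symmetric = TRUE)
  lam <- pmax(eig$values, 0) # clip tiny negative eigenvalues
  structure(list(L_rw = L_rw, pi = pi, d = d, dsq = dsq,
                 lambda = lam, V = eig$vectors, N = N, ids = G$ids),
            class = "diffusion_operator")
}

#' @export
print.diffusion_operator <- function(x, ...) {
  cat("diffusion_operator:", x$N, "nodes\n")
  invisible(x)
}

#' Diffusion transition kernel P(t)
#'
#' Evaluates `P(t) = expm(-t L_RW)`: a row-stochastic matrix whose entry
#' `(i, j)` is the probability that a continuous-time random walker
#' starting at node `i` is at node `j` after Markov time `t`. `P(0)` is
#' the identity; as `t` grows every row approaches the stationary
#' distribution.
#'
#' @param op a [diffusion_operator()].
#' @param t nonnegative Markov time.
#' @return `N x N` stochastic matrix.
#' @export
transition_kernel <- function(op, t) {
  stopifnot(inherits(op, "diffusion_operator"))
  if (t < 0) stop("Markov time must be nonnegative")
  if (t == 0) return(diag(op$N))
  W <- op$V * rep(exp(-t * op$lambda), each = op$N)
  M <- tcrossprod(W, op$V)
  M * outer(1 / op$dsq, op$dsq)
}

# stability matrix B(t) = Pi P(t) - pi pi^T, computed in its exactly
# symmetric form (1/sum d) D^{1/2} V e^{-t Lambda} V' D^{1/2} - pi pi'
.stability_B <- function(op, t) {
  W <- op$V * rep(exp(-t * op$lambda), each = op$N)
  S <- tcrossprod(W, op$V)
  B <- (op$dsq %o% op$dsq) * S / sum(op$d) - op$pi %o% op$pi
  (B + t(B)) / 2
}

#' Canonicalise a partition membership vector
#'
#' Relabels community indices to be contiguous `1..C` in order of first
#' appearance.
#'
#' @param membership vector of community assignments (any labels).
#' @return integer vector with attribute-free contiguous labels.
#' @export
as_partition <- function(membership) {
  f <- match(membership, unique(membership))
  as.integer(f)
}

# sum of B entries within communities, given membership (1..C)
.partition_r <- function(B, memb) {
  agg <- rowsum(B, memb)
  sum(rowsum(t(agg), memb)[cbind(seq_len(max(memb)), seq_len(max(memb)))])
}

#' Clustered autocovariance matrix R(t, H)
#'
#' `R = H' (Pi P(t) - pi pi') H`, a `C x C` matrix whose entry (a, b) is
#' the probability that a walker starting in community a is found in
#' community b at Markov time t, minus the probability of that event at
#' stationarity. All entries sum to zero.
#'
#' @param op a [diffusion_operator()].
#' @param P_t transition kernel from [transition_kernel()].
#' @param partition membership vector (length N).
#' @return `C x C` numeric matrix.
#' @export
clustered_autocovariance <- function(op, P_t, partition) {
  stopifnot(inherits(op, "diffusion_operator"))
  memb <- as_partition(partition)
  if (length(memb) != op$N) stop("membership length must equal node count")
  B <- op$pi * P_t - op$pi %o% op$pi
  agg <- rowsum(B, memb)
  t(rowsum(t(agg), memb))
}

#' Markov Stability of a partition
#'
#' `r(t, H) = trace(R(t, H))`: the probability mass that diffusion keeps
#' inside communities over time `t`, beyond what stationarity would give.
#' The one-community partition scores exactly 0; at `t = 0` the
#' all-singletons partition attains the maximum `1 - sum(pi^2)`.
#'
#' @inheritParams clustered_autocovariance
#' @return scalar stability value.
#' @export
stability <- function(op, P_t, partition) {
  sum(diag(clustered_autocovariance(op, P_t, partition)))
}

# run fn with a temporary RNG seed, restoring global state
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Louvain-ensemble optimisation of Markov Stability at one time
#'
#' Runs a Louvain-style greedy optimiser `n_runs` times on the (signed)
#' stability matrix `B(t) = Pi P(t) - pi pi'`, each run visiting nodes in
#' an independently shuffled order (seeds derived from `seed` by a
#' counter), and keeps the `n_top` highest-stability partitions. Ties in
#' the best value keep the lowest run index.
#'
#' @param op a [diffusion_operator()].
#' @param t Markov time.
#' @param n_runs number of optimisation runs (default 500).
#' @param n_top size of the retained ensemble (default 50).
#' @param seed master seed for the run-order shuffles.
#' @return list with `best` (membership), `r` (its stability), `top`
#'   (list of the `n_top` best memberships, descending r), `r_top`
#'   (their stability values).
#' @export
optimise_partition <- function(op, t, n_runs = 500L, n_top = 50L, seed = 1L) {
  stopifnot(inherits(op, "diffusion_operator"), n_top <= n_runs)
  B <- .stability_B(op, t)
  .optimise_on_B(B, op$N, n_runs, n_top, seed)
}

.optimise_on_B <- function(B, N, n_runs, n_top, seed) {
  runs <- vector("list", n_runs)
  rvals <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    ord <- .with_seed(seed + run - 1L, function() sample.int(N)) - 1L
    memb <- as_partition(.louvain_signed_cpp(B, as.integer(ord)) + 1L)
    runs[[run]] <- memb
    rvals[run] <- .partition_r(B, memb)
  }
  ord <- order(-rvals, seq_len(n_runs), method = "radix")
  top <- ord[seq_len(min(n_top, n_runs))]
  list(best = runs[[ord[1]]], r = rvals[ord[1]],
       top = runs[top], r_top = rvals[top])
}

#' Variation of information between two partitions
#'
#' `VI(C, D) = H(C) + H(D) - 2 I(C, D)` in natural-log units: a metric on
#' partitions (zero iff equal up to relabelling; symmetric; triangle
#' inequality).
#'
#' @param c1,c2 membership vectors over the same node set.
#' @return nonnegative scalar.
#' @export
variation_of_information <- function(c1, c2) {
  if (length(c1) != length(c2)) stop("partitions are over different node sets")
  n <- length(c1)
  tab <- table(c1, c2) / n
  pc <- rowSums(tab)
  pd <- colSums(tab)
  Hc <- -sum(pc * log(pc), na.rm = TRUE)
  Hd <- -sum(pd * log(pd), na.rm = TRUE)
  nz <- tab > 0
  I <- sum(tab[nz] * log(tab[nz] / (pc[row(tab)[nz]] * pd[col(tab)[nz]])))
  max(Hc + Hd - 2 * I, 0)
}

#' Geometric or linear grid of Markov times
#'
#' @param t_min,t_max grid endpoints (positive).
#' @param n number of grid points.
#' @param grid `"log"` (geometric spacing, default) or `"linear"`.
#' @return numeric vector of times, ascending.
#' @export
ms_time_grid <- function(t_min = 0.01, t_max = 100, n = 200L,
                         grid = c("log", "linear")) {
  grid <- match.arg(grid)
  stopifnot(t_min > 0, t_max > t_min, n >= 1)
  if (grid == "log") exp(seq(log(t_min), log(t_max), length.out = n))
  else seq(t_min, t_max, length.out = n)
}

#' Markov-time grid adapted to a graph's diffusion timescales
#'
#' The coarsest community structure of a graph resolves at Markov times
#' comparable to the relaxation time `1 / lambda_2` of the diffusion's
#' slowest non-stationary mode; a fixed scan window can therefore stop
#' short of the coarse scales on small or sparsely coupled graphs. This
#' helper returns a geometric grid from `t_min` to
#' `horizon / lambda_2`, which guarantees the sweep reaches the regime
#' where the slowest mode has decayed to `exp(-horizon)` of its initial
#' amplitude (about 2% for the default `horizon = 4`).
#'
#' @param G an `ms_graph` (or a [diffusion_operator()]).
#' @param n number of grid points.
#' @param t_min smallest Markov time.
#' @param horizon multiple of the relaxation time to scan up to.
#' @return numeric vector of times, ascending.
#' @export
auto_time_grid <- function(G, n = 200L, t_min = 0.01, horizon = 4) {
  op <- if (inherits(G, "diffusion_operator")) G else diffusion_operator(G)
  lam2 <- sort(op$lambda)[2]
  if (lam2 <= 0) stop("graph has a disconnected spectrum; no finite horizon")
  t_max <- max(horizon / lam2, t_min * 10)
  ms_time_grid(t_min, t_max, n, "log")
}

#' Markov Stability scan across Markov times
#'
#' For every time in the grid, optimises the partition with a Louvain
#' ensemble and records the best partition, its stability, the community
#' count, and the ensemble reproducibility `VI(t)` (mean pairwise
#' variation of information among the top `n_top` partitions). After the
#' per-time scan, every stored optimal partition is re-scored at every
#' other time in a single sweep and replaces the incumbent wherever it
#' scores strictly higher; finally the cross-time matrix `VI(t, t')`
#' between optimal partitions is computed.
#'
#' @param G an `ms_graph`.
#' @param times ascending positive Markov-time grid ([ms_time_grid()]).
#' @param n_runs Louvain runs per time (default 500).
#' @param n_top ensemble size retained per time (default 50).
#' @param seed master seed; per-run seeds are derived by a counter.
#' @return an `ms_scan_result`: `times`, `memberships` (list),
#'   `r_best`, `n_comms`, `vi_ensemble`, `vi_cross`, `ids`.
#' @export
ms_scan <- function(G, times = ms_time_grid(), n_runs = 500L, n_top = 50L,
                    seed = 1L) {
  stopifnot(inherits(G, "ms_graph"))
  if (length(times) == 0L) stop("empty Markov-time grid")
  if (is.unsorted(times) || any(times <= 0))
    stop("times must be ascending and positive")
  op <- diffusion_operator(G)
  T_ <- length(times)
  memberships <- vector("list", T_)
  r_best <- numeric(T_)
  vi_ens <- numeric(T_)
  for (i in seq_len(T_)) {
    res <- optimise_partition(op, times[i], n_runs = n_runs, n_top = n_top,
                              seed = seed + (i - 1L) * n_runs)
    memberships[[i]] <- res$best
    r_best[i] <- res$r
    vi_ens[i] <- .mean_pairwise_vi(res$top)
  }
  # cross-time sweep: re-score every optimal partition at every time
  uniq <- .unique_partitions(memberships)
  for (i in seq_len(T_)) {
    B <- .stability_B(op, times[i])
    for (p in uniq) {
      rp <- .partition_r(B, p)
      if (rp > r_best[i] + 1e-12) {
        r_best[i] <- rp
        memberships[[i]] <- p
      }
    }
  }
  n_comms <- vapply(memberships, max, integer(1))
  vi_cross <- matrix(0, T_, T_)
  for (i in seq_len(T_)) for (j in seq_len(T_)) {
    if (j > i) vi_cross[i, j] <-
        variation_of_information(memberships[[i]], memberships[[j]])
    else if (j < i) vi_cross[i, j] <- vi_cross[j, i]
  }
  structure(list(times = times, memberships = memberships, r_best = r_best,
                 n_comms = n_comms, vi_ensemble = vi_ens,
                 vi_cross = vi_cross, ids = G$ids,
                 n_runs = n_runs, n_top = n_top, seed = seed),
            class = "ms_scan_result")
}

#' @export
print.ms_scan_result <- function(x, ...) {
  cat("ms_scan_result:", length(x$times), "Markov times, community counts",
      min(x$n_comms), "-", max(x$n_comms), "\n")
  invisible(x)
}

.mean_pairwise_vi <- function(parts) {
  n <- length(parts)
  if (n < 2L) return(0)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    tot <- tot + variation_of_information(parts[[i]], parts[[j]])
  tot / (n * (n - 1L) / 2)
}

.unique_partitions <- function(parts) {
  out <- list()
  for (p in parts) {
    dup <- FALSE
    for (q in out) if (identical(as_partition(q), as_partition(p))) {
      dup <- TRUE
      break
    }
    if (!dup) out[[length(out) + 1L]] <- p
  }
  out
}

#' Select robust scales from a Markov Stability scan
#'
#' A scale (Markov time) is selected when it is a local minimum of the
#' ensemble variation of information `VI(t)` lying at or below the
#' `dip_quantile` quantile of `VI(t)` (a "dip": the optimisation is
#' reproducible there), and it sits inside a cross-time plateau: a
#' contiguous block of times whose optimal partitions differ from this
#' one by less than `plateau_eps` in `VI(t, t')` (the partition persists
#' across resolution). Candidate times whose partitions coincide are
#' merged, keeping the candidate with the longest plateau. The trivial
#' endpoint partitions (all nodes in one community, every node its own
#' community) are excluded by default: they are the degenerate limits of
#' the resolution sweep and carry no cluster structure. Exclusion is
#' applied at the same resolution that defines a plateau: any candidate
#' whose partition lies within `plateau_eps` (in VI) of either trivial
#' endpoint is treated as that endpoint.
#'
#' @param res an `ms_scan_result`.
#' @param plateau_eps cross-time VI threshold defining a plateau
#'   (default 0.05, natural-log units).
#' @param dip_quantile quantile of `VI(t)` that a dip must not exceed
#'   (default 0.25).
#' @param min_plateau minimum plateau length in grid points (default 3).
#' @param exclude_trivial drop the all-in-one and all-singletons
#'   partitions (default `TRUE`).
#' @return an `ms_scales` object: parallel vectors `time`, `index`,
#'   `n_comms`, `plateau_len`, and a list `memberships`, sorted by
#'   descending plateau length. May be empty.
#' @export
select_scales <- function(res, plateau_eps = 0.05, dip_quantile = 0.25,
                          min_plateau = 3L, exclude_trivial = TRUE) {
  stopifnot(inherits(res, "ms_scan_result"))
  vi <- res$vi_ensemble
  T_ <- length(res$times)
  N <- length(res$ids)
  thr <- stats::quantile(vi, dip_quantile, names = FALSE) + 1e-12
  is_min <- vapply(seq_len(T_), function(i) {
    left <- i == 1L || vi[i] <= vi[i - 1L] + 1e-12
    right <- i == T_ || vi[i] <= vi[i + 1L] + 1e-12
    left && right && vi[i] <= thr
  }, logical(1))
  cand <- which(is_min)
  if (exclude_trivial && length(cand)) {
    singletons <- seq_len(N)
    all_one <- rep(1L, N)
    near_trivial <- vapply(cand, function(i) {
      p <- res$memberships[[i]]
      variation_of_information(p, singletons) < plateau_eps ||
        variation_of_information(p, all_one) < plateau_eps
    }, logical(1))
    cand <- cand[!near_trivial]
  }
  if (length(cand) == 0L) return(.empty_scales())
  plen <- vapply(cand, function(i) {
    lo <- i
    while (lo > 1L && res$vi_cross[i, lo - 1L] < plateau_eps) lo <- lo - 1L
    hi <- i
    while (hi < T_ && res$vi_cross[i, hi + 1L] < plateau_eps) hi <- hi + 1L
    hi - lo + 1L
  }, integer(1))
  keep <- plen >= min_plateau
  cand <- cand[keep]
  plen <- plen[keep]
  if (length(cand) == 0L) return(.empty_scales())
  # merge candidates carrying the same partition
  reps <- integer(0)
  rep_len <- integer(0)
  for (j in seq_along(cand)) {
    merged <- FALSE
    for (g in seq_along(reps)) {
      if (variation_of_information(res$memberships[[cand[j]]],
                                   res$memberships[[reps[g]]]) < 1e-9) {
        if (plen[j] > rep_len[g] ||
            (plen[j] == rep_len[g] && res$times[cand[j]] < res$times[reps[g]])) {
          reps[g] <- cand[j]
          rep_len[g] <- plen[j]
        }
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      reps <- c(reps, cand[j])
      rep_len <- c(rep_len, plen[j])
    }
  }
  ord <- order(-rep_len, res$times[reps], method = "radix")
  reps <- reps[ord]
  rep_len <- rep_len[ord]
  structure(list(time = res$times[reps], index = reps,
                 n_comms = res$n_comms[reps], plateau_len = rep_len,
                 memberships = res$memberships[reps], ids = res$ids),
            class = "ms_scales")
}

.empty_scales <- function() {
  structure(list(time = numeric(0), index = integer(0),
                 n_comms = integer(0), plateau_len = integer(0),
                 memberships = list(), ids = character(0)),
            class = "ms_scales")
}

#' @export
print.ms_scales <- function(x, ...) {
  cat("ms_scales:", length(x$time), "selected scale(s)\n")
  if (length(x$time))
    print(data.frame(time = signif(x$time, 4), n_comms = x$n_comms,
                     plateau_len = x$plateau_len))
  invisible(x)
}

#' Write scan diagnostics as CSV
#'
#' Columns `t`, `n_comms`, `r`, `vi_ensemble`, one row per Markov time.
#'
#' @param res an `ms_scan_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(res, path) {
  stopifnot(inherits(res, "ms_scan_result"))
  utils::write.csv(data.frame(t = res$times, n_comms = res$n_comms,
                              r = res$r_best,
                              vi_ensemble = res$vi_ensemble),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write selected-scale memberships as CSV
#'
#' One row per document id, one column per selected scale (named by its
#' community count and Markov time).
#'
#' @param scales an `ms_scales` from [select_scales()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_memberships_csv <- function(scales, path) {
  stopifnot(inherits(scales, "ms_scales"))
  df <- data.frame(id = scales$ids)
  for (j in seq_along(scales$time)) {
    df[[sprintf("C%d_t%.4g", scales$n_comms[j], scales$time[j])]] <-
      scales$memberships[[j]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
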