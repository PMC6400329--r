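# Geometric similarity graph: normalised cosine similarity matrix and the
# MST-kNN sparsifier (union of the minimum spanning tree of the normalised
# distance matrix and each node's k nearest neighbours), with the surviving
# edges re-weighted by the normalised similarity.

#' Normalised document similarity matrix
#'
#' From an `N x d` vector set, computes pairwise cosine similarities
#' `S_cos`, the cosine distance `D_cos = 1 - S_cos`, rescales by the
#' maximum off-diagonal distance (`D_hat = D_cos / max(D_cos)`), and
#' returns the normalised similarity `S_hat = 1 - D_hat`, whose entries
#' lie in `[0, 1]`: the most distant pair attains similarity 0 and the
#' diagonal is 1. If all documents are identical (every distance zero)
#' the normalisation is degenerate; `S_hat` is then defined as all ones
#' and a warning is emitted.
#'
#' @param vectors a [doc_vectors()] set with `N >= 2` rows.
#' @return a `similarity_matrix` object: list with `S_hat` (symmetric
#'   `N x N`), `D_hat`, and `ids`.
#' @export
similarity_matrix <- function(vectors) {
  stopifnot(inherits(vectors, "doc_vectors"))
  X <- vectors$vectors
  N <- nrow(X)
  if (N < 2L) stop("need at least 2 documents")
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("zero-norm vector for document: ",
         paste(vectors$ids[nrm == 0], collapse = ", "))
  Xu <- X / nrm
  S_cos <- tcrossprod(Xu)
  S_cos <- (S_cos + t(S_cos)) / 2
  S_cos[S_cos > 1] <- 1
  S_cos[S_cos < -1] <- -1
  D_cos <- 1 - S_cos
  diag(D_cos) <- 0
  dmax <- max(D_cos[upper.tri(D_cos)])
  if (dmax <= .Machine$double.eps^0.5) {
    warning("all pairwise distances are zero; S_hat defined as all ones")
    D_hat <- matrix(0, N, N)
  } else {
    D_hat <- D_cos / dmax
  }
  S_hat <- 1 - D_hat
  diag(S_hat) <- 1
  dimnames(S_hat) <- dimnames(D_hat) <- list(vectors$ids, vectors$ids)
  structure(list(S_hat = S_hat, D_hat = D_hat, ids = vectors$ids),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix:", length(x$ids), "documents\n")
  invisible(x)
}

# Kruskal MST on a dense symmetric distance matrix. Edges sorted by
# (distance, smaller index, larger index) with a stable sort, so ties are
# resolved reproducibly. Returns a 2-column matrix of node index pairs.
.kruskal_mst <- function(D) {
  N <- nrow(D)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  ord <- order(w, iu[, 1], iu[, 2], method = "radix")
  parent <- seq_len(N)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- matrix(0L, N - 1L, 2L)
  m <- 0L
  for (e in ord) {
    a <- find(iu[e, 1]); b <- find(iu[e, 2])
    if (a != b) {
      parent[a] <- b
      m <- m + 1L
      edges[m, ] <- c(iu[e, 1], iu[e, 2])
      if (m == N - 1L) break
    }
  }
  edges[seq_len(m), , drop = FALSE]
}

#' MST-kNN sparsified graph
#'
#' Sparsifies the similarity structure to the union of the minimum
#' spanning tree of the normalised distance matrix (global connectivity,
#' computed with Kruskal's algorithm) and each node's `k` nearest
#' neighbours (local geometry; neighbourhoods are directed and then
#' symmetrised, and ties at the k-th distance are all included). The kept
#' edges are weighted by the normalised similarity `S_hat`
#' (Hadamard product of the binary edge mask with `S_hat`).
#'
#' @param S a [similarity_matrix()].
#' @param k number of nearest neighbours, `0 <= k <= N-1`; `k = 0` gives
#'   the MST alone. Default 13.
#' @return an `ms_graph` object: adjacency `A` (symmetric, zero
#'   diagonal), binary `edge_mask`, `k`, and `ids`.
#' @export
mst_knn <- function(S, k = 13L) {
  stopifnot(inherits(S, "similarity_matrix"))
  N <- length(S$ids)
  k <- as.integer(k)
  if (k < 0L || k > N - 1L) stop("k must be in [0, N-1]")
  D <- S$D_hat
  E <- matrix(FALSE, N, N)
  mst <- .kruskal_mst(D)
  E[mst] <- TRUE
  if (k > 0L) {
    for (i in seq_len(N)) {
      di <- D[i, ]
      di[i] <- Inf
      kth <- sort(di, partial = k)[k]
      nb <- which(di <= kth) # all ties at the k-th distance included
      E[i, nb] <- TRUE
    }
  }
  E <- E | t(E)
  diag(E) <- FALSE
  A <- ifelse(E, S$S_hat, 0)
  diag(A) <- 0
  dimnames(A) <- list(S$ids, S$ids)
  structure(list(A = A, edge_mask = E, k = k, ids = S$ids),
            class = "ms_graph")
}

#' Build an ms_graph directly from an adjacency matrix
#'
#' For synthetic or externally constructed weighted graphs.
#'
#' @param A symmetric nonnegative adjacency matrix (zero diagonal).
#' @param ids node identifiers; default `1..N` as characters.
#' @return an `ms_graph`.
#' @export
ms_graph <- function(A, ids = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  diag(A) <- 0
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, edge_mask = A > 0, k = NA_integer_,
                 ids = as.character(ids)),
            class = "ms_graph")
}

#' @export
print.ms_graph <- function(x, ...) {
  cat("ms_graph:", length(x$ids), "nodes,",
      sum(x$edge_mask[upper.tri(x$edge_mask)]), "edges",
      if (!is.na(x$k)) sprintf("(MST-kNN, k = %d)", x$k) else "", "\n")
  invisible(x)
}

#' Number of edges of an ms_graph
#' @param G an `ms_graph`.
#' @return integer edge count (undirected).
#' @export
n_edges <- function(G) {
  stopifnot(inherits(G, "ms_graph"))
  sum(G$edge_mask[upper.tri(G$edge_mask)])
}

#' Is the graph connected?
#' @param G an `ms_graph`.
#' @return logical.
#' @export
is_connected <- function(G) {
  stopifnot(inherits(G, "ms_graph"))
  ig <- .as_igraph(G)
  igraph::is_connected(ig)
}

.as_igraph <- function(G) {
  igraph::graph_from_adjacency_matrix(G$A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Export a graph as a weighted edge list
#'
#' Tab-separated columns `id_u`, `id_v`, `weight`, one undirected edge per
#' line, ordered by (u, v).
#'
#' @param G an `ms_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(G, path) {
  stopifnot(inherits(G, "ms_graph"))
  ut <- which(G$edge_mask & upper.tri(G$edge_mask), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  df <- data.frame(id_u = G$ids[ut[, 1]], id_v = G$ids[ut[, 2]],
                   weight = G$A[ut])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a graph as GraphML
#'
#' @param G an `ms_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(G, path) {
  stopifnot(inherits(G, "ms_graph"))
  ig <- .as_igraph(G) # node ids are carried as the vertex `name` attribute
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
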