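# Small graphs used across the suite, built in code.

path_graph <- function(n, w = 1) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- w
  weighted_graph(A)
}

cycle_graph <- function(n, w = 1) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- w
  }
  weighted_graph(A)
}

complete_graph <- function(n, w = 1) {
  A <- matrix(w, n, n)
  diag(A) <- 0
  weighted_graph(A)
}

# two triangles as one 6-node graph; optionally joined by a bridge edge
two_triangles_graph <- function(bridged = FALSE) {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 3] <- A[1, 3] <- 1
  A[4, 5] <- A[5, 6] <- A[4, 6] <- 1
  if (bridged) A[3, 4] <- 1
  weighted_graph(A + t(A))
}

two_triangles_planted <- function() partition(c(1, 1, 1, 2, 2, 2))

# two K4 cliques joined by a single edge
barbell_graph <- function() {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  weighted_graph(A)
}

# random connected weighted graph: spanning tree plus random extra edges
random_connected_graph <- function(n, seed, weighted = TRUE, extra = n) {
  set.seed(seed)
  A <- matrix(0, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1, 1)
    A[i, j] <- A[j, i] <- if (weighted) stats::runif(1, 0.5, 2) else 1
  }
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2)
    if (A[ij[1], ij[2]] == 0) {
      w <- if (weighted) stats::runif(1, 0.5, 2) else 1
      A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- w
    }
  }
  weighted_graph(A)
}

random_partition <- function(n, k, seed) {
  set.seed(seed)
  # ensure all k labels appear
  partition(c(sample.int(k), sample.int(k, n - k, replace = TRUE))[sample.int(n)])
}
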