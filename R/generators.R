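# Constructive benchmark generators with planted ground truth.  The first two
# families build communities that are deliberately *not* clique-like — rings
# and small worlds have large internal hop-diameters — which is exactly the
# regime where one-step methods overpartition.  The block model and the
# Erdős–Rényi control provide the clique-like counterpart and the
# no-structure null.

benchmark_result <- function(kind, graph, planted, parameters, seed = NULL) {
  structure(list(kind = kind, graph = graph, planted = planted,
                 parameters = parameters, seed = seed),
            class = "benchmark_graph")
}

#' @export
print.benchmark_graph <- function(x, ...) {
  cat(sprintf("benchmark '%s': %d nodes%s\n", x$kind, x$graph$n_nodes,
              if (!is.null(x$planted))
                sprintf(", planted partition with %d communities",
                        n_communities(x$planted)) else ""))
  invisible(x)
}

# deterministic inter-block coupling shared by the ring-of-X generators:
# block k's node 0 connects to block k+1's node floor(size/2) (maximal
# separation from the other junction); for 2 blocks a single edge is used.
ring_coupling_edges <- function(n_blocks, block_size) {
  n_inter <- if (n_blocks == 2L) 1L else n_blocks
  k <- seq_len(n_inter) - 1L
  cbind(from = k * block_size,
        to   = ((k + 1L) %% n_blocks) * block_size + block_size %/% 2L)
}

edges_to_graph <- function(edges, weights, n) {
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]) + 1L,
                            j = c(edges[, 2], edges[, 1]) + 1L,
                            x = c(weights, weights), dims = c(n, n))
  weighted_graph(A)
}

#' Ring-of-rings benchmark
#'
#' `n_rings` cycles of `ring_size` nodes each, with intra-ring edge weight
#' `w_intra`, joined cyclically by single edges of weight `w_inter` (node 0
#' of each ring to the opposite-side node of the next; one edge only when
#' `n_rings = 2`). Entirely deterministic. The planted partition is the
#' rings. With the default 5:1 weight ratio each ring is a long-range
#' community of hop-diameter `ring_size/2` — far beyond a one-step field of
#' view.
#'
#' @param n_rings number of rings (`>= 2`).
#' @param ring_size nodes per ring (`>= 3`).
#' @param w_intra,w_inter intra- and inter-ring weights, `w_intra > w_inter > 0`.
#' @return object of class `benchmark_graph`: list with `graph`
#'   (a [weighted_graph()]), `planted` (an [partition()]), `kind`,
#'   `parameters`, `seed`.
#' @export
ring_of_rings <- function(n_rings = 5L, ring_size = 20L, w_intra = 5,
                          w_inter = 1) {
  if (n_rings < 2L) stop("n_rings must be at least 2")
  if (ring_size < 3L) stop("ring_size must be at least 3")
  if (!(w_intra > w_inter && w_inter > 0)) stop("need w_intra > w_inter > 0")
  n <- n_rings * ring_size
  intra <- do.call(rbind, lapply(seq_len(n_rings) - 1L, function(k) {
    i <- seq_len(ring_size) - 1L
    cbind(from = k * ring_size + i,
          to   = k * ring_size + (i + 1L) %% ring_size)
  }))
  inter <- ring_coupling_edges(n_rings, ring_size)
  graph <- edges_to_graph(rbind(intra, inter),
                          c(rep(w_intra, nrow(intra)), rep(w_inter, nrow(inter))),
                          n)
  planted <- partition(rep(seq_len(n_rings), each = ring_size))
  benchmark_result("ring_of_rings", graph, planted,
                   list(n_rings = n_rings, ring_size = ring_size,
                        w_intra = w_intra, w_inter = w_inter))
}

#' Ring-of-small-worlds benchmark
#'
#' Each block is a Watts–Strogatz-style small world: a ring of `block_size`
#' nodes with nearest and next-nearest connections, plus — with probability
#' `p_shortcut` per node — one shortcut from that node to a uniformly chosen
#' non-adjacent node of the same block. All within-block edges have weight
#' `w_intra`. Blocks are joined cyclically by single edges of weight
#' `w_inter` (same attachment rule as [ring_of_rings()]). Increasing
#' `p_shortcut` shrinks the block diameter (large world to small world)
#' without changing local structure, which moves the planted communities
#' into and out of a one-step method's field of view.
#'
#' @param n_blocks number of small-world blocks.
#' @param block_size nodes per block (`>= 5`).
#' @param p_shortcut per-node shortcut probability in `[0, 1]`.
#' @param w_intra,w_inter weights as in [ring_of_rings()].
#' @param seed RNG seed for the shortcuts.
#' @return a `benchmark_graph` (see [ring_of_rings()]).
#' @export
ring_of_smallworlds <- function(n_blocks = 5L, block_size = 200L,
                                p_shortcut = 0.02, w_intra = 5, w_inter = 1,
                                seed = 0L) {
  if (n_blocks < 2L) stop("n_blocks must be at least 2")
  if (block_size < 5L) stop("block_size must be at least 5")
  if (p_shortcut < 0 || p_shortcut > 1) stop("p_shortcut must be in [0, 1]")
  if (!(w_intra > w_inter && w_inter > 0)) stop("need w_intra > w_inter > 0")
  set.seed(as.integer(seed))
  n <- n_blocks * block_size
  edge_list <- vector("list", n_blocks + 1L)
  for (k in seq_len(n_blocks) - 1L) {
    i <- seq_len(block_size) - 1L
    ring1 <- cbind(i, (i + 1L) %% block_size)
    ring2 <- cbind(i, (i + 2L) %% block_size)
    base <- cbind(rbind(ring1, ring2))
    # existing neighborhood of each node within the block (distances 1, 2)
    shortcuts <- NULL
    add <- stats::runif(block_size) < p_shortcut
    for (v in i[add]) {
      banned <- c(v, (v + c(-2L, -1L, 1L, 2L)) %% block_size)
      cand <- setdiff(i, banned)
      u <- cand[sample.int(length(cand), 1L)]
      shortcuts <- rbind(shortcuts, c(v, u))
    }
    blk <- rbind(base, shortcuts)
    edge_list[[k + 1L]] <- blk + k * block_size
  }
  intra <- do.call(rbind, edge_list[seq_len(n_blocks)])
  # drop duplicate unordered pairs (a shortcut may coincide with another)
  key <- paste(pmin(intra[, 1], intra[, 2]), pmax(intra[, 1], intra[, 2]))
  intra <- intra[!duplicated(key), , drop = FALSE]
  inter <- ring_coupling_edges(n_blocks, block_size)
  graph <- edges_to_graph(rbind(intra, inter),
                          c(rep(w_intra, nrow(intra)), rep(w_inter, nrow(inter))),
                          n)
  planted <- partition(rep(seq_len(n_blocks), each = block_size))
  benchmark_result("ring_of_smallworlds", graph, planted,
                   list(n_blocks = n_blocks, block_size = block_size,
                        p_shortcut = p_shortcut, w_intra = w_intra,
                        w_inter = w_inter), seed = as.integer(seed))
}

MAX_CONNECT_RETRIES <- 100L

#' Planted block model (stochastic clique of cliques)
#'
#' Unweighted Bernoulli graph with within-block edge probability `p_in` and
#' between-block probability `p_out`; the planted partition is the blocks.
#' This is the homogeneous, clique-like notion of community that one-step
#' methods implicitly assume. Connectivity is enforced by regeneration (up
#' to 100 attempts).
#'
#' @param sizes integer vector of block sizes.
#' @param p_in,p_out probabilities with `p_in > p_out >= 0`.
#' @param seed RNG seed.
#' @return a `benchmark_graph` (see [ring_of_rings()]).
#' @export
planted_blockmodel <- function(sizes, p_in, p_out, seed = 0L) {
  if (!(p_in > p_out && p_out >= 0 && p_in <= 1)) {
    stop("need p_in > p_out >= 0: otherwise blocks are not communities")
  }
  sizes <- as.integer(sizes)
  k <- length(sizes)
  pref <- matrix(p_out, k, k); diag(pref) <- p_in
  set.seed(as.integer(seed))
  for (attempt in seq_len(MAX_CONNECT_RETRIES)) {
    g <- igraph::sample_sbm(sum(sizes), pref.matrix = pref, block.sizes = sizes)
    if (igraph::is_connected(g)) {
      graph <- from_igraph(g)
      planted <- partition(rep(seq_len(k), times = sizes))
      return(benchmark_result("blockmodel", graph, planted,
                              list(sizes = sizes, p_in = p_in, p_out = p_out),
                              seed = as.integer(seed)))
    }
  }
  stop("could not generate a connected block model in 100 attempts; increase p_in/p_out")
}

#' Connected Erdős–Rényi control graph
#'
#' G(n, p) with unit weights and no planted structure: on such graphs the
#' stability sweep should report no robust partition at any scale.
#' Connectivity enforced by regeneration (up to 100 attempts).
#'
#' @param n number of nodes.
#' @param p edge probability (needs `n p` comfortably above `log n` for
#'   connectivity to be reachable by retries).
#' @param seed RNG seed.
#' @return a `benchmark_graph` with `planted = NULL`.
#' @export
erdos_renyi_graph <- function(n, p, seed = 0L) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  set.seed(as.integer(seed))
  for (attempt in seq_len(MAX_CONNECT_RETRIES)) {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      return(benchmark_result("erdos_renyi", from_igraph(g), NULL,
                              list(n = n, p = p), seed = as.integer(seed)))
    }
  }
  stop("could not generate a connected G(n, p) in 100 attempts; increase p")
}
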