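# Quality-matrix construction and generalized Louvain optimization of the
# stability at a fixed Markov time, plus an exhaustive oracle for tiny graphs.

LOUVAIN_GAIN_TOL <- 1e-9
DENSE_QUALITY_MAX <- 5000L

#' Build the stability quality matrix B(t)
#'
#' Symmetric surrogate whose intra-community sum reproduces the stability:
#' \eqn{B(t) = \tfrac12(\Pi P(t) + P(t)^\top \Pi) - \pi^\top\pi}, so that
#' \eqn{\mathrm{tr}\, H^\top B(t) H = r(t; H)} for every partition (the
#' symmetrization preserves the trace). With `linearized = TRUE` the
#' first-order surrogate \eqn{(1-t)\Pi + tA/2m - \pi^\top\pi} is built
#' instead; at `t = 1` that is exactly the modularity matrix.
#'
#' All entries of B(t) sum to zero, so the all-in-one partition always scores
#' zero.
#'
#' @inheritParams propagator
#' @param linearized build the linear-in-t (one-step) surrogate instead of
#'   the full exponential.
#' @param spectrum optional precomputed spectral decomposition (sweep
#'   amortization).
#' @return object of class `quality_matrix`: list with `time`, `matrix`
#'   (dense symmetric), `dynamics`, `linearized`.
#' @export
build_quality_matrix <- function(graph, t, dynamics = "normalized",
                                 linearized = FALSE, spectrum = NULL) {
  stopifnot_graph(graph)
  dynamics <- match.arg(dynamics, DYNAMICS)
  # the linear surrogate only needs strengths, not an ergodic diffusion, so
  # it is also defined on disconnected graphs (as modularity is)
  if (!linearized) assert_connected(graph)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("Markov time t must be a single nonnegative number")
  }
  if (graph$n_nodes > DENSE_QUALITY_MAX) {
    stop(sprintf("dense quality matrices are limited to %d nodes", DENSE_QUALITY_MAX))
  }
  pi <- pi_vector(graph, dynamics)
  if (linearized) {
    B <- as.matrix(graph$adjacency) * (t / graph$total_weight)
    diag(B) <- diag(B) + (1 - t) * pi
    B <- B - tcrossprod(pi)
  } else {
    if (is.null(spectrum)) spectrum <- rw_spectrum(graph, dynamics)
    P <- propagator_from_spectrum(spectrum, t)
    PiP <- pi * P
    B <- (PiP + t(PiP)) / 2 - tcrossprod(pi)
  }
  structure(list(time = t, matrix = B, dynamics = dynamics,
                 linearized = linearized),
            class = "quality_matrix")
}

#' @export
print.quality_matrix <- function(x, ...) {
  cat(sprintf("quality_matrix: %d x %d at t = %g (%s%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$time, x$dynamics,
              if (x$linearized) ", linearized" else ""))
  invisible(x)
}

#' Generalized Louvain optimization of a quality matrix
#'
#' Two-phase greedy optimization adapted to an arbitrary symmetric quality
#' matrix: repeated single-node moves that maximize the gain in the total
#' intra-community sum of `B`, followed by aggregation of `B` over the found
#' communities, until no move improves the objective by more than the gain
#' tolerance (`1e-9`; ties keep the current community). Initialization is
#' all-singletons; the only stochastic element is the node sweep order, which
#' is shuffled from `seed`, so runs are reproducible.
#'
#' @param qmatrix a [build_quality_matrix()] result (or a plain symmetric
#'   matrix).
#' @param seed integer seed for the sweep-order shuffle.
#' @return an [partition()] with attributes `objective` (the attained
#'   intra-community sum, a local maximum) and `levels` (aggregation levels).
#' @export
louvain_optimize <- function(qmatrix, seed = 0L) {
  B <- if (inherits(qmatrix, "quality_matrix")) qmatrix$matrix else as.matrix(qmatrix)
  if (nrow(B) != ncol(B)) stop("quality matrix must be square")
  if (max(abs(B - t(B))) > 1e-10) stop("quality matrix must be symmetric")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  res <- .louvain_dense(B, LOUVAIN_GAIN_TOL)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  p <- partition(res$membership + 1L)
  attr(p, "objective") <- res$objective
  attr(p, "levels") <- res$levels
  attr(p, "seed") <- as.integer(seed)
  p
}

#' Best partition over repeated Louvain restarts
#'
#' Runs [louvain_optimize()] with seeds `base_seed, ..., base_seed + n_runs - 1`
#' and returns the partition with the highest objective together with all
#' restart partitions (needed for the variation-of-information robustness
#' analysis). The default protocol is 100 restarts.
#'
#' @inheritParams build_quality_matrix
#' @param n_runs number of Louvain restarts (`>= 1`).
#' @param base_seed first seed; consecutive integers are used.
#' @param qmatrix optionally, a prebuilt [build_quality_matrix()] (then
#'   `graph`/`t` are not consulted for the matrix).
#' @return list with `best` (an [partition()] with `objective` attribute),
#'   `partitions` (all `n_runs` results) and `objectives` (numeric vector).
#' @export
best_of_runs <- function(graph = NULL, t = NULL, n_runs = 100L, base_seed = 0L,
                         dynamics = "normalized", linearized = FALSE,
                         qmatrix = NULL) {
  if (n_runs < 1L) stop("n_runs must be at least 1")
  if (is.null(qmatrix)) {
    qmatrix <- build_quality_matrix(graph, t, dynamics = dynamics,
                                    linearized = linearized)
  }
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  parts <- lapply(seeds, function(s) louvain_optimize(qmatrix, seed = s))
  objs <- vapply(parts, function(p) attr(p, "objective"), numeric(1))
  list(best = parts[[which.max(objs)]], partitions = parts, objectives = objs)
}

# restricted-growth-string enumeration of all set partitions of n items,
# in lexicographic order of the membership strings
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, k) {
    i <- length(prefix) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (c in seq_len(k + 1L)) rec(c(prefix, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

#' Exhaustive global optimum over all partitions (small graphs)
#'
#' Enumerates every set partition of the nodes (feasible for `n <= 10`) and
#' returns the global maximizer of the stability objective at Markov time
#' `t`. Ties are broken toward fewer communities, then toward the
#' lexicographically smallest membership string. Intended as a test oracle
#' for the Louvain heuristic.
#'
#' @inheritParams build_quality_matrix
#' @return an [partition()] with attribute `objective`.
#' @export
exhaustive_optimum <- function(graph, t, dynamics = "normalized",
                               linearized = FALSE) {
  stopifnot_graph(graph)
  if (graph$n_nodes > 10L) {
    stop("exhaustive enumeration is refused for more than 10 nodes")
  }
  B <- build_quality_matrix(graph, t, dynamics = dynamics,
                            linearized = linearized)$matrix
  parts <- all_set_partitions(graph$n_nodes)
  # ties broken toward fewer communities, then first hit in enumeration
  # order, which is lexicographic on membership strings
  best <- NULL; best_obj <- -Inf; best_k <- Inf
  for (m in parts) {
    obj <- sum(B[outer(m, m, "==")])
    k <- max(m)
    if (is.null(best) || obj > best_obj + 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 && k < best_k)) {
      best <- m; best_obj <- obj; best_k <- k
    }
  }
  p <- partition(best)
  attr(p, "objective") <- sum(B[outer(best, best, "==")])
  p
}
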