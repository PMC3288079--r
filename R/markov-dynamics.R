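# Diffusion dynamics on the graph and the partition quality measures built on
# it: stationary distribution, propagator P(t), Markov stability r(t; H) with
# its clustered autocovariance R(t), the discrete-time analog, and the
# linearization that recovers modularity at t = 1.
#
# Default dynamics is the normalized (random-walk) Laplacian generator
# -D^{-1}L, under which pi = d/2m is stationary and the embedded discrete
# chain is M = D^{-1}A.  The switch dynamics = "combinatorial" offers
# P(t) = exp(-t L / <d>) (uniform stationary distribution) for sensitivity
# checks.

DYNAMICS <- c("normalized", "combinatorial")

#' Stationary distribution of the random walk
#'
#' For the normalized dynamics the stationary distribution is
#' \eqn{\pi_i = d_i / 2m}: strength-proportional. Requires a connected graph.
#'
#' @param graph a [weighted_graph()].
#' @return numeric probability vector of length `n_nodes`.
#' @export
stationary_distribution <- function(graph) {
  stopifnot_graph(graph)
  assert_connected(graph)
  graph$strengths / graph$total_weight
}

# Spectral decomposition of the symmetric normalized Laplacian
# L_sym = I - D^{-1/2} A D^{-1/2} (or the combinatorial Laplacian scaled by
# the mean strength).  P(t) and the quality matrix are cheap per time once
# this is done, which is what makes the Markov-time sweep affordable.
rw_spectrum <- function(graph, dynamics = "normalized") {
  dynamics <- match.arg(dynamics, DYNAMICS)
  A <- as.matrix(graph$adjacency)
  d <- graph$strengths
  if (dynamics == "normalized") {
    ds <- sqrt(d)
    Lsym <- -A / tcrossprod(ds)
    diag(Lsym) <- diag(Lsym) + 1
    e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
    list(dynamics = dynamics, values = pmax(e$values, 0), vectors = e$vectors,
         dsqrt = ds)
  } else {
    L <- -A
    diag(L) <- diag(L) + d
    e <- eigen((L + t(L)) / 2 / mean(d), symmetric = TRUE)
    list(dynamics = dynamics, values = pmax(e$values, 0), vectors = e$vectors,
         dsqrt = rep(1, graph$n_nodes))
  }
}

# reconstruct P(t) = D^{-1/2} U exp(-t Lambda) U' D^{1/2} from a spectrum
propagator_from_spectrum <- function(spec, t) {
  U <- spec$vectors
  E <- exp(-t * spec$values)
  n <- nrow(U)
  S <- tcrossprod(U * rep(E, each = n), U)         # U diag(E) U'
  # P = diag(1/ds) S diag(ds):  P[i, j] = S[i, j] * ds[j] / ds[i]
  S * (rep(spec$dsqrt, each = n) / spec$dsqrt)
}

PROP_NEG_FLOOR <- -1e-9  # spectral reconstruction roundoff floor

clamp_propagator <- function(P) {
  neg <- min(P)
  if (neg < PROP_NEG_FLOOR) {
    stop(sprintf("propagator has entries as negative as %g; numerical failure", neg))
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Diffusion propagator P(t)
#'
#' Transition matrix of the continuous-time Markov process on the graph after
#' Markov time `t`: \eqn{P(t) = \exp(-t D^{-1} L)} for the normalized
#' dynamics. Row-stochastic, with \eqn{\pi P(t) = \pi}; `P(0)` is the
#' identity. Computed by dense spectral decomposition of the symmetric
#' similarity transform; refuses graphs above 5000 nodes.
#'
#' @param graph a connected [weighted_graph()].
#' @param t Markov time, `t >= 0`.
#' @param dynamics `"normalized"` (default, generator \eqn{-D^{-1}L}) or
#'   `"combinatorial"` (generator \eqn{-L/\langle d\rangle}).
#' @return object of class `propagator`: list with `time`, `matrix`
#'   (dense, rows sum to 1, entries clamped to `[0, 1]`) and `dynamics`.
#' @export
propagator <- function(graph, t, dynamics = "normalized") {
  stopifnot_graph(graph)
  assert_connected(graph)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("Markov time t must be a single nonnegative number")
  }
  if (graph$n_nodes > 5000L) {
    stop("dense propagator is limited to graphs of at most 5000 nodes")
  }
  spec <- rw_spectrum(graph, dynamics)
  P <- clamp_propagator(propagator_from_spectrum(spec, t))
  structure(list(time = t, matrix = P, dynamics = spec$dynamics),
            class = "propagator")
}

#' @export
print.propagator <- function(x, ...) {
  cat(sprintf("propagator: %d x %d, Markov time t = %g (%s dynamics)\n",
              nrow(x$matrix), ncol(x$matrix), x$time, x$dynamics))
  invisible(x)
}

# stationary distribution under a given dynamics; unlike
# stationary_distribution() this does not insist on connectivity, since the
# linearized (one-step) surrogates remain well defined without it
pi_vector <- function(graph, dynamics = "normalized") {
  if (dynamics == "normalized") graph$strengths / graph$total_weight
  else rep(1 / graph$n_nodes, graph$n_nodes)
}

#' Newman-Girvan modularity of a partition
#'
#' Fraction of edge weight inside communities minus the expectation under the
#' strength-preserving null model:
#' \eqn{Q = \sum_c [ w_c/2m - (d_c/2m)^2 ]}. In the dynamical reading this is
#' the one-step transition quality \eqn{\mathrm{tr}\, H^\top(\Pi M - \pi^\top\pi)H}
#' with \eqn{M = D^{-1}A}; the two forms agree to numerical precision.
#'
#' @param graph a [weighted_graph()].
#' @param p an [partition()] (or membership vector).
#' @return scalar modularity.
#' @export
modularity_score <- function(graph, p) {
  stopifnot_graph(graph)
  p <- as_partition(p)
  check_partition_graph(graph, p)
  H <- indicator_matrix(p)
  m2 <- graph$total_weight
  intra <- sum(Matrix::diag(Matrix::t(H) %*% graph$adjacency %*% H)) / m2
  pic <- as.numeric(Matrix::t(H) %*% (graph$strengths / m2))
  intra - sum(pic^2)
}

# stationary community masses pi(c)
community_masses <- function(graph, p, dynamics = "normalized") {
  pi <- pi_vector(graph, dynamics)
  as.numeric(rowsum(pi, group = as.integer(p)))
}

# X = P(t)' (Pi H) by uniformization: with generator M - I,
# P(t) = e^{-t} sum_k (t^k/k!) M^k, all terms nonnegative, so the series is
# numerically benign.  Used when the graph is too large for a dense spectrum.
expm_action_rw <- function(graph, t, X, tol = 1e-12) {
  Mt <- Matrix::t(graph$adjacency / graph$strengths)  # M' = (D^{-1}A)'
  if (t == 0) return(X)
  K <- max(20L, ceiling(t + 12 * sqrt(t) + 20))
  logw <- -t            # log of e^{-t} t^k / k!, k = 0
  acc <- X * exp(logw)
  V <- X
  for (k in seq_len(K)) {
    V <- Mt %*% V
    logw <- logw + log(t) - log(k)
    acc <- acc + V * exp(logw)
    if (k > t && exp(logw) < tol) break
  }
  as.matrix(acc)
}

#' Markov stability of a partition
#'
#' The stability of partition `H` at Markov time `t` is the trace of the
#' clustered autocovariance matrix
#' \eqn{R(t) = H^\top(\Pi P(t) - \pi^\top\pi)H}. Entry `(c1, c2)` of `R(t)`
#' is the probability for a walker started at stationarity in community `c1`
#' to be in `c2` after time `t`, minus the probability for two independent
#' stationary walkers to be in `c1` and `c2`.
#'
#' For graphs up to 2000 nodes the propagator is applied through its dense
#' spectral form; above that the action of the matrix exponential on the `c`
#' columns of \eqn{\Pi H} is computed by uniformization of the continuous
#' chain, so `P(t)` is never formed.
#'
#' @inheritParams propagator
#' @param p an [partition()] (or membership vector).
#' @param spectrum optional precomputed result of the internal spectral
#'   decomposition (used by the sweep to amortize work across times).
#' @return object of class `stability_value`: list with `time`, `score`
#'   (\eqn{r(t;H)}) and `autocovariance` (the c-by-c matrix `R(t)`).
#' @export
stability_score <- function(graph, p, t, dynamics = "normalized",
                            spectrum = NULL) {
  stopifnot_graph(graph)
  assert_connected(graph)
  dynamics <- match.arg(dynamics, DYNAMICS)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("Markov time t must be a single nonnegative number")
  }
  p <- as_partition(p)
  check_partition_graph(graph, p)
  H <- indicator_matrix(p)
  pi <- pi_vector(graph, dynamics)
  pic <- as.numeric(Matrix::t(H) %*% pi)
  if (!is.null(spectrum) || graph$n_nodes <= 2000L || dynamics == "combinatorial") {
    if (is.null(spectrum)) spectrum <- rw_spectrum(graph, dynamics)
    P <- propagator_from_spectrum(spectrum, t)
    PiPH <- (pi * P) %*% as.matrix(H)          # Pi P(t) H
    R <- as.matrix(Matrix::t(H) %*% PiPH) - tcrossprod(pic)
  } else {
    X <- expm_action_rw(graph, t, as.matrix(pi * H))  # P(t)' Pi H
    R <- t(as.matrix(Matrix::t(H) %*% X)) - tcrossprod(pic)
    R <- (R + t(R)) / 2
  }
  structure(list(time = t, score = sum(diag(R)), autocovariance = R),
            class = "stability_value")
}

#' @export
print.stability_value <- function(x, ...) {
  cat(sprintf("stability r(t = %g) = %.6g over %d communities\n",
              x$time, x$score, nrow(x$autocovariance)))
  invisible(x)
}

#' Discrete-time stability
#'
#' Stability of the embedded discrete random walk after a whole number of
#' steps: \eqn{\mathrm{tr}\, H^\top(\Pi M^k - \pi^\top\pi)H} with
#' \eqn{M = D^{-1}A}. At `steps = 1` this is exactly modularity, which is the
#' sense in which modularity is a one-step method.
#'
#' @param graph a [weighted_graph()].
#' @param p an [partition()] (or membership vector).
#' @param steps nonnegative integer number of steps.
#' @return scalar.
#' @export
discrete_stability_score <- function(graph, p, steps) {
  stopifnot_graph(graph)
  if (!is.numeric(steps) || length(steps) != 1L || is.na(steps) ||
      steps < 0 || steps != round(steps)) {
    stop("steps must be a single nonnegative integer")
  }
  p <- as_partition(p)
  check_partition_graph(graph, p)
  pi <- pi_vector(graph)   # like modularity, defined without ergodicity
  H <- as.matrix(indicator_matrix(p))
  M <- graph$adjacency / graph$strengths
  Y <- H
  for (k in seq_len(steps)) Y <- as.matrix(M %*% Y)
  pic <- as.numeric(crossprod(H, pi))
  sum(pi * Y[cbind(seq_along(p), as.integer(p))]) - sum(pic^2)
}

#' Linearized stability
#'
#' First-order expansion of the stability in Markov time:
#' \eqn{\mathrm{tr}\, H^\top[(1-t)\Pi + t A/2m - \pi^\top\pi]H}. At `t = 1`
#' this equals modularity exactly; at `t = 0` it equals
#' \eqn{1 - \sum_c \pi(c)^2}. Being linear in the adjacency it is also the
#' natural objective for one-step (modularity-style) optimization at
#' resolution `t`.
#'
#' @inheritParams discrete_stability_score
#' @param t Markov time, `t >= 0`.
#' @return scalar.
#' @export
linearized_stability <- function(graph, p, t) {
  stopifnot_graph(graph)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("Markov time t must be a single nonnegative number")
  }
  p <- as_partition(p)
  check_partition_graph(graph, p)
  H <- indicator_matrix(p)
  m2 <- graph$total_weight
  pi <- graph$strengths / m2
  intra <- sum(Matrix::diag(Matrix::t(H) %*% graph$adjacency %*% H)) / m2
  pic <- as.numeric(Matrix::t(H) %*% pi)
  (1 - t) + t * intra - sum(pic^2)
}
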