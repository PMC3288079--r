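test_that("stationary distribution is strength-proportional", {
  expect_equal(stationary_distribution(cycle_graph(4)), rep(0.25, 4))
  expect_equal(stationary_distribution(path_graph(3)), c(0.25, 0.5, 0.25))
  expect_equal(stationary_distribution(weighted_graph(matrix(c(0, 3, 3, 0), 2))),
               c(0.5, 0.5))
  expect_error(stationary_distribution(two_triangles_graph()), "disconnected")
})

test_that("propagator matches the closed form on two nodes and P(0) = I", {
  g <- weighted_graph(matrix(c(0, 1, 1, 0), 2))
  for (t in c(0.3, 1, 2.5)) {
    e <- exp(-2 * t)
    expect_equal(propagator(g, t)$matrix,
                 matrix(c(1 + e, 1 - e, 1 - e, 1 + e) / 2, 2),
                 tolerance = 1e-12)
  }
  g2 <- random_connected_graph(9, seed = 5)
  expect_equal(propagator(g2, 0)$matrix, diag(9), tolerance = 1e-12)
  expect_error(propagator(g2, -1), "nonnegative")
})

test_that("propagator agrees with a direct matrix exponential", {
  # independent route: Matrix::expm of the full generator
  for (seed in c(1, 2)) {
    g <- random_connected_graph(7, seed = seed)
    L <- diag(g$strengths) - as.matrix(g$adjacency)
    gen <- -diag(1 / g$strengths) %*% L
    for (t in c(0.5, 2)) {
      ref <- as.matrix(Matrix::expm(t * Matrix::Matrix(gen)))
      expect_equal(propagator(g, t)$matrix, ref, tolerance = 1e-8)
    }
  }
})

test_that("propagator is row-stochastic and pi-stationary, with semigroup property", {
  for (seed in 1:3) {
    g <- random_connected_graph(20, seed = seed)
    pi <- stationary_distribution(g)
    for (t in c(0.1, 1, 10, 100)) {
      P <- propagator(g, t)$matrix
      expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
      expect_lt(max(abs(pi %*% P - pi)), 1e-9)
      expect_true(all(P >= 0 & P <= 1))
    }
    P1 <- propagator(g, 0.6)$matrix
    P2 <- propagator(g, 1.7)$matrix
    expect_equal(P1 %*% P2, propagator(g, 2.3)$matrix, tolerance = 1e-8)
  }
  # ergodic limit: every row approaches the stationary distribution
  P <- propagator(cycle_graph(4), 50)$matrix
  expect_equal(P, matrix(0.25, 4, 4), tolerance = 1e-6)
})

test_that("modularity agrees with igraph and with its trace form", {
  g <- two_triangles_graph()
  expect_equal(modularity_score(g, two_triangles_planted()), 0.5)
  for (seed in 1:50) {
    g <- random_connected_graph(sample(5:12, 1), seed = 100 + seed)
    p <- random_partition(g$n_nodes, sample(2:4, 1), seed = 200 + seed)
    q <- modularity_score(g, p)
    # independent oracle: igraph's combinatorial implementation
    ig <- as_igraph(g)
    expect_equal(q, igraph::modularity(ig, as.integer(p),
                                       weights = igraph::E(ig)$weight),
                 tolerance = 1e-9)
    # dynamical (trace) form via the one-step discrete stability
    expect_equal(q, discrete_stability_score(g, p, 1), tolerance = 1e-9)
  }
  # degenerate partitions
  g <- random_connected_graph(8, seed = 3)
  expect_equal(modularity_score(g, rep(1, 8)), 0, tolerance = 1e-12)
  pi <- stationary_distribution(g)
  expect_equal(modularity_score(g, 1:8), -sum(pi^2), tolerance = 1e-12)
})

test_that("stability score satisfies its boundary identities", {
  g <- cycle_graph(4)
  p2 <- partition(c(1, 1, 2, 2))
  # all-in-one scores zero at every time
  for (t in c(0, 0.5, 3, 40)) {
    expect_equal(stability_score(g, rep(1, 4), t)$score, 0, tolerance = 1e-10)
  }
  # t = 0: r(0) = 1 - sum pi(c)^2
  pi <- stationary_distribution(g)
  masses <- c(0.5, 0.5)
  expect_equal(stability_score(g, p2, 0)$score, 1 - sum(masses^2),
               tolerance = 1e-10)
  # t -> infinity: decays to zero
  expect_lt(abs(stability_score(g, p2, 200)$score), 1e-6)
  # score equals the trace of the autocovariance
  sv <- stability_score(g, p2, 1.3)
  expect_equal(sv$score, sum(diag(sv$autocovariance)), tolerance = 1e-12)
  expect_error(stability_score(g, p2, -0.1), "nonnegative")
  expect_error(stability_score(two_triangles_graph(), rep(1, 6), 1), "disconnected")
})

test_that("autocovariance entries are walker probabilities minus independence", {
  # R(t)[c1, c2] = P(start in c1 at stationarity, end in c2 at t) - pi(c1) pi(c2)
  g <- random_connected_graph(8, seed = 11)
  p <- random_partition(8, 3, seed = 12)
  t <- 1.7
  P <- propagator(g, t)$matrix
  pi <- stationary_distribution(g)
  R <- stability_score(g, p, t)$autocovariance
  for (c1 in 1:3) for (c2 in 1:3) {
    direct <- sum((pi[p == c1] * P[p == c1, , drop = FALSE])[, p == c2]) -
      sum(pi[p == c1]) * sum(pi[p == c2])
    expect_equal(R[c1, c2], direct, tolerance = 1e-10)
  }
})

test_that("uniformization path agrees with the dense propagator", {
  g <- random_connected_graph(30, seed = 9)
  p <- random_partition(30, 4, seed = 9)
  pi <- stationary_distribution(g)
  H <- matrix(0, 30, 4); H[cbind(1:30, as.integer(p))] <- 1
  for (t in c(0.5, 5, 50)) {
    X <- markovstability:::expm_action_rw(g, t, pi * H)  # P(t)' Pi H
    dense <- t(propagator(g, t)$matrix) %*% (pi * H)
    expect_equal(X, dense, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("discrete stability: one step is modularity, zero steps is 1 - sum pi(c)^2", {
  for (seed in 1:10) {
    g <- random_connected_graph(sample(5:10, 1), seed = 300 + seed)
    p <- random_partition(g$n_nodes, 3, seed = 400 + seed)
    expect_equal(discrete_stability_score(g, p, 1), modularity_score(g, p),
                 tolerance = 1e-12)
    pic <- rowsum(stationary_distribution(g), as.integer(p))
    expect_equal(discrete_stability_score(g, p, 0), 1 - sum(pic^2),
                 tolerance = 1e-12)
  }
  # two disjoint triangles, two steps: explicit 6x6 matrix arithmetic oracle
  g <- two_triangles_graph()
  p <- two_triangles_planted()
  A <- as.matrix(g$adjacency)
  M <- diag(1 / rowSums(A)) %*% A
  pi <- rowSums(A) / sum(A)
  H <- matrix(0, 6, 2); H[cbind(1:6, as.integer(p))] <- 1
  oracle <- sum(diag(t(H) %*% (diag(pi) %*% (M %*% M) - outer(pi, pi)) %*% H))
  expect_equal(discrete_stability_score(g, p, 2), oracle, tolerance = 1e-12)
})

test_that("linearized stability equals modularity at t = 1 and r(0) at t = 0", {
  for (seed in 1:20) {
    g <- random_connected_graph(sample(5:12, 1), seed = 500 + seed)
    p <- random_partition(g$n_nodes, sample(2:4, 1), seed = 600 + seed)
    expect_equal(linearized_stability(g, p, 1), modularity_score(g, p),
                 tolerance = 1e-12)
    pic <- rowsum(stationary_distribution(g), as.integer(p))
    expect_equal(linearized_stability(g, p, 0), 1 - sum(pic^2),
                 tolerance = 1e-12)
  }
})

test_that("linearization error shrinks quadratically in t", {
  g <- cycle_graph(4)
  p <- partition(c(1, 1, 2, 2))
  err <- function(t) abs(stability_score(g, p, t)$score -
                           linearized_stability(g, p, t))
  # Richardson-style ratio: halving t divides the gap by about 4
  r1 <- err(0.2) / err(0.1)
  r2 <- err(0.1) / err(0.05)
  expect_gt(r1, 3); expect_lt(r1, 5)
  expect_gt(r2, 3); expect_lt(r2, 5)
})

test_that("combinatorial dynamics variant is available and stochastic", {
  g <- path_graph(5)
  P <- propagator(g, 1.5, dynamics = "combinatorial")$matrix
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # uniform distribution is stationary for the combinatorial generator
  u <- rep(0.2, 5)
  expect_lt(max(abs(u %*% P - u)), 1e-9)
  expect_equal(stability_score(g, rep(1, 5), 2, dynamics = "combinatorial")$score,
               0, tolerance = 1e-10)
})
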