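test_that("time grids are logarithmic with validated bounds", {
  expect_equal(time_grid(0.1, 10, 3), c(0.1, 1, 10), tolerance = 1e-12)
  expect_error(time_grid(1, 1, 5), "t_min < t_max")
  expect_error(time_grid(-1, 2, 5), "t_min")
  expect_error(time_grid(0.1, 1, 1), "at least 2")
  g <- time_grid(0.01, 100, 41)
  expect_length(g, 41)
  expect_true(all(diff(g) > 0))
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 40), tolerance = 1e-10)
})

test_that("variation of information matches closed forms and igraph", {
  p <- random_partition(12, 3, seed = 1)
  expect_equal(variation_of_information(p, p), 0)
  n <- 10
  expect_equal(variation_of_information(partition(1:n), partition(rep(1, n))),
               log(n), tolerance = 1e-12)
  # crossed pairs on 4 nodes: joint cells all 1/4, zero mutual information
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               2 * log(2), tolerance = 1e-12)
  # independent oracle: igraph's VI distance
  for (seed in 1:20) {
    a <- random_partition(15, 3, seed = 800 + seed)
    b <- random_partition(15, 4, seed = 900 + seed)
    expect_equal(variation_of_information(a, b),
                 igraph::compare(as.integer(a), as.integer(b), method = "vi"),
                 tolerance = 1e-10)
  }
  expect_error(variation_of_information(partition(1:3), partition(1:4)),
               "different numbers")
})

test_that("VI is a relabeling-invariant metric", {
  for (seed in 1:200) {
    n <- 8 + seed %% 7
    a <- random_partition(n, 2 + seed %% 3, seed = 3 * seed)
    b <- random_partition(n, 2 + (seed + 1) %% 3, seed = 3 * seed + 1)
    c <- random_partition(n, 2 + (seed + 2) %% 3, seed = 3 * seed + 2)
    vab <- variation_of_information(a, b)
    # symmetry, identity, triangle inequality
    expect_identical(vab, variation_of_information(b, a))
    expect_lte(variation_of_information(a, c),
               vab + variation_of_information(b, c) + 1e-12)
    # invariance under relabeling of the communities
    relab <- partition(sample.int(n_communities(a))[as.integer(a)])
    expect_equal(variation_of_information(relab, b), vab, tolerance = 1e-12)
    expect_lte(vab, log(n) + 1e-12)
  }
})

test_that("mean pairwise VI averages all unordered pairs", {
  p <- random_partition(10, 3, seed = 5)
  q <- random_partition(10, 2, seed = 6)
  expect_equal(mean_pairwise_vi(rep(list(p), 100)), 0)
  expect_equal(mean_pairwise_vi(list(partition(1:8), partition(rep(1, 8)))),
               log(8), tolerance = 1e-12)
  expect_equal(mean_pairwise_vi(list(p, p, q)),
               (2 / 3) * variation_of_information(p, q), tolerance = 1e-12)
  expect_error(mean_pairwise_vi(list(p)), "at least two")
})

test_that("plateau detection ranks persistent low-VI runs and excludes trivia", {
  # synthetic sweep: singleton prefix, a robust 3-community plateau, a noisy
  # tail, and an all-in-one plateau at long times
  mk <- function(t, c, vi) list(time = t, best_partition = partition(rep(seq_len(c), length.out = 20)),
                                stability = 0.5, n_communities = c, mean_vi = vi)
  times <- 10^seq(-2, 3, length.out = 11)
  cs <- c(20, 20, 3, 3, 3, 3, 7, 7, 1, 1, 1)
  vis <- c(0, 0, 0.01, 0, 0, 0.01, 0.4, 0.5, 0, 0, 0)
  recs <- Map(mk, times, cs, vis)
  res <- structure(list(
    summary = data.frame(t = times, stability = 0.5, n_communities = cs, mean_vi = vis),
    records = recs,
    config = list(n_nodes = 20, vi_threshold = 0.05 * log(20),
                  min_persistence = 0.5)), class = "stability_sweep")
  tab <- find_robust_plateaus(res)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$n_communities, c(20L, 3L, 7L, 1L))
  expect_equal(tab$trivial, c(TRUE, FALSE, FALSE, TRUE))
  # singleton prefix and all-in-one tail are robust but unranked
  expect_true(tab$robust[1]); expect_true(is.na(tab$rank[1]))
  expect_true(tab$robust[4]); expect_true(is.na(tab$rank[4]))
  # the 3-community plateau is the only ranked one; the noisy 7 fails on VI
  expect_equal(tab$rank[2], 1L)
  expect_false(tab$robust[3])
  expect_equal(tab$persistence[2], log10(times[6] / times[3]), tolerance = 1e-10)
  # raising the bar empties the ranking
  tab2 <- find_robust_plateaus(res, vi_threshold = 1e-9, min_persistence = 3)
  expect_true(all(is.na(tab2$rank)))
})

test_that("a small ring-of-rings sweep finds the planted rings as its plateau", {
  b <- ring_of_rings(3, 6)
  res <- run_sweep(b$graph, times = time_grid(0.2, 20, 13), n_runs = 20,
                   base_seed = 0)
  expect_true(all(diff(res$summary$t) > 0))
  # recorded stability equals an independent stability evaluation
  k <- 7
  expect_equal(res$summary$stability[k],
               stability_score(b$graph, res$records[[k]]$best_partition,
                               res$summary$t[k])$score,
               tolerance = 1e-9)
  tp <- top_plateau(res)
  expect_false(is.null(tp))
  expect_equal(tp$n_communities, 3L)
  expect_equal(variation_of_information(tp$partition, b$planted), 0)
})

test_that("single-time single-run sweeps make no plateau claims", {
  g <- cycle_graph(6)
  res <- run_sweep(g, times = 1, n_runs = 1, base_seed = 0)
  expect_equal(nrow(res$summary), 1L)
  expect_true(is.na(res$summary$mean_vi))
  expect_true(all(is.na(res$plateaus$rank)))
})

test_that("planted rings outscore the modularity-style overpartition at coarse times", {
  b <- ring_of_rings(5, 20)
  r <- best_of_runs(b$graph, 1, n_runs = 25, base_seed = 0, linearized = TRUE)
  expect_gt(n_communities(r$best), 5L)   # one-step objective overpartitions
  for (t in c(3, 10, 50)) {
    expect_gt(stability_score(b$graph, b$planted, t)$score,
              stability_score(b$graph, r$best, t)$score)
  }
})

test_that("sweep CSV output is byte-identical across repeated runs", {
  g <- ring_of_rings(3, 6)$graph
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  res1 <- run_sweep(g, times = time_grid(0.5, 5, 5), n_runs = 5, base_seed = 2)
  res2 <- run_sweep(g, times = time_grid(0.5, 5, 5), n_runs = 5, base_seed = 2)
  write_sweep_csv(res1, f1); write_sweep_csv(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
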