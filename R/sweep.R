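# The zooming lens: scan Markov times, optimize stability at each time with
# repeated Louvain restarts, quantify robustness by the mean pairwise
# variation of information across restarts, and detect persistent, low-VI
# plateaus.

#' Logarithmic Markov-time grid
#'
#' @param t_min,t_max positive bounds, `t_min < t_max`.
#' @param n_points number of grid points (`>= 2`), endpoints included.
#' @return strictly increasing numeric vector with a constant ratio between
#'   consecutive times.
#' @export
time_grid <- function(t_min, t_max, n_points) {
  if (!is.numeric(t_min) || !is.numeric(t_max) || t_min <= 0 || t_max <= t_min) {
    stop("need 0 < t_min < t_max")
  }
  if (n_points < 2L) stop("n_points must be at least 2")
  exp(seq(log(t_min), log(t_max), length.out = as.integer(n_points)))
}

#' Variation of information between two partitions
#'
#' Information-theoretic metric \eqn{VI = H(X) + H(Y) - 2 I(X;Y)} computed in
#' nats from the confusion table of shared node counts. Zero iff the
#' partitions are identical (up to relabeling); at most \eqn{\ln n}. Used to
#' quantify how much optimizer restarts disagree.
#'
#' @param p1,p2 [partition()] objects (or membership vectors) over the same
#'   node set.
#' @param normalized divide by \eqn{\ln n} for cross-size comparability.
#' @return scalar VI in nats (or normalized units).
#' @export
variation_of_information <- function(p1, p2, normalized = FALSE) {
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  n <- length(p1)
  if (length(p2) != n) stop("partitions cover different numbers of nodes")
  # canonical argument order makes symmetry exact (summation order and all)
  s1 <- paste(as.integer(p1), collapse = ","); s2 <- paste(as.integer(p2), collapse = ",")
  if (s2 < s1) { tmp <- p1; p1 <- p2; p2 <- tmp }
  joint <- table(as.integer(p1), as.integer(p2)) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  Hxy <- -sum(joint[nz] * log(joint[nz]))
  Hx <- -sum(px[px > 0] * log(px[px > 0]))
  Hy <- -sum(py[py > 0] * log(py[py > 0]))
  vi <- max(0, 2 * Hxy - Hx - Hy)   # H(X|Y) + H(Y|X)
  if (normalized) vi / log(n) else vi
}

#' Mean pairwise variation of information
#'
#' Average VI over all unordered pairs of the given partitions; the
#' robustness summary reported at each Markov time of a sweep. Identical
#' duplicates are collapsed before the pairwise pass, which makes the
#' common all-restarts-agree case cheap.
#'
#' @param partitions list of at least two partitions on the same node set.
#' @inheritParams variation_of_information
#' @return scalar mean VI.
#' @export
mean_pairwise_vi <- function(partitions, normalized = FALSE) {
  k <- length(partitions)
  if (k < 2L) stop("need at least two partitions")
  partitions <- lapply(partitions, as_partition)
  sig <- vapply(partitions, function(p) paste(as.integer(p), collapse = ","),
                character(1))
  uniq <- !duplicated(sig)
  reps <- partitions[uniq]
  counts <- as.numeric(table(factor(sig, levels = sig[uniq])))
  u <- length(reps)
  if (u == 1L) return(0)
  tot <- 0
  for (a in seq_len(u - 1L)) {
    for (b in (a + 1L):u) {
      tot <- tot + counts[a] * counts[b] *
        variation_of_information(reps[[a]], reps[[b]], normalized = normalized)
    }
  }
  tot / (k * (k - 1) / 2)
}

default_vi_threshold <- function(n) 0.05 * log(n)

#' Markov-time sweep with robustness analysis
#'
#' For every time in `times`, builds the stability quality matrix, runs
#' `n_runs` Louvain restarts (seeds `base_seed .. base_seed + n_runs - 1`,
#' singleton initialization at every time, no warm starts), and records the
#' best partition, its stability, the community count, and the mean pairwise
#' VI of the restarts. Plateau detection is then applied via
#' [find_robust_plateaus()].
#'
#' The spectral decomposition of the dynamics is computed once and shared
#' across all times.
#'
#' @inheritParams best_of_runs
#' @param graph a connected [weighted_graph()].
#' @param times increasing vector of Markov times (see [time_grid()];
#'   default grid `0.01`–`1000`, 61 points).
#' @param vi_threshold robustness threshold on the mean VI of a plateau;
#'   default `0.05 * log(n)` nats.
#' @param min_persistence minimum plateau width in decades of Markov time.
#' @param verbose print one line per time point.
#' @return object of class `stability_sweep`: list with `summary` (data frame
#'   of `t`, `stability`, `n_communities`, `mean_vi`), `records` (list of
#'   per-time records incl. best partition and all restart partitions'
#'   objectives), `plateaus` (see [find_robust_plateaus()]) and the run
#'   configuration.
#' @export
run_sweep <- function(graph, times = time_grid(0.01, 1000, 61), n_runs = 100L,
                      base_seed = 0L, dynamics = "normalized",
                      linearized = FALSE,
                      vi_threshold = NULL, min_persistence = 0.5,
                      verbose = FALSE) {
  stopifnot_graph(graph)
  assert_connected(graph)
  dynamics <- match.arg(dynamics, DYNAMICS)
  times <- sort(unique(as.numeric(times)))
  if (any(times <= 0)) stop("Markov times must be positive")
  spectrum <- if (linearized) NULL else rw_spectrum(graph, dynamics)
  records <- vector("list", length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    qm <- build_quality_matrix(graph, t, dynamics = dynamics,
                               linearized = linearized, spectrum = spectrum)
    runs <- best_of_runs(n_runs = n_runs, base_seed = base_seed, qmatrix = qm)
    mv <- if (n_runs >= 2L) mean_pairwise_vi(runs$partitions) else NA_real_
    records[[k]] <- list(
      time = t,
      best_partition = runs$best,
      stability = attr(runs$best, "objective"),
      n_communities = n_communities(runs$best),
      mean_vi = mv
    )
    if (verbose) {
      message(sprintf("t = %-10.4g r = %-10.6g c = %-4d <VI> = %.4g",
                      t, records[[k]]$stability, records[[k]]$n_communities, mv))
    }
  }
  summary <- data.frame(
    t = times,
    stability = vapply(records, `[[`, numeric(1), "stability"),
    n_communities = vapply(records, `[[`, integer(1), "n_communities"),
    mean_vi = vapply(records, `[[`, numeric(1), "mean_vi")
  )
  res <- structure(
    list(summary = summary, records = records, plateaus = NULL,
         config = list(n_runs = n_runs, base_seed = base_seed,
                       dynamics = dynamics, linearized = linearized,
                       n_nodes = graph$n_nodes,
                       vi_threshold = if (is.null(vi_threshold))
                         default_vi_threshold(graph$n_nodes) else vi_threshold,
                       min_persistence = min_persistence)),
    class = "stability_sweep")
  res$plateaus <- find_robust_plateaus(res)
  res
}

#' Detect robust plateaus in a sweep
#'
#' A plateau is a maximal run of consecutive sweep records with identical
#' community count. It is robust when its mean (over records) of the mean
#' pairwise VI is at most `vi_threshold` and its persistence
#' \eqn{\log_{10}(t_{end}/t_{start})} is at least `min_persistence` decades.
#' Robust plateaus are ranked by persistence (descending), ties by mean VI
#' (ascending). Trivial partitions — all singletons and all-in-one — are
#' reported but excluded from the ranking. The representative partition of a
#' plateau is the best partition at the record of maximal stability inside
#' it.
#'
#' @param result a [run_sweep()] result.
#' @param vi_threshold,min_persistence override the thresholds stored in the
#'   sweep configuration.
#' @return data frame with one row per plateau: `t_start`, `t_end`,
#'   `n_communities`, `persistence` (decades), `mean_vi`, `trivial`,
#'   `robust`, `rank` (NA for unranked rows); representative partitions in
#'   attribute `representatives` (list parallel to the rows).
#' @export
find_robust_plateaus <- function(result, vi_threshold = NULL,
                                 min_persistence = NULL) {
  if (!inherits(result, "stability_sweep")) stop("expected a stability_sweep")
  if (is.null(vi_threshold)) vi_threshold <- result$config$vi_threshold
  if (is.null(min_persistence)) min_persistence <- result$config$min_persistence
  s <- result$summary
  n_nodes <- result$config$n_nodes
  runs <- rle(s$n_communities)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- list(); reps <- list()
  for (k in seq_along(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    best_idx <- idx[which.max(s$stability[idx])]
    rows[[k]] <- data.frame(
      t_start = s$t[i0], t_end = s$t[i1],
      n_communities = runs$values[k],
      persistence = log10(s$t[i1] / s$t[i0]),
      mean_vi = mean(s$mean_vi[idx]),
      trivial = runs$values[k] %in% c(1L, n_nodes)
    )
    reps[[k]] <- result$records[[best_idx]]$best_partition
  }
  tab <- do.call(rbind, rows)
  tab$robust <- !is.na(tab$mean_vi) & tab$mean_vi <= vi_threshold &
    tab$persistence >= min_persistence
  tab$rank <- NA_integer_
  cand <- which(tab$robust & !tab$trivial)
  if (length(cand) > 0L) {
    ord <- cand[order(-tab$persistence[cand], tab$mean_vi[cand])]
    tab$rank[ord] <- seq_along(ord)
  }
  attr(tab, "representatives") <- reps
  tab
}

#' Top-ranked robust plateau of a sweep
#'
#' @param result a [run_sweep()] result.
#' @return list with the plateau row (`t_start`, `t_end`, ...) and its
#'   representative `partition`, or `NULL` when no non-trivial robust plateau
#'   exists.
#' @export
top_plateau <- function(result) {
  tab <- result$plateaus
  i <- which(tab$rank == 1L)
  if (length(i) == 0L) return(NULL)
  c(as.list(tab[i, , drop = FALSE]),
    list(partition = attr(tab, "representatives")[[i]]))
}

#' @export
print.stability_sweep <- function(x, ...) {
  s <- x$summary
  cat(sprintf("stability sweep: %d times in [%g, %g], %d restarts per time\n",
              nrow(s), min(s$t), max(s$t), x$config$n_runs))
  tp <- top_plateau(x)
  if (is.null(tp)) {
    cat("no non-trivial robust plateau detected\n")
  } else {
    cat(sprintf("top plateau: %d communities over t in [%g, %g] (%.2f decades, mean VI %.4g)\n",
                tp$n_communities, tp$t_start, tp$t_end, tp$persistence, tp$mean_vi))
  }
  invisible(x)
}

#' Write the sweep curve as CSV
#'
#' Columns `t, stability, n_communities, mean_vi`, rendered with 17
#' significant digits so identical runs give byte-identical files.
#'
#' @param result a [run_sweep()] result.
#' @param path output path.
#' @export
write_sweep_csv <- function(result, path) {
  s <- result$summary
  lines <- c("t,stability,n_communities,mean_vi",
             sprintf("%.17g,%.17g,%d,%.17g",
                     s$t, s$stability, s$n_communities, s$mean_vi))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Plot community count and VI against Markov time
#'
#' @param x a [run_sweep()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stability_sweep <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mar = c(4.5, 4.5, 1.5, 4.5))
  on.exit(graphics::par(op))
  graphics::plot(s$t, s$n_communities, log = "xy", type = "s", col = "blue",
                 xlab = "Markov time t", ylab = "number of communities", ...)
  graphics::par(new = TRUE)
  graphics::plot(s$t, s$mean_vi, log = "x", type = "l", col = "darkgreen",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "darkgreen")
  graphics::mtext("mean pairwise VI (nats)", side = 4, line = 3,
                  col = "darkgreen")
  invisible(x)
}
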