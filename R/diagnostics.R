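# Field-of-view diagnostics.  One-step quality functions can only resolve
# communities whose effective diameter fits within a single transition; when
# the communities they return are wide, that is a warning sign of
# overpartitioning.  These helpers measure community hop-diameters, raise the
# field-of-view flag, and estimate mixing times from the spectral gap.

#' Hop-count diameters of the induced community subgraphs
#'
#' For each community, the diameter (maximum over node pairs of the shortest
#' path length, in hops — weights encode affinity, not length, and are
#' ignored) of the subgraph induced by the community. The mean over
#' communities is the paper-and-pencil indicator of whether a partition is
#' within a one-step method's field of view.
#'
#' Disconnected induced communities are counted and flagged; their diameter
#' is taken as the maximum over their finite (within-component) distances so
#' the mean stays finite, and a warning is emitted.
#'
#' @param graph a [weighted_graph()].
#' @param p an [partition()] (or membership vector).
#' @return object of class `diameter_report`: list with `per_community`
#'   (integer vector), `mean_diameter`, `n_disconnected_communities` and
#'   `sizes`.
#' @export
community_diameters <- function(graph, p) {
  stopifnot_graph(graph)
  p <- as_partition(p)
  check_partition_graph(graph, p)
  subs <- induced_community_subgraphs(graph, p)
  n_disc <- 0L
  diams <- vapply(subs, function(sg) {
    if (sg$n_nodes == 1L) return(0L)
    g <- igraph::graph_from_adjacency_matrix(sg$adjacency, mode = "undirected",
                                             weighted = TRUE)
    D <- igraph::distances(g, weights = NA)   # unweighted hop counts
    fin <- D[is.finite(D)]
    if (any(!is.finite(D))) n_disc <<- n_disc + 1L
    as.integer(max(fin))
  }, integer(1))
  if (n_disc > 0L) {
    warning(sprintf("%d induced communit%s disconnected; using largest finite distances",
                    n_disc, if (n_disc == 1L) "y is" else "ies are"))
  }
  structure(list(per_community = diams,
                 mean_diameter = mean(diams),
                 n_disconnected_communities = n_disc,
                 sizes = vapply(subs, `[[`, integer(1), "n_nodes")),
            class = "diameter_report")
}

#' @export
print.diameter_report <- function(x, ...) {
  cat(sprintf("diameter report: %d communities, mean hop-diameter %.3g (%d disconnected)\n",
              length(x$per_community), x$mean_diameter,
              x$n_disconnected_communities))
  invisible(x)
}

#' Field-of-view flag
#'
#' Raised when the mean community hop-diameter exceeds `threshold` (default
#' 2: communities wider than two steps lie beyond a one-step horizon). A
#' raised flag on the output of a one-step method (modularity, other
#' single-transition objectives) indicates the method is operating outside
#' its implicit clique-like notion of community and is likely
#' overpartitioning; longer Markov times are needed to resolve such
#' structure.
#'
#' @param report a [community_diameters()] result.
#' @param threshold mean-diameter threshold in hops.
#' @return list with `flagged` (logical) and `message`.
#' @export
fov_flag <- function(report, threshold = 2) {
  if (!inherits(report, "diameter_report")) stop("expected a diameter_report")
  flagged <- report$mean_diameter > threshold
  msg <- if (flagged) {
    sprintf(paste0("mean community hop-diameter %.3g exceeds %.3g: these communities ",
                   "are wider than a one-step horizon, so a one-step objective ",
                   "(e.g. modularity) is likely overpartitioning; sweep longer ",
                   "Markov times to resolve long-range structure"),
            report$mean_diameter, threshold)
  } else {
    sprintf("mean community hop-diameter %.3g is within the one-step field of view (threshold %.3g)",
            report$mean_diameter, threshold)
  }
  list(flagged = flagged, message = msg)
}

#' Spectral gap and mixing-time estimate
#'
#' Smallest nonzero eigenvalue of the random-walk Laplacian \eqn{D^{-1}L}
#' (computed through the symmetric similarity transform
#' \eqn{D^{-1/2} L D^{-1/2}}). Its inverse estimates the mixing time of the
#' diffusion and hence the Markov time needed before a slowly mixing module
#' becomes detectable.
#'
#' @param graph a connected [weighted_graph()].
#' @return list with `gap` (positive scalar) and `mixing_time` (`1/gap`).
#' @export
spectral_gap <- function(graph) {
  stopifnot_graph(graph)
  if (!is_connected_graph(graph)) {
    stop("graph is disconnected: the spectral gap is zero and the mixing time undefined")
  }
  spec <- rw_spectrum(graph, "normalized")
  ev <- sort(spec$values)
  gap <- ev[2]
  list(gap = gap, mixing_time = 1 / gap)
}
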