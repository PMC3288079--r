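# Graph container, validation and file I/O used by every other module.
#
# A weighted_graph is a lightweight S3 wrapper around a symmetric sparse
# adjacency matrix together with cached node strengths.  All analysis in this
# package assumes undirected, connected, weighted graphs with a zero diagonal.

SYMMETRY_TOL <- 1e-12

#' Construct a weighted graph from an adjacency matrix
#'
#' Central container for all analyses in the package: a symmetric, nonnegative
#' weighted adjacency matrix with zero diagonal, plus cached node strengths
#' \eqn{d_i = \sum_j A_{ij}} and total edge weight \eqn{2m = \sum_i d_i}.
#'
#' @param adjacency square numeric matrix (dense or `Matrix` sparse),
#'   symmetric within `1e-12`, nonnegative, zero diagonal.
#' @param labels optional character vector of original node labels (defaults
#'   to `0:(n-1)`); kept so results can be reported in input labels.
#' @param allow_isolated keep nodes of zero strength. The stability framework
#'   requires every node to have positive strength; induced community
#'   subgraphs used by the diagnostics module may legitimately contain
#'   isolated nodes, which is the only intended use of this flag.
#' @return object of class `weighted_graph` with fields `adjacency`
#'   (`dgCMatrix`), `n_nodes`, `strengths`, `total_weight` and `labels`.
#' @export
weighted_graph <- function(adjacency, labels = NULL, allow_isolated = FALSE) {
  A <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  n <- nrow(A)
  if (n < 1L) stop("graph must have at least one node")
  asym <- max(abs(A - Matrix::t(A)))
  if (asym > SYMMETRY_TOL) {
    stop(sprintf("adjacency is not symmetric (max |A - t(A)| = %g)", asym))
  }
  A <- (A + Matrix::t(A)) / 2
  dimnames(A) <- NULL
  if (any(A@x < 0)) stop("negative edge weights are not allowed")
  if (any(Matrix::diag(A) != 0)) stop("self-loops (nonzero diagonal) are not allowed")
  d <- Matrix::rowSums(A)
  if (!allow_isolated && any(d <= 0)) {
    stop("isolated nodes (zero strength) are not allowed")
  }
  if (is.null(labels)) labels <- as.character(0:(n - 1L))
  if (length(labels) != n) stop("labels must have one entry per node")
  structure(
    list(
      adjacency    = A,
      n_nodes      = n,
      strengths    = as.numeric(d),
      total_weight = sum(d),
      labels       = as.character(labels)
    ),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  n_edges <- Matrix::nnzero(x$adjacency) / 2
  cat(sprintf("weighted_graph: %d nodes, %d edges, total weight 2m = %g\n",
              x$n_nodes, as.integer(n_edges), x$total_weight))
  invisible(x)
}

is_weighted_graph <- function(x) inherits(x, "weighted_graph")

stopifnot_graph <- function(graph) {
  if (!is_weighted_graph(graph)) stop("expected a weighted_graph object")
  invisible(graph)
}

#' Read a whitespace edge list into a weighted graph
#'
#' File rows are `"i j w"` with `w` optional (default 1). Lines starting with
#' `#` (and inline `#` comments) are ignored. Node ids are integers, compacted
#' to internal indices; the original labels are retained in the `labels` field
#' so partitions and edge lists can be written back in input labels.
#'
#' Rows are symmetrized: a row `i j w` implies weight `w` on the edge in both
#' directions. Duplicate rows for the same unordered pair are tolerated if the
#' weights agree exactly and rejected (with the offending row numbers)
#' otherwise. Self-loops and negative weights are rejected.
#'
#' @param path path to the edge list file (UTF-8).
#' @param one_based interpret node ids as 1-based (cosmetic only; ids are
#'   compacted either way and retained as labels).
#' @return a [weighted_graph()].
#' @export
load_edgelist <- function(path, one_based = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("edge list contains no edges: ", path)
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf < 2L | nf > 3L)) {
    stop("malformed edge list rows (need 'i j [w]') at line(s): ",
         paste(keep[nf < 2L | nf > 3L], collapse = ", "))
  }
  i <- suppressWarnings(as.integer(vapply(toks, `[`, "", 1L)))
  j <- suppressWarnings(as.integer(vapply(toks, `[`, "", 2L)))
  w <- vapply(seq_along(toks), function(k) {
    if (nf[k] == 3L) suppressWarnings(as.numeric(toks[[k]][3L])) else 1.0
  }, numeric(1))
  bad <- is.na(i) | is.na(j) | is.na(w)
  if (any(bad)) {
    stop("non-numeric edge list entries at line(s): ",
         paste(keep[bad], collapse = ", "))
  }
  if (any(w < 0)) {
    stop("negative edge weights at line(s): ", paste(keep[w < 0], collapse = ", "))
  }
  if (any(i == j)) {
    stop("self-loop rows at line(s): ", paste(keep[i == j], collapse = ", "))
  }
  # resolve duplicates on unordered pairs
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  first <- match(key, key)
  clash <- which(w != w[first])
  if (length(clash) > 0L) {
    stop("inconsistent duplicate edges at line(s): ",
         paste(sort(unique(c(keep[first[clash]], keep[clash]))), collapse = ", "))
  }
  dedup <- !duplicated(key)
  lo <- lo[dedup]; hi <- hi[dedup]; w <- w[dedup]
  ids <- sort(unique(c(lo, hi)))
  n <- length(ids)
  A <- Matrix::sparseMatrix(
    i = c(match(lo, ids), match(hi, ids)),
    j = c(match(hi, ids), match(lo, ids)),
    x = c(w, w), dims = c(n, n)
  )
  weighted_graph(A, labels = as.character(ids))
}

#' Write a weighted graph as a whitespace edge list
#'
#' One row per edge (`i j w`, upper triangle only) in the graph's original
#' node labels. Weights are rendered with 17 significant digits so that a
#' write/load round trip reproduces them exactly.
#'
#' @param graph a [weighted_graph()].
#' @param path output path.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot_graph(graph)
  A <- methods::as(Matrix::triu(graph$adjacency), "TsparseMatrix")
  ord <- order(A@i, A@j)
  lines <- sprintf("%s %s %.17g",
                   graph$labels[A@i[ord] + 1L],
                   graph$labels[A@j[ord] + 1L],
                   A@x[ord])
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Convert to an igraph object
#'
#' @param graph a [weighted_graph()].
#' @return an undirected `igraph` graph with edge attribute `weight` and
#'   vertex attribute `name` carrying the original labels.
#' @export
as_igraph <- function(graph) {
  stopifnot_graph(graph)
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- graph$labels
  g
}

from_igraph <- function(g) {
  A <- igraph::as_adjacency_matrix(g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
                                   sparse = TRUE)
  labels <- if ("name" %in% igraph::vertex_attr_names(g)) igraph::V(g)$name else NULL
  weighted_graph(A, labels = labels)
}

#' Read / write GraphML
#'
#' Edge weights are stored in the `weight` edge attribute; missing weights
#' default to 1.
#'
#' @param path file path.
#' @return [read_graphml()] returns a [weighted_graph()].
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  from_igraph(g)
}

#' @rdname read_graphml
#' @param graph a [weighted_graph()].
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Is the graph connected?
#'
#' Connectivity (treating any positive weight as an edge) is a precondition of
#' the diffusion framework: the stationary distribution is only well defined
#' on a connected graph.
#'
#' @param graph a [weighted_graph()].
#' @return logical.
#' @export
is_connected_graph <- function(graph) {
  stopifnot_graph(graph)
  if (graph$n_nodes == 1L) return(TRUE)
  igraph::is_connected(as_igraph(graph))
}

assert_connected <- function(graph) {
  if (!is_connected_graph(graph)) {
    stop("graph is disconnected; the Markov stability framework requires a connected graph")
  }
  invisible(graph)
}

# ---- partitions -------------------------------------------------------------

#' Construct a hard partition
#'
#' A partition assigns every node to exactly one community (the indicator
#' matrix H of the stability framework has one 1 per row). Labels are
#' compacted to contiguous integers `1..c` in order of first appearance.
#'
#' @param membership vector of community labels, one per node (any atomic
#'   type; compacted internally).
#' @return object of class `mstab_partition`: an integer membership vector
#'   with attribute `n_communities`.
#' @export
partition <- function(membership) {
  if (length(membership) < 1L) stop("membership must be non-empty")
  if (anyNA(membership)) stop("membership must not contain NA")
  m <- match(membership, unique(membership))
  structure(as.integer(m),
            n_communities = max(m),
            class = "mstab_partition")
}

#' @export
print.mstab_partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes in %d communities\n",
              length(x), n_communities(x)))
  invisible(x)
}

#' Number of communities of a partition
#' @param p an [partition()] object.
#' @export
n_communities <- function(p) {
  attr(p, "n_communities", exact = TRUE)
}

as_partition <- function(p) {
  if (inherits(p, "mstab_partition")) p else partition(p)
}

check_partition_graph <- function(graph, p) {
  if (length(p) != graph$n_nodes) {
    stop(sprintf("partition covers %d nodes but the graph has %d",
                 length(p), graph$n_nodes))
  }
  invisible(p)
}

# community indicator matrix H (n x c, one 1 per row)
indicator_matrix <- function(p) {
  p <- as_partition(p)
  Matrix::sparseMatrix(i = seq_along(p), j = as.integer(p), x = 1,
                       dims = c(length(p), n_communities(p)))
}

#' Read / write a partition file
#'
#' Two whitespace-separated columns, `node_label community_id`; `#` comments
#' allowed. On reading, node labels are matched against the graph's labels.
#'
#' @param path file path.
#' @param graph the [weighted_graph()] the partition refers to.
#' @return [read_partition()] returns an [partition()] object.
#' @export
read_partition <- function(path, graph) {
  stopifnot_graph(graph)
  lines <- sub("#.*$", "", readLines(path, encoding = "UTF-8"))
  keep <- nzchar(trimws(lines))
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  if (any(lengths(toks) != 2L)) stop("partition rows must be 'node_label community_id'")
  node <- vapply(toks, `[`, "", 1L)
  comm <- vapply(toks, `[`, "", 2L)
  idx <- match(graph$labels, node)
  if (anyNA(idx)) {
    stop("partition file is missing node(s): ",
         paste(utils::head(graph$labels[is.na(idx)], 5L), collapse = ", "))
  }
  partition(comm[idx])
}

#' @rdname read_partition
#' @param p an [partition()] object (or any membership vector).
#' @export
write_partition <- function(p, graph, path) {
  stopifnot_graph(graph)
  p <- as_partition(p)
  check_partition_graph(graph, p)
  writeLines(sprintf("%s %d", graph$labels, as.integer(p)), path, useBytes = TRUE)
  invisible(path)
}

#' Induced subgraphs of each community
#'
#' Returns one induced subgraph per community, preserving intra-community
#' weights only. Induced subgraphs may be disconnected or contain isolated
#' nodes; they are built with `allow_isolated = TRUE` since the diagnostics
#' module must handle them.
#'
#' @param graph a [weighted_graph()].
#' @param p an [partition()] of the graph's nodes.
#' @return list of `weighted_graph` objects, one per community (in label
#'   order 1..c).
#' @export
induced_community_subgraphs <- function(graph, p) {
  stopifnot_graph(graph)
  p <- as_partition(p)
  check_partition_graph(graph, p)
  lapply(seq_len(n_communities(p)), function(c) {
    idx <- which(p == c)
    weighted_graph(graph$adjacency[idx, idx, drop = FALSE],
                   labels = graph$labels[idx], allow_isolated = TRUE)
  })
}
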