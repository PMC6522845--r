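#' Markov Clustering (MCL)
#'
#' Self-contained implementation of van Dongen's Markov Cluster algorithm
#' on an undirected weighted graph.  The column-stochastic transition
#' matrix (after adding self-loops) is alternately expanded (matrix
#' power), inflated (entrywise power followed by column renormalisation)
#' and pruned (entries below `prune_below` zeroed, then renormalised)
#' until the matrix stops changing.  Clusters are read off as the
#' connected components of the symmetrised support of the converged
#' matrix, which makes the output a true partition and deterministic.
#'
#' @param edges edge list: a data frame (or 3-column matrix) whose first
#'   two columns are node ids and whose third column (optional, default 1)
#'   is a positive weight.  Self-edges are ignored (self-loops are
#'   controlled by `self_loops`).
#' @param inflation inflation exponent (default 2.0, the standard choice).
#' @param expansion expansion power (default 2).
#' @param self_loops self-loop weight added to every node (default 1).
#' @param prune_below entries smaller than this are dropped after each
#'   inflation (default 1e-5).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   maximum entrywise change.
#' @param nodes optional character vector of additional (possibly
#'   isolated) nodes; isolated nodes form singleton clusters.
#' @return Named integer vector: cluster membership for every node.
#'   Cluster ids are numbered 1, 2, ... in order of each cluster's
#'   byte-wise smallest member.  If the iteration cap is hit first, the
#'   current partition is returned with `attr(, "converged") = FALSE` and
#'   a warning.
#' @examples
#' tri2 <- data.frame(
#'   from = c("a", "b", "c", "x", "y", "z"),
#'   to   = c("b", "c", "a", "y", "z", "x")
#' )
#' mcl_cluster(tri2) # two clusters, one per triangle
#' @export
mcl_cluster <- function(edges, inflation = 2.0, expansion = 2,
                        self_loops = 1.0, prune_below = 1e-5,
                        max_iter = 200, tol = 1e-8, nodes = NULL) {
  el <- as_edge_list(edges)
  all_nodes <- sort_c(unique(c(el$from, el$to, as.character(nodes %||% character(0)))))
  n <- length(all_nodes)
  if (n == 0L) {
    return(structure(integer(0), names = character(0), converged = TRUE))
  }
  if (nrow(el) && any(el$weight <= 0)) {
    stop_data("mcl_cluster: edge weights must be positive")
  }
  el <- el[el$from != el$to, , drop = FALSE]
  i <- c(match(el$from, all_nodes), match(el$to, all_nodes), seq_len(n))
  j <- c(match(el$to, all_nodes), match(el$from, all_nodes), seq_len(n))
  x <- c(el$weight, el$weight, rep(self_loops, n))
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                            dimnames = list(all_nodes, all_nodes))
  A <- normalize_columns(A)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    M <- A
    for (e in seq_len(expansion - 1L)) M <- M %*% A
    M <- methods::as(M, "CsparseMatrix")
    M@x <- M@x^inflation
    M <- normalize_columns(M)
    M <- prune_matrix(M, prune_below)
    delta <- max(abs(M - A))
    A <- M
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within max_iter = ", max_iter,
            "; returning current partition")
  }
  membership <- support_components(A)
  structure(membership, converged = converged)
}

as_edge_list <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(edges))
  if (ncol(edges) < 2L) stop_data("edge list needs at least 2 columns")
  data.frame(
    from = as.character(edges[[1L]]),
    to = as.character(edges[[2L]]),
    weight = if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else
      rep(1, nrow(edges)),
    stringsAsFactors = FALSE
  )
}

normalize_columns <- function(A) {
  cs <- Matrix::colSums(A)
  if (any(cs == 0)) stop_data("column with zero mass during MCL normalisation")
  A %*% Matrix::Diagonal(x = 1 / cs)
}

prune_matrix <- function(A, prune_below) {
  A <- methods::as(A, "CsparseMatrix")
  if (length(A@x) == 0L) {
    return(A)
  }
  # Never empty a column: keep each column's maximum entry regardless.
  keep <- A@x >= prune_below
  colptr <- A@p
  for (jj in seq_len(ncol(A))) {
    rng <- if (colptr[jj + 1L] > colptr[jj]) (colptr[jj] + 1L):colptr[jj + 1L] else integer(0)
    if (length(rng) && !any(keep[rng])) {
      keep[rng[which.max(A@x[rng])]] <- TRUE
    }
  }
  A@x[!keep] <- 0
  A <- Matrix::drop0(A)
  normalize_columns(A)
}

# Connected components of the symmetrised support, renumbered so cluster 1
# contains the byte-wise smallest node.
support_components <- function(A) {
  supp <- methods::as(A, "CsparseMatrix")
  sym <- (supp + Matrix::t(supp)) > 0
  g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  nodes <- rownames(A)
  names(comp) <- nodes
  first_member <- vapply(
    split(nodes, comp), function(v) sort_c(v)[1L], character(1)
  )
  ord <- order_c(first_member)
  new_id <- integer(length(first_member))
  new_id[as.integer(names(first_member)[ord])] <- seq_along(ord)
  out <- new_id[comp]
  names(out) <- nodes
  out
}

#' Read / write ABC-format edge lists
#'
#' The whitespace-separated `node node weight` format used by the original
#' `mcl` tool.
#'
#' @param path file path.
#' @return `read_abc`: a data frame `from`, `to`, `weight`.
#' @export
read_abc <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 2L) tab$V3 <- 1
  stats::setNames(tab[1:3], c("from", "to", "weight"))
}

#' @rdname read_abc
#' @param edges edge list data frame (2 or 3 columns).
#' @export
write_abc <- function(edges, path) {
  el <- as_edge_list(edges)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
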