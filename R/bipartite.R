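#' Bipartite relations between genes, modules and phenotypes
#'
#' The decomposition represents every intermediate result as a binary
#' bipartite relation: `GP` (gene-phenotype), `GM` (gene-module), `MP`
#' (module-phenotype) and `SP` (SNP-phenotype).  A relation stores its edge
#' list together with the full node universes of both partitions, so that
#' isolated nodes keep a well-defined degree of zero.
#'
#' @param edges data frame with character columns `from` and `to`.
#' @param role one of `"GP"`, `"GM"`, `"MP"`, `"SP"` (free-form tags are
#'   allowed for derived relations).
#' @param left,right optional character vectors giving the complete node
#'   universe of each partition; defaults to the nodes present in `edges`.
#'
#' @return An object of class `mpa_bipartite`: a list with elements
#'   `edges` (deduplicated, deterministically ordered), `left`, `right`
#'   and `role`.
#' @examples
#' gp <- bipartite(data.frame(from = "g1", to = c("P1", "P2")), role = "GP")
#' left_degree(gp)
#' @export
bipartite <- function(edges, role = "GP", left = NULL, right = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges <- data.frame(
    from = as.character(edges$from),
    to = as.character(edges$to),
    stringsAsFactors = FALSE
  )
  edges <- unique(edges)
  edges <- edges[order_c(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  left <- sort_c(unique(c(as.character(left %||% character(0)), edges$from)))
  right <- sort_c(unique(c(as.character(right %||% character(0)), edges$to)))
  structure(
    list(edges = edges, left = left, right = right, role = role),
    class = "mpa_bipartite"
  )
}

#' @export
print.mpa_bipartite <- function(x, ...) {
  cat(sprintf(
    "<%s bipartite relation: %d x %d nodes, %d edges>\n",
    x$role, length(x$left), length(x$right), nrow(x$edges)
  ))
  invisible(x)
}

#' Node degrees of a bipartite relation
#'
#' @param b an [bipartite()] relation.
#' @return Named integer vector over the full left (resp. right) partition;
#'   isolated nodes have degree 0.
#' @export
left_degree <- function(b) {
  stopifnot(inherits(b, "mpa_bipartite"))
  d <- stats::setNames(integer(length(b$left)), b$left)
  if (nrow(b$edges)) {
    tab <- table(b$edges$from)
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' @rdname left_degree
#' @export
right_degree <- function(b) {
  stopifnot(inherits(b, "mpa_bipartite"))
  d <- stats::setNames(integer(length(b$right)), b$right)
  if (nrow(b$edges)) {
    tab <- table(b$edges$to)
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Sparse incidence matrix of a bipartite relation
#'
#' @param b an [bipartite()] relation.
#' @return A `dgCMatrix` with one row per left node and one column per right
#'   node (both sorted byte-wise), entries 1 where an edge exists.
#' @export
incidence_matrix <- function(b) {
  stopifnot(inherits(b, "mpa_bipartite"))
  Matrix::sparseMatrix(
    i = match(b$edges$from, b$left),
    j = match(b$edges$to, b$right),
    x = 1,
    dims = c(length(b$left), length(b$right)),
    dimnames = list(b$left, b$right)
  )
}

#' Neighbour sets of every left node
#'
#' @param b an [bipartite()] relation.
#' @return Named list mapping each left node to the sorted character vector
#'   of its right-partition neighbours (possibly empty).
#' @export
neighbors_of <- function(b) {
  stopifnot(inherits(b, "mpa_bipartite"))
  out <- stats::setNames(
    rep(list(character(0)), length(b$left)), b$left
  )
  if (nrow(b$edges)) {
    sp <- split(b$edges$to, b$edges$from)
    out[names(sp)] <- lapply(sp, sort_c)
  }
  out
}
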