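#' Build the GWAS profile matrix M
#'
#' Binary SNP-by-phenotype matrix with `M[i, j] = 1` iff SNP i has a
#' significant association with phenotype j.  Rows are restricted to SNPs
#' residing in gene regions (present in `snp_gene_map`); each row of the
#' result is the GWAS profile of one SNP.  Row and column order is
#' byte-wise lexicographic, so the matrix is reproducible.
#'
#' @param records significant association records: either the output of
#'   [hierarchical_filter()] (rows with `significant == TRUE` are used) or
#'   any data frame of already-selected records with `snp_id` and
#'   `phenotype_id`.
#' @param snp_gene_map SNP-to-gene map from [map_snps_to_genes()].
#' @return A sparse `dgCMatrix` with SNP ids as rownames and phenotype ids
#'   as colnames; every row has at least one nonzero entry.
#' @export
build_profile_matrix <- function(records, snp_gene_map) {
  stopifnot(is.data.frame(records),
            all(c("snp_id", "phenotype_id") %in% names(records)))
  if ("significant" %in% names(records)) {
    records <- records[records$significant, , drop = FALSE]
  }
  records <- records[records$snp_id %in% snp_gene_map$snp_id, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop_data("no in-gene significant SNPs: profile matrix would be empty")
  }
  snps <- sort_c(unique(records$snp_id))
  phens <- sort_c(unique(records$phenotype_id))
  M <- Matrix::sparseMatrix(
    i = match(records$snp_id, snps),
    j = match(records$phenotype_id, phens),
    x = 1,
    dims = c(length(snps), length(phens)),
    dimnames = list(snps, phens)
  )
  M@x[] <- 1 # collapse duplicates produced by summing
  M
}

#' Proportional Similarity (Czekanowski) index
#'
#' `PS(X, Y) = 2 * sum_i min(x_i, y_i) / sum_i (x_i + y_i)`, a similarity
#' in \[0, 1\] for nonnegative vectors.  For binary GWAS profiles PS = 1
#' exactly when the two profiles are identical and 0 when their supports
#' are disjoint.
#'
#' @param x,y nonnegative numeric vectors of equal length, each with at
#'   least one nonzero entry.
#' @return A single similarity value in \[0, 1\].
#' @examples
#' proportional_similarity(c(1, 1, 0), c(0, 1, 1)) # 0.5
#' @export
proportional_similarity <- function(x, y) {
  if (length(x) != length(y)) stop_data("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop_data("entries must be nonnegative")
  denom <- sum(x) + sum(y)
  if (denom == 0) stop_data("PS undefined: both vectors are all-zero")
  2 * sum(pmin(x, y)) / denom
}

#' Build the gene-phenotype (GP) relation
#'
#' A gene links to a phenotype when it contains a SNP significantly
#' associated with that phenotype: the per-gene union of its SNPs'
#' profiles.
#'
#' @inheritParams build_profile_matrix
#' @return A `"GP"` [bipartite()] relation.
#' @export
build_gp <- function(records, snp_gene_map) {
  if ("significant" %in% names(records)) {
    records <- records[records$significant, , drop = FALSE]
  }
  merged <- merge(records[c("snp_id", "phenotype_id")], snp_gene_map,
                  by = "snp_id")
  if (nrow(merged) == 0L) {
    stop_data("no in-gene significant associations: GP relation is empty")
  }
  bipartite(data.frame(from = merged$gene_id, to = merged$phenotype_id),
            role = "GP")
}

#' Identify multi-phenotype-association (MPA) genes
#'
#' MPA genes are those associated with two or more phenotypes (GP
#' degree 2 or higher); all others are single-phenotype-association
#' (SPA) genes.
#'
#' @param gp a `"GP"` [bipartite()] relation from [build_gp()].
#' @return Sorted character vector of MPA gene ids.
#' @export
identify_mpa_genes <- function(gp) {
  d <- left_degree(gp)
  sort_c(names(d)[d >= 2L])
}

#' All-vs-all Proportional Similarity SNP network
#'
#' Computes PS between every unordered pair of rows of `M` (optionally
#' restricted to a SNP subset, typically the SNPs residing in MPA genes).
#' Zero-weight pairs -- profiles with disjoint support -- are omitted from
#' the returned edge list; semantically the network is complete and
#' unpruned, with those edges present at weight 0.
#'
#' @param M profile matrix from [build_profile_matrix()].
#' @param restrict_to_snps optional character vector of row names to keep.
#' @return Data frame `snp_a`, `snp_b`, `weight` with `snp_a < snp_b`
#'   byte-wise, deterministically ordered.
#' @export
build_snp_network <- function(M, restrict_to_snps = NULL) {
  A <- restrict_profile(M, restrict_to_snps)
  ov <- Matrix::tcrossprod(A) # pairwise sum of min for binary rows
  rs <- Matrix::rowSums(A)
  tri <- methods::as(Matrix::triu(ov, 1), "TsparseMatrix")
  w <- 2 * tri@x / (rs[tri@i + 1L] + rs[tri@j + 1L])
  edges <- data.frame(
    snp_a = rownames(A)[tri@i + 1L],
    snp_b = rownames(A)[tri@j + 1L],
    weight = w,
    stringsAsFactors = FALSE
  )
  edges <- edges[order_c(edges$snp_a, edges$snp_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

restrict_profile <- function(M, restrict_to_snps) {
  if (!is.null(restrict_to_snps)) {
    missing <- setdiff(restrict_to_snps, rownames(M))
    if (length(missing)) {
      stop_data("restriction contains SNPs absent from M: ",
                paste(utils::head(missing, 3L), collapse = ", "))
    }
    M <- M[rownames(M) %in% restrict_to_snps, , drop = FALSE]
  }
  if (nrow(M) == 0L) stop_data("empty SNP restriction")
  M
}

#' Construct association modules
#'
#' An association module is a maximal set of SNPs sharing one identical
#' significant-phenotype profile -- an observed element of the powerset of
#' phenotypes.  `method = "exact"` groups SNPs directly by identical rows
#' of `M` (the PS = 1 equivalence classes; the threshold is evaluated as
#' exact support equality, not floating-point equality).  `method = "mcl"`
#' reproduces the original network route: prune the PS network to
#' weight-1 edges and cluster the remaining subgraph with [mcl_cluster()];
#' on threshold-1 graphs (disjoint unions of cliques) the two routes give
#' identical partitions.  Module ids are assigned by the byte-wise sorted
#' phenotype-set key, so they are stable across runs.
#'
#' @inheritParams build_snp_network
#' @param method `"exact"` (default) or `"mcl"`.
#' @param ... passed on to [mcl_cluster()] when `method = "mcl"`.
#' @return An object of class `mpa_modules`: a list with `module_id`
#'   (character), `snps` (named list of member SNP sets) and `phenotypes`
#'   (named list of the shared phenotype set of each module).
#' @export
build_modules <- function(M, restrict_to_snps = NULL,
                          method = c("exact", "mcl"), ...) {
  method <- match.arg(method)
  A <- restrict_profile(M, restrict_to_snps)
  keys <- profile_keys(A)
  if (any(keys == "")) stop_data("profile matrix has an all-zero row")
  if (method == "exact") {
    groups <- split(rownames(A), keys)
  } else {
    edges <- build_snp_network(A)
    unit <- edges[abs(edges$weight - 1) < 1e-12, c("snp_a", "snp_b", "weight")]
    membership <- mcl_cluster(unit, nodes = rownames(A), ...)
    groups <- split(names(membership), membership)
    # key each MCL cluster by the phenotypes shared by all members
    names(groups) <- vapply(groups, function(snps) {
      shared <- Reduce(intersect, strsplit(keys[match(snps, rownames(A))], "|",
                                           fixed = TRUE))
      paste(sort_c(shared), collapse = "|")
    }, character(1))
  }
  ord <- order_c(names(groups))
  groups <- groups[ord]
  ids <- seq_ids("M", length(groups))
  snps <- stats::setNames(lapply(groups, sort_c), ids)
  phenotypes <- stats::setNames(
    lapply(strsplit(names(groups), "|", fixed = TRUE), sort_c), ids
  )
  structure(
    list(module_id = ids, snps = snps, phenotypes = phenotypes),
    class = "mpa_modules"
  )
}

#' @export
print.mpa_modules <- function(x, ...) {
  cat(sprintf(
    "<%d association modules over %d SNPs and %d phenotypes>\n",
    length(x$module_id), sum(lengths(x$snps)),
    length(unique(unlist(x$phenotypes)))
  ))
  invisible(x)
}

#' Module membership as a data frame
#'
#' @param modules an `mpa_modules` object.
#' @return Data frame `module_id`, `snp_id`.
#' @export
module_members <- function(modules) {
  stopifnot(inherits(modules, "mpa_modules"))
  data.frame(
    module_id = rep(modules$module_id, lengths(modules$snps)),
    snp_id = unlist(modules$snps, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Build the module-phenotype (MP) relation
#'
#' A module links to a phenotype when that phenotype is significantly
#' associated with every SNP in the module -- i.e. the module's shared
#' profile.  The MP row of a module therefore equals the M row of each of
#' its member SNPs.
#'
#' @param modules an `mpa_modules` object from [build_modules()].
#' @return An `"MP"` [bipartite()] relation.
#' @export
build_mp <- function(modules) {
  stopifnot(inherits(modules, "mpa_modules"))
  bipartite(
    data.frame(
      from = rep(modules$module_id, lengths(modules$phenotypes)),
      to = unlist(modules$phenotypes, use.names = FALSE)
    ),
    role = "MP", left = modules$module_id
  )
}

#' Build the gene-module (GM) relation
#'
#' A gene links to a module when the module contains at least one SNP
#' residing within the gene.  This maps genes into powerset space: the GM
#' row of a gene is its detailed MPA signature.
#'
#' @param modules an `mpa_modules` object.
#' @param snp_gene_map SNP-to-gene map from [map_snps_to_genes()].
#' @return A `"GM"` [bipartite()] relation.
#' @export
build_gm <- function(modules, snp_gene_map) {
  stopifnot(inherits(modules, "mpa_modules"))
  mem <- module_members(modules)
  merged <- merge(mem, snp_gene_map, by = "snp_id")
  bipartite(
    data.frame(from = merged$gene_id, to = merged$module_id),
    role = "GM", right = modules$module_id
  )
}

#' Verify the decomposition identity GP = GM o MP
#'
#' Checks, gene by gene, that the boolean product of the gene-module and
#' module-phenotype relations reconstructs the gene-phenotype relation:
#' `GP(g, p) = OR_m [GM(g, m) AND MP(m, p)]`.  The check runs over the
#' genes present in GM (all MPA genes under the default restriction;
#' include-SPA runs extend it to every gene).
#'
#' @param gp,gm,mp the three relations from one decomposition run.
#' @return List with `ok` (logical) and `mismatches`, a data frame of
#'   `gene_id`, `phenotype_id`, `in_gp`, `in_composition` rows where the
#'   two sides disagree (empty when `ok`).
#' @export
verify_decomposition <- function(gp, gm, mp) {
  stopifnot(inherits(gp, "mpa_bipartite"), inherits(gm, "mpa_bipartite"),
            inherits(mp, "mpa_bipartite"))
  if (!all(gm$right %in% mp$left)) {
    stop_data("partition label mismatch: GM modules missing from MP")
  }
  genes <- gm$left
  gm_nb <- neighbors_of(gm)
  mp_nb <- neighbors_of(mp)
  gp_nb <- neighbors_of(gp)
  mism <- list()
  for (g in genes) {
    composed <- sort_c(unique(unlist(mp_nb[gm_nb[[g]]], use.names = FALSE)))
    observed <- gp_nb[[g]] %||% character(0)
    only_gp <- setdiff(observed, composed)
    only_comp <- setdiff(composed, observed)
    if (length(only_gp) || length(only_comp)) {
      mism[[g]] <- data.frame(
        gene_id = g,
        phenotype_id = c(only_gp, only_comp),
        in_gp = c(rep(TRUE, length(only_gp)), rep(FALSE, length(only_comp))),
        in_composition = c(rep(FALSE, length(only_gp)), rep(TRUE, length(only_comp))),
        stringsAsFactors = FALSE
      )
    }
  }
  mismatches <- if (length(mism)) do.call(rbind, mism) else
    data.frame(gene_id = character(0), phenotype_id = character(0),
               in_gp = logical(0), in_composition = logical(0),
               stringsAsFactors = FALSE)
  rownames(mismatches) <- NULL
  list(ok = nrow(mismatches) == 0L, mismatches = mismatches)
}

#' Full MPA decomposition from significant records
#'
#' Convenience orchestrator for the core method: builds the profile
#' matrix, the GP relation, the association modules (restricted to SNPs in
#' MPA genes unless `include_spa`), and the GM and MP relations, then
#' verifies the decomposition identity.
#'
#' @inheritParams build_profile_matrix
#' @param include_spa also decompose SNPs residing only in SPA genes, so
#'   the identity extends to all genes (default `FALSE`, matching the
#'   method's MPA focus).
#' @param method module construction route, `"exact"` or `"mcl"`.
#' @return List with `M`, `gp`, `modules`, `gm`, `mp`, `mpa_genes` and
#'   `identity` (the [verify_decomposition()] result).
#' @export
mpa_decompose <- function(records, snp_gene_map, include_spa = FALSE,
                          method = c("exact", "mcl")) {
  method <- match.arg(method)
  M <- build_profile_matrix(records, snp_gene_map)
  gp <- build_gp(records, snp_gene_map)
  mpa_genes <- identify_mpa_genes(gp)
  restrict <- if (include_spa) {
    rownames(M)
  } else {
    keep <- snp_gene_map$gene_id %in% mpa_genes
    intersect(rownames(M), snp_gene_map$snp_id[keep])
  }
  modules <- build_modules(M, restrict_to_snps = restrict, method = method)
  gm <- build_gm(modules, snp_gene_map)
  mp <- build_mp(modules)
  list(
    M = M, gp = gp, modules = modules, gm = gm, mp = mp,
    mpa_genes = mpa_genes,
    identity = verify_decomposition(gp, gm, mp)
  )
}
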