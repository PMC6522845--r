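#' Classify genes by MPA signature type
#'
#' A gene connected to exactly one association module carries a Type 1
#' signature when that module is multi-phenotype (one variant group
#' associated with several phenotypes) and is a single-phenotype (SPA)
#' gene when the module has one phenotype.  A gene connected to two or
#' more modules carries a Type 2 signature (different variants associated
#' with different phenotype sets); Type 2 takes precedence when both
#' patterns co-occur, and such mixed genes are flagged `complex` (at
#' least one member module is itself multi-phenotype).
#'
#' @param gm,mp the gene-module and module-phenotype relations from
#'   [build_gm()] / [build_mp()].
#' @return Data frame with one row per gene in GM: `gene_id`, `class`
#'   (`"SPA"`, `"TYPE1"` or `"TYPE2"`), `complex` (logical), `n_modules`,
#'   `n_phenotypes` (size of the union of member-module phenotype sets).
#' @export
classify_genes <- function(gm, mp) {
  stopifnot(inherits(gm, "mpa_bipartite"), inherits(mp, "mpa_bipartite"))
  if (!all(gm$right %in% mp$left)) {
    stop_data("partition label mismatch: GM modules missing from MP")
  }
  mp_nb <- neighbors_of(mp)
  gm_nb <- neighbors_of(gm)
  rows <- lapply(gm$left, function(g) {
    mods <- gm_nb[[g]]
    phen_sets <- mp_nb[mods]
    n_mod <- length(mods)
    n_phen <- length(unique(unlist(phen_sets, use.names = FALSE)))
    multi <- any(lengths(phen_sets) >= 2L)
    cls <- if (n_mod >= 2L) "TYPE2" else if (multi) "TYPE1" else "SPA"
    data.frame(
      gene_id = g, class = cls,
      complex = cls == "TYPE2" && multi,
      n_modules = n_mod, n_phenotypes = n_phen,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a single gene
#'
#' @param gene gene id; must be present in GM.
#' @inheritParams classify_genes
#' @return One-row data frame as in [classify_genes()].
#' @export
classify_gene <- function(gene, gm, mp) {
  if (!gene %in% gm$left) stop_data("gene '", gene, "' absent from GM")
  cls <- classify_genes(gm, mp)
  cls[cls$gene_id == gene, , drop = FALSE]
}

#' Cluster genes by identical MPA signatures in powerset space
#'
#' Signature clustering groups genes whose GM rows are identical -- genes
#' associated with exactly the same set of association modules, i.e. the
#' same detailed MPA signature.  As for module construction, the
#' similarity is Proportional Similarity thresholded at 1, evaluated
#' either as exact support equality (`method = "exact"`) or via the
#' weight-1 PS graph clustered with [mcl_cluster()] (`method = "mcl"`);
#' the two agree on every threshold-1 graph.  Singleton clusters are
#' allowed (minimum cluster size one).
#'
#' @param gm the gene-module relation.
#' @param method `"exact"` (default) or `"mcl"`.
#' @param ... passed to [mcl_cluster()] when `method = "mcl"`.
#' @return Data frame `cluster_id`, `gene_id`, one row per gene, with the
#'   shared module set of every cluster attached as
#'   `attr(, "signatures")` (named list).  Cluster ids are assigned by the
#'   byte-wise sorted signature key.
#' @export
cluster_signatures <- function(gm, method = c("exact", "mcl"), ...) {
  method <- match.arg(method)
  stopifnot(inherits(gm, "mpa_bipartite"))
  if (length(gm$left) == 0L) stop_data("GM relation has no genes")
  G <- incidence_matrix(gm)
  keys <- profile_keys(G)
  if (any(keys == "")) stop_data("gene with empty module signature in GM")
  if (method == "exact") {
    groups <- split(rownames(G), keys)
  } else {
    edges <- ps_unit_edges(G)
    membership <- mcl_cluster(edges, nodes = rownames(G), ...)
    groups <- split(names(membership), membership)
    names(groups) <- vapply(groups, function(genes) {
      shared <- Reduce(intersect, strsplit(keys[match(genes, rownames(G))],
                                           "|", fixed = TRUE))
      paste(sort_c(shared), collapse = "|")
    }, character(1))
  }
  groups <- groups[order_c(names(groups))]
  ids <- seq_ids("C", length(groups))
  out <- data.frame(
    cluster_id = rep(ids, lengths(groups)),
    gene_id = unlist(lapply(groups, sort_c), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  attr(out, "signatures") <- stats::setNames(
    lapply(strsplit(names(groups), "|", fixed = TRUE), sort_c), ids
  )
  out
}

# Weight-1 PS edges between identical rows of a binary incidence matrix.
ps_unit_edges <- function(G) {
  ov <- Matrix::tcrossprod(G)
  rs <- Matrix::rowSums(G)
  tri <- methods::as(Matrix::triu(ov, 1), "TsparseMatrix")
  w <- 2 * tri@x / (rs[tri@i + 1L] + rs[tri@j + 1L])
  keep <- abs(w - 1) < 1e-12
  data.frame(
    from = rownames(G)[tri@i[keep] + 1L],
    to = rownames(G)[tri@j[keep] + 1L],
    weight = rep(1, sum(keep)),
    stringsAsFactors = FALSE
  )
}

#' Summarise signature clusters by size
#'
#' Tabulates, for each cluster size s, the number of clusters of that
#' size and the mean number of modules and phenotypes per member gene --
#' the summary behind the observed inverse relationship between cluster
#' size and signature complexity.
#'
#' @param clusters output of [cluster_signatures()].
#' @param gm,mp the relations the clustering was computed from.
#' @return Data frame `size`, `n_clusters`, `mean_modules`,
#'   `mean_phenotypes`, ascending in `size`; the per-cluster table is
#'   attached as `attr(, "per_cluster")`.
#' @export
summarize_clusters <- function(clusters, gm, mp) {
  cls_genes <- split(clusters$gene_id, clusters$cluster_id)
  gm_nb <- neighbors_of(gm)
  mp_nb <- neighbors_of(mp)
  per_gene_modules <- lengths(gm_nb)
  per_gene_phens <- vapply(gm_nb, function(mods) {
    length(unique(unlist(mp_nb[mods], use.names = FALSE)))
  }, integer(1))
  per_cluster <- data.frame(
    cluster_id = names(cls_genes),
    size = lengths(cls_genes),
    mean_modules = vapply(cls_genes, function(g)
      mean(per_gene_modules[g]), numeric(1)),
    mean_phenotypes = vapply(cls_genes, function(g)
      mean(per_gene_phens[g]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_cluster) <- NULL
  sizes <- sort(unique(per_cluster$size))
  out <- do.call(rbind, lapply(sizes, function(s) {
    sel <- per_cluster$size == s
    data.frame(
      size = s,
      n_clusters = sum(sel),
      mean_modules = mean(rep(per_cluster$mean_modules[sel],
                              per_cluster$size[sel])),
      mean_phenotypes = mean(rep(per_cluster$mean_phenotypes[sel],
                                 per_cluster$size[sel])),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "per_cluster") <- per_cluster
  out
}

#' Beta-sign summary per signature class
#'
#' Counts positive, negative and zero effect sizes among the significant
#' associations of genes in each signature class, summarising whether
#' minor alleles tend to raise or lower phenotype values.  A significant
#' record contributes once per (record, gene) pair, so a SNP inside two
#' overlapping genes is counted for both.  Genes absent from `classes`
#' (single-phenotype genes excluded from the decomposition) are tallied
#' as `"SPA"`.
#'
#' @param records association records carrying `beta`; if a `significant`
#'   column is present only significant rows are counted.
#' @param classes classification table from [classify_genes()].
#' @param snp_gene_map SNP-to-gene map.
#' @return Data frame `class`, `n_pos`, `n_neg`, `n_zero`.
#' @export
beta_sign_summary <- function(records, classes, snp_gene_map) {
  stopifnot("beta" %in% names(records))
  if ("significant" %in% names(records)) {
    records <- records[records$significant, , drop = FALSE]
  }
  merged <- merge(records[c("snp_id", "phenotype_id", "beta")], snp_gene_map,
                  by = "snp_id")
  cls <- stats::setNames(classes$class, classes$gene_id)
  gene_class <- cls[merged$gene_id]
  gene_class[is.na(gene_class)] <- "SPA"
  out <- do.call(rbind, lapply(c("SPA", "TYPE1", "TYPE2"), function(k) {
    b <- merged$beta[gene_class == k]
    data.frame(class = k, n_pos = sum(b > 0), n_neg = sum(b < 0),
               n_zero = sum(b == 0), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
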