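#' Export a labelled sparse matrix as MatrixMarket with label sidecars
#'
#' Writes coordinate-format MatrixMarket plus `<path>.rows` /
#' `<path>.cols` files holding the row and column labels, one per line.
#'
#' @param m a matrix or sparse `Matrix` with dimnames; must have at least
#'   one row and one column.
#' @param path output path (conventionally `.mtx`).
#' @return `path`, invisibly.
#' @export
export_matrix <- function(m, path) {
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop_data("refusing to export an empty matrix: ", path)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_data("matrix must carry row and column labels: ", path)
  }
  sm <- Matrix::Matrix(m, sparse = TRUE)
  sm <- methods::as(methods::as(methods::as(sm, "dMatrix"), "CsparseMatrix"),
                    "generalMatrix")
  Matrix::writeMM(sm, path)
  writeLines(rownames(m), paste0(path, ".rows"))
  writeLines(colnames(m), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname export_matrix
#' @return `import_matrix`: the `dgCMatrix` with labels restored.
#' @export
import_matrix <- function(path) {
  m <- methods::as(methods::as(Matrix::readMM(path), "dMatrix"),
                   "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(path, ".rows")),
                      readLines(paste0(path, ".cols")))
  m
}

#' Export a bipartite relation as TSV, SIF or GraphML
#'
#' Node partitions are preserved: TSV carries `from_type` / `to_type`
#' columns (and round-trips losslessly via [import_network_tsv()]), SIF
#' uses the relation role as the interaction type, and GraphML stores a
#' `type` vertex attribute.
#'
#' @param b an [bipartite()] relation.
#' @param path output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(b, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(b, "mpa_bipartite"))
  format <- match.arg(format)
  types <- role_types(b$role)
  if (format == "tsv") {
    df <- data.frame(
      from = b$edges$from, from_type = types[1L],
      to = b$edges$to, to_type = types[2L],
      role = b$role, stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    writeLines(paste(b$edges$from, b$role, b$edges$to, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      b$edges, directed = FALSE,
      vertices = data.frame(
        name = c(b$left, b$right),
        type = c(rep(types[1L], length(b$left)),
                 rep(types[2L], length(b$right))),
        stringsAsFactors = FALSE
      )
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @return `import_network_tsv`: the relation rebuilt from its TSV export.
#' @export
import_network_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  bipartite(data.frame(from = df$from, to = df$to), role = df$role[1L])
}

role_types <- function(role) {
  switch(role,
    GP = c("gene", "phenotype"),
    GM = c("gene", "module"),
    MP = c("module", "phenotype"),
    SP = c("snp", "phenotype"),
    c("left", "right")
  )
}

#' Run the full MPA decomposition pipeline
#'
#' Orchestrates every stage: optional phenotype QC (dropping associations
#' whose phenotype fails the screen), significance selection, SNP-to-gene
#' mapping, the decomposition itself, signature classification and
#' clustering, and summary statistics.  Inputs may be in-memory data
#' frames or file paths (GFF3 / TSV), so the same entry point serves both
#' programmatic use and the command-line wrapper.
#'
#' @param associations association records data frame, or path(s) passed
#'   to [read_associations()].
#' @param genes gene model data frame, or a GFF3 path.
#' @param phenotype_matrix optional intensity matrix (or TSV path) run
#'   through [filter_metabolites()] first; associations for dropped
#'   phenotypes are removed before significance testing.
#' @param q1,q2,sig_mode,alpha passed to [hierarchical_filter()].
#' @param mad_k,min_valid passed to [filter_metabolites()].
#' @param method module construction route (`"exact"` or `"mcl"`).
#' @param include_spa include single-phenotype genes in the decomposition.
#' @param out_dir optional output directory; when given, all matrices,
#'   relations and tables are written there along with `report.json`.
#' @return List with all intermediate objects (`records`, `map`, `M`,
#'   `gp`, `modules`, `gm`, `mp`, `classes`, `clusters`, `cluster_summary`,
#'   `beta_signs`, `qc`) and `report`, a list of run counts and the
#'   decomposition-identity verdict.
#' @export
run_pipeline <- function(associations, genes, phenotype_matrix = NULL,
                         q1 = 0.1, q2 = 7.9e-6,
                         sig_mode = c("hierarchical", "flat", "fixed"),
                         alpha = NULL, mad_k = 5, min_valid = 100,
                         method = c("exact", "mcl"), include_spa = FALSE,
                         out_dir = NULL) {
  sig_mode <- match.arg(sig_mode)
  method <- match.arg(method)
  if (is.character(genes)) genes <- read_gene_models(genes)
  if (is.character(associations)) associations <- read_associations(associations)
  qc <- NULL
  if (!is.null(phenotype_matrix)) {
    if (is.character(phenotype_matrix)) {
      phenotype_matrix <- read_phenotype_matrix(phenotype_matrix)
    }
    qc <- filter_metabolites(phenotype_matrix, k = mad_k, min_valid = min_valid)
    kept <- qc$report$phenotype_id[qc$report$kept]
    associations <- associations[associations$phenotype_id %in% kept, ,
                                 drop = FALSE]
    if (nrow(associations) == 0L) {
      stop_data("phenotype QC removed every association")
    }
  }
  records <- hierarchical_filter(associations, q1 = q1, q2 = q2,
                                 mode = sig_mode, alpha = alpha)
  map <- map_snps_to_genes(records[records$significant, , drop = FALSE], genes)
  dec <- mpa_decompose(records, map, include_spa = include_spa, method = method)
  classes <- classify_genes(dec$gm, dec$mp)
  clusters <- cluster_signatures(dec$gm, method = method)
  cluster_summary <- summarize_clusters(clusters, dec$gm, dec$mp)
  beta_signs <- beta_sign_summary(records, classes, map)
  size_hist <- stats::setNames(as.list(cluster_summary$n_clusters),
                               cluster_summary$size)
  report <- list(
    n_records = nrow(associations),
    n_significant = sum(records$significant),
    n_snps_in_matrix = nrow(dec$M),
    n_phenotypes_hit = ncol(dec$M),
    n_genes_hit = length(unique(map$gene_id[map$snp_id %in% rownames(dec$M)])),
    n_mpa_genes = length(dec$mpa_genes),
    n_modules = length(dec$modules$module_id),
    n_clusters = length(unique(clusters$cluster_id)),
    class_counts = as.list(table(classes$class)),
    n_complex = sum(classes$complex),
    cluster_size_histogram = size_hist,
    decomposition_identity = dec$identity$ok,
    parameters = list(q1 = q1, q2 = q2, sig_mode = sig_mode, alpha = alpha,
                      mad_k = mad_k, min_valid = min_valid, method = method,
                      include_spa = include_spa)
  )
  result <- list(
    records = records, map = map, M = dec$M, gp = dec$gp,
    modules = dec$modules, gm = dec$gm, mp = dec$mp,
    mpa_genes = dec$mpa_genes, classes = classes, clusters = clusters,
    cluster_summary = cluster_summary, beta_signs = beta_signs,
    qc = qc, report = report
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  export_matrix(result$M, file.path(out_dir, "M.mtx"))
  export_network(result$gp, file.path(out_dir, "GP.tsv"))
  export_network(result$gm, file.path(out_dir, "GM.tsv"))
  export_network(result$mp, file.path(out_dir, "MP.tsv"))
  w(module_members(result$modules), "modules.tsv")
  w(result$classes, "classes.tsv")
  w(result$clusters, "clusters.tsv")
  w(result$cluster_summary, "cluster_summary.tsv")
  w(result$beta_signs, "beta_signs.tsv")
  sig <- result$records
  attr(sig, "q1") <- attr(sig, "q2") <- attr(sig, "mode") <- NULL
  w(sig, "significance.tsv")
  if (!is.null(result$qc)) {
    write_outlier_report(result$qc$report, file.path(out_dir, "qc_report.tsv"))
  }
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
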