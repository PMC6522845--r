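#' Read gene models from a GFF3 annotation
#'
#' Parses features of type `gene` from a GFF3 file.  The gene span in the
#' annotation already includes UTRs, so child features (mRNA, exon, UTR,
#' CDS) are ignored.  Coordinates are taken verbatim: GFF3 is 1-based with
#' inclusive ends, the same convention VCF uses for SNP positions.
#'
#' @param path path to a GFF3 file (plain text; `#` lines are comments).
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, one row per gene, in file order.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c(
#'   "##gff-version 3",
#'   "Chr01\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1"
#' ), gff)
#' read_gene_models(gff)
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  rows <- which(keep)
  out <- vector("list", length(rows))
  n <- 0L
  for (ln in rows) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop_data("malformed GFF3 line ", ln, ": expected 9 tab-separated columns, got ",
                length(fields))
    }
    if (fields[3L] != "gene") next
    start <- suppressWarnings(as.integer(fields[4L]))
    end <- suppressWarnings(as.integer(fields[5L]))
    if (is.na(start) || is.na(end)) {
      stop_data("malformed GFF3 line ", ln, ": non-integer coordinates")
    }
    if (start > end) {
      stop_data("malformed GFF3 line ", ln, ": start > end")
    }
    strand <- fields[7L]
    if (!strand %in% c("+", "-", ".")) {
      stop_data("malformed GFF3 line ", ln, ": bad strand '", strand, "'")
    }
    attrs <- strsplit(fields[9L], ";", fixed = TRUE)[[1L]]
    id <- sub("^ID=", "", attrs[startsWith(attrs, "ID=")])
    if (length(id) != 1L || !nzchar(id)) {
      stop_data("malformed GFF3 line ", ln, ": gene feature without an ID attribute")
    }
    n <- n + 1L
    out[[n]] <- data.frame(
      gene_id = id, chrom = fields[1L], start = start, end = end,
      strand = strand, stringsAsFactors = FALSE
    )
  }
  genes <- if (n) do.call(rbind, out[seq_len(n)]) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) {
    stop_data("duplicate gene id(s) in annotation: ", paste(unique(dup), collapse = ", "))
  }
  rownames(genes) <- NULL
  genes
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]; round-trips all fields.
#'
#' @param genes data frame as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tmpadecomp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Accepts either a long-format table with a header naming at least
#' `snp_id`, `p_value` and `beta` (tab- or comma-separated; `chrom`, `pos`
#' and `phenotype_id` columns used when present), or a header-less
#' EMMAX-style `.ps` triplet `snp_id  beta  p_value` with one file per
#' phenotype.  The phenotype id is resolved in the order: explicit
#' `phenotype_id` argument, then a `phenotype_id` column, then the file
#' name stem.  When `chrom`/`pos` are absent they are recovered from SNP
#' ids following the `chrom_pos` convention.
#'
#' @param paths character vector of input files.
#' @param phenotype_id optional explicit phenotype id(s); either length 1
#'   or one per file.
#' @param format `"auto"` (default), `"long"` or `"ps"`.
#' @param col_map named character vector remapping long-format column
#'   names, e.g. `c(snp_id = "SNP", p_value = "P", beta = "BETA")`.
#' @return Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `phenotype_id`, `p_value`, `beta`.  Rows with non-numeric p or beta
#'   are dropped with a warning; a p-value outside (0, 1] is an error
#'   naming the offending row.
#' @export
read_associations <- function(paths, phenotype_id = NULL,
                              format = c("auto", "long", "ps"),
                              col_map = NULL) {
  format <- match.arg(format)
  if (!is.null(phenotype_id) && !length(phenotype_id) %in% c(1L, length(paths))) {
    stop_data("phenotype_id must have length 1 or one entry per file")
  }
  res <- lapply(seq_along(paths), function(k) {
    pid <- if (is.null(phenotype_id)) NULL else
      phenotype_id[[if (length(phenotype_id) == 1L) 1L else k]]
    read_assoc_one(paths[[k]], pid, format, col_map)
  })
  out <- do.call(rbind, res)
  dup <- duplicated(out[c("snp_id", "phenotype_id")])
  if (any(dup)) {
    stop_data("duplicate (snp_id, phenotype_id) records, first at row ", which(dup)[1L])
  }
  rownames(out) <- NULL
  out
}

read_assoc_one <- function(path, phenotype_id, format, col_map) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE) && !grepl("\t", first, fixed = TRUE)) "," else "\t"
  header_fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  p_name <- if (!is.null(col_map) && "p_value" %in% names(col_map)) {
    col_map[["p_value"]]
  } else {
    "p_value"
  }
  if (format == "auto") {
    format <- if (p_name %in% header_fields) "long" else "ps"
  }
  if (format == "long") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character")
    nm <- c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
            phenotype_id = "phenotype_id", p_value = "p_value", beta = "beta")
    if (!is.null(col_map)) nm[names(col_map)] <- col_map
    for (req in c("snp_id", "p_value", "beta")) {
      if (!nm[[req]] %in% names(tab)) {
        stop_data("missing required column '", nm[[req]], "' in ", path)
      }
    }
    rec <- data.frame(
      snp_id = tab[[nm[["snp_id"]]]],
      chrom = if (nm[["chrom"]] %in% names(tab)) tab[[nm[["chrom"]]]] else NA_character_,
      pos = if (nm[["pos"]] %in% names(tab)) suppressWarnings(as.integer(tab[[nm[["pos"]]]])) else NA_integer_,
      phenotype_id = if (!is.null(phenotype_id)) as.character(phenotype_id)
        else if (nm[["phenotype_id"]] %in% names(tab)) tab[[nm[["phenotype_id"]]]]
        else tools::file_path_sans_ext(basename(path)),
      p_value = suppressWarnings(as.numeric(tab[[nm[["p_value"]]]])),
      beta = suppressWarnings(as.numeric(tab[[nm[["beta"]]]])),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) != 3L) {
      stop_data("EMMAX-style .ps file ", path, " must have 3 columns, found ", ncol(tab))
    }
    rec <- data.frame(
      snp_id = tab[[1L]],
      chrom = NA_character_,
      pos = NA_integer_,
      phenotype_id = as.character(phenotype_id %||%
                                    tools::file_path_sans_ext(basename(path))),
      p_value = suppressWarnings(as.numeric(tab[[3L]])),
      beta = suppressWarnings(as.numeric(tab[[2L]])),
      stringsAsFactors = FALSE
    )
  }
  bad <- is.na(rec$p_value) | is.na(rec$beta)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-numeric p or beta dropped from ", path)
    rec <- rec[!bad, , drop = FALSE]
  }
  oob <- which(rec$p_value <= 0 | rec$p_value > 1)
  if (length(oob)) {
    stop_data("p-value outside (0, 1] at row ", oob[1L], " of ", path,
              " (snp ", rec$snp_id[oob[1L]], ")")
  }
  # Recover chrom/pos from the chrom_pos id convention where absent.
  miss <- is.na(rec$chrom) | is.na(rec$pos)
  if (any(miss)) {
    parts <- regmatches(rec$snp_id[miss], regexpr("_[0-9]+$", rec$snp_id[miss]))
    ok <- lengths(regmatches(rec$snp_id[miss], gregexpr("_[0-9]+$", rec$snp_id[miss]))) == 1L
    if (!all(ok)) {
      stop_data("cannot recover chrom/pos from snp id '",
                rec$snp_id[miss][!ok][1L], "' in ", path)
    }
    rec$pos[miss] <- as.integer(sub("^_", "", parts))
    rec$chrom[miss] <- substr(rec$snp_id[miss], 1L,
                              nchar(rec$snp_id[miss]) - nchar(parts))
  }
  rownames(rec) <- NULL
  rec
}

#' Map SNPs into the gene regions they reside in
#'
#' A SNP maps to a gene when its position lies within the gene span
#' (1-based, inclusive on both ends) on the same chromosome; strand is
#' ignored.  A SNP covered by k overlapping genes yields k pairs; SNPs
#' residing in no gene are absent from the map.
#'
#' @param records association records ([read_associations()]) or any data
#'   frame with `snp_id`, `chrom`, `pos`.
#' @param genes gene models ([read_gene_models()]).
#' @return Data frame `snp_id`, `gene_id`, one row per (SNP, gene) pair,
#'   deterministically ordered.
#' @export
map_snps_to_genes <- function(records, genes) {
  snps <- unique(records[c("snp_id", "chrom", "pos")])
  if (nrow(snps) == 0L || nrow(genes) == 0L) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  gr_snp <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L)
  )
  gr_gene <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end)
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_snp, gr_gene, ignore.strand = TRUE)
  )
  map <- data.frame(
    snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  map <- unique(map)
  map <- map[order_c(map$snp_id, map$gene_id), , drop = FALSE]
  rownames(map) <- NULL
  map
}
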