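# Fixture builders and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two genes, each with two SNPs: one SNP associated with gentisic
# acid-2-O-glucoside, the other with cis-3-O-caffeoyl-quinate -- the
# worked Type 2 signature-cluster topology.
fig12_fixture <- function() {
  genes <- data.frame(
    gene_id = c("Potri.012G132600", "Potri.016G125500"),
    chrom = c("Chr12", "Chr16"),
    start = c(100L, 100L), end = c(5000L, 5000L), strand = "+",
    stringsAsFactors = FALSE
  )
  records <- data.frame(
    snp_id = c("Chr12_500", "Chr12_1500", "Chr16_700", "Chr16_2400"),
    chrom = c("Chr12", "Chr12", "Chr16", "Chr16"),
    pos = c(500L, 1500L, 700L, 2400L),
    phenotype_id = c("gentisic_acid_2_O_glucoside", "cis_3_O_caffeoyl_quinate",
                     "gentisic_acid_2_O_glucoside", "cis_3_O_caffeoyl_quinate"),
    p_value = 1e-15, beta = -0.4, significant = TRUE,
    stringsAsFactors = FALSE
  )
  list(genes = genes, records = records,
       map = map_snps_to_genes(records, genes))
}

# One Type 1 gene (a single SNP associated with two phenotypes) and one
# Type 2 gene (two SNPs, each with a different single association).
fig10_fixture <- function() {
  genes <- data.frame(
    gene_id = c("Potri.013G092400", "Potri.001G419800"),
    chrom = c("Chr13", "Chr01"),
    start = c(100L, 100L), end = c(4000L, 4000L), strand = "+",
    stringsAsFactors = FALSE
  )
  records <- data.frame(
    snp_id = c("Chr13_800", "Chr13_800", "Chr01_900", "Chr01_2100"),
    chrom = c("Chr13", "Chr13", "Chr01", "Chr01"),
    pos = c(800L, 800L, 900L, 2100L),
    phenotype_id = c("P1", "P2", "P1", "P2"),
    p_value = 1e-15, beta = -0.4, significant = TRUE,
    stringsAsFactors = FALSE
  )
  list(genes = genes, records = records,
       map = map_snps_to_genes(records, genes))
}

# Quadratic brute-force interval oracle for SNP-to-gene mapping.
brute_force_map <- function(records, genes) {
  snps <- unique(records[c("snp_id", "chrom", "pos")])
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes))) {
      if (snps$chrom[i] == genes$chrom[j] &&
          genes$start[j] <= snps$pos[i] && snps$pos[i] <= genes$end[j]) {
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = snps$snp_id[i], gene_id = genes$gene_id[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(snp_id = character(0), gene_id = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$snp_id, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independent BH reference through stats::p.adjust.
ref_bh <- function(p, q) stats::p.adjust(p, method = "BH") <= q

# Random binary profile matrix with no all-zero rows.
random_profile_matrix <- function(n_snps, n_phen, density = 0.3) {
  repeat {
    m <- matrix(as.numeric(stats::runif(n_snps * n_phen) < density),
                n_snps, n_phen,
                dimnames = list(sprintf("s%03d", seq_len(n_snps)),
                                sprintf("P%02d", seq_len(n_phen))))
    if (all(rowSums(m) >= 1)) {
      return(Matrix::Matrix(m, sparse = TRUE))
    }
  }
}

# All-pairs PS oracle from the scalar definition.
brute_force_ps_edges <- function(M) {
  M <- as.matrix(M)
  ids <- rownames(M)
  rows <- list()
  for (i in seq_len(nrow(M) - 1L)) {
    for (j in (i + 1L):nrow(M)) {
      w <- proportional_similarity(M[i, ], M[j, ])
      if (w > 0) {
        a <- sort(c(ids[i], ids[j]), method = "radix")
        rows[[length(rows) + 1L]] <- data.frame(
          snp_a = a[1L], snp_b = a[2L], weight = w, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$snp_a, out$snp_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical form of a partition for label-free comparison.
partition_key <- function(membership) {
  groups <- split(names(membership), membership)
  groups <- lapply(groups, sort, method = "radix")
  unname(sort(vapply(groups, paste, character(1), collapse = ","),
              method = "radix"))
}

write_gff3_fixture <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}
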