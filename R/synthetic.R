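#' Generate a planted-signature truth specification
#'
#' Lays out synthetic gene models on chromosomes and assigns each gene a
#' planted MPA signature: a set of distinct phenotype subsets, each
#' realised by one or more SNPs placed inside the gene span.  Signature
#' classes follow the supplied mixture: `spa` (one subset of size 1),
#' `type1` (one subset of size >= 2), `type2` (>= 2 singleton subsets) and
#' `complex` (>= 2 subsets, at least one of size >= 2).  Null SNPs with no
#' planted association are added inside genes and in intergenic gaps.
#'
#' @param n_genes number of genes.
#' @param n_phenotypes size of the phenotype universe.
#' @param mix named numeric vector of class proportions over
#'   `c("spa", "type1", "type2", "complex")`; must sum to 1.
#' @param snps_per_subset integer vector of candidate SNP counts per
#'   planted subset (sampled uniformly); SNP multiplicity within a module
#'   stands in for LD between nearby variants.
#' @param n_null_snps number of null SNPs (default `n_genes`), half placed
#'   inside genes, half intergenic.
#' @param beta_sign_bias probability that an effect size is negative
#'   (default 0.8, mirroring the predominance of minor alleles that lower
#'   metabolite intensities).
#' @param p_floor planted p-values are drawn from Uniform(0, `p_floor`)
#'   (default 1e-12, safely below the within-family selection level).
#' @param seed optional integer seed; fixed seed gives an identical truth.
#' @return An object of class `mpa_truth`: list with `genes` (gene model
#'   data frame), `signatures` (per gene: class and list of phenotype
#'   subsets), `snps` (planted SNP table: `snp_id`, `chrom`, `pos`,
#'   `gene_id`, `subset_idx`), `null_snps`, `phenotypes`, and the
#'   generator parameters.
#' @export
generate_truth <- function(n_genes = 200, n_phenotypes = 40,
                           mix = c(spa = 0.25, type1 = 0.25,
                                   type2 = 0.25, complex = 0.25),
                           snps_per_subset = 1:3,
                           n_null_snps = n_genes,
                           beta_sign_bias = 0.8,
                           p_floor = 1e-12,
                           seed = NULL) {
  stopifnot(n_genes >= 1, n_phenotypes >= 1)
  mix <- mix[c("spa", "type1", "type2", "complex")]
  if (anyNA(mix) || abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
    stop_data("mix must be nonnegative proportions over spa/type1/type2/complex summing to 1")
  }
  if ((mix[["type1"]] > 0 || mix[["complex"]] > 0) && n_phenotypes < 2) {
    stop_data("type1/complex signatures need n_phenotypes >= 2")
  }
  if ((mix[["type2"]] > 0 || mix[["complex"]] > 0) && n_phenotypes < 2) {
    stop_data("type2/complex signatures need n_phenotypes >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  phenotypes <- seq_ids("P", n_phenotypes)

  # Gene layout: 50 genes per chromosome, 2 kb genes separated by 1 kb gaps.
  gene_len <- 2000L
  gap <- 1000L
  chrom_of <- sprintf("Chr%02d", (seq_len(n_genes) - 1L) %/% 50L + 1L)
  idx_on_chrom <- (seq_len(n_genes) - 1L) %% 50L
  start <- 1L + idx_on_chrom * (gene_len + gap)
  genes <- data.frame(
    gene_id = seq_ids("GENE", n_genes),
    chrom = chrom_of,
    start = start,
    end = start + gene_len - 1L,
    strand = rep(c("+", "-"), length.out = n_genes),
    stringsAsFactors = FALSE
  )

  classes <- sample(names(mix), n_genes, replace = TRUE, prob = mix)
  signatures <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    signatures[[i]] <- plant_signature(classes[i], phenotypes)
  }
  names(signatures) <- genes$gene_id

  # Planted SNPs: distinct random positions inside the gene span.
  snp_rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    subsets <- signatures[[i]]
    counts <- sample(snps_per_subset, length(subsets), replace = TRUE)
    total <- sum(counts)
    pos <- sort(sample(genes$start[i]:genes$end[i], total))
    snp_rows[[i]] <- data.frame(
      snp_id = paste0(genes$chrom[i], "_", pos),
      chrom = genes$chrom[i],
      pos = pos,
      gene_id = genes$gene_id[i],
      subset_idx = rep(seq_along(subsets), counts),
      stringsAsFactors = FALSE
    )
  }
  snps <- do.call(rbind, snp_rows)
  rownames(snps) <- NULL

  # Null SNPs: half inside random genes, half in intergenic gaps.
  null_snps <- make_null_snps(genes, snps, n_null_snps, gene_len, gap)

  structure(
    list(
      genes = genes,
      classes = stats::setNames(classes, genes$gene_id),
      signatures = signatures,
      snps = snps,
      null_snps = null_snps,
      phenotypes = phenotypes,
      beta_sign_bias = beta_sign_bias,
      p_floor = p_floor,
      seed = seed
    ),
    class = "mpa_truth"
  )
}

# One planted signature: a list of distinct phenotype subsets obeying the
# class definition.
plant_signature <- function(class, phenotypes) {
  pick <- function(k) sort_c(sample(phenotypes, k))
  n_p <- length(phenotypes)
  repeat {
    subsets <- switch(class,
      spa = list(pick(1L)),
      type1 = list(pick(sample(2:min(3L, n_p), 1L))),
      type2 = {
        n_sub <- sample(2:3, 1L)
        singles <- sample(phenotypes, n_sub)
        lapply(singles, identity)
      },
      complex = {
        n_sub <- sample(2:3, 1L)
        sizes <- c(sample(2:min(3L, n_p), 1L),
                   sample(1:2, n_sub - 1L, replace = TRUE))
        lapply(sizes, pick)
      },
      stop_data("unknown signature class '", class, "'")
    )
    keys <- vapply(subsets, paste, character(1), collapse = "|")
    if (!anyDuplicated(keys)) {
      return(subsets)
    }
  }
}

make_null_snps <- function(genes, planted, n_null_snps, gene_len, gap) {
  if (n_null_snps == 0L) {
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  }
  n_in <- n_null_snps %/% 2L
  n_out <- n_null_snps - n_in
  rows <- list()
  if (n_in > 0L) {
    gi <- sample(nrow(genes), n_in, replace = TRUE)
    pos <- genes$start[gi] + vapply(gi, function(i)
      sample.int(gene_len, 1L) - 1L, integer(1))
    rows$inside <- data.frame(chrom = genes$chrom[gi], pos = pos,
                              stringsAsFactors = FALSE)
  }
  if (n_out > 0L) {
    gi <- sample(nrow(genes), n_out, replace = TRUE)
    pos <- genes$end[gi] + vapply(seq_len(n_out), function(i)
      sample.int(gap, 1L), integer(1))
    rows$outside <- data.frame(chrom = genes$chrom[gi], pos = pos,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$snp_id <- paste0(out$chrom, "_", out$pos)
  out <- out[!out$snp_id %in% planted$snp_id, c("snp_id", "chrom", "pos")]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Emit GWAS summary statistics (and gene models) from a truth spec
#'
#' Every SNP (planted and null) is tested against every phenotype.
#' Planted pairs draw p from Uniform(0, `p_floor`); all other pairs draw p
#' from Uniform(0, 1).  Effect sizes are |N(0, 1)| with sign forced
#' negative with probability `beta_sign_bias`.  When `dir` is given the
#' records and a matching GFF3 are also written to disk so the full
#' ingest path can be exercised.
#'
#' @param truth an `mpa_truth` object.
#' @param dir optional output directory; writes `associations.tsv` and
#'   `genes.gff3`.
#' @param seed optional integer seed for the p-value / beta draws.
#' @return List with `records` (association data frame) and `genes`; when
#'   `dir` is given, also `paths`.
#' @export
emit_associations <- function(truth, dir = NULL, seed = NULL) {
  stopifnot(inherits(truth, "mpa_truth"))
  if (!is.null(seed)) set.seed(seed)
  all_snps <- unique(rbind(truth$snps[c("snp_id", "chrom", "pos")],
                           truth$null_snps))
  n_s <- nrow(all_snps)
  n_p <- length(truth$phenotypes)
  rec <- data.frame(
    snp_id = rep(all_snps$snp_id, each = n_p),
    chrom = rep(all_snps$chrom, each = n_p),
    pos = rep(all_snps$pos, each = n_p),
    phenotype_id = rep(truth$phenotypes, times = n_s),
    stringsAsFactors = FALSE
  )
  rec$p_value <- stats::runif(nrow(rec))
  # Planted pairs: SNP x each phenotype of its subset.
  planted_pairs <- do.call(rbind, lapply(seq_len(nrow(truth$snps)), function(i) {
    subset <- truth$signatures[[truth$snps$gene_id[i]]][[truth$snps$subset_idx[i]]]
    data.frame(snp_id = truth$snps$snp_id[i], phenotype_id = subset,
               stringsAsFactors = FALSE)
  }))
  planted_pairs <- unique(planted_pairs)
  key <- paste(rec$snp_id, rec$phenotype_id, sep = "\r")
  hit <- key %in% paste(planted_pairs$snp_id, planted_pairs$phenotype_id,
                        sep = "\r")
  rec$p_value[hit] <- stats::runif(sum(hit), 0, truth$p_floor)
  sign <- ifelse(stats::runif(nrow(rec)) < truth$beta_sign_bias, -1, 1)
  rec$beta <- sign * abs(stats::rnorm(nrow(rec)))
  rec <- rec[order_c(rec$snp_id, rec$phenotype_id), , drop = FALSE]
  rownames(rec) <- NULL
  out <- list(records = rec, genes = truth$genes)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    assoc_path <- file.path(dir, "associations.tsv")
    gff_path <- file.path(dir, "genes.gff3")
    utils::write.table(rec, assoc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_gene_models(truth$genes, gff_path)
    out$paths <- c(associations = assoc_path, genes = gff_path)
  }
  out
}

#' Emit a phenotype intensity matrix with planted outliers
#'
#' Baseline intensities per metabolite are log-normal with a truncated
#' tail (log-scale z restricted to |z| <= 1.8), so that clean values sit
#' within 5 raw asymmetric MADs of the median by construction.
#' Optionally a fraction of entries is set to zero (metabolite not
#' detected; default 0) -- zeros sit roughly 4 lower-tail MADs below the
#' median, close enough to the cut-off that they are only generated when
#' the under-representation rule itself is under study.  Planted outliers
#' displace the recorded cell to
#' `median + outlier_magnitude * upper_mad` of its column; the upper tail
#' is used because intensities are nonnegative and the lower tail has no
#' room for a 5-MAD displacement.
#'
#' @param truth an `mpa_truth` object (supplies the phenotype ids).
#' @param n_genotypes number of genotype rows (default 200).
#' @param outlier_fraction fraction of cells displaced (default 0.01).
#' @param outlier_magnitude displacement in raw upper-MAD units; must
#'   exceed the intended flagging cut-off `k` (default 8).
#' @param zero_fraction fraction of cells set to zero (default 0).
#' @param seed optional integer seed.
#' @return Numeric matrix (genotypes x phenotypes) with the planted cells
#'   recorded in `attr(, "outliers")` (`genotype_id`, `phenotype_id`,
#'   `row`, `col`, `value`).
#' @export
emit_phenotypes <- function(truth, n_genotypes = 200,
                            outlier_fraction = 0.01, outlier_magnitude = 8,
                            zero_fraction = 0, seed = NULL) {
  stopifnot(inherits(truth, "mpa_truth"))
  if (outlier_magnitude <= 5) {
    stop_data("outlier_magnitude must exceed the flagging cut-off (5)")
  }
  if (!is.null(seed)) set.seed(seed)
  n_p <- length(truth$phenotypes)
  meanlog <- stats::runif(n_p, 2, 4)
  sdlog <- 0.4
  z <- matrix(stats::rnorm(n_genotypes * n_p), n_genotypes, n_p)
  z <- pmin(pmax(z, -1.8), 1.8) # truncate tails: clean values stay < 5 MADs out
  mat <- exp(sweep(z * sdlog, 2, meanlog, "+"))
  mat[matrix(stats::runif(length(mat)) < zero_fraction,
             n_genotypes, n_p)] <- 0
  dimnames(mat) <- list(seq_ids("GT", n_genotypes), truth$phenotypes)
  n_out <- round(outlier_fraction * length(mat))
  planted <- data.frame(genotype_id = character(0), phenotype_id = character(0),
                        row = integer(0), col = integer(0), value = numeric(0),
                        stringsAsFactors = FALSE)
  if (n_out > 0L) {
    cells <- sample(length(mat), n_out)
    rows <- (cells - 1L) %% n_genotypes + 1L
    cols <- (cells - 1L) %/% n_genotypes + 1L
    vals <- numeric(n_out)
    for (k in seq_len(n_out)) {
      m <- asymmetric_mad(mat[, cols[k]])
      vals[k] <- m$median + outlier_magnitude * m$upper_mad
      mat[rows[k], cols[k]] <- vals[k]
    }
    planted <- data.frame(
      genotype_id = rownames(mat)[rows],
      phenotype_id = colnames(mat)[cols],
      row = rows, col = cols, value = vals,
      stringsAsFactors = FALSE
    )
  }
  attr(mat, "outliers") <- planted
  mat
}

#' Score recovery of planted signatures from a pipeline run
#'
#' Compares the planted truth with a decomposition result: per-gene module
#' phenotype-subset equality, the signature-class confusion matrix, and
#' the Rand index between the planted and the recovered signature-cluster
#' partitions.  A gene absent from GM is recovered as `"SPA"` (the default
#' decomposition excludes single-phenotype genes).
#'
#' @param truth an `mpa_truth` object.
#' @param result list with `gm`, `mp` and (optionally) `clusters`,
#'   `classes` -- e.g. the output of [mpa_decompose()] plus
#'   [cluster_signatures()] / [classify_genes()], or of [run_pipeline()].
#' @return List with `gene_table` (per gene: planted vs recovered subset
#'   sets and an `exact` flag), `class_confusion` (planted x recovered),
#'   `rand_index` (over genes present in the recovered clustering; `NA`
#'   when no clustering was supplied) and `all_exact`.
#' @export
score_recovery <- function(truth, result) {
  stopifnot(inherits(truth, "mpa_truth"))
  gm <- result$gm
  mp <- result$mp
  if (is.null(gm) || is.null(mp)) stop_data("result must contain gm and mp")
  if (!all(gm$left %in% truth$genes$gene_id)) {
    stop_data("recovered GM contains genes absent from the truth spec")
  }
  gm_nb <- neighbors_of(gm)
  mp_nb <- neighbors_of(mp)
  subset_key <- function(sets) {
    paste(sort_c(vapply(sets, paste, character(1), collapse = "|")),
          collapse = " ; ")
  }
  planted_keys <- vapply(truth$signatures, subset_key, character(1))
  recovered_keys <- vapply(truth$genes$gene_id, function(g) {
    if (!g %in% gm$left) {
      return(NA_character_)
    }
    subset_key(mp_nb[gm_nb[[g]]])
  }, character(1))
  planted_class <- truth$classes
  planted_is_spa <- planted_class == "spa"
  exact <- ifelse(
    is.na(recovered_keys), planted_is_spa,
    recovered_keys == planted_keys
  )
  gene_table <- data.frame(
    gene_id = truth$genes$gene_id,
    planted_class = unname(planted_class),
    planted_signature = unname(planted_keys),
    recovered_signature = unname(recovered_keys),
    exact = unname(exact),
    stringsAsFactors = FALSE
  )
  # Class confusion: planted class vs recovered class.
  expected <- c(spa = "SPA", type1 = "TYPE1", type2 = "TYPE2",
                complex = "TYPE2")[planted_class]
  recovered_class <- rep("SPA", nrow(truth$genes))
  names(recovered_class) <- truth$genes$gene_id
  if (!is.null(result$classes)) {
    cc <- result$classes
    recovered_class[cc$gene_id] <- cc$class
  } else {
    cc <- classify_genes(gm, mp)
    recovered_class[cc$gene_id] <- cc$class
  }
  confusion <- table(planted = expected, recovered = recovered_class)
  ri <- NA_real_
  if (!is.null(result$clusters)) {
    rec_part <- stats::setNames(result$clusters$cluster_id,
                                result$clusters$gene_id)
    planted_part <- planted_keys[names(rec_part)]
    ri <- rand_index(planted_part, rec_part)
  }
  list(
    gene_table = gene_table,
    class_confusion = confusion,
    rand_index = ri,
    all_exact = all(gene_table$exact)
  )
}
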