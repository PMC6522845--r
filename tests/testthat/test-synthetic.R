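test_that("truth generation is reproducible and honours the class mix", {
  t1 <- generate_truth(n_genes = 30, n_phenotypes = 8, seed = 51)
  t2 <- generate_truth(n_genes = 30, n_phenotypes = 8, seed = 51)
  expect_identical(t1, t2)

  all_t1 <- generate_truth(
    n_genes = 10, n_phenotypes = 6,
    mix = c(spa = 0, type1 = 1, type2 = 0, complex = 0), seed = 52
  )
  expect_true(all(all_t1$classes == "type1"))
  expect_true(all(vapply(all_t1$signatures, function(s)
    length(s) == 1L && length(s[[1L]]) >= 2L, logical(1))))

  expect_error(
    generate_truth(n_genes = 5, n_phenotypes = 1,
                   mix = c(spa = 0, type1 = 1, type2 = 0, complex = 0)),
    "n_phenotypes"
  )
  expect_error(
    generate_truth(n_genes = 5, n_phenotypes = 8,
                   mix = c(spa = 0.5, type1 = 0.2, type2 = 0.2, complex = 0.2)),
    "summing to 1"
  )
})

test_that("class counts fall within multinomial bounds at n = 400", {
  truth <- generate_truth(n_genes = 400, n_phenotypes = 10, seed = 53)
  counts <- table(factor(truth$classes,
                         levels = c("spa", "type1", "type2", "complex")))
  half_width <- stats::qnorm(0.995) * sqrt(400 * 0.25 * 0.75)
  expect_true(all(abs(counts - 100) <= half_width))
})

test_that("planted signatures obey their class definitions", {
  truth <- generate_truth(n_genes = 120, n_phenotypes = 12, seed = 54)
  for (g in truth$genes$gene_id) {
    subsets <- truth$signatures[[g]]
    keys <- vapply(subsets, paste, character(1), collapse = "|")
    expect_false(anyDuplicated(keys) > 0)
    switch(truth$classes[[g]],
      spa = {
        expect_equal(length(subsets), 1L)
        expect_equal(length(subsets[[1L]]), 1L)
      },
      type1 = {
        expect_equal(length(subsets), 1L)
        expect_gte(length(subsets[[1L]]), 2L)
      },
      type2 = expect_gte(length(subsets), 2L),
      complex = {
        expect_gte(length(subsets), 2L)
        expect_true(any(lengths(subsets) >= 2L))
      }
    )
  }
  # planted SNPs sit inside their gene spans
  gi <- match(truth$snps$gene_id, truth$genes$gene_id)
  expect_true(all(truth$snps$pos >= truth$genes$start[gi] &
                    truth$snps$pos <= truth$genes$end[gi]))
})

test_that("a Type 1 truth gene emits exactly its planted significant records", {
  truth <- generate_truth(
    n_genes = 1, n_phenotypes = 4,
    mix = c(spa = 0, type1 = 1, type2 = 0, complex = 0),
    snps_per_subset = 1, n_null_snps = 0, seed = 55
  )
  sim <- emit_associations(truth, seed = 56)
  planted_phens <- truth$signatures[[1L]][[1L]]
  rec <- hierarchical_filter(sim$records)
  sig <- rec[rec$significant, ]
  expect_equal(nrow(sig), length(planted_phens))
  expect_setequal(sig$phenotype_id, planted_phens)
  expect_equal(length(unique(sig$snp_id)), 1L)
})

test_that("a null-only truth yields at most FDR-level false positives", {
  truth <- generate_truth(n_genes = 10, n_phenotypes = 10,
                          mix = c(spa = 1, type1 = 0, type2 = 0, complex = 0),
                          n_null_snps = 50, seed = 57)
  truth$snps <- truth$snps[0, ]        # suppress all planted signal
  truth$signatures <- lapply(truth$signatures, function(s) s[0])
  sim <- emit_associations(truth, seed = 58)
  rec <- hierarchical_filter(sim$records)
  expect_lte(sum(rec$significant), 2L)
})

test_that("emitted files survive the full ingest path", {
  truth <- generate_truth(n_genes = 12, n_phenotypes = 6, seed = 59)
  dir <- tempfile()
  sim <- emit_associations(truth, dir = dir, seed = 60)
  expect_true(file.exists(sim$paths[["associations"]]))
  genes_back <- read_gene_models(sim$paths[["genes"]])
  expect_identical(genes_back, truth$genes)
  rec_back <- read_associations(sim$paths[["associations"]])
  expect_equal(nrow(rec_back), nrow(sim$records))
  expect_equal(rec_back$p_value, sim$records$p_value)
})

test_that("phenotype emission plants recoverable outliers and nothing else", {
  truth <- generate_truth(n_genes = 5, n_phenotypes = 15, seed = 61)
  clean <- emit_phenotypes(truth, n_genotypes = 150, outlier_fraction = 0,
                           seed = 62)
  expect_equal(nrow(attr(clean, "outliers")), 0L)
  res_clean <- filter_metabolites(clean, k = 5, min_valid = 1)
  expect_equal(sum(res_clean$report$n_flagged), 0L)

  planted <- emit_phenotypes(truth, n_genotypes = 150, outlier_fraction = 0.01,
                             outlier_magnitude = 8, seed = 63)
  cells <- attr(planted, "outliers")
  expect_gt(nrow(cells), 0L)
  res <- filter_metabolites(planted, k = 5, min_valid = 1)
  flagged <- attr(res$report, "flagged")
  expect_setequal(
    paste(flagged$genotype_id, flagged$phenotype_id),
    paste(cells$genotype_id, cells$phenotype_id)
  )
  # determinism under a fixed seed
  again <- emit_phenotypes(truth, n_genotypes = 150, outlier_fraction = 0.01,
                           outlier_magnitude = 8, seed = 63)
  expect_identical(planted, again)
  expect_error(emit_phenotypes(truth, outlier_magnitude = 4), "exceed")
})

test_that("generated zeros are never upper-tail outliers and do not count as valid", {
  truth <- generate_truth(n_genes = 4, n_phenotypes = 8, seed = 68)
  mat <- emit_phenotypes(truth, n_genotypes = 120, outlier_fraction = 0,
                         zero_fraction = 0.1, seed = 69)
  res <- filter_metabolites(mat, k = 5, min_valid = 1)
  flagged <- attr(res$report, "flagged")
  # any flag above the median is a positive intensity: zeros cannot be
  # upper-tail outliers by construction
  med <- res$report$median[match(flagged$phenotype_id, res$report$phenotype_id)]
  expect_true(all(flagged$value[flagged$value > med] > 0))
  # zeros never count towards n_valid, flagged or not
  flag_mat <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  if (nrow(flagged)) {
    flag_mat[cbind(match(flagged$genotype_id, rownames(mat)),
                   match(flagged$phenotype_id, colnames(mat)))] <- TRUE
  }
  expect_equal(res$report$n_valid, unname(colSums(mat > 0 & !flag_mat)))
})

test_that("a perfect run scores exact recovery and a suppressed signal is flagged", {
  truth <- generate_truth(n_genes = 40, n_phenotypes = 10, seed = 64)
  sim <- emit_associations(truth, seed = 65)
  rec <- hierarchical_filter(sim$records)
  map <- map_snps_to_genes(rec[rec$significant, ], sim$genes)
  dec <- mpa_decompose(rec, map)
  dec$clusters <- cluster_signatures(dec$gm)
  dec$classes <- classify_genes(dec$gm, dec$mp)
  score <- score_recovery(truth, dec)
  expect_true(score$all_exact)
  expect_equal(score$rand_index, 1.0)
  off_diag <- score$class_confusion
  diag_names <- intersect(rownames(off_diag), colnames(off_diag))
  total_off <- sum(off_diag) - sum(off_diag[cbind(diag_names, diag_names)])
  expect_equal(total_off, 0)

  # mutation: silence one planted association of a type1 gene
  t1_genes <- names(truth$classes)[truth$classes == "type1"]
  victim <- t1_genes[1L]
  victim_snps <- truth$snps$snp_id[truth$snps$gene_id == victim]
  drop_phen <- truth$signatures[[victim]][[1L]][1L]
  rec2 <- rec
  hit <- rec2$snp_id %in% victim_snps & rec2$phenotype_id == drop_phen
  rec2$significant[hit] <- FALSE
  map2 <- map_snps_to_genes(rec2[rec2$significant, ], sim$genes)
  dec2 <- mpa_decompose(rec2, map2)
  score2 <- score_recovery(truth, dec2)
  expect_false(score2$gene_table$exact[score2$gene_table$gene_id == victim])
})

test_that("the emit-analyze-score path is deterministic under a fixed seed", {
  run_once <- function() {
    truth <- generate_truth(n_genes = 25, n_phenotypes = 8, seed = 66)
    sim <- emit_associations(truth, seed = 67)
    rec <- hierarchical_filter(sim$records)
    map <- map_snps_to_genes(rec[rec$significant, ], sim$genes)
    dec <- mpa_decompose(rec, map)
    dec$clusters <- cluster_signatures(dec$gm)
    score_recovery(truth, dec)
  }
  expect_identical(run_once(), run_once())
})
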