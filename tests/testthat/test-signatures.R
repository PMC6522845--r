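test_that("worked Type 1 / Type 2 topologies are classified correctly", {
  f <- fig10_fixture()
  dec <- mpa_decompose(f$records, f$map)
  cls <- classify_genes(dec$gm, dec$mp)
  t1 <- cls[cls$gene_id == "Potri.013G092400", ]
  t2 <- cls[cls$gene_id == "Potri.001G419800", ]
  expect_equal(t1$class, "TYPE1")
  expect_equal(t1$n_modules, 1L)
  expect_equal(t1$n_phenotypes, 2L)
  expect_equal(t2$class, "TYPE2")
  expect_false(t2$complex)
  expect_equal(t2$n_modules, 2L)
  expect_error(classify_gene("missing_gene", dec$gm, dec$mp), "absent")
})

test_that("a multi-phenotype module within a multi-module gene marks it complex", {
  genes <- data.frame(gene_id = "gC", chrom = "Chr01", start = 100L,
                      end = 900L, strand = "+", stringsAsFactors = FALSE)
  rec <- data.frame(
    snp_id = c("Chr01_200", "Chr01_200", "Chr01_700"),
    chrom = "Chr01", pos = c(200L, 200L, 700L),
    phenotype_id = c("P1", "P2", "P3"),
    p_value = 1e-12, beta = -1, significant = TRUE,
    stringsAsFactors = FALSE
  )
  dec <- mpa_decompose(rec, map_snps_to_genes(rec, genes))
  cls <- classify_gene("gC", dec$gm, dec$mp)
  expect_equal(cls$class, "TYPE2")
  expect_true(cls$complex)
  expect_equal(cls$n_modules, 2L)
  expect_equal(cls$n_phenotypes, 3L)
})

test_that("classification is total and partitions the GM gene set", {
  set.seed(41)
  truth <- generate_truth(n_genes = 60, n_phenotypes = 12, seed = 41)
  sim <- emit_associations(truth, seed = 42)
  rec <- hierarchical_filter(sim$records)
  map <- map_snps_to_genes(rec[rec$significant, ], sim$genes)
  dec <- mpa_decompose(rec, map)
  cls <- classify_genes(dec$gm, dec$mp)
  expect_setequal(cls$gene_id, dec$gm$left)
  expect_equal(sum(cls$class %in% c("SPA", "TYPE1", "TYPE2")), nrow(cls))
  expect_true(all(cls$complex[cls$class != "TYPE2"] == FALSE))
})

test_that("genes sharing a module set form one signature cluster", {
  f <- fig12_fixture()
  dec <- mpa_decompose(f$records, f$map)
  cl <- cluster_signatures(dec$gm)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_setequal(cl$gene_id, c("Potri.012G132600", "Potri.016G125500"))
  sig <- attr(cl, "signatures")[[cl$cluster_id[1]]]
  expect_equal(sort(sig), sort(dec$modules$module_id))
})

test_that("genes with distinct module sets all end up in singleton clusters", {
  f <- fig10_fixture()
  dec <- mpa_decompose(f$records, f$map)
  cl <- cluster_signatures(dec$gm)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  expect_equal(max(table(cl$cluster_id)), 1L)
})

test_that("exact and MCL signature clustering agree, members share one class", {
  set.seed(43)
  for (rep in 1:10) {
    truth <- generate_truth(n_genes = 40, n_phenotypes = 8, seed = NULL)
    sim <- emit_associations(truth)
    rec <- hierarchical_filter(sim$records)
    map <- map_snps_to_genes(rec[rec$significant, ], sim$genes)
    dec <- try(mpa_decompose(rec, map), silent = TRUE)
    if (inherits(dec, "try-error")) next
    exact <- cluster_signatures(dec$gm, method = "exact")
    mcl <- cluster_signatures(dec$gm, method = "mcl")
    expect_equal(exact, mcl)
    cls <- classify_genes(dec$gm, dec$mp)
    per_cluster <- split(cls$class[match(exact$gene_id, cls$gene_id)],
                         exact$cluster_id)
    expect_true(all(vapply(per_cluster, function(x)
      length(unique(x)) == 1L, logical(1))))
  }
})

test_that("planted signature groups are recovered as clusters", {
  # 7 distinct signatures spread over 50 genes
  set.seed(44)
  sig_defs <- list(
    list(c("P1", "P2")), list(c("P3")), list(c("P1"), c("P4")),
    list(c("P2"), c("P5")), list(c("P1", "P2"), c("P3")),
    list(c("P4"), c("P5"), c("P6")), list(c("P2", "P6"))
  )
  assign_to <- rep(seq_along(sig_defs), length.out = 50)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:50), chrom = "Chr01",
    start = seq(1L, by = 1000L, length.out = 50), strand = "+",
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + 800L
  rec <- do.call(rbind, lapply(1:50, function(i) {
    subsets <- sig_defs[[assign_to[i]]]
    do.call(rbind, lapply(seq_along(subsets), function(k) {
      pos <- genes$start[i] + 10L * k
      data.frame(snp_id = paste0("Chr01_", pos), chrom = "Chr01", pos = pos,
                 phenotype_id = subsets[[k]], p_value = 1e-12, beta = -1,
                 significant = TRUE, stringsAsFactors = FALSE)
    }))
  }))
  dec <- mpa_decompose(rec, map_snps_to_genes(rec, genes))
  cl <- cluster_signatures(dec$gm)
  # signature 2 is single-phenotype (SPA): its genes are excluded by default
  expect_equal(length(unique(cl$cluster_id)), 6L)
  expected <- split(genes$gene_id[assign_to != 2], assign_to[assign_to != 2])
  got <- split(cl$gene_id, cl$cluster_id)
  expect_setequal(
    unname(vapply(got, function(g) paste(sort(g), collapse = ","), character(1))),
    unname(vapply(expected, function(g) paste(sort(g), collapse = ","), character(1)))
  )
})

test_that("cluster summaries match hand tabulation and brute-force recomputation", {
  f <- fig12_fixture()
  dec <- mpa_decompose(f$records, f$map)
  cl <- cluster_signatures(dec$gm)
  summ <- summarize_clusters(cl, dec$gm, dec$mp)
  expect_equal(summ$size, 2L)
  expect_equal(summ$n_clusters, 1L)
  expect_equal(summ$mean_modules, 2)
  expect_equal(summ$mean_phenotypes, 2)

  # all-singleton case: histogram mass entirely at size 1
  f10 <- fig10_fixture()
  dec10 <- mpa_decompose(f10$records, f10$map)
  summ10 <- summarize_clusters(cluster_signatures(dec10$gm), dec10$gm, dec10$mp)
  expect_equal(summ10$size, 1L)
  expect_equal(summ10$n_clusters, 2L)

  # synthetic run: recompute means straight from the relations
  set.seed(45)
  truth <- generate_truth(n_genes = 50, n_phenotypes = 10, seed = 45)
  sim <- emit_associations(truth, seed = 46)
  rec <- hierarchical_filter(sim$records)
  map <- map_snps_to_genes(rec[rec$significant, ], sim$genes)
  decS <- mpa_decompose(rec, map)
  clS <- cluster_signatures(decS$gm)
  summS <- summarize_clusters(clS, decS$gm, decS$mp)
  gm_nb <- neighbors_of(decS$gm)
  mp_nb <- neighbors_of(decS$mp)
  for (i in seq_len(nrow(summS))) {
    s <- summS$size[i]
    ids <- names(which(table(clS$cluster_id) == s))
    genes_s <- clS$gene_id[clS$cluster_id %in% ids]
    expect_equal(summS$mean_modules[i],
                 mean(vapply(gm_nb[genes_s], length, integer(1))))
    expect_equal(summS$mean_phenotypes[i],
                 mean(vapply(genes_s, function(g)
                   length(unique(unlist(mp_nb[gm_nb[[g]]]))), integer(1))))
  }
})

test_that("beta signs are tallied per signature class", {
  f <- fig10_fixture()
  rec <- f$records
  rec$beta <- c(0.5, -1, -0.2, -0.3) # Type 1 gene: 1 pos 1 neg; Type 2: 2 neg
  dec <- mpa_decompose(rec, f$map)
  cls <- classify_genes(dec$gm, dec$mp)
  tab <- beta_sign_summary(rec, cls, f$map)
  expect_equal(tab$n_pos[tab$class == "TYPE1"], 1L)
  expect_equal(tab$n_neg[tab$class == "TYPE1"], 1L)
  expect_equal(tab$n_neg[tab$class == "TYPE2"], 2L)
  expect_equal(sum(tab$n_zero), 0L)

  rec$beta <- -abs(rec$beta)
  tab_neg <- beta_sign_summary(rec, cls, f$map)
  expect_equal(sum(tab_neg$n_pos), 0L)
})

test_that("the configured beta sign bias is visible in the emitted records", {
  truth <- generate_truth(n_genes = 80, n_phenotypes = 15,
                          beta_sign_bias = 0.8, seed = 47)
  sim <- emit_associations(truth, seed = 48)
  rec <- hierarchical_filter(sim$records)
  sig <- rec[rec$significant, ]
  n <- nrow(sig)
  frac_neg <- mean(sig$beta < 0)
  half_width <- stats::qnorm(0.995) * sqrt(0.8 * 0.2 / n)
  expect_gt(frac_neg, 0.8 - half_width)
  expect_lt(frac_neg, 0.8 + half_width)
})
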