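test_that("SNP adjacency windows are half-open with clamping at zero", {
  ann <- toy_annotation(c("g1", "g2"), c("lncRNA", "protein_coding"),
                        start = c(100000, 10000), end = c(120000, 12000))
  snps <- data.frame(snp_id = c("s_in", "s_out", "s_clamp"),
                     chrom = "chr1", pos = c(50000, 49999, 0),
                     disease_label = "shared")
  adj <- snp_adjacent_genes(ann, snps, window = 50000)
  expect_true("s_in" %in% adj$snps_by_gene[["g1"]])     # 50,000 inclusive
  expect_false("s_out" %in% (adj$snps_by_gene[["g1"]] %||% character(0)))
  expect_true("s_clamp" %in% adj$snps_by_gene[["g2"]])  # window clamped at 0
})

test_that("gene-window intersection equals SNP-window intersection", {
  set.seed(17)
  ann <- toy_annotation(paste0("g", 1:50), "lncRNA",
                        start = runif(50, 0, 5e6))
  snps <- data.frame(snp_id = paste0("s", 1:80), chrom = "chr1",
                     pos = floor(runif(80, 0, 5.2e6)))
  adj <- snp_adjacent_genes(ann, snps, window = 50000)
  # oracle: symmetric formulation, extend the SNP instead of the gene
  for (i in seq_len(nrow(ann))) {
    hits <- snps$snp_id[snps$pos + 50000 >= ann$start[i] &
                        snps$pos - 50000 < ann$end[i] &
                        snps$pos >= ann$start[i] - 50000]
    got <- adj$snps_by_gene[[ann$gene_id[i]]] %||% character(0)
    expect_setequal(got, hits)
  }
})

test_that("bootstrap enrichment endpoints behave", {
  set.seed(21)
  ann <- toy_annotation(paste0("g", 1:200),
                        rep(c("lncRNA", "protein_coding"), 100))
  universe <- ann$gene_id
  adjacent <- setNames(runif(200) < 0.1, universe)
  # module == universe: null draws reproduce the observed proportion
  e_all <- bootstrap_enrichment(universe, universe, adjacent, ann,
                                n_boot = 200, seed = 3)
  expect_equal(e_all$p, c(1, 1))
  # fully adjacent module vs 10% background
  adjacent2 <- adjacent
  mod <- universe[1:50]
  adjacent2[mod] <- TRUE
  e <- bootstrap_enrichment(mod, universe, adjacent2, ann,
                            n_boot = 2000, seed = 4)
  expect_true(all(e$p <= 0.001))
  expect_error(bootstrap_enrichment(c("nope"), universe, adjacent, ann),
               "subset")
})

test_that("bootstrap p decreases as planted enrichment grows", {
  set.seed(30)
  ann <- toy_annotation(paste0("g", 1:400),
                        rep(c("lncRNA", "protein_coding"), 200))
  universe <- ann$gene_id
  mod <- sample(universe, 60)
  ps <- vapply(c(0.1, 0.4, 0.8), function(rate) {
    adjacent <- setNames(runif(400) < 0.1, universe)
    adjacent[mod] <- adjacent[mod] | runif(60) < rate
    min(bootstrap_enrichment(mod, universe, adjacent, ann,
                             n_boot = 1000, seed = 5)$p)
  }, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("modules lacking one biotype get a missing p for it", {
  ann <- toy_annotation(paste0("g", 1:40),
                        rep(c("lncRNA", "protein_coding"), each = 20))
  universe <- ann$gene_id
  adjacent <- setNames(rep(c(TRUE, FALSE), 20), universe)
  e <- bootstrap_enrichment(universe[1:10], universe, adjacent, ann,
                            n_boot = 100, seed = 1)
  expect_true(is.na(e$p[e$biotype == "protein_coding"]))
})

test_that("disease-specific proportions follow the min-count rule", {
  ann <- toy_annotation(paste0("g", 1:8),
                        c(rep("lncRNA", 6), rep("protein_coding", 2)))
  asg <- structure(list(modules = setNames(
    c(rep("blue", 4), rep("brown", 2), "blue", "brown"), ann$gene_id)),
    class = "module_assignment")
  labels_by_gene <- list(
    g1 = "UC-specific", g2 = "UC-specific", g3 = c("UC-specific", "shared"),
    g4 = "CD-specific", g5 = "UC-specific", g6 = "shared")
  adjacency_map <- list(labels_by_gene = labels_by_gene)
  out <- disease_specific_proportions(asg, adjacency_map, ann, min_count = 3)
  # blue: g1,g2,g3 UC + g4 CD = 4 specific -> 0.75 / 0.25
  expect_equal(out$module, "blue")
  expect_equal(out$frac_UC, 0.75)
  expect_equal(out$frac_CD, 0.25)
  # brown has only 1 disease-specific lncRNA (g5): omitted
})

test_that("hypergeometric overlap matches the exact tail and Fisher", {
  res <- module_de_overlap(paste0("m", 1:5), c(paste0("m", 1:3), "x"),
                           universe_size = 20)
  expect_equal(res$overlap, 3)
  exact <- (choose(5, 3) * choose(15, 1) + choose(5, 4)) / choose(20, 4)
  expect_equal(res$p, exact, tolerance = 1e-12)

  set.seed(40)
  for (i in 1:50) {
    K <- sample(5:20, 1); n <- sample(5:20, 1)
    N <- K + n + sample(5:200, 1)
    ov <- sample(0:min(K, n), 1)
    de <- c(paste0("a", 1:K)[seq_len(ov)],
            if (n > ov) paste0("b", seq_len(n - ov)))
    p_hyper <- module_de_overlap(paste0("a", 1:K), de,
                                 universe_size = N)$p
    tab <- matrix(c(ov, K - ov, n - ov, N - K - n + ov), 2)
    p_fisher <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p_hyper, p_fisher, tolerance = 1e-10)
  }
})

test_that("degenerate overlaps behave at the endpoints", {
  expect_gt(module_de_overlap(paste0("a", 1:5), paste0("b", 1:5), 100)$p,
            0.99)
  same <- module_de_overlap(paste0("a", 1:5), paste0("a", 1:5), 100)
  expect_equal(same$overlap, 5)
  expect_lt(same$p, 1e-6)
})
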