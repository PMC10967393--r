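# a toy expression matrix whose modules are driven by known latent factors
latent_modules <- function(n = 80, sizes = c(20, 15), noise = 0.3,
                           seed = 50, factor_cor = 0) {
  set.seed(seed)
  f1 <- rnorm(n)
  f2 <- factor_cor * f1 + sqrt(1 - factor_cor^2) * rnorm(n)
  vals <- cbind(
    sapply(seq_len(sizes[1]), function(i) f1 + rnorm(n, 0, noise)),
    sapply(seq_len(sizes[2]), function(i) f2 + rnorm(n, 0, noise)))
  colnames(vals) <- paste0("g", seq_len(sum(sizes)))
  rownames(vals) <- sprintf("S%03d", seq_len(n))
  labels <- setNames(rep(c("blue", "brown"), sizes), colnames(vals))
  expr <- expression_matrix(vals - min(vals), "logTPM")
  asg <- structure(list(modules = labels, sizes = table(labels),
                        dendrogram = NULL), class = "module_assignment")
  list(expr = expr, assignment = asg, f1 = f1, f2 = f2)
}

test_that("a module of identical genes has eigengene = profile, varexp 1", {
  set.seed(9)
  prof <- rnorm(40)
  vals <- matrix(rep(prof, 5), 40, dimnames = list(sprintf("S%02d", 1:40),
                                                   paste0("g", 1:5)))
  expr <- expression_matrix(vals - min(vals), "logTPM")
  asg <- structure(list(modules = setNames(rep("blue", 5), colnames(vals))),
                   class = "module_assignment")
  me <- module_eigengenes(expr, asg)
  expect_equal(unname(me$var_explained["blue"]), 1)
  expect_equal(unname(cor(me$eigengenes[, "blue"], prof)), 1)
  expect_equal(sd(me$eigengenes[, "blue"]), 1)
})

test_that("two anti-correlated genes still explain full variance", {
  x <- seq(-2, 2, length.out = 30)
  vals <- cbind(g1 = x + 5, g2 = -x + 10)
  rownames(vals) <- sprintf("S%02d", 1:30)
  expr <- expression_matrix(vals, "logTPM")
  asg <- structure(list(modules = setNames(rep("blue", 2), c("g1", "g2"))),
                   class = "module_assignment")
  me <- module_eigengenes(expr, asg)
  expect_equal(unname(me$var_explained["blue"]), 1)
})

test_that("eigengenes match an independent SVD oracle", {
  lm_ <- latent_modules()
  me <- module_eigengenes(lm_$expr, lm_$assignment)
  for (mod in c("blue", "brown")) {
    genes <- names(lm_$assignment$modules)[lm_$assignment$modules == mod]
    z <- scale(lm_$expr$values[, genes])
    u1 <- svd(z)$u[, 1]
    expect_equal(abs(cor(me$eigengenes[, mod], u1)), 1, tolerance = 1e-10)
  }
  # orientation: positively correlated with module mean expression
  expect_gt(cor(me$eigengenes[, "blue"],
                rowMeans(scale(lm_$expr$values[, 1:20]))), 0)
})

test_that("correlated module eigengenes merge below the height cutoff", {
  near <- latent_modules(factor_cor = 0.95, seed = 51)
  m_near <- merge_modules(near$expr, near$assignment, cut_height = 0.20)
  expect_equal(m_near$n_after, 1)
  expect_equal(unname(m_near$lineage["brown"]), "blue")  # larger wins

  far <- latent_modules(factor_cor = 0.5, seed = 52)
  m_far <- merge_modules(far$expr, far$assignment, cut_height = 0.20)
  expect_equal(m_far$n_after, 2)
})

test_that("raising the merge height never increases the module count", {
  sc <- small_cohort()
  net <- build_network(sc$resid, beta = 8)
  asg <- detect_modules(net, 30)
  counts <- vapply(c(0.05, 0.2, 0.5, 0.8), function(h)
    merge_modules(sc$resid, asg, cut_height = h)$n_after, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("kME is the gene-eigengene correlation with exact endpoints", {
  lm_ <- latent_modules()
  me <- module_eigengenes(lm_$expr, lm_$assignment)
  vals <- cbind(lm_$expr$values,
                g_me = me$eigengenes[, "blue"] - min(me$eigengenes[, "blue"]),
                g_anti = -me$eigengenes[, "blue"] + 10)
  expr2 <- expression_matrix(vals, "logTPM")
  kme <- module_kme(expr2, me)
  expect_equal(unname(kme["g_me", "blue"]), 1)
  expect_equal(unname(kme["g_anti", "blue"]), -1)
  # own-module kME dominates for planted genes
  own <- kme[1:20, "blue"]
  other <- kme[1:20, "brown"]
  expect_true(mean(abs(own) > abs(other)) >= 0.95)
})

test_that("intramodular connectivity equals the brute-force sum", {
  sc <- small_cohort()
  expr <- sc$resid
  expr$values <- expr$values[, 1:50]
  net <- build_network(expr, beta = 4)
  labels <- setNames(rep(c("blue", "brown", "grey"), length.out = 50),
                     net$genes)
  asg <- structure(list(modules = labels), class = "module_assignment")
  kim <- intramodular_connectivity(net, asg)
  g <- net$genes[7]
  mates <- setdiff(names(labels)[labels == labels[g]], g)
  expect_equal(unname(kim[g]), sum(net$adjacency[g, mates]))
})

test_that("three genes at adjacency 0.5 each have kIM 1; singletons 0", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
  net <- structure(list(genes = paste0("g", 1:3), adjacency = a),
                   class = "coexpression_network")
  asg <- structure(list(modules = setNames(c("blue", "blue", "blue"),
                                           paste0("g", 1:3))),
                   class = "module_assignment")
  expect_equal(as.numeric(intramodular_connectivity(net, asg)), rep(1, 3))
  asg2 <- structure(list(modules = setNames(c("blue", "blue", "brown"),
                                            paste0("g", 1:3))),
                    class = "module_assignment")
  expect_equal(unname(intramodular_connectivity(net, asg2)["g3"]), 0)
})

test_that("module-trait correlation recovers planted effects with stars", {
  lm_ <- latent_modules(seed = 53)
  me <- module_eigengenes(lm_$expr, lm_$assignment)
  traits <- cbind(follows_blue = lm_$f1,
                  random = rnorm(80),
                  sparse = c(rep(NA, 78), 1, 0))
  rownames(traits) <- rownames(lm_$expr$values)
  mt <- module_trait_correlation(me, traits)
  expect_gt(mt$r["blue", "follows_blue"], 0.9)
  expect_equal(mt$stars["blue", "follows_blue"], "***")
  expect_true(is.na(mt$r["blue", "sparse"]))  # < 3 complete samples
  # exact trait == eigengene gives r = 1
  traits2 <- cbind(me_itself = me$eigengenes[, "blue"])
  rownames(traits2) <- rownames(me$eigengenes)
  expect_equal(unname(module_trait_correlation(me, traits2)$r["blue", 1]), 1)
})

test_that("gene-trait significance handles exact and constant genes", {
  lm_ <- latent_modules(seed = 54)
  gs <- gene_trait_significance(lm_$expr, lm_$f1)
  expect_gt(max(gs[1:20]), 0.9)
  vals <- cbind(lm_$expr$values, g_const = rep(1, 80))
  expr2 <- expression_matrix(vals, "logTPM")
  gs2 <- gene_trait_significance(expr2, lm_$f1)
  expect_true(is.na(gs2["g_const"]))
  expect_error(gene_trait_significance(lm_$expr, rep(NA, 80)), ">= 3")
})

test_that("module composition reports lncRNA and 50 kb proximity fractions", {
  # lnc g1 ends at 1000; coding g2 starts 1000 + 49999 (gap 49,999: proximal)
  # lnc g3 ends at 200000; coding g4 starts 200000 + 50001 (not proximal)
  ann <- toy_annotation(c("g1", "g2", "g3", "g4"),
                        c("lncRNA", "protein_coding", "lncRNA",
                          "protein_coding"),
                        start = c(0, 50999, 150000, 250001),
                        end = c(1000, 52000, 200000, 251000))
  asg <- structure(list(modules = setNames(c("blue", "blue", "brown", "brown"),
                                           ann$gene_id)),
                   class = "module_assignment")
  comp <- module_composition(asg, ann, window = 50000)
  expect_equal(comp$frac_lncRNA, c(0.5, 0.5))
  expect_equal(comp$frac_lnc_proximal[comp$module == "blue"], 1)
  expect_equal(comp$frac_lnc_proximal[comp$module == "brown"], 0)
  # all-lncRNA module
  ann2 <- toy_annotation(c("a", "b"), "lncRNA")
  asg2 <- structure(list(modules = setNames(c("m", "m"), c("a", "b"))),
                    class = "module_assignment")
  expect_equal(module_composition(asg2, ann2)$frac_lncRNA, 1)
})
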