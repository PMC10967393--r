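# TOM-like toy matrix with one designated module
toy_tom <- function(weights) {
  n <- nrow(weights)
  dimnames(weights) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  diag(weights) <- 1
  weights
}

toy_assignment <- function(genes, module = "blue") {
  structure(list(modules = setNames(rep(module, length(genes)), genes)),
            class = "module_assignment")
}

test_that("threshold zero keeps the full module graph", {
  set.seed(3)
  w <- matrix(runif(36, 0.01, 0.5), 6, 6)
  w <- (w + t(w)) / 2
  tom <- toy_tom(w)
  ann <- toy_annotation(rownames(tom), rep(c("lncRNA", "protein_coding"), 3))
  g <- hub_network(tom, toy_assignment(rownames(tom)), "blue", ann,
                   threshold = 0)
  expect_equal(nrow(g$edges), choose(6, 2))
  expect_setequal(g$nodes$gene_id, rownames(tom))
})

test_that("a lncRNA keeps only its directly connected neighbors", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5   # lncRNA g1 -- coding g2
  w[3, 4] <- w[4, 3] <- 0.5   # coding g3 -- coding g4 (no lncRNA involved)
  tom <- toy_tom(w)
  ann <- toy_annotation(rownames(tom),
                        c("lncRNA", rep("protein_coding", 3)))
  g <- hub_network(tom, toy_assignment(rownames(tom)), "blue", ann,
                   threshold = 0.1)
  expect_setequal(g$nodes$gene_id, c("g1", "g2"))
})

test_that("the planted hub has top degree and empty exports warn", {
  # hub-and-spoke: g1 (lncRNA) connected to every other node
  n <- 8
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- 0.2
  tom <- toy_tom(w)
  ann <- toy_annotation(rownames(tom),
                        c("lncRNA", rep("protein_coding", n - 1)))
  g <- hub_network(tom, toy_assignment(rownames(tom)), "blue", ann,
                   threshold = 0.1)
  expect_equal(g$nodes$gene_id[1], "g1")
  expect_equal(g$nodes$degree[1], n - 1)
  expect_warning(
    empty <- hub_network(tom, toy_assignment(rownames(tom)), "blue", ann,
                         threshold = 0.9), "removes all edges")
  expect_equal(nrow(empty$edges), 0)
  expect_error(hub_network(tom, toy_assignment(rownames(tom)), "nope", ann),
               "module not found")
})

test_that("module graphs round-trip through edge-list TSV and GraphML", {
  set.seed(5)
  w <- matrix(runif(25, 0.1, 0.6), 5, 5); w <- (w + t(w)) / 2
  tom <- toy_tom(w)
  ann <- toy_annotation(rownames(tom), rep(c("lncRNA", "protein_coding"),
                                           length.out = 5))
  g <- hub_network(tom, toy_assignment(rownames(tom)), "blue", ann, 0.2)
  edges_path <- withr::local_tempfile(fileext = ".tsv")
  graphml_path <- withr::local_tempfile(fileext = ".graphml")
  export_module_graph(g, graphml_path, edges_path)
  back <- read_module_edges(edges_path)
  expect_equal(back$weight, g$edges$weight, tolerance = 1e-12)
  ig <- igraph::read_graph(graphml_path, format = "graphml")
  expect_equal(igraph::gsize(ig), nrow(g$edges))
  expect_setequal(igraph::vertex_attr(ig, "biotype"),
                  unique(g$nodes$biotype))
})

test_that("PCA loadings match the prcomp oracle and the hypotenuse rule", {
  set.seed(12)
  vals <- matrix(rnorm(40 * 8), 40,
                 dimnames = list(sprintf("S%02d", 1:40), paste0("g", 1:8)))
  expr <- expression_matrix(vals - min(vals), "logTPM")
  pc <- pca_contributions(expr)
  oracle <- prcomp(scale(expr$values))
  ora_load <- sweep(oracle$rotation[, 1:2], 2, oracle$sdev[1:2], "*")
  # sign convention may differ per axis; compare up to sign
  for (j in 1:2) {
    agree <- max(abs(pc$loadings[, j] - ora_load[, j]),
                 abs(pc$loadings[, j] + ora_load[, j]))
    match_ <- min(max(abs(pc$loadings[, j] - ora_load[, j])),
                  max(abs(pc$loadings[, j] + ora_load[, j])))
    expect_lt(match_, 1e-10)
    expect_gt(agree, 0)
  }
  expect_equal(pc$magnitude,
               sqrt(pc$loadings[, 1]^2 + pc$loadings[, 2]^2))
  expect_error(pca_contributions(expression_matrix(vals[1:2, 1:3] -
    min(vals), "logTPM")), ">= 3")
})

test_that("a dominant planted lncRNA tops the contributor ranking", {
  set.seed(13)
  f <- rnorm(60)
  vals <- cbind(
    lnc_star = 3 * f,
    sapply(1:6, function(i) 0.5 * f + rnorm(60, 0, 1)))
  colnames(vals)[2:7] <- paste0("pc", 1:6)
  rownames(vals) <- sprintf("S%02d", 1:60)
  expr <- expression_matrix(vals - min(vals), "logTPM")
  ann <- toy_annotation(colnames(vals),
                        c("lncRNA", rep("protein_coding", 6)))
  pc <- pca_contributions(expr)
  top <- top_contributors(pc, ann, k = 1)
  expect_equal(top$gene_id, "lnc_star")
  all_ <- top_contributors(pc, ann, k = 50, biotype = NULL)
  expect_equal(nrow(all_), 7)  # k beyond n returns everything
})

test_that("contributor ties break deterministically by gene id", {
  contributions <- list(
    loadings = matrix(0, 3, 2, dimnames = list(c("b", "a", "c"),
                                               c("PC1", "PC2"))),
    magnitude = setNames(rep(0, 3), c("b", "a", "c")))
  ann <- toy_annotation(c("a", "b", "c"), "lncRNA")
  out <- top_contributors(contributions, ann, k = 3)
  expect_equal(out$gene_id, c("a", "b", "c"))
})
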