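test_that("covariate regression removes planted batch effects only", {
  set.seed(8)
  n <- 60
  batch <- factor(rep(c("B1", "B2"), each = n / 2))
  samples <- data.frame(sample_id = sprintf("S%02d", 1:n), batch = batch)
  base <- matrix(rnorm(n * 4), n, dimnames = list(samples$sample_id,
                                                  paste0("g", 1:4)))
  shifted <- base
  shifted[, 1] <- shifted[, 1] + 2 * (batch == "B2")   # planted batch effect
  # make gene 3 exactly orthogonal to the batch design
  shifted[, 3] <- shifted[, 3] - ave(shifted[, 3], batch) + 5
  expr <- expression_matrix(shifted - min(shifted), "logTPM", samples)
  out <- regress_covariates(expr, "batch")
  means <- tapply(out$values[, 1], batch, mean)
  expect_lt(abs(diff(means)), 1e-10)
  # an orthogonal gene is unchanged by residualization
  expect_equal(unname(out$values[, 3]), unname(expr$values[, 3]),
               tolerance = 1e-10)
  # an exact linear function of the covariate residualizes to a constant
  shifted[, 4] <- 3 * (batch == "B2") + 1
  expr2 <- expression_matrix(shifted - min(shifted), "logTPM", samples)
  out2 <- regress_covariates(expr2, "batch")
  expect_lt(sd(out2$values[, 4]), 1e-10)
  expect_error(regress_covariates(expr, "nope"), "absent")
})

test_that("rank-deficient covariate designs are rejected by name", {
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        x1 = c(1, 2, 3), x2 = c(2, 4, 6))
  vals <- matrix(1:6, 3, dimnames = list(samples$sample_id, c("g1", "g2")))
  expr <- expression_matrix(vals, "logTPM", samples)
  expect_error(regress_covariates(expr, c("x1", "x2")), "collinear")
})

test_that("adjacency is |r|^beta with unit diagonal", {
  sc <- small_cohort()
  expr <- sc$resid
  expr$values <- expr$values[, 1:30]
  net1 <- build_network(expr, beta = 1)
  expect_equal(unname(net1$adjacency[2, 9]), abs(net1$cor[2, 9]))
  net2 <- build_network(expr, beta = 2)
  expect_equal(net2$adjacency[1, 5], abs(net2$cor[1, 5])^2)
  expect_true(all(diag(net2$adjacency) == 1))
})

test_that("raising beta weakly shrinks every off-diagonal adjacency", {
  sc <- small_cohort()
  expr <- sc$resid
  expr$values <- expr$values[, 1:40]
  a2 <- build_network(expr, beta = 2)$adjacency
  a6 <- build_network(expr, beta = 6)$adjacency
  off <- upper.tri(a2)
  expect_true(all(a6[off] <= a2[off] + 1e-12))
})

test_that("constant genes are dropped with a warning", {
  sc <- small_cohort()
  expr <- sc$resid
  expr$values <- expr$values[, 1:10]
  expr$values[, 3] <- 5
  expect_warning(net <- build_network(expr, beta = 2), "constant")
  expect_equal(length(net$genes), 9)
})

test_that("TOM matches the hand-computed three-node case", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- tom_similarity(a)
  # L = 0.25, denominator min(k) + 1 - a = 1 + 0.5 = 1.5
  expect_equal(tom[1, 2], (0.25 + 0.5) / 1.5)
  expect_equal(diag(tom), rep(1, 3))
})

test_that("two-node TOM reduces to the adjacency", {
  a <- matrix(c(1, 0.37, 0.37, 1), 2)
  expect_equal(tom_similarity(a)[1, 2], 0.37)
})

test_that("TOM equals the brute-force triple loop on random instances", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    r <- cor(matrix(rnorm(40 * n), 40, n))
    a <- abs(r)^sample(1:8, 1)
    expect_equal(tom_similarity(a), tom_oracle(a), tolerance = 1e-12)
  }
})

test_that("soft threshold table flags degenerate inputs and finds structure", {
  # perfectly correlated genes: degenerate connectivity, no crash
  x <- rnorm(30)
  vals <- sapply(1:8, function(i) x * i)
  dimnames(vals) <- list(sprintf("S%02d", 1:30), paste0("g", 1:8))
  expr <- expression_matrix(vals - min(vals), "logTPM")
  res <- pick_soft_threshold(expr, candidate_powers = 1:6)
  expect_true(!is.null(res$flag))

  sc <- small_cohort()
  res2 <- pick_soft_threshold(sc$resid, candidate_powers = c(1, 4, 8, 12))
  expect_equal(nrow(res2$table), 4)
  if (!is.na(res2$power)) {
    expect_gte(res2$table$r2[res2$table$power == res2$power], 0.80)
  }
})

test_that("perfect block structure yields exactly two modules, empty grey", {
  d <- matrix(1, 60, 60)
  d[1:30, 1:30] <- 0; d[31:60, 31:60] <- 0
  diag(d) <- 0
  colnames(d) <- rownames(d) <- paste0("g", 1:60)
  asg <- detect_modules(d, min_module_size = 20)
  expect_equal(sum(names(asg$sizes) != "grey"), 2)
  expect_false("grey" %in% asg$modules)
})

test_that("undersized branches fall to grey", {
  d <- matrix(1, 45, 45)
  d[1:30, 1:30] <- 0; d[31:45, 31:45] <- 0
  diag(d) <- 0
  colnames(d) <- rownames(d) <- paste0("g", 1:45)
  asg <- detect_modules(d, min_module_size = 20)
  expect_equal(sum(asg$modules == "grey"), 15)
  expect_equal(as.integer(asg$sizes[names(asg$sizes) != "grey"]), 30)
})

test_that("module detection is invariant to gene order", {
  sc <- small_cohort()
  net <- build_network(sc$resid, beta = 8)
  tom <- tom_similarity(net)
  asg1 <- detect_modules(1 - tom, 30)
  set.seed(14)
  perm <- sample(colnames(tom))
  asg2 <- detect_modules(1 - tom[perm, perm], 30)
  common <- names(asg1$modules)
  expect_equal(adjusted_rand_index(asg1$modules[common],
                                   asg2$modules[common]), 1)
})

test_that("fewer genes than the minimum size produce a single grey module", {
  d <- matrix(0.5, 5, 5); diag(d) <- 0
  colnames(d) <- rownames(d) <- paste0("g", 1:5)
  asg <- detect_modules(d, min_module_size = 10)
  expect_true(all(asg$modules == "grey"))
})
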