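# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A small planted cohort processed through thresholding, TPM, log and
# covariate regression; used by network/module/preservation tests.
small_cohort <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  cc <- cohort_config(n_patients = 40, n_genes = 400, n_modules = 3,
                      module_sizes = 60, module_loading = 0.85,
                      trait_effects = list(c(UC = 0.8), c(rectum = 0.8),
                                           numeric(0)),
                      seed = 101)
  coh <- generate_cohort(cc)
  counts <- expression_matrix(coh$counts, "counts", coh$samples)
  retained <- threshold_genes(counts, annotation = coh$annotation)
  lengths <- setNames(coh$annotation$length, coh$annotation$gene_id)
  logtpm <- log_transform(tpm_normalize(counts, lengths, retained))
  resid <- regress_covariates(logtpm, "batch")
  .fixtures$small <- list(cohort = coh, counts = counts, logtpm = logtpm,
                          resid = resid)
  .fixtures$small
}

# counts matrix with hand-set values and disease metadata
toy_counts <- function(values, diseases) {
  n <- length(diseases)
  rownames(values) <- sprintf("S%02d", seq_len(n))
  samples <- data.frame(sample_id = rownames(values), disease = diseases,
                        stringsAsFactors = FALSE)
  expression_matrix(values, "counts", samples)
}

toy_annotation <- function(gene_id, biotype, chrom = "chr1",
                           start = NULL, end = NULL, source = "synthetic") {
  n <- length(gene_id)
  if (is.null(start)) start <- seq(0, by = 10000, length.out = n)
  if (is.null(end)) end <- start + 1000
  gene_annotation(data.frame(
    gene_id = gene_id, biotype = biotype, source = source,
    chrom = rep_len(chrom, n), start = start, end = end,
    strand = "+", stringsAsFactors = FALSE))
}

# brute-force topological overlap, entry by entry from the definition
# (independent of the matrix-product implementation)
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    others <- setdiff(seq_len(n), c(i, j))
    l <- sum(a[i, others] * a[others, j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# brute-force betweenness centrality by BFS shortest-path enumeration
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  dist_counts <- function(s) {
    d <- rep(Inf, n); sigma <- numeric(n)
    d[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        if (d[w] == d[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
      frontier <- unique(nxt)
    }
    list(d = d, sigma = sigma)
  }
  paths <- lapply(seq_len(n), dist_counts)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- paths[[s]]; pt <- paths[[t]]
    if (is.infinite(ps$d[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (ps$d[v] + pt$d[v] == ps$d[t])
        bc[v] <- bc[v] + ps$sigma[v] * pt$sigma[v] / ps$sigma[t]
    }
  }
  bc
}
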