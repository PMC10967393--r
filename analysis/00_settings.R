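# Shared settings for the analysis drivers: one demo cohort specification
# used by every numbered script, rebuilt deterministically on demand so the
# scripts can be run independently and in any order.

library(lncnet)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

DEMO_SEED <- 20260920L

demo_cohort_config <- function() {
  cohort_config(n_patients = 110, n_genes = 2000, n_modules = 6,
                module_sizes = 150, module_loading = 0.7,
                frac_lncRNA = 0.4, n_batches = 4, seed = DEMO_SEED)
}

# cohort processed to the residualized logTPM matrix the network uses
demo_processed <- function() {
  coh <- generate_cohort(demo_cohort_config())
  counts <- expression_matrix(coh$counts, "counts", coh$samples)
  retained <- threshold_genes(counts, annotation = coh$annotation)
  lengths <- setNames(coh$annotation$length, coh$annotation$gene_id)
  tpm <- tpm_normalize(counts, lengths, retained)
  logtpm <- log_transform(tpm)
  resid <- regress_covariates(logtpm, "batch")
  list(cohort = coh, counts = counts, retained = retained, tpm = tpm,
       logtpm = logtpm, resid = resid)
}

demo_modules <- function(d = demo_processed()) {
  net <- build_network(d$resid, beta = 8)
  tom <- tom_similarity(net)
  assignment <- detect_modules(1 - tom, min_module_size = 30,
                               cor_matrix = net$cor,
                               n_samples = net$n_samples)
  merged <- merge_modules(d$resid, assignment)
  c(d, list(net = net, tom = tom, assignment = merged$assignment,
            eigengenes = merged$eigengenes, lineage = merged$lineage))
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
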