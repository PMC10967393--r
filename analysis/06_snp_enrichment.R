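#!/usr/bin/env Rscript
# Genetics overlay: a synthetic GWAS SNP catalog with excess SNPs planted
# in the windows of the first planted module, +/- 50 kb gene-window
# adjacency, composition-matched bootstrap enrichment per module (10,000
# draws), disease-specific SNP proportions, and the hypergeometric overlap
# of a module with a DE gene set.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_settings.R"))

m <- demo_modules()
ann <- m$cohort$annotation
truth <- m$cohort$truth

snps <- generate_snp_catalog(ann, enriched_modules = "1", truth = truth,
                             n_snps = 400, excess_rate = 0.5,
                             seed = DEMO_SEED + 3L)
write_tsv(snps, "snp_catalog.tsv")
adj <- snp_adjacent_genes(ann, snps, window = 50000)
message(sprintf("%d of %d genes are SNP-adjacent (background %.1f%%)",
                sum(adj$adjacent), length(adj$adjacent),
                100 * mean(adj$adjacent)))

universe <- names(m$assignment$modules)
mods <- setdiff(names(sort(table(m$assignment$modules),
                           decreasing = TRUE)), "grey")
enr <- do.call(rbind, lapply(mods, function(mod) {
  genes <- universe[m$assignment$modules == mod]
  e <- bootstrap_enrichment(genes, universe, adj$adjacent, ann,
                            n_boot = 10000, seed = DEMO_SEED + 4L)
  cbind(module = mod,
        planted = paste(sort(unique(truth$modules[genes])), collapse = "/"),
        e)
}))
message("bootstrap SNP-adjacency enrichment per module:")
print(enr, row.names = FALSE, digits = 3)
write_tsv(enr, "snp_enrichment.tsv")

dsp <- disease_specific_proportions(m$assignment, adj, ann, min_count = 3)
if (!is.null(dsp)) {
  message("disease-specific SNP-adjacent lncRNA proportions:")
  print(dsp, row.names = FALSE, digits = 2)
  write_tsv(dsp, "disease_specific_proportions.tsv")
}

# overlap of the most enriched module with a planted "DE-like" gene set
best <- enr$module[which.min(enr$p)]
best_genes <- universe[m$assignment$modules == best]
de_like <- names(truth$modules)[truth$modules == "1"]
ovl <- module_de_overlap(best_genes, de_like,
                         universe_size = length(universe))
message(sprintf("module %s vs planted module-1 gene set: overlap %d, hypergeometric p = %.3g",
                best, ovl$overlap, ovl$p))
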