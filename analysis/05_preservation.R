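#!/usr/bin/env Rscript
# Network reproducibility: a severity-stratified 70/30 split, train-vs-test
# mean-expression agreement, cross-set module membership (kME), the
# permutation Zsummary preservation statistic, and betweenness-centrality
# overlap of high-influence nodes between the two networks.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_settings.R"))

d <- demo_processed()
sp <- stratified_split(d$resid$samples, frac_train = 0.70,
                       strata = "severity", seed = DEMO_SEED + 1L,
                       expr = d$resid)
message(sprintf("split: %d train / %d test; per-gene mean-expression r = %.4f (slope %.3f)",
                length(sp$train), length(sp$test),
                sp$report$mean_expression$r, sp$report$mean_expression$slope))

subset_expr <- function(e, ids) {
  e$values <- e$values[ids, , drop = FALSE]
  e$samples <- e$samples[ids, , drop = FALSE]
  e
}
tr <- subset_expr(d$resid, sp$train)
te <- subset_expr(d$resid, sp$test)

net_tr <- build_network(tr, beta = 8)
asg_tr <- detect_modules(net_tr, min_module_size = 30)
me_tr <- module_eigengenes(tr, asg_tr)

kme_tr <- module_kme(tr, me_tr)
kme_te <- cross_kme(te, me_tr)
common <- intersect(colnames(kme_tr), colnames(kme_te))
kme_agreement <- diag(cor(kme_tr[, common], kme_te[, common],
                          use = "pairwise.complete.obs"))
message(sprintf("train-vs-test kME agreement per module: %s",
                paste(sprintf("%.2f", kme_agreement), collapse = " ")))

zs <- module_zsummary(tr, te, asg_tr, beta = 8, n_permutations = 200,
                      seed = DEMO_SEED + 2L)
message("module preservation (test vs train):")
print(zs, row.names = FALSE, digits = 3)
write_tsv(zs, "module_preservation.tsv")

tom_tr <- tom_similarity(net_tr)
tom_te <- tom_similarity(build_network(te, beta = 8))
thr <- quantile(tom_tr[upper.tri(tom_tr)], 0.999)
bc <- bc_overlap(tom_tr, tom_te, edge_threshold = thr,
                 annotation = d$cohort$annotation)
message(sprintf("high-influence (top-quartile BC) overlap: %.0f%% overall; %s",
                100 * bc$overlap,
                paste(names(bc$by_biotype),
                      sprintf("%.0f%%", 100 * bc$by_biotype),
                      collapse = ", ")))
write_tsv(data.frame(biotype = names(bc$by_biotype),
                     overlap = unname(bc$by_biotype)),
          "bc_overlap.tsv")
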