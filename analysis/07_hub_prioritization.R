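#!/usr/bin/env Rscript
# lncRNA prioritization inside the largest module: TOM-thresholded hub
# network restricted to lncRNAs and their direct neighbors (exported as
# GraphML + edge-list TSV for Cytoscape-style viewers), and PCA
# "hypotenuse" contributions ranking the lncRNAs that drive the module's
# first two principal components.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_settings.R"))

m <- demo_modules()
mods <- setdiff(names(sort(table(m$assignment$modules),
                           decreasing = TRUE)), "grey")
module <- mods[1]
message(sprintf("hub analysis of module '%s' (%d genes)", module,
                sum(m$assignment$modules == module)))

thr <- quantile(m$tom[upper.tri(m$tom)], 0.999)
hub <- hub_network(m$tom, m$assignment, module, m$cohort$annotation,
                   threshold = thr)
message(sprintf("thresholded graph: %d nodes, %d edges (TOM >= %.4f)",
                nrow(hub$nodes), nrow(hub$edges), thr))
message("top hub genes by degree:")
print(head(hub$nodes, 5), row.names = FALSE)
export_module_graph(hub,
                    graphml_path = file.path(RESULTS_DIR, "hub_module.graphml"),
                    edges_path = file.path(RESULTS_DIR, "hub_edges.tsv"))
write_tsv(hub$nodes, "hub_nodes.tsv")

genes <- names(m$assignment$modules)[m$assignment$modules == module]
pc <- pca_contributions(m$resid, genes)
message(sprintf("PC1/PC2 explain %.0f%% / %.0f%% of the module's variance",
                100 * pc$var_explained[1], 100 * pc$var_explained[2]))
top <- top_contributors(pc, m$cohort$annotation, k = 10,
                        biotype = "lncRNA")
message("top lncRNA contributors (hypotenuse of PC1/PC2 loadings):")
print(top, row.names = FALSE, digits = 2)
write_tsv(top, "top_lncRNA_contributors.tsv")
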