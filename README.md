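# lncnet

Coexpression-network analysis of long noncoding RNAs (lncRNAs) in
inflammatory bowel disease (IBD) gut biopsy transcriptomes, packaged as a
tested, fully reproducible R pipeline.

Most lncRNAs are expressed at low levels, with high between-sample
variability and strong tissue specificity, which makes them hard to study
one gene at a time. The approach implemented here embeds them in a
weighted gene coexpression network built from bulk biopsy RNA-seq: genes
with correlated expression across hundreds of biopsies form modules, the
modules are summarized by eigengenes and correlated with clinical traits
(inflammation, disease subtype, severity, sampling location, CRP), and
lncRNAs are prioritized by their position in that network — as
intramodular hubs, as top principal-component contributors, or by
adjacency to GWAS risk loci — and finally tested functionally with a
pooled CRISPR-activation screen read out on TNF-α production.

## What the package implements

* **Synthetic cohort generator** — a multi-tissue HC/UC/CD biopsy cohort
  with planted coexpression modules, trait-driven module eigengenes,
  biotype-dependent expression (lncRNAs lower and more dispersed),
  negative binomial counts with logistic dropout, plus SNP catalogs with
  planted enrichment and CRISPRa screen counts with planted regulators.
  Every downstream stage is testable against this known truth.
* **Expression** — read-support thresholding per disease class (>10 reads
  in ≥40% of libraries), TPM over retained genes, log2(TPM+1),
  tissue-specificity calls, biotype contrasts.
* **Differential expression** — per-gene zero-inflated Gaussian model:
  logistic zero part + Gaussian linear mixed model (batch and/or patient
  random intercepts) on the positive part, mixed-model fallback on
  non-convergence, BH-adjusted Wald tests, DE calls at adjusted p < 0.05
  and |log2FC| > 1.
* **Network core** — unsigned adjacency |r|^β (soft threshold scan with
  scale-free fit R², β = 8 for these networks), topological overlap
  matrix, deterministic size-adaptive tree cut, color-labeled modules
  with grey for unassigned genes.
* **Module analysis** — eigengenes (first PC, sign-fixed), merging at
  eigengene dissimilarity 0.2, kME, intramodular connectivity,
  module–trait correlation with star annotation, biotype composition and
  50 kb lncRNA–coding proximity.
* **Preservation** — stratified 70/30 split, cross-set kME, permutation
  Zsummary (high >10, moderate 5–10, low <5), betweenness-centrality
  overlap of high-influence nodes.
* **Genetics** — ±50 kb SNP-adjacency windows, composition-matched
  10,000-draw bootstrap enrichment per module, disease-specific SNP
  proportions, hypergeometric module–DE overlap.
* **Screen scoring** — RPM log2 fold-changes per sgRNA, binomial rank
  score over the top 4% with the ≥2-guide rule, permutation FDR, hit
  calls at FDR < 0.25.

The statistical details, default parameters and design decisions are
documented in `vignettes/lncnet-methods.Rmd`.

## Worked example

The numbered drivers under `analysis/` run the full study on the demo
cohort (2,000 genes, ~330 biopsies from 110 patients, six planted
modules) and write their tables under `results/`. For instance:

```sh
Rscript analysis/04_coexpression_network.R
```

prints

```
detected 6 modules (+ 1034 grey genes); ARI vs planted truth = 0.997
module composition (lncRNA fraction, 50 kb coding proximity):
    module size n_lncRNA frac_lncRNA frac_lnc_proximal
 turquoise  145       65        0.45              0.69
      blue  144       57        0.40              0.88
 ...
strongest module-trait correlations:
 module              trait    r       p stars
  green    rectum_vs_colon 0.36 1.3e-09   ***
  brown           inflamed 0.33 2.6e-11   ***
```

All six planted modules are recovered (adjusted Rand index 0.997 against
the generator's truth), each module mixes lncRNAs and protein-coding
genes, and the module eigengenes correlate with exactly the clinical
traits the generator wired them to (the rectum-driven module with
sampling location, the inflammation-driven module with inflamed status,
and so on). `analysis/08_screen_scoring.R` ends with

```
planted regulators recovered: 4 of 4 (LNC0007, LNC0019, LNC0042, LNC0066)
```

meaning all four planted TNF-α regulators pass the screen's FDR < 0.25
call with the correct sign. The same stages can be driven
programmatically:

```r
library(lncnet)
coh    <- generate_cohort(cohort_config(seed = 1))
counts <- expression_matrix(coh$counts, "counts", coh$samples)
kept   <- threshold_genes(counts)
expr   <- log_transform(tpm_normalize(counts,
            setNames(coh$annotation$length, coh$annotation$gene_id), kept))
net    <- build_network(regress_covariates(expr, "batch"), beta = 8)
mods   <- detect_modules(net, min_module_size = 30)
```

or end to end with one seed:

```r
run_pipeline(pipeline_config(seed = 5), "out/")          # or:
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "lncnet"), "out/")
```

Two runs with the same configuration produce byte-identical artifacts
(the manifest records per-stage seeds and checksums).

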