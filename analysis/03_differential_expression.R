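#!/usr/bin/env Rscript
# Zero-inflated Gaussian differential expression for inflamed UC vs
# noninflamed HC in the nonrectal colon (patient + batch random
# intercepts), on the 300 most variable genes to keep the demo quick.
# Calls DE sets at adjusted p < 0.05 and |log2FC| > 1 and summarizes the
# up/down overlap with the CD contrast.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_settings.R"))

d <- demo_processed()
nsd <- apply(d$logtpm$values, 2, sd)
top <- names(sort(nsd, decreasing = TRUE))[1:300]
expr <- d$logtpm
expr$values <- expr$values[, top]

de_uc <- run_de(expr, d$cohort$annotation, "UC-inf", "colon_nonrectal")
de_cd <- run_de(expr, d$cohort$annotation, "CD-inf", "colon_nonrectal")

ok <- !is.na(de_uc$p_adj)
message(sprintf("UC-inf vs HC: %d genes fit, %d excluded, %d with p_adj < 0.05",
                sum(ok), sum(!ok), sum(de_uc$p_adj[ok] < 0.05)))
message(sprintf("models used: %s",
                paste(names(table(de_uc$model_used)),
                      table(de_uc$model_used), collapse = ", ")))

sets_uc <- call_de(de_uc, alpha = 0.05, min_abs_lfc = 1)
sets_cd <- call_de(de_cd, alpha = 0.05, min_abs_lfc = 1)
message(sprintf("UC DE: %d up / %d down; CD DE: %d up / %d down",
                length(sets_uc$up), length(sets_uc$down),
                length(sets_cd$up), length(sets_cd$down)))

ov <- de_overlap(list(UC_up = sets_uc$up, CD_up = sets_cd$up))
message("up-regulated overlap (Venn regions):")
print(ov, row.names = FALSE)

write_tsv(de_uc, "de_UCinf_vs_HC_colon.tsv")
write_tsv(de_cd, "de_CDinf_vs_HC_colon.tsv")
write_tsv(ov, "de_overlap_up.tsv")
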