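#' Default pipeline configuration
#'
#' Parameters for every stage of the end-to-end workflow, with the scaled
#' defaults of the packaged demo cohort. Any element can be overridden via
#' \code{overrides} (a nested list) or by editing the YAML written with
#' \code{\link{write_pipeline_config}}.
#'
#' @param seed master seed; each stage derives its own seed from it.
#' @param overrides nested list merged over the defaults.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(n_patients = 60, n_genes = 800, n_modules = 4,
                  module_sizes = 80, module_loading = 0.8,
                  frac_lncRNA = 0.4, n_batches = 3),
    threshold = list(min_reads = 10, min_frac = 0.40, group_by = "disease"),
    de = list(enabled = TRUE, contrast = "UC-inf",
              location = "colon_nonrectal", max_genes = 150),
    network = list(power = 8, covariates = "batch", min_module_size = 25,
                   cut_height = 0.99, merge_height = 0.20),
    preservation = list(enabled = TRUE, frac_train = 0.70,
                        n_permutations = 50),
    genetics = list(enabled = TRUE, n_snps = 300, window = 50000,
                    n_boot = 2000, enrich_first_module = TRUE,
                    excess_rate = 0.5),
    hubs = list(threshold = 0.02, top_k = 10),
    screen = list(enabled = TRUE, n_genes = 80, guides_per_gene = 6,
                  n_controls = 80, n_regulators = 4, effect = 1.5,
                  depth = 1e6, n_perm = 400))
  modifyList(cfg, overrides)
}

#' @rdname pipeline_config
#' @param config configuration list.
#' @param path YAML destination / source.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipeline_config(seed = cfg$seed %||% 1L, overrides = cfg)
}

stage_seed <- function(seed, offset) (as.integer(seed) * 113L + offset) %% 2147483647L

#' Run the full coexpression workflow end to end
#'
#' Simulate -> threshold/TPM -> differential expression -> network ->
#' modules/traits -> preservation -> SNP enrichment -> hubs/PCA -> screen
#' scoring, writing one TSV per stage plus a provenance manifest (stage
#' seeds, parameters hash, artifact checksums) under \code{out_dir}.
#' Re-running with the same config and seed reproduces every artifact
#' byte for byte.
#'
#' @param config list from \code{\link{pipeline_config}} (or a YAML path).
#' @param out_dir output directory (created).
#' @return invisible list with the in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- list()
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)

  ## simulate ------------------------------------------------------------
  cc <- do.call(cohort_config,
                c(config$cohort, list(seed = stage_seed(seed, 1L))))
  cohort <- generate_cohort(cc)
  res$cohort <- cohort
  paths["annotation"] <- tsv(cohort$annotation, "annotation.tsv")
  paths["samples"] <- tsv(cohort$samples, "samples.tsv")

  ## threshold + normalize ----------------------------------------------
  counts <- expression_matrix(cohort$counts, "counts", cohort$samples)
  retained <- threshold_genes(counts, config$threshold$min_reads,
                              config$threshold$min_frac,
                              config$threshold$group_by,
                              annotation = cohort$annotation)
  tpm <- tpm_normalize(counts, setNames(cohort$annotation$length,
                                        cohort$annotation$gene_id), retained)
  logtpm <- log_transform(tpm)
  res$retained <- retained
  paths["retained"] <- tsv(data.frame(gene_id = retained), "retained_genes.tsv")

  ## differential expression ---------------------------------------------
  if (isTRUE(config$de$enabled)) {
    nsd <- apply(logtpm$values, 2, sd)
    de_genes <- names(sort(nsd, decreasing = TRUE))[
      seq_len(min(config$de$max_genes, length(nsd)))]
    de_expr <- logtpm
    de_expr$values <- de_expr$values[, de_genes, drop = FALSE]
    de <- run_de(de_expr, cohort$annotation, config$de$contrast,
                 config$de$location)
    res$de <- de
    paths["de"] <- tsv(de, "differential_expression.tsv")
  }

  ## network + modules ----------------------------------------------------
  resid <- regress_covariates(logtpm, config$network$covariates)
  net <- build_network(resid, beta = config$network$power)
  tom <- tom_similarity(net)
  assignment <- detect_modules(1 - tom, config$network$min_module_size,
                               cor_matrix = net$cor)
  me <- module_eigengenes(resid, assignment)
  merged <- merge_modules(resid, assignment, me, config$network$merge_height)
  res$network <- net; res$tom <- tom; res$assignment <- merged$assignment
  res$eigengenes <- merged$eigengenes
  res$merge_lineage <- merged$lineage
  paths["modules"] <- tsv(
    data.frame(gene_id = names(merged$assignment$modules),
               module = unname(merged$assignment$modules),
               biotype = cohort$annotation$biotype[
                 match(names(merged$assignment$modules),
                       cohort$annotation$gene_id)]),
    "module_assignment.tsv")

  traits <- clinical_traits(resid$samples)
  mt <- module_trait_correlation(merged$eigengenes, traits)
  res$module_trait <- mt
  paths["module_trait"] <- tsv(mt$table, "module_trait_correlation.tsv")
  comp <- module_composition(merged$assignment, cohort$annotation)
  paths["composition"] <- tsv(comp, "module_composition.tsv")

  ## preservation ---------------------------------------------------------
  if (isTRUE(config$preservation$enabled)) {
    sp <- stratified_split(resid$samples, config$preservation$frac_train,
                           seed = stage_seed(seed, 2L), expr = resid)
    tr <- resid; tr$values <- tr$values[sp$train, , drop = FALSE]
    tr$samples <- tr$samples[sp$train, , drop = FALSE]
    te <- resid; te$values <- te$values[sp$test, , drop = FALSE]
    te$samples <- te$samples[sp$test, , drop = FALSE]
    zs <- module_zsummary(tr, te, merged$assignment,
                          beta = config$network$power,
                          n_permutations = config$preservation$n_permutations,
                          seed = stage_seed(seed, 3L))
    res$preservation <- zs
    paths["preservation"] <- tsv(zs, "module_preservation.tsv")
  }

  ## genetics --------------------------------------------------------------
  if (isTRUE(config$genetics$enabled) &&
      any(merged$assignment$modules != "grey")) {
    mods <- setdiff(names(sort(table(merged$assignment$modules),
                               decreasing = TRUE)), "grey")
    planted_label <- unique(cohort$truth$modules[
      names(merged$assignment$modules)[merged$assignment$modules == mods[1]]])
    planted_label <- setdiff(planted_label, "grey")[1]
    enriched <- if (isTRUE(config$genetics$enrich_first_module) &&
                    !is.na(planted_label)) planted_label else character(0)
    snps <- generate_snp_catalog(cohort$annotation, enriched, cohort$truth,
                                 n_snps = config$genetics$n_snps,
                                 excess_rate = config$genetics$excess_rate,
                                 window = config$genetics$window,
                                 seed = stage_seed(seed, 4L))
    adj <- snp_adjacent_genes(cohort$annotation, snps,
                              config$genetics$window)
    universe <- names(merged$assignment$modules)
    enr <- do.call(rbind, lapply(mods, function(m) {
      genes <- universe[merged$assignment$modules == m]
      e <- bootstrap_enrichment(genes, universe, adj$adjacent,
                                cohort$annotation,
                                n_boot = config$genetics$n_boot,
                                seed = stage_seed(seed, 5L))
      cbind(module = m, e)
    }))
    res$snps <- snps; res$enrichment <- enr
    paths["snps"] <- tsv(snps, "snp_catalog.tsv")
    paths["enrichment"] <- tsv(enr, "snp_enrichment.tsv")
  }

  ## hubs + PCA ------------------------------------------------------------
  mods <- setdiff(names(sort(table(merged$assignment$modules),
                             decreasing = TRUE)), "grey")
  if (length(mods)) {
    hub <- hub_network(tom, merged$assignment, mods[1], cohort$annotation,
                       config$hubs$threshold)
    res$hub <- hub
    if (nrow(hub$edges))
      paths["hub_edges"] <- tsv(hub$edges, "hub_edges.tsv")
    genes1 <- names(merged$assignment$modules)[
      merged$assignment$modules == mods[1]]
    pc <- pca_contributions(resid, genes1)
    topc <- top_contributors(pc, cohort$annotation, config$hubs$top_k)
    res$pca <- pc; res$top_contributors <- topc
    paths["top_contributors"] <- tsv(topc, "top_lncRNA_contributors.tsv")
  }

  ## screen ----------------------------------------------------------------
  if (isTRUE(config$screen$enabled)) {
    scfg <- config$screen
    set.seed(stage_seed(seed, 6L))
    reg_genes <- sprintf("LNC%04d", sample.int(scfg$n_genes,
                                               scfg$n_regulators))
    regulators <- setNames(
      rep(c(scfg$effect, -scfg$effect), length.out = scfg$n_regulators),
      reg_genes)
    screen <- generate_screen(scfg$n_genes, scfg$guides_per_gene,
                              scfg$n_controls, regulators,
                              depth = scfg$depth,
                              seed = stage_seed(seed, 7L))
    lfc <- screen_log2fc(screen, "TNF_hi")
    gg <- setNames(screen$gene, screen$sgrna)
    up <- stars_fdr(lfc, gg, "enriched", n_perm = scfg$n_perm,
                    seed = stage_seed(seed, 8L))
    dn <- stars_fdr(lfc, gg, "depleted", n_perm = scfg$n_perm,
                    seed = stage_seed(seed, 9L))
    hits <- screen_hits(list(up, dn))
    res$screen <- list(table = screen, regulators = regulators, hits = hits)
    paths["screen_hits"] <- tsv(hits, "screen_hits.tsv")
  }

  ## manifest --------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("lncnet")),
    seed = seed,
    parameters = config,
    checksums = as.list(tools::md5sum(unname(paths))))
  names(manifest$checksums) <- basename(unname(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
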