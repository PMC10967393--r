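#' Configuration for the synthetic IBD cohort generator
#'
#' Bundles every knob of the simulated multi-tissue, multi-disease biopsy
#' cohort: cohort composition, gene universe, planted coexpression modules,
#' trait effects on module eigengenes, and the biotype-dependent expression
#' model (lncRNAs are simulated with lower baseline expression, higher
#' dispersion, and consequently more dropout than protein-coding genes).
#'
#' The latent model is: per-sample module eigengene = linear combination of
#' binary clinical traits + standard normal noise; per-gene log2 mean =
#' baseline + loading x eigengene; counts are negative binomial at the gene's
#' dispersion, then zeroed by a logistic dropout whose probability decreases
#' with log-mean expression.
#'
#' @param n_patients number of patients; each contributes 1-6 biopsies
#'   (tissue x inflammation combinations).
#' @param tissues biopsy locations sampled per patient.
#' @param diseases named proportions over HC/UC/CD (must sum to 1).
#' @param severity_levels ordered severity labels; HC patients are always
#'   "inactive".
#' @param n_batches number of sequencing batches.
#' @param n_genes total genes in the synthetic annotation.
#' @param frac_lncRNA fraction of genes with lncRNA biotype.
#' @param n_modules number of planted coexpression modules.
#' @param module_sizes integer vector of module sizes (sum must be <=
#'   \code{n_genes}); recycled to length \code{n_modules}.
#' @param module_loading loading of module genes on their eigengene, in sd
#'   units of log2 expression.
#' @param trait_effects list (length \code{n_modules}) of named numeric
#'   vectors: effect of each binary trait (\code{inflamed}, \code{active},
#'   \code{UC}, \code{CD}, \code{rectum}) on the module eigengene, in
#'   standardized units.
#' @param lnc_expression_shift additive offset (log2 units, negative) on the
#'   baseline log-mean of lncRNAs.
#' @param lnc_dispersion_mult multiplier (>= 1) on the negative binomial
#'   dispersion of lncRNAs.
#' @param dropout_midpoint,dropout_slope logistic dropout parameters: a gene
#'   at log2 mean equal to the midpoint has dropout probability 0.5, and the
#'   probability decreases with slope \code{dropout_slope} per log2 unit.
#' @param library_size_range range (reads) of per-sample library sizes.
#' @param co_locate_modules if TRUE, genes of a module are placed in one
#'   contiguous genomic neighborhood so SNP enrichment has spatial meaning.
#' @param seed integer seed driving all randomness of the generator.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 110,
                          tissues = c("ileum", "colon", "rectum"),
                          diseases = c(HC = 0.25, UC = 0.375, CD = 0.375),
                          severity_levels = c("inactive", "mild", "moderate", "severe"),
                          n_batches = 4,
                          n_genes = 2000,
                          frac_lncRNA = 0.4,
                          n_modules = 6,
                          module_sizes = 150,
                          module_loading = 0.7,
                          trait_effects = NULL,
                          lnc_expression_shift = -2,
                          lnc_dispersion_mult = 2,
                          dropout_midpoint = 1,
                          dropout_slope = 1,
                          library_size_range = c(1e6, 2e6),
                          co_locate_modules = TRUE,
                          seed = 1L) {
  module_sizes <- rep_len(as.integer(module_sizes), n_modules)
  if (abs(sum(diseases) - 1) > 1e-8)
    stop("disease proportions must sum to 1")
  if (sum(module_sizes) > n_genes)
    stop("module_sizes sum (", sum(module_sizes), ") exceeds n_genes (", n_genes, ")")
  if (n_patients < 1 || n_genes < 1 || n_batches < 1)
    stop("counts must be positive")
  if (frac_lncRNA < 0 || frac_lncRNA > 1)
    stop("frac_lncRNA must be in [0, 1]")
  if (is.null(trait_effects)) {
    defaults <- list(c(inflamed = 1.0), c(active = 0.8), c(UC = 0.6),
                     c(CD = 0.6), c(rectum = 0.8), numeric(0))
    trait_effects <- rep_len(defaults, n_modules)
  }
  structure(list(
    n_patients = n_patients, tissues = tissues, diseases = diseases,
    severity_levels = severity_levels, n_batches = n_batches,
    n_genes = n_genes, frac_lncRNA = frac_lncRNA, n_modules = n_modules,
    module_sizes = module_sizes, module_loading = module_loading,
    trait_effects = trait_effects,
    lnc_expression_shift = lnc_expression_shift,
    lnc_dispersion_mult = lnc_dispersion_mult,
    dropout_midpoint = dropout_midpoint, dropout_slope = dropout_slope,
    library_size_range = library_size_range,
    co_locate_modules = co_locate_modules, seed = as.integer(seed)
  ), class = "cohort_config")
}

# synthetic genome: 5 chromosomes of 50 Mb, 0-based half-open coordinates
synthetic_chromosomes <- function() {
  setNames(rep(50e6, 5), paste0("chr", 1:5))
}

#' Generate a synthetic gut-biopsy cohort with planted coexpression modules
#'
#' Emulates a multi-tissue IBD biopsy cohort: HC patients contribute only
#' noninflamed biopsies; UC/CD patients contribute inflamed and noninflamed
#' biopsies across tissues, with per-patient severity and CRP linked to it.
#' Module eigengenes are driven by binary clinical traits, module genes load
#' on their eigengene, and counts follow a negative binomial with logistic
#' dropout. Gene lengths are log-uniform on 500-20,000 bp so raw-count and
#' TPM-based filters differ.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return A list with \code{annotation} (gene table, 0-based half-open
#'   coordinates), \code{samples} (per-biopsy metadata), \code{counts}
#'   (samples x genes integer matrix), and \code{truth} (planted module
#'   labels, eigengenes, and trait effects).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cfg <- config

  ## ---- samples ---------------------------------------------------------
  disease <- sample(names(cfg$diseases), cfg$n_patients, replace = TRUE,
                    prob = cfg$diseases)
  severity <- ifelse(disease == "HC", "inactive",
                     sample(cfg$severity_levels, cfg$n_patients, replace = TRUE,
                            prob = c(0.3, 0.3, 0.25, 0.15)))
  rows <- list()
  for (p in seq_len(cfg$n_patients)) {
    n_bx <- sample(1:6, 1)
    tis <- sample(cfg$tissues, n_bx, replace = TRUE)
    # HC biopsies are never inflamed; UC/CD biopsies are inflamed with
    # probability rising with severity
    p_inf <- switch(severity[p], inactive = 0.1, mild = 0.4,
                    moderate = 0.65, severe = 0.85)
    inf <- if (disease[p] == "HC") rep("no", n_bx)
           else ifelse(runif(n_bx) < p_inf, "yes", "no")
    rows[[p]] <- data.frame(
      patient = sprintf("P%03d", p), disease = disease[p],
      severity = severity[p], tissue = tis, inflamed = inf,
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  samples$batch <- sprintf("B%02d", sample.int(cfg$n_batches, nrow(samples),
                                               replace = TRUE))
  sev_num <- match(samples$severity, cfg$severity_levels) - 1
  samples$crp <- round(exp(rnorm(nrow(samples),
                                 mean = 0.5 + 0.6 * sev_num, sd = 0.6)), 2)
  rownames(samples) <- samples$sample_id
  samples <- samples[, c("sample_id", "patient", "disease", "tissue",
                         "inflamed", "severity", "batch", "crp")]
  n_samples <- nrow(samples)

  ## ---- annotation ------------------------------------------------------
  gene_id <- sprintf("G%05d", seq_len(cfg$n_genes))
  biotype <- ifelse(runif(cfg$n_genes) < cfg$frac_lncRNA,
                    "lncRNA", "protein_coding")
  length_bp <- round(exp(runif(cfg$n_genes, log(500), log(20000))))
  chroms <- synthetic_chromosomes()

  module_of <- rep("grey", cfg$n_genes)
  idx <- 1
  for (m in seq_len(cfg$n_modules)) {
    module_of[idx:(idx + cfg$module_sizes[m] - 1)] <- as.character(m)
    idx <- idx + cfg$module_sizes[m]
  }
  # shuffle gene order so module membership is not positional in the matrix
  ord <- sample.int(cfg$n_genes)
  module_of <- module_of[ord]

  chrom <- character(cfg$n_genes); start <- numeric(cfg$n_genes)
  if (cfg$co_locate_modules) {
    # each module gets a contiguous neighborhood; grey genes are scattered
    anchors_chr <- sample(names(chroms), cfg$n_modules, replace = TRUE)
    anchors_pos <- round(runif(cfg$n_modules, 1e6, 40e6))
    for (g in seq_len(cfg$n_genes)) {
      if (module_of[g] == "grey") {
        chrom[g] <- sample(names(chroms), 1)
        start[g] <- round(runif(1, 0, chroms[chrom[g]] - length_bp[g] - 1))
      } else {
        m <- as.integer(module_of[g])
        chrom[g] <- anchors_chr[m]
        start[g] <- anchors_pos[m] + round(runif(1, 0, 5e6))
      }
    }
  } else {
    chrom <- sample(names(chroms), cfg$n_genes, replace = TRUE)
    start <- round(runif(cfg$n_genes, 0, chroms[chrom] - 21000))
  }
  annotation <- data.frame(
    gene_id = gene_id, biotype = biotype, source = "synthetic",
    chrom = chrom, start = start, end = start + length_bp,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    length = length_bp, stringsAsFactors = FALSE)

  ## ---- expression ------------------------------------------------------
  trait_design <- cbind(
    inflamed = as.numeric(samples$inflamed == "yes"),
    active = as.numeric(samples$severity %in% c("moderate", "severe")),
    UC = as.numeric(samples$disease == "UC"),
    CD = as.numeric(samples$disease == "CD"),
    rectum = as.numeric(samples$tissue == "rectum"))

  eigengenes <- matrix(rnorm(n_samples * cfg$n_modules), n_samples,
                       dimnames = list(samples$sample_id,
                                       as.character(seq_len(cfg$n_modules))))
  for (m in seq_len(cfg$n_modules)) {
    eff <- cfg$trait_effects[[m]]
    for (tr in names(eff))
      eigengenes[, m] <- eigengenes[, m] + eff[[tr]] * trait_design[, tr]
  }

  baseline <- rnorm(cfg$n_genes, mean = 5, sd = 1.5) +
    ifelse(biotype == "lncRNA", cfg$lnc_expression_shift, 0)
  dispersion <- exp(rnorm(cfg$n_genes, log(0.15), 0.4)) *
    ifelse(biotype == "lncRNA", cfg$lnc_dispersion_mult, 1)

  # per-gene loadings jitter around the module loading so modules carry
  # hub structure (genes differ in membership strength), as real
  # coexpression modules do
  loading <- rep(0, cfg$n_genes)
  in_mod <- module_of != "grey"
  loading[in_mod] <- cfg$module_loading * runif(sum(in_mod), 0.6, 1.4)
  log_mean <- matrix(rep(baseline, each = n_samples), n_samples)
  for (m in seq_len(cfg$n_modules)) {
    in_m <- module_of == as.character(m)
    if (any(in_m))
      log_mean[, in_m] <- log_mean[, in_m] +
        rep(loading[in_m], each = n_samples) * eigengenes[, m]
  }

  lib_size <- runif(n_samples, cfg$library_size_range[1],
                    cfg$library_size_range[2])
  # expected reads proportional to expression x length, scaled per sample
  rate <- 2^log_mean * rep(length_bp / 1000, each = n_samples)
  mu <- rate / rowSums(rate) * lib_size
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = rep(1 / dispersion, each = n_samples)),
                   n_samples,
                   dimnames = list(samples$sample_id, gene_id))
  p_drop <- plogis(cfg$dropout_slope * (cfg$dropout_midpoint - log_mean))
  counts[runif(length(counts)) < p_drop] <- 0L
  storage.mode(counts) <- "integer"

  truth <- list(
    modules = setNames(module_of, gene_id),
    eigengenes = eigengenes,
    loadings = setNames(loading, gene_id),
    trait_effects = cfg$trait_effects,
    module_loading = cfg$module_loading)

  list(annotation = annotation, samples = samples, counts = counts,
       truth = truth, config = cfg)
}

#' Generate a synthetic GWAS SNP catalog with optional planted enrichment
#'
#' SNPs are placed uniformly on the synthetic chromosomes except for an
#' excess fraction forced to fall within the +/- 50 kb windows of genes
#' belonging to designated enriched modules. Each SNP is labeled UC-specific,
#' CD-specific, or shared.
#'
#' @param annotation gene annotation (as from \code{\link{generate_cohort}}).
#' @param enriched_modules character module labels receiving excess SNPs
#'   (must appear in \code{truth$modules}); may be empty.
#' @param truth planted truth from \code{\link{generate_cohort}}.
#' @param n_snps number of SNPs.
#' @param frac_uc,frac_cd,frac_shared label proportions (sum to 1).
#' @param excess_rate probability a SNP is planted inside an enriched
#'   module's gene windows rather than placed uniformly; 0 disables planting.
#' @param window half-window width in bp used for planting (matches the
#'   adjacency analysis default).
#' @param seed integer seed.
#' @return data.frame with snp_id, chrom, pos (0-based), disease_label.
#' @export
generate_snp_catalog <- function(annotation, enriched_modules = character(0),
                                 truth = NULL, n_snps = 300,
                                 frac_uc = 0.25, frac_cd = 0.25,
                                 frac_shared = 0.5, excess_rate = 0.5,
                                 window = 50000, seed = 1L) {
  if (abs(frac_uc + frac_cd + frac_shared - 1) > 1e-8)
    stop("label fractions must sum to 1")
  if (length(enriched_modules)) {
    if (is.null(truth)) stop("truth required when enriched_modules given")
    known <- unique(truth$modules)
    bad <- setdiff(enriched_modules, known)
    if (length(bad)) stop("unknown module label(s): ", paste(bad, collapse = ", "))
  }
  set.seed(seed)
  chroms <- synthetic_chromosomes()
  chrom <- sample(names(chroms), n_snps, replace = TRUE)
  pos <- floor(runif(n_snps, 0, chroms[chrom]))

  if (length(enriched_modules) && excess_rate > 0) {
    target_genes <- names(truth$modules)[truth$modules %in% enriched_modules]
    tg <- annotation[annotation$gene_id %in% target_genes, ]
    planted <- which(runif(n_snps) < excess_rate)
    if (length(planted) && nrow(tg)) {
      gi <- sample.int(nrow(tg), length(planted), replace = TRUE)
      lo <- pmax(0, tg$start[gi] - window)
      hi <- tg$end[gi] + window - 1
      chrom[planted] <- tg$chrom[gi]
      pos[planted] <- floor(runif(length(planted), lo, hi))
    }
  }
  data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    chrom = chrom, pos = pos,
    disease_label = sample(c("UC-specific", "CD-specific", "shared"),
                           n_snps, replace = TRUE,
                           prob = c(frac_uc, frac_cd, frac_shared)),
    stringsAsFactors = FALSE)
}

#' Generate synthetic pooled CRISPRa screen counts
#'
#' Simulates an sgRNA library (targeting guides plus intergenic controls)
#' sequenced in a pooled (presorted) population and in sorted TNF-alpha
#' bins. Pooled counts are multinomial over sgRNAs with lognormal base
#' abundances; sorted-bin abundances are shifted by the target gene's signed
#' log2 effect (positive regulators enrich in TNF-positive/high bins and
#' deplete in TNF-negative/low bins) plus guide-level noise.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene sgRNAs per gene (the library used ~6 per TSS).
#' @param n_controls number of intergenic control sgRNAs (zero effect).
#' @param regulators named numeric vector: signed log2 effects for a subset
#'   of genes (positive = activator of TNF-alpha).
#' @param bins sorted-bin labels; names containing "pos"/"hi" take the
#'   effect with positive sign, "neg"/"lo" with negative sign.
#' @param depth sequencing reads per condition.
#' @param guide_noise_sd sd of guide-level log2 noise around the gene effect.
#' @param seed integer seed.
#' @return data.frame: sgrna, gene (NA for controls), class, and one count
#'   column per condition (pooled first).
#' @export
generate_screen <- function(n_genes = 100, guides_per_gene = 6,
                            n_controls = 100, regulators = numeric(0),
                            bins = c("TNF_pos", "TNF_neg", "TNF_hi", "TNF_lo"),
                            depth = 1e6, guide_noise_sd = 0.25, seed = 1L) {
  if (depth <= 0) stop("zero depth")
  if (length(regulators) && guides_per_gene < 2)
    stop("guides_per_gene must be >= 2 when regulators are planted")
  set.seed(seed)
  genes <- sprintf("LNC%04d", seq_len(n_genes))
  guide_gene <- rep(genes, each = guides_per_gene)
  sgrna <- c(paste0(guide_gene, "_g", rep(seq_len(guides_per_gene), n_genes)),
             sprintf("CTRL%04d_g1", seq_len(n_controls)))
  gene <- c(guide_gene, rep(NA_character_, n_controls))
  class <- c(rep("targeting", n_genes * guides_per_gene),
             rep("intergenic_control", n_controls))
  n_guides <- length(sgrna)

  base_w <- exp(rnorm(n_guides, 0, 0.5))
  effect <- ifelse(is.na(gene), 0,
                   unname(ifelse(gene %in% names(regulators),
                                 regulators[gene], 0)))
  effect[is.na(effect)] <- 0
  guide_eff <- effect + ifelse(effect != 0, rnorm(n_guides, 0, guide_noise_sd), 0)

  out <- data.frame(sgrna = sgrna, gene = gene, class = class,
                    stringsAsFactors = FALSE)
  out$pooled <- as.integer(rmultinom(1, depth, base_w))
  bin_sign <- function(b) {
    if (grepl("pos|hi", b, ignore.case = TRUE)) 1
    else if (grepl("neg|lo", b, ignore.case = TRUE)) -1
    else 0
  }
  for (b in bins) {
    w <- base_w * 2^(bin_sign(b) * guide_eff)
    out[[b]] <- as.integer(rmultinom(1, depth, w))
  }
  out
}

#' Simulate one gene's log-expression under the zero-inflated Gaussian model
#'
#' A small parameter-recovery driver for the differential-expression model:
#' a two-group design with batch (and optional patient) random intercepts,
#' Gaussian noise on the positive part, and exact zeros inserted completely
#' at random with probability \code{pi0}.
#'
#' @param n samples; split evenly between two groups crossed with batches.
#' @param beta group effect (log2 units) on the continuous part.
#' @param sigma residual sd of the continuous part.
#' @param pi0 zero-inflation probability.
#' @param n_batches number of batches (crossed with group).
#' @param batch_sd sd of the batch random intercept.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return data.frame with y, group (factor, reference "ref"), batch.
#' @export
simulate_zig_gene <- function(n = 400, beta = 1, sigma = 1, pi0 = 0.3,
                              n_batches = 8, batch_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  group <- factor(rep(c("ref", "alt"), length.out = n), levels = c("ref", "alt"))
  batch <- factor(rep_len(rep(seq_len(n_batches), each = 2), n))
  b_eff <- rnorm(n_batches, 0, batch_sd)
  mu <- 4 + beta * (group == "alt") + b_eff[as.integer(batch)]
  y <- rnorm(n, mu, sigma)
  y[runif(n) < pi0] <- 0
  data.frame(y = y, group = group, batch = batch)
}
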