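#' Construct an expression matrix with sample metadata
#'
#' The container used throughout the pipeline: a samples x genes numeric
#' matrix with a declared scale and aligned per-sample metadata.
#'
#' @param values samples x genes numeric matrix with dimnames.
#' @param scale one of "counts", "TPM", "logTPM".
#' @param samples data.frame of per-sample metadata with a \code{sample_id}
#'   column (or rownames) matching \code{rownames(values)}.
#' @return list of class \code{expr_matrix} with elements \code{values},
#'   \code{scale}, \code{samples}.
#' @export
expression_matrix <- function(values, scale = c("counts", "TPM", "logTPM"),
                              samples = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample rownames and gene colnames")
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique")
  if (any(values < 0)) stop("negative expression values")
  if (is.null(samples))
    samples <- data.frame(sample_id = rownames(values),
                          stringsAsFactors = FALSE)
  if (is.null(samples$sample_id)) samples$sample_id <- rownames(samples)
  if (!all(rownames(values) %in% samples$sample_id))
    stop("metadata missing for some samples")
  samples <- samples[match(rownames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- samples$sample_id
  structure(list(values = values, scale = scale, samples = samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Threshold genes on raw read support within metadata groups
#'
#' A gene is retained if, in at least one group (default: disease
#' classification), strictly more than \code{min_reads} reads are observed
#' in at least \code{min_frac} of that group's libraries. Set
#' \code{require_all = TRUE} to demand the criterion in every group.
#'
#' @param counts \code{expr_matrix} on the counts scale.
#' @param min_reads read threshold (strict inequality).
#' @param min_frac fraction of group libraries that must exceed it (>=).
#' @param group_by metadata column defining the groups.
#' @param require_all pass in all groups instead of any group.
#' @param annotation optional annotation for the per-biotype retention report.
#' @return character vector of retained gene ids; per-biotype retention
#'   fractions (when annotation given) in \code{attr(, "biotype_retention")}.
#' @export
threshold_genes <- function(counts, min_reads = 10, min_frac = 0.40,
                            group_by = "disease", require_all = FALSE,
                            annotation = NULL) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$scale != "counts") stop("thresholding requires the counts scale")
  if (!group_by %in% names(counts$samples))
    stop("unknown group key: ", group_by)
  groups <- split(seq_len(nrow(counts$values)), counts$samples[[group_by]])
  pass <- vapply(groups, function(idx) {
    colMeans(counts$values[idx, , drop = FALSE] > min_reads) >= min_frac
  }, logical(ncol(counts$values)))
  keep <- if (require_all) rowSums(!pass) == 0 else rowSums(pass) > 0
  retained <- colnames(counts$values)[keep]
  if (!is.null(annotation)) {
    bt <- annotation$biotype[match(colnames(counts$values), annotation$gene_id)]
    attr(retained, "biotype_retention") <-
      tapply(keep, bt, mean)
  }
  retained
}

#' TPM-normalize counts over a retained gene set
#'
#' TPM is computed over the retained genes only: per sample, the
#' length-normalized read rate of each gene divided by the sample's total
#' rate, times 1e6. Rows of the result sum to 1e6.
#'
#' @param counts \code{expr_matrix} (counts scale).
#' @param lengths named vector of gene lengths in bp (> 0 for retained genes).
#' @param retained gene ids to keep (default: all).
#' @return \code{expr_matrix} on the TPM scale, restricted to retained genes.
#' @export
tpm_normalize <- function(counts, lengths, retained = NULL) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$scale != "counts") stop("tpm_normalize requires counts")
  retained <- retained %||% colnames(counts$values)
  m <- counts$values[, retained, drop = FALSE]
  len <- lengths[retained]
  if (any(is.na(len)) || any(len <= 0))
    stop("missing or nonpositive length for retained genes")
  rate <- sweep(m, 2, len / 1000, "/")
  total <- rowSums(rate)
  if (any(total == 0))
    stop("sample(s) with zero total rate: ",
         paste(rownames(m)[total == 0], collapse = ", "))
  tpm <- rate / total * 1e6
  expression_matrix(tpm, "TPM", counts$samples)
}

#' Log-transform TPM values
#'
#' The display and modeling scale of the pipeline: log2(TPM + 1). A
#' gene-wise median-centering variant (subtract each gene's median log
#' value) is available behind \code{center = TRUE}.
#'
#' @param tpm \code{expr_matrix} on the TPM scale.
#' @param center gene-wise median-center after transforming.
#' @return \code{expr_matrix} on the logTPM scale.
#' @export
log_transform <- function(tpm, center = FALSE) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$scale != "TPM") stop("log_transform requires TPM")
  if (any(tpm$values < 0)) stop("negative TPM values")
  lv <- log2(tpm$values + 1)
  if (center) lv <- sweep(lv, 2, apply(lv, 2, median), "-")
  out <- expression_matrix(pmax(lv, 0), "logTPM", tpm$samples)
  if (center) out$values <- lv  # centering may legitimately go negative
  out
}

#' Call tissue-specific genes
#'
#' A gene is specific to tissue T if its TPM exceeds \code{min_tpm}
#' (strictly) in at least \code{min_frac} of T's samples and fails that
#' criterion in every other tissue. The resulting per-tissue sets are
#' pairwise disjoint by construction.
#'
#' @param tpm \code{expr_matrix} (TPM scale) with a \code{tissue} metadata
#'   column.
#' @param min_tpm TPM threshold (strict).
#' @param min_frac fraction of tissue samples required (>=).
#' @return named list: tissue -> character vector of specific gene ids.
#' @export
tissue_specific_genes <- function(tpm, min_tpm = 0.5, min_frac = 0.30) {
  stopifnot(inherits(tpm, "expr_matrix"))
  tissues <- unique(tpm$samples$tissue)
  if (length(tissues) < 2) stop("need >= 2 tissues")
  passes <- vapply(tissues, function(t) {
    idx <- which(tpm$samples$tissue == t)
    colMeans(tpm$values[idx, , drop = FALSE] > min_tpm) >= min_frac
  }, logical(ncol(tpm$values)))
  out <- lapply(seq_along(tissues), function(i) {
    colnames(tpm$values)[passes[, i] & rowSums(passes[, -i, drop = FALSE]) == 0]
  })
  names(out) <- tissues
  out
}

#' Normalized standard deviation (coefficient of variation) per gene
#'
#' Standard deviation of expression divided by the gene's mean, on the
#' scale the matrix carries (use logTPM for parity with the network).
#' Genes with zero mean are excluded with a warning.
#'
#' @param expr \code{expr_matrix}.
#' @param genes gene ids to evaluate (default: all).
#' @return named numeric vector (sample sd / mean).
#' @export
normalized_sd <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- genes %||% colnames(expr$values)
  m <- expr$values[, genes, drop = FALSE]
  mu <- colMeans(m)
  bad <- mu == 0
  if (any(bad)) {
    warning(sum(bad), " zero-mean gene(s) excluded from normalized SD")
    m <- m[, !bad, drop = FALSE]; mu <- mu[!bad]
  }
  apply(m, 2, sd) / mu
}

#' Compare network statistics between biotypes
#'
#' The descriptive biotype contrasts of the module characterization:
#' a Kolmogorov-Smirnov test comparing the intramodular-connectivity
#' distributions of lncRNAs vs protein-coding genes, and two-sided t tests
#' of normalized SD and mean expression.
#'
#' @param expr \code{expr_matrix} (logTPM recommended).
#' @param annotation gene annotation covering the matrix columns.
#' @param kim optional named vector of intramodular connectivity.
#' @return list with \code{ks_kim} (statistic, p; NULL when \code{kim}
#'   missing), \code{t_normalized_sd}, \code{t_mean_expression}, and the
#'   per-biotype summary table.
#' @export
biotype_stats <- function(expr, annotation, kim = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  bt <- annotation$biotype[match(colnames(expr$values), annotation$gene_id)]
  if (length(unique(bt[!is.na(bt)])) < 2)
    stop("both biotypes must be present")
  is_lnc <- bt == "lncRNA"
  mu <- colMeans(expr$values)
  nsd <- suppressWarnings(normalized_sd(expr))
  nsd <- nsd[colnames(expr$values)]
  ks <- NULL
  if (!is.null(kim)) {
    kim <- kim[colnames(expr$values)]
    ok <- !is.na(kim)
    ks <- suppressWarnings(ks.test(kim[ok & is_lnc], kim[ok & !is_lnc]))
    ks <- list(statistic = unname(ks$statistic), p = ks$p.value)
  }
  tt <- function(x) {
    t <- t.test(x[is_lnc], x[!is_lnc])
    list(estimate_diff = unname(diff(rev(t$estimate))) * -1,
         mean_lncRNA = unname(t$estimate[1]),
         mean_protein_coding = unname(t$estimate[2]),
         p = t$p.value)
  }
  list(ks_kim = ks,
       t_normalized_sd = tt(nsd),
       t_mean_expression = tt(mu),
       summary = data.frame(
         biotype = c("lncRNA", "protein_coding"),
         n = c(sum(is_lnc), sum(!is_lnc)),
         mean_expression = c(mean(mu[is_lnc]), mean(mu[!is_lnc])),
         mean_normalized_sd = c(mean(nsd[is_lnc], na.rm = TRUE),
                                mean(nsd[!is_lnc], na.rm = TRUE))))
}
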