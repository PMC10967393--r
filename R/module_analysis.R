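#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' gene-standardized sample x gene submatrix, scaled to unit variance and
#' oriented to correlate positively with the module's average (standardized)
#' expression. The fraction of expression variance it explains is reported.
#'
#' @param expr \code{expr_matrix}.
#' @param assignment \code{module_assignment} (grey is skipped).
#' @return list of class \code{module_eigengenes}: \code{eigengenes}
#'   (samples x modules matrix), \code{var_explained}, \code{weights}
#'   (per-module named gene weight vectors, for projecting new samples).
#' @export
module_eigengenes <- function(expr, assignment) {
  stopifnot(inherits(expr, "expr_matrix"))
  labels <- assignment$modules
  mods <- setdiff(unique(labels), "grey")
  mods <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))
  me <- matrix(NA_real_, nrow(expr$values), length(mods),
               dimnames = list(rownames(expr$values), mods))
  varexp <- setNames(numeric(length(mods)), mods)
  weights <- vector("list", length(mods)); names(weights) <- mods
  for (m in mods) {
    genes <- names(labels)[labels == m]
    genes <- intersect(genes, colnames(expr$values))
    if (length(genes) < 2) stop("module ", m, " has < 2 genes")
    sub <- expr$values[, genes, drop = FALSE]
    sds <- apply(sub, 2, sd)
    if (all(sds == 0)) stop("module ", m, " is constant")
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " constant gene(s) in module ", m)
      sub <- sub[, sds > 0, drop = FALSE]; sds <- sds[sds > 0]
    }
    z <- scale(sub)
    sv <- svd(z, nu = 1, nv = 1)
    score <- sv$u[, 1]
    # orient so the eigengene tracks the module's average expression
    if (cor(score, rowMeans(z)) < 0) { score <- -score; sv$v <- -sv$v }
    me[, m] <- score / sd(score)
    varexp[m] <- sv$d[1]^2 / sum(sv$d^2)
    w <- sv$v[, 1] / sds  # weights applicable to centered raw expression
    weights[[m]] <- setNames(w, colnames(z))
  }
  structure(list(eigengenes = me, var_explained = varexp, weights = weights,
                 means = colMeans(expr$values)),
            class = "module_eigengenes")
}

#' Merge modules with similar eigengenes
#'
#' Average-linkage clustering of the eigengene dissimilarity
#' 1 - cor(ME_i, ME_j); clusters merging below \code{cut_height} are
#' combined, the merged module inheriting the larger constituent's label.
#' Eigengenes are recomputed for the merged assignment and the lineage
#' (old label -> new label) is recorded.
#'
#' @param expr \code{expr_matrix}.
#' @param assignment \code{module_assignment}.
#' @param eigengenes optional precomputed \code{module_eigengenes}.
#' @param cut_height dissimilarity below which modules merge.
#' @return list: \code{assignment} (merged), \code{eigengenes} (recomputed),
#'   \code{lineage} (named old -> new), \code{n_before}, \code{n_after}.
#' @export
merge_modules <- function(expr, assignment, eigengenes = NULL,
                          cut_height = 0.20) {
  if (is.null(eigengenes)) eigengenes <- module_eigengenes(expr, assignment)
  me <- eigengenes$eigengenes
  mods <- colnames(me)
  if (length(mods) < 2) {
    lineage <- setNames(mods, mods)
    return(list(assignment = assignment, eigengenes = eigengenes,
                lineage = lineage, n_before = length(mods),
                n_after = length(mods)))
  }
  diss <- 1 - cor(me)
  tree <- hclust(as.dist(diss), method = "average")
  cl <- cutree(tree, h = cut_height)
  sizes <- table(assignment$modules)
  lineage <- setNames(character(length(mods)), mods)
  for (g in unique(cl)) {
    members <- mods[cl == g]
    keep <- members[which.max(sizes[members])]
    lineage[members] <- keep
  }
  labels <- assignment$modules
  nz <- labels != "grey"
  labels[nz] <- lineage[labels[nz]]
  merged <- structure(list(modules = labels,
                           sizes = sort(table(labels), decreasing = TRUE),
                           dendrogram = assignment$dendrogram),
                      class = "module_assignment")
  list(assignment = merged,
       eigengenes = module_eigengenes(expr, merged),
       lineage = lineage, n_before = length(mods),
       n_after = length(unique(lineage)))
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene's expression with every module
#' eigengene. Constant genes yield missing values.
#'
#' @param expr \code{expr_matrix}.
#' @param eigengenes \code{module_eigengenes}.
#' @return genes x modules correlation matrix.
#' @export
module_kme <- function(expr, eigengenes) {
  me <- if (inherits(eigengenes, "module_eigengenes"))
    eigengenes$eigengenes else as.matrix(eigengenes)
  suppressWarnings(cor(expr$values, me))
}

#' Intramodular connectivity
#'
#' kIM_i = sum of adjacency from gene i to the other genes of its module.
#' Grey genes receive their connectivity within grey, flagged via the
#' \code{grey_is_module} attribute.
#'
#' @param net \code{coexpression_network}.
#' @param assignment \code{module_assignment}.
#' @return named per-gene numeric vector.
#' @export
intramodular_connectivity <- function(net, assignment) {
  labels <- assignment$modules[net$genes]
  kim <- setNames(numeric(length(net$genes)), net$genes)
  for (m in unique(labels)) {
    idx <- which(labels == m)
    if (length(idx) == 1) { kim[idx] <- 0; next }
    sub <- net$adjacency[idx, idx, drop = FALSE]
    kim[idx] <- rowSums(sub) - 1   # drop the unit diagonal
  }
  attr(kim, "grey_is_module") <- TRUE
  kim
}

#' Standard clinical trait contrasts for the cohort
#'
#' Binarized contrasts used for module-trait correlation: inflamed vs
#' noninflamed; rectum vs nonrectal colon (ileum missing); mild vs inactive;
#' active (moderate + severe) vs inactive; active vs mild; CD vs HC; UC vs
#' HC; UC vs CD; CRP as a continuous trait. Samples outside a contrast's
#' two arms are missing for that trait.
#'
#' @param samples cohort metadata data.frame.
#' @return samples x traits numeric matrix (0/1 or continuous, NA outside
#'   the contrast).
#' @export
clinical_traits <- function(samples) {
  bin <- function(pos, neg) {
    out <- rep(NA_real_, nrow(samples))
    out[pos] <- 1; out[neg] <- 0
    out
  }
  sev <- samples$severity
  active <- sev %in% c("moderate", "severe")
  traits <- cbind(
    inflamed = as.numeric(samples$inflamed == "yes"),
    rectum_vs_colon = bin(samples$tissue == "rectum", samples$tissue == "colon"),
    mild_vs_inactive = bin(sev == "mild", sev == "inactive"),
    active_vs_inactive = bin(active, sev == "inactive"),
    active_vs_mild = bin(active, sev == "mild"),
    CD_vs_HC = bin(samples$disease == "CD", samples$disease == "HC"),
    UC_vs_HC = bin(samples$disease == "UC", samples$disease == "HC"),
    UC_vs_CD = bin(samples$disease == "UC", samples$disease == "CD"),
    CRP = if ("crp" %in% names(samples)) samples$crp else NULL)
  rownames(traits) <- samples$sample_id
  traits
}

#' Module-trait correlation matrix
#'
#' Pearson correlation between each module eigengene and each trait,
#' pairwise-complete over samples, with two-sided asymptotic p-values and a
#' star annotation (* p < 0.05, ** p < 0.01, *** p < 0.001). Raw p-values
#' are reported without multiplicity adjustment, matching the conventional
#' module-trait heatmap annotation.
#'
#' @param eigengenes \code{module_eigengenes}.
#' @param traits samples x traits matrix (see \code{\link{clinical_traits}}).
#' @return list of matrices \code{r}, \code{p}, \code{stars} and a long-form
#'   data.frame \code{table}.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  me <- eigengenes$eigengenes
  traits <- as.matrix(traits)[rownames(me), , drop = FALSE]
  nmod <- ncol(me); ntr <- ncol(traits)
  r <- p <- matrix(NA_real_, nmod, ntr,
                   dimnames = list(colnames(me), colnames(traits)))
  for (j in seq_len(ntr)) {
    ok <- !is.na(traits[, j])
    n <- sum(ok)
    if (n < 3) next
    if (sd(traits[ok, j]) == 0) next
    r[, j] <- cor(me[ok, , drop = FALSE], traits[ok, j])
    tstat <- r[, j] * sqrt((n - 2) / pmax(1 - r[, j]^2, .Machine$double.eps))
    p[, j] <- 2 * pt(-abs(tstat), df = n - 2)
  }
  stars <- matrix(star_annotation(p), nmod, ntr, dimnames = dimnames(p))
  tab <- data.frame(module = rep(rownames(r), ntr),
                    trait = rep(colnames(r), each = nmod),
                    r = as.vector(r), p = as.vector(p),
                    stars = as.vector(stars), stringsAsFactors = FALSE)
  list(r = r, p = p, stars = stars, table = tab)
}

#' Gene-trait significance
#'
#' Pearson correlation of each gene's expression with a trait vector,
#' pairwise-complete; constant genes are missing.
#'
#' @param expr \code{expr_matrix}.
#' @param trait numeric per-sample vector (NA allowed).
#' @return named per-gene correlation vector.
#' @export
gene_trait_significance <- function(expr, trait) {
  stopifnot(inherits(expr, "expr_matrix"))
  ok <- !is.na(trait)
  if (sum(ok) < 3) stop("trait needs >= 3 non-missing samples")
  suppressWarnings(drop(cor(expr$values[ok, , drop = FALSE], trait[ok])))
}

#' Module biotype composition and lncRNA-coding proximity
#'
#' Per module: the fraction of lncRNA genes, and the fraction of the
#' module's lncRNAs whose gene body extended by \code{window} bp on each
#' side overlaps the body of a protein-coding gene of the same module
#' (0-based half-open intervals).
#'
#' @param assignment \code{module_assignment}.
#' @param annotation gene annotation with coordinates.
#' @param window half-window in bp (default 50 kb).
#' @param include_grey include the grey pseudo-module.
#' @return data.frame: module, size, n_lncRNA, frac_lncRNA, frac_lnc_proximal.
#' @export
module_composition <- function(assignment, annotation, window = 50000,
                               include_grey = FALSE) {
  labels <- assignment$modules
  ann <- annotation[match(names(labels), annotation$gene_id), ]
  mods <- setdiff(unique(labels), if (include_grey) character(0) else "grey")
  rows <- lapply(mods, function(m) {
    idx <- which(labels == m)
    a <- ann[idx, ]
    lnc <- a[a$biotype == "lncRNA", ]
    pc <- a[a$biotype == "protein_coding", ]
    prox <- NA_real_
    if (nrow(lnc)) {
      if (nrow(pc)) {
        lv <- union(unique(lnc$chrom), unique(pc$chrom))
        lr <- GenomicRanges::GRanges(factor(lnc$chrom, lv),
          IRanges::IRanges(pmax(0, lnc$start - window) + 1, lnc$end + window))
        pr <- GenomicRanges::GRanges(factor(pc$chrom, lv),
          IRanges::IRanges(pc$start + 1, pc$end))
        prox <- mean(IRanges::overlapsAny(lr, pr))
      } else prox <- 0
    }
    data.frame(module = m, size = length(idx), n_lncRNA = nrow(lnc),
               frac_lncRNA = nrow(lnc) / length(idx),
               frac_lnc_proximal = prox, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(module = character(0), size = integer(0),
                      n_lncRNA = integer(0), frac_lncRNA = numeric(0),
                      frac_lnc_proximal = numeric(0)))
  out[order(-out$size), ]
}
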