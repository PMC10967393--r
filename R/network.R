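#' Regress covariates out of an expression matrix
#'
#' Per gene, replaces the expression profile by the residuals of a linear
#' regression on the covariate design, re-centered to the gene's original
#' mean. Used before network construction so modules are not driven by
#' batch or other nuisance structure.
#'
#' @param expr \code{expr_matrix} (logTPM).
#' @param covariates metadata column names to regress out.
#' @return residualized \code{expr_matrix} (same scale label).
#' @export
regress_covariates <- function(expr, covariates) {
  stopifnot(inherits(expr, "expr_matrix"))
  missing <- setdiff(covariates, names(expr$samples))
  if (length(missing)) stop("covariate(s) absent: ", paste(missing, collapse = ", "))
  X <- model.matrix(stats::as.formula(
    paste("~", paste(covariates, collapse = " + "))), expr$samples)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  fitted <- X %*% qr.coef(qrX, expr$values)
  resid <- expr$values - fitted
  resid <- sweep(resid, 2, colMeans(expr$values), "+")
  out <- expr
  out$values <- resid
  out
}

#' Choose the soft-threshold power for approximate scale-free topology
#'
#' For each candidate power, connectivity k is computed from the unsigned
#' adjacency |r|^beta and the scale-free fit index is the squared
#' correlation between log10 p(k) and log10 k over connectivity-histogram
#' bins, signed negative when the slope is positive. Returns the smallest
#' power whose fit reaches \code{r2_target}, with the full diagnostic table.
#'
#' @param expr \code{expr_matrix} (>= 20 samples) or a genes-correlation
#'   matrix supplied via \code{cor_matrix}.
#' @param candidate_powers integer powers to scan.
#' @param r2_target scale-free fit threshold.
#' @param n_bins connectivity histogram bins.
#' @param cor_matrix optional precomputed gene correlation matrix.
#' @return list: \code{power} (NA when no candidate reaches the target --
#'   callers may force one, the study's network used 8), \code{table}
#'   (power, r2, slope, mean_k, median_k), \code{flag}.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:20,
                                r2_target = 0.80, n_bins = 10,
                                cor_matrix = NULL) {
  if (is.null(cor_matrix)) {
    stopifnot(inherits(expr, "expr_matrix"))
    if (nrow(expr$values) < 20) stop("need >= 20 samples")
    cor_matrix <- cor(expr$values)
  }
  absr <- abs(cor_matrix); diag(absr) <- 0
  rows <- lapply(candidate_powers, function(beta) {
    k <- rowSums(absr^beta)
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = beta, r2 = fit$r2, slope = fit$slope,
               mean_k = mean(k), median_k = median(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$r2 >= r2_target)
  flag <- if (sd(tab$mean_k) == 0 || all(is.na(tab$r2)))
    "degenerate connectivity distribution" else NA_character_
  list(power = if (length(ok)) tab$power[min(ok)] else NA_integer_,
       table = tab,
       flag = if (!length(ok) && is.na(flag)) "no power reaches r2_target"
              else flag)
}

# signed scale-free model fit: R^2 of log10 p(k) ~ log10 k over bins,
# negated when the slope is positive (scale-free topology needs a
# decreasing degree distribution)
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3 || diff(range(k)) < 1e-8)
    return(list(r2 = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kc <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & !is.na(kc) & kc > 0
  if (sum(ok) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  x <- log10(kc[ok]); y <- log10(pk[ok])
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2])
  list(r2 = if (slope > 0) -r2 else r2, slope = slope)
}

#' Build the unsigned weighted coexpression network
#'
#' Pearson correlation over samples, unsigned soft-thresholded adjacency
#' a_ij = |r_ij|^beta (signed variant ((1 + r)/2)^beta behind
#' \code{type = "signed"}), and connectivity k_i = sum of off-diagonal
#' adjacency. Constant genes have undefined correlation and are dropped
#' with a warning.
#'
#' @param expr \code{expr_matrix}.
#' @param beta soft-threshold power (>= 1).
#' @param type "unsigned" (default) or "signed".
#' @return list of class \code{coexpression_network}: gene ids, \code{cor},
#'   \code{adjacency}, \code{k}, \code{beta}, \code{type}.
#' @export
build_network <- function(expr, beta = 8, type = c("unsigned", "signed")) {
  stopifnot(inherits(expr, "expr_matrix"), beta >= 1)
  type <- match.arg(type)
  v <- expr$values
  constant <- apply(v, 2, sd) == 0
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant gene(s)")
    v <- v[, !constant, drop = FALSE]
  }
  r <- cor(v)
  a <- if (type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  structure(list(genes = colnames(v), cor = r, adjacency = a,
                 k = rowSums(a) - 1, beta = beta, type = type,
                 n_samples = nrow(v)),
            class = "coexpression_network")
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j, where
#' L_ij sums the shared-neighbor adjacency products over all other nodes;
#' TOM_ii = 1 by convention. Computed by matrix multiplication; a test
#' checks it against a brute-force triple loop.
#'
#' @param net \code{coexpression_network} (or a plain adjacency matrix).
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(net) {
  a <- if (inherits(net, "coexpression_network")) net$adjacency else as.matrix(net)
  diag(a) <- 0
  L <- a %*% a                     # L_ij = sum_u a_iu a_uj (u != i,j after diag(a)=0)
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect coexpression modules by size-adaptive tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' d = 1 - TOM, followed by a deterministic, size-adaptive branch
#' decomposition: every dendrogram branch of at least
#' \code{min_module_size} genes is scored by its persistence -- how long it
#' survives intact, measured as branch size times the gap between the
#' height at which the branch completes and the height at which it merges
#' into its parent, on the -log(1 - h) scale -- and a branch becomes a
#' module when its persistence exceeds the combined persistence of the best
#' decomposition of its sub-branches. Genes outside every selected branch
#' go to "grey". A plain static cut at an absolute height is available via
#' \code{cut_method = "static"}. Modules are labeled from a fixed ordered
#' color palette, largest module first; "grey" is reserved for unassigned
#' genes.
#'
#' Soft-thresholded TOM dissimilarities concentrate just below 1, so
#' absolute cut heights are fragile; the log-scale persistence criterion
#' uses only the tree shape near each branch and needs no height
#' threshold.
#'
#' @param dissimilarity symmetric matrix in [0, 1] (1 - TOM), or a
#'   \code{coexpression_network} whose TOM is computed on the fly.
#' @param min_module_size smallest branch kept as a module.
#' @param cut_method "adaptive" (default) or "static".
#' @param cut_height absolute cut height for \code{cut_method = "static"}.
#' @param cor_matrix optional gene correlation matrix (taken from the
#'   network when one is passed). When available, candidate modules whose
#'   median absolute within-branch correlation falls below
#'   \code{min_median_cor} are rejected (sent to grey): with thousands of
#'   genes, average-linkage trees over near-independent genes produce
#'   chance branches above the minimum size, and those chaining artifacts
#'   carry no real coexpression.
#' @param min_median_cor minimum median |r| within an accepted module;
#'   NULL (default) sets it to 2.5x the expected median absolute null
#'   correlation, 2.5 x 0.6745/sqrt(n_samples), falling back to 0.1 when
#'   the sample count is unknown.
#' @param n_samples samples behind \code{cor_matrix} (taken from the
#'   network when one is passed); drives the adaptive filter level.
#' @return list of class \code{module_assignment}: \code{modules} (named
#'   gene -> label), \code{sizes}, \code{dendrogram} (hclust).
#' @export
detect_modules <- function(dissimilarity, min_module_size = 30,
                           cut_method = c("adaptive", "static"),
                           cut_height = 0.99, cor_matrix = NULL,
                           min_median_cor = NULL, n_samples = NULL) {
  cut_method <- match.arg(cut_method)
  if (inherits(dissimilarity, "coexpression_network")) {
    cor_matrix <- cor_matrix %||% dissimilarity$cor
    n_samples <- n_samples %||% dissimilarity$n_samples
    dissimilarity <- 1 - tom_similarity(dissimilarity)
  }
  if (is.null(min_median_cor))
    min_median_cor <- if (!is.null(n_samples))
      2.5 * 0.6745 / sqrt(n_samples) else 0.1
  d <- as.matrix(dissimilarity)
  stopifnot(isSymmetric(unname(d), tol = 1e-8))
  genes <- colnames(d) %||% paste0("g", seq_len(ncol(d)))
  if (ncol(d) < min_module_size) {
    labels <- setNames(rep("grey", ncol(d)), genes)
    return(structure(list(modules = labels,
                          sizes = table(labels), dendrogram = NULL),
                     class = "module_assignment"))
  }
  tree <- hclust(as.dist(d), method = "average")
  cm_ordered <- if (!is.null(cor_matrix)) cor_matrix[genes, genes]
  raw <- if (cut_method == "static") cutree(tree, h = cut_height)
         else adaptive_tree_cut(tree, min_module_size, cm_ordered,
                                min_median_cor)
  if (!is.null(cor_matrix)) {
    cm <- abs(cor_matrix[genes, genes])
    for (lab in setdiff(unique(raw), 0)) {
      idx <- which(raw == lab)
      if (length(idx) < 2) next
      # prune weakly attached members first (chained-in background
      # genes): a gene must correlate with the rest of its module at the
      # same level the module itself must reach
      repeat {
        sub <- cm[idx, idx]
        attach_ <- (rowSums(sub) - 1) / (length(idx) - 1)
        weak <- attach_ < min_median_cor
        if (!any(weak) || all(weak)) break
        raw[idx[weak]] <- 0L
        idx <- idx[!weak]
        if (length(idx) < 2) break
      }
      if (length(idx) < 2) { raw[idx] <- 0L; next }
      sub <- cm[idx, idx]
      if (median(sub[upper.tri(sub)]) < min_median_cor) raw[idx] <- 0L
    }
  }
  sizes <- table(raw[raw != 0])
  keep <- names(sizes)[sizes >= min_module_size]
  ord <- keep[order(-sizes[keep])]
  labels <- setNames(rep("grey", length(genes)), genes)
  pal <- module_labels_for(length(ord))
  for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- pal[i]
  structure(list(modules = labels,
                 sizes = sort(table(labels), decreasing = TRUE),
                 dendrogram = tree),
            class = "module_assignment")
}

# Persistence-guided cluster selection on an hclust tree, following the
# condensed-tree idea of density-based clustering: a merge where only one
# side holds at least min_size leaves is not a split but the continuation
# of that side's cluster (the small side "chains in"), while a merge of
# two >= min_size sides is a true split where both child clusters die.
# Each candidate cluster is born at its core (the node below which no
# single >= min_size side continues) and its persistence is core size x
# (death height - birth height), on the raw dissimilarity scale so the
# crowded near-1 region where unrelated genes chain together carries
# little weight. An excess-of-mass dynamic program keeps a cluster when
# its persistence beats the best selection among its descendants. A
# cluster is only eligible when the mean |correlation| over its core
# pairs reaches min_cor, so chained mixtures of background genes never
# outcompete genuine modules. Returns integer labels (a cluster's label
# covers everything chained in below its death; callers prune weak
# attachments); 0 = grey.
adaptive_tree_cut <- function(tree, min_size, cor_matrix = NULL,
                              min_cor = 0) {
  n <- length(tree$order)
  m <- tree$merge
  if (is.null(m) || nrow(m) == 0) return(rep(1L, n))
  u <- tree$height

  n_nodes <- nrow(m)
  size <- integer(n_nodes)
  members <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    kids <- m[i, ]
    mem_k <- lapply(kids, function(k) if (k < 0) -k else members[[k]])
    members[[i]] <- c(mem_k[[1]], mem_k[[2]])
    size[i] <- length(members[[i]])
  }
  node_size <- function(k) if (k < 0) 1L else size[k]
  have_cor <- !is.null(cor_matrix)
  if (have_cor) cm <- abs(cor_matrix)

  ## condense: candidate clusters from root downward
  clusters <- list()
  # stack entries: c(top_node, death_u, parent_cluster_index)
  stack <- list(list(top = n_nodes, death = u[n_nodes], parent = 0L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    cur <- fr$top
    repeat {
      kids <- m[cur, ]
      big <- kids[vapply(kids, node_size, 0L) >= min_size]
      big <- big[big > 0]   # leaves can never reach min_size (min_size >= 2)
      if (length(big) == 1) { cur <- big } else break
    }
    core <- members[[cur]]
    eligible <- length(core) >= min_size
    if (eligible && have_cor) {
      sub <- cm[core, core]
      eligible <- mean(sub[upper.tri(sub)]) >= min_cor
    }
    if (eligible && have_cor) {
      # separability check: when the core itself is a split of two
      # >= min_size halves whose cross-correlation is much weaker than
      # their internal correlation, the cluster is a union of distinct
      # modules and must defer to its children
      kk <- m[cur, ]
      bigk <- kk[vapply(kk, node_size, 0L) >= min_size]; bigk <- bigk[bigk > 0]
      if (length(bigk) == 2) {
        a <- members[[bigk[1]]]; b <- members[[bigk[2]]]
        wa <- cm[a, a]; wb <- cm[b, b]
        within <- mean(c(wa[upper.tri(wa)], wb[upper.tri(wb)]))
        cross <- mean(cm[a, b])
        if (cross < 0.5 * within) eligible <- FALSE
      }
    }
    # membership excludes genes chaining in at the death height itself
    # (they belong to the merged parent, not this cluster)
    emit_node <- fr$top
    while (u[emit_node] >= fr$death) {
      kk <- m[emit_node, ]
      bigk <- kk[vapply(kk, node_size, 0L) >= min_size]; bigk <- bigk[bigk > 0]
      if (length(bigk) != 1) break
      emit_node <- bigk
    }
    idx <- length(clusters) + 1L
    clusters[[idx]] <- list(
      top = emit_node, bottom = cur, parent = fr$parent,
      own = if (eligible) length(core) * (fr$death - u[cur]) else 0)
    kids <- m[cur, ]
    big <- kids[vapply(kids, node_size, 0L) >= min_size]
    big <- big[big > 0]
    if (length(big) == 2) {
      stack[[length(stack) + 1L]] <- list(top = big[1], death = u[cur],
                                          parent = idx)
      stack[[length(stack) + 1L]] <- list(top = big[2], death = u[cur],
                                          parent = idx)
    }
  }

  ## excess-of-mass selection over the cluster tree (children appear
  ## after parents in `clusters`, so iterate in reverse)
  nc <- length(clusters)
  value <- numeric(nc); take <- logical(nc)
  child_sum <- numeric(nc)
  for (i in rev(seq_len(nc))) {
    own <- clusters[[i]]$own
    take[i] <- own > child_sum[i]
    value[i] <- max(own, child_sum[i])
    p <- clusters[[i]]$parent
    if (p > 0) child_sum[p] <- child_sum[p] + value[i]
  }

  labels <- integer(n)
  next_label <- 0L
  emit <- function(i) {
    next_label <<- next_label + 1L
    labels[members[[clusters[[i]]$top]]] <<- next_label
  }
  # assign top-down; a taken cluster masks its descendants
  taken_under <- logical(nc)
  for (i in seq_len(nc)) {
    p <- clusters[[i]]$parent
    masked <- p > 0 && (taken_under[p])
    taken_under[i] <- masked || take[i]
    if (take[i] && !masked) emit(i)
  }
  labels
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d genes, %d modules (+ grey)\n",
              length(x$modules), sum(names(x$sizes) != "grey")))
  invisible(x)
}
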