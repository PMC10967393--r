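#' Stratified train/test split of cohort samples
#'
#' Per stratum (default: disease severity), floor(frac_train x n) samples go
#' to the training set, with largest-remainder rounding so the overall
#' train fraction is as close as possible to the target. Singleton strata go
#' to train with a warning. The report carries the stratum distribution
#' tables and, when an expression matrix is supplied, the per-gene
#' train-vs-test mean-expression correlation with fitted slope.
#'
#' @param samples cohort metadata.
#' @param frac_train training fraction.
#' @param strata metadata column to stratify on.
#' @param seed integer seed.
#' @param expr optional \code{expr_matrix} for the mean-expression report.
#' @return list: \code{train}, \code{test} (sample ids), \code{report}.
#' @export
stratified_split <- function(samples, frac_train = 0.70, strata = "severity",
                             seed = 1L, expr = NULL) {
  if (!strata %in% names(samples)) stop("stratum column absent: ", strata)
  set.seed(seed)
  ids <- split(samples$sample_id, samples[[strata]])
  sizes <- lengths(ids)
  raw <- frac_train * sizes
  n_train <- floor(raw)
  # largest-remainder: top up strata with the biggest fractional parts
  deficit <- round(frac_train * sum(sizes)) - sum(n_train)
  if (deficit > 0) {
    ord <- order(raw - n_train, decreasing = TRUE)
    top <- ord[seq_len(min(deficit, length(ord)))]
    n_train[top] <- pmin(n_train[top] + 1, sizes[top])
  }
  train <- character(0)
  for (s in names(ids)) {
    if (sizes[s] == 1) {
      warning("stratum '", s, "' has a single sample; assigned to train")
      train <- c(train, ids[[s]])
    } else {
      train <- c(train, sample(ids[[s]], n_train[s]))
    }
  }
  test <- setdiff(samples$sample_id, train)
  report <- list(
    strata_table = table(samples[[strata]],
                         ifelse(samples$sample_id %in% train, "train", "test")))
  if (!is.null(expr)) {
    mu_tr <- colMeans(expr$values[train, , drop = FALSE])
    mu_te <- colMeans(expr$values[test, , drop = FALSE])
    fit <- lm(mu_te ~ mu_tr)
    report$mean_expression <- list(r = cor(mu_tr, mu_te),
                                   slope = unname(coef(fit)[2]),
                                   intercept = unname(coef(fit)[1]))
  }
  list(train = sort(train), test = sort(test), report = report)
}

#' Cross-set module membership
#'
#' Projects test samples onto the training set's eigengene weight vectors
#' (applied to centered test expression) and correlates each test-set gene
#' with the projected eigengenes. On the training data itself this
#' reproduces the training kME.
#'
#' @param expr test-set \code{expr_matrix}.
#' @param train_eigengenes \code{module_eigengenes} fit on the training set.
#' @return genes x modules kME matrix; number of weight genes missing from
#'   the test matrix in \code{attr(, "n_missing")}.
#' @export
cross_kme <- function(expr, train_eigengenes) {
  stopifnot(inherits(train_eigengenes, "module_eigengenes"))
  w <- train_eigengenes$weights
  n_missing <- 0
  proj <- sapply(names(w), function(m) {
    genes <- intersect(names(w[[m]]), colnames(expr$values))
    n_missing <<- n_missing + (length(w[[m]]) - length(genes))
    centered <- sweep(expr$values[, genes, drop = FALSE], 2,
                      colMeans(expr$values[, genes, drop = FALSE]), "-")
    drop(centered %*% w[[m]][genes])
  })
  out <- suppressWarnings(cor(expr$values, proj))
  attr(out, "n_missing") <- n_missing
  out
}

#' Permutation Zsummary module preservation
#'
#' Measures whether reference modules replicate in a test dataset. Observed
#' per-module statistics in the test network: density (mean within-module
#' adjacency) and three connectivity concordances (cor of intramodular
#' connectivity, cor of kME, cor of within-module adjacency between
#' reference and test). The permutation null reassigns each module label to
#' a random same-size gene set; Z = (obs - mean_perm)/sd_perm,
#' Zconnectivity = median of the three connectivity Zs, and
#' Zsummary = (Zdensity + Zconnectivity)/2. Modules with Zsummary > 10 are
#' highly preserved, 5-10 moderately, < 5 weakly.
#'
#' A connectivity statistic whose permutation distribution is degenerate
#' (zero spread with the observed value sitting on the point mass, as
#' happens for the cross-network correlations when test and reference are
#' the same data: every gene set scores exactly 1) carries no information
#' and is excluded from the composite; if all three are degenerate,
#' Zsummary reduces to Zdensity.
#'
#' @param ref_expr,test_expr \code{expr_matrix} objects over the same genes.
#' @param assignment reference \code{module_assignment} (grey excluded).
#' @param beta soft power for both networks.
#' @param n_permutations permutation draws for the null.
#' @param seed integer seed.
#' @return data.frame of class \code{preservation_report}: module, size,
#'   Zdensity, Zconnectivity, Zsummary, classification.
#' @export
module_zsummary <- function(ref_expr, test_expr, assignment, beta = 8,
                            n_permutations = 200, seed = 1L) {
  set.seed(seed)
  genes <- intersect(colnames(ref_expr$values), colnames(test_expr$values))
  labels <- assignment$modules[genes]
  a_ref <- abs(cor(ref_expr$values[, genes]))^beta
  a_test <- abs(cor(test_expr$values[, genes]))^beta
  diag(a_ref) <- diag(a_test) <- 0
  z_ref <- scale(ref_expr$values[, genes])
  z_test <- scale(test_expr$values[, genes])
  n <- length(genes)

  stats_for <- function(idx) {
    sr <- a_ref[idx, idx]; st <- a_test[idx, idx]
    off <- upper.tri(sr)
    me_r <- module_score(z_ref[, idx, drop = FALSE])
    me_t <- module_score(z_test[, idx, drop = FALSE])
    kme_r <- drop(cor(z_ref[, idx], me_r))
    kme_t <- drop(cor(z_test[, idx], me_t))
    c(density = mean(st[off]),
      cor_kim = cor(rowSums(sr), rowSums(st)),
      cor_kme = cor(kme_r, kme_t),
      cor_adj = cor(sr[off], st[off]))
  }

  mods <- setdiff(unique(labels), "grey")
  rows <- lapply(mods, function(m) {
    idx <- which(labels == m)
    if (length(idx) < 3) return(NULL)
    obs <- stats_for(idx)
    perm <- vapply(seq_len(n_permutations), function(i)
      stats_for(sample.int(n, length(idx))), obs)
    mu <- rowMeans(perm); sdev <- apply(perm, 1, sd)
    degenerate <- sdev < 1e-12 & abs(obs - mu) < 1e-10
    z <- (obs - mu) / pmax(sdev, .Machine$double.eps)
    zden <- z["density"]
    con_stats <- setdiff(c("cor_kim", "cor_kme", "cor_adj"),
                         names(which(degenerate)))
    zcon <- if (length(con_stats)) median(z[con_stats]) else NA_real_
    zsum <- if (is.na(zcon)) unname(zden) else unname((zden + zcon) / 2)
    data.frame(module = m, size = length(idx),
               Zdensity = unname(zden), Zconnectivity = unname(zcon),
               Zsummary = zsum,
               classification = if (zsum > 10) "high"
                                else if (zsum >= 5) "moderate" else "low",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module = character(0), size = integer(0),
                      Zdensity = numeric(0), Zconnectivity = numeric(0),
                      Zsummary = numeric(0), classification = character(0),
                      stringsAsFactors = FALSE)
  class(out) <- c("preservation_report", "data.frame")
  out
}

# first principal component score of an already-standardized submatrix,
# oriented along mean expression (lightweight eigengene for permutations)
module_score <- function(z) {
  sv <- svd(z, nu = 1, nv = 0)
  s <- sv$u[, 1]
  if (cor(s, rowMeans(z)) < 0) s <- -s
  s
}

#' Betweenness-centrality overlap between two networks
#'
#' Builds unweighted graphs with an edge wherever TOM >= threshold,
#' computes betweenness centrality per node, marks the top quantile
#' (default: top quartile) per network as high-influence, and reports the
#' overlap fraction |top_a intersect top_b| / |top_a| per biotype.
#'
#' @param tom_a,tom_b TOM matrices over a shared gene universe.
#' @param edge_threshold minimum TOM for an edge.
#' @param quantile_cut quantile defining "high influence" (0.75 = top
#'   quartile).
#' @param annotation optional annotation for per-biotype results.
#' @return list: \code{overlap} (overall fraction), \code{by_biotype},
#'   \code{bc_a}, \code{bc_b}.
#' @export
bc_overlap <- function(tom_a, tom_b, edge_threshold, quantile_cut = 0.75,
                       annotation = NULL) {
  genes <- intersect(colnames(tom_a), colnames(tom_b))
  bc <- function(tm) {
    adj <- (tm[genes, genes] >= edge_threshold) * 1
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::betweenness(g, directed = FALSE)
  }
  bc_a <- bc(tom_a); bc_b <- bc(tom_b)
  top <- function(x) names(x)[x >= quantile(x, quantile_cut)]
  top_a <- top(bc_a); top_b <- top(bc_b)
  overall <- length(intersect(top_a, top_b)) / max(length(top_a), 1)
  by_bt <- NULL
  if (!is.null(annotation)) {
    bt <- setNames(annotation$biotype, annotation$gene_id)[genes]
    by_bt <- vapply(unique(bt), function(b) {
      ta <- intersect(top_a, genes[bt == b])
      tb <- intersect(top_b, genes[bt == b])
      if (!length(ta)) return(NA_real_)
      length(intersect(ta, tb)) / length(ta)
    }, 0)
  }
  list(overlap = overall, by_biotype = by_bt, bc_a = bc_a, bc_b = bc_b)
}
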