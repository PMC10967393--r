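#' Extract a lncRNA-centered hub network from one module
#'
#' Keeps intra-module edges with TOM at or above the threshold, then
#' retains every lncRNA node plus each lncRNA's directly connected
#' neighbors. Node degree (unweighted, on the retained subgraph) doubles as
#' the display size attribute; the top-degree nodes are the module hubs.
#'
#' @param tom TOM matrix.
#' @param assignment \code{module_assignment}.
#' @param module module label.
#' @param annotation gene annotation (biotype).
#' @param threshold minimum TOM edge weight.
#' @return list of class \code{module_graph}: \code{nodes} (gene, biotype,
#'   degree, in data.frame form), \code{edges} (from, to, weight),
#'   \code{threshold}.
#' @export
hub_network <- function(tom, assignment, module, annotation, threshold = 0.01) {
  labels <- assignment$modules
  if (!module %in% labels) stop("module not found: ", module)
  genes <- intersect(names(labels)[labels == module], colnames(tom))
  sub <- tom[genes, genes, drop = FALSE]
  diag(sub) <- 0
  keep_edge <- sub >= threshold & upper.tri(sub)
  if (!any(keep_edge)) {
    warning("threshold removes all edges in module ", module)
    return(structure(list(nodes = data.frame(), edges = data.frame(),
                          threshold = threshold), class = "module_graph"))
  }
  idx <- which(keep_edge, arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                      weight = sub[keep_edge], stringsAsFactors = FALSE)
  bt <- setNames(annotation$biotype, annotation$gene_id)
  lnc <- genes[bt[genes] == "lncRNA"]
  neigh <- unique(c(edges$from[edges$to %in% lnc],
                    edges$to[edges$from %in% lnc]))
  nodes_keep <- union(lnc, neigh)
  edges <- edges[edges$from %in% nodes_keep & edges$to %in% nodes_keep, ]
  deg <- table(factor(c(edges$from, edges$to), levels = nodes_keep))
  nodes <- data.frame(gene_id = nodes_keep,
                      biotype = unname(bt[nodes_keep]),
                      degree = as.integer(deg[nodes_keep]),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$degree, nodes$gene_id), ]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "module_graph")
}

#' Export a module graph as GraphML and edge-list TSV
#'
#' @param graph \code{module_graph}.
#' @param graphml_path,edges_path output paths (either may be NULL).
#' @return invisible list of written paths.
#' @export
export_module_graph <- function(graph, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(edges_path))
    write.table(graph$edges, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                       vertices = graph$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(list(graphml = graphml_path, edges = edges_path))
}

#' Read a module graph back from an edge-list TSV
#' @param edges_path path written by \code{\link{export_module_graph}}.
#' @return data.frame of edges (from, to, weight).
#' @export
read_module_edges <- function(edges_path) {
  read.delim(edges_path, stringsAsFactors = FALSE)
}

#' PCA loadings and hypotenuse contributions for one module
#'
#' Principal component analysis of the module's standardized expression
#' (samples as observations). Loadings are correlation-scale variable
#' weights (unit-norm axes times singular values / sqrt(n - 1)); each
#' gene's contribution magnitude is the hypotenuse
#' sqrt(loading1^2 + loading2^2), with the loading signs retained for
#' direction. PC1 is oriented positively with mean module expression so
#' signs are reproducible. Sample scores are returned for trait overlays.
#'
#' @param expr \code{expr_matrix} restricted (or restrictable) to the
#'   module's genes.
#' @param genes optional gene subset.
#' @return list: \code{loadings} (gene x PC1/PC2), \code{magnitude},
#'   \code{angle} (radians), \code{scores} (samples x 2),
#'   \code{var_explained}.
#' @export
pca_contributions <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  m <- expr$values
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  if (ncol(m) < 3 || nrow(m) < 3) stop("need >= 3 genes and >= 3 samples")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s)")
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  sv <- svd(z, nu = 2, nv = 2)
  if (cor(sv$u[, 1], rowMeans(z)) < 0) {
    sv$u[, 1] <- -sv$u[, 1]; sv$v[, 1] <- -sv$v[, 1]
  }
  n <- nrow(z)
  loadings <- sweep(sv$v, 2, sv$d[1:2] / sqrt(n - 1), "*")
  dimnames(loadings) <- list(colnames(z), c("PC1", "PC2"))
  scores <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  dimnames(scores) <- list(rownames(z), c("PC1", "PC2"))
  magnitude <- sqrt(rowSums(loadings^2))
  list(loadings = loadings, magnitude = magnitude,
       angle = atan2(loadings[, 2], loadings[, 1]),
       scores = scores,
       var_explained = sv$d[1:2]^2 / sum(sv$d^2))
}

#' Rank top PCA contributors of a biotype
#'
#' Genes ranked by contribution magnitude (descending), ties broken by
#' gene id for determinism, optionally filtered to one biotype.
#'
#' @param contributions result of \code{\link{pca_contributions}}.
#' @param annotation gene annotation (biotype filter).
#' @param k number of genes to return (all if \code{k} >= n).
#' @param biotype "lncRNA" (default), "protein_coding", or NULL for all.
#' @return data.frame: gene_id, biotype, PC1, PC2, magnitude.
#' @export
top_contributors <- function(contributions, annotation, k = 10,
                             biotype = "lncRNA") {
  mag <- contributions$magnitude
  bt <- setNames(annotation$biotype, annotation$gene_id)[names(mag)]
  out <- data.frame(gene_id = names(mag), biotype = unname(bt),
                    PC1 = contributions$loadings[, 1],
                    PC2 = contributions$loadings[, 2],
                    magnitude = unname(mag), stringsAsFactors = FALSE)
  if (!is.null(biotype)) out <- out[out$biotype %in% biotype, ]
  out <- out[order(-out$magnitude, out$gene_id), ]
  rownames(out) <- NULL
  head(out, k)
}
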