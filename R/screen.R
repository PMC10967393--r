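#' Per-sgRNA log2 fold-changes between screen conditions
#'
#' Each condition's counts are normalized to reads per million, a
#' pseudocount is added, and the log2 ratio numerator/denominator is
#' returned. Uniformly doubling a condition's depth leaves the values
#' unchanged.
#'
#' @param screen screen count table (as from \code{\link{generate_screen}}).
#' @param numerator,denominator condition column names (denominator
#'   defaults to the pooled, presorted population).
#' @param pseudocount added to RPM before the ratio.
#' @return named numeric vector (sgRNA -> log2 fold-change).
#' @export
screen_log2fc <- function(screen, numerator, denominator = "pooled",
                          pseudocount = 1) {
  for (b in c(numerator, denominator))
    if (!b %in% names(screen)) stop("condition absent: ", b)
  rpm <- function(x) {
    tot <- sum(x)
    if (tot == 0) stop("condition with zero total reads")
    x / tot * 1e6
  }
  lfc <- log2((rpm(screen[[numerator]]) + pseudocount) /
              (rpm(screen[[denominator]]) + pseudocount))
  setNames(lfc, screen$sgrna)
}

# Binomial rank score for one gene's guides inside the top bin.
# ranks: sorted global ranks of the gene's guides within the top bin;
# m: the gene's total guide count; N: library size.
stars_gene_score <- function(ranks, m, N, min_guides = 2,
                             tail = TRUE, rank_rule = c("deepest", "best")) {
  rank_rule <- match.arg(rank_rule)
  J <- length(ranks)
  if (J < min_guides) return(c(score = NA_real_, rank_used = NA_real_))
  j <- if (rank_rule == "deepest") J else min_guides
  r <- ranks[j]
  p_each <- r / N
  score <- if (tail)
    -log10(stats::pbinom(j - 1, m, p_each, lower.tail = FALSE))
  else
    -log10(stats::dbinom(j, m, p_each))
  c(score = score, rank_used = r)
}

#' STARS-style gene scores from ranked sgRNA fold-changes
#'
#' sgRNAs are ranked by log2 fold-change (descending for enrichment,
#' ascending for depletion). For each gene with at least \code{min_guides}
#' guides inside the top \code{top_frac} of the ranking, the score is the
#' upper-tail binomial probability -log10 P(X >= j) with X ~ Binomial(m,
#' r_j/N), evaluated at the gene's deepest qualifying guide (rank r_j, the
#' j-th of its guides inside the top bin; m = the gene's guide count, N =
#' library size). Genes with fewer qualifying guides are unscored. A pure
#' point-PMF variant is available via \code{tail = FALSE}, and
#' \code{rank_rule = "best"} scores at the best qualifying guide instead.
#'
#' @param log2fc named per-sgRNA values (see \code{\link{screen_log2fc}}).
#' @param guide_gene named character vector sgRNA -> gene (NA for control
#'   guides, which are ranked but never scored).
#' @param direction "enriched" or "depleted".
#' @param top_frac fraction of the library forming the top bin.
#' @param min_guides minimum guides of a gene inside the top bin.
#' @param tail use the upper-tail binomial sum (default) or the point PMF.
#' @param rank_rule score at the deepest ("deepest") or best ("best")
#'   qualifying guide.
#' @return data.frame: gene, score, n_guides_in_top, rank_used, m.
#' @export
stars_score <- function(log2fc, guide_gene,
                        direction = c("enriched", "depleted"),
                        top_frac = 0.04, min_guides = 2, tail = TRUE,
                        rank_rule = "deepest") {
  direction <- match.arg(direction)
  N <- length(log2fc)
  if (ceiling(top_frac * N) < 1) stop("library too small for top_frac")
  guide_gene <- guide_gene[names(log2fc)]
  ord <- order(log2fc, decreasing = (direction == "enriched"))
  ranked_gene <- guide_gene[ord]
  top_n <- ceiling(top_frac * N)
  m_all <- table(guide_gene[!is.na(guide_gene)])
  top_gene <- ranked_gene[seq_len(top_n)]
  in_top <- split(seq_len(top_n)[!is.na(top_gene)],
                  top_gene[!is.na(top_gene)])
  rows <- lapply(names(in_top), function(g) {
    sc <- stars_gene_score(sort(in_top[[g]]), m_all[[g]], N,
                           min_guides, tail, rank_rule)
    data.frame(gene = g, score = sc[["score"]],
               n_guides_in_top = length(in_top[[g]]),
               rank_used = sc[["rank_used"]], m = m_all[[g]],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(0), score = numeric(0),
                         n_guides_in_top = integer(0),
                         rank_used = numeric(0), m = integer(0))
  key <- ifelse(is.na(out$score), -Inf, out$score)
  out <- out[order(-key, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation p-values and FDR for screen gene scores
#'
#' The null distribution pools gene scores from screens in which the
#' guide -> gene assignment is permuted structure-preservingly: control
#' guides stay controls and every gene keeps its guide count. p = (1 +
#' #null scores >= observed) / (1 + total null scores); FDR is
#' Benjamini-Hochberg across scored genes within the direction.
#'
#' @inheritParams stars_score
#' @param n_perm permutations of the library.
#' @param seed integer seed.
#' @return data.frame: gene, score, n_guides_in_top, p, fdr, direction.
#' @export
stars_fdr <- function(log2fc, guide_gene,
                      direction = c("enriched", "depleted"),
                      top_frac = 0.04, min_guides = 2, n_perm = 1000,
                      seed = 1L, tail = TRUE, rank_rule = "deepest") {
  direction <- match.arg(direction)
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  obs <- stars_score(log2fc, guide_gene, direction, top_frac, min_guides,
                     tail, rank_rule)
  obs <- obs[!is.na(obs$score), , drop = FALSE]
  guide_gene <- guide_gene[names(log2fc)]
  targeting <- which(!is.na(guide_gene))
  null_scores <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    gg <- guide_gene
    gg[targeting] <- guide_gene[sample(targeting)]
    ns <- stars_score(log2fc, gg, direction, top_frac, min_guides,
                      tail, rank_rule)$score
    null_scores[[i]] <- ns[!is.na(ns)]
  }
  null <- unlist(null_scores)
  # scale per-permutation so p reflects a per-gene null draw
  n_null <- length(null)
  obs$p <- vapply(obs$score, function(s)
    (1 + sum(null >= s)) / (1 + n_null), 0)
  obs$fdr <- p.adjust(obs$p, "BH")
  obs$direction <- rep(direction, nrow(obs))
  obs
}

#' Call screen hits at an FDR threshold
#'
#' Combines scored results from one or more direction x comparison runs and
#' keeps genes with FDR strictly below the cutoff, labeled as positive
#' regulators (enriched) or negative regulators (depleted).
#'
#' @param results list of \code{\link{stars_fdr}} data.frames (a single
#'   data.frame is accepted).
#' @param fdr_cutoff strict FDR threshold.
#' @return data.frame of hits with a \code{regulator} label column.
#' @export
screen_hits <- function(results, fdr_cutoff = 0.25) {
  if (is.data.frame(results)) results <- list(results)
  all <- do.call(rbind, results)
  if (is.null(all) || !nrow(all))
    return(data.frame(gene = character(0), score = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      direction = character(0), regulator = character(0)))
  hits <- all[!is.na(all$fdr) & all$fdr < fdr_cutoff, , drop = FALSE]
  hits$regulator <- ifelse(hits$direction == "enriched",
                           "positive", "negative")
  rownames(hits) <- NULL
  hits[order(hits$fdr, hits$gene), , drop = FALSE]
}
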