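#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd var rnorm rbinom rnbinom rmultinom runif
#'   quantile p.adjust pt pnorm phyper ks.test t.test glm binomial
#'   lm coef vcov model.matrix hclust as.dist cutree setNames ave
#'   pbinom dbinom plogis median pchisq relevel as.formula sigma
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to compare detected coexpression modules with planted truth; 1 means
#' identical partitions, 0 is the expectation under random labeling.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Ordered color palette for module labels; mirrors the conventional
# WGCNA-style naming where "grey" is reserved for unassigned genes.
module_color_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
    "sienna3", "yellowgreen", "skyblue3", "plum1", "orangered4", "brown4",
    "coral1", "lightyellow2", "ivory", "honeydew1", "firebrick4",
    "lightsteelblue1", "mediumpurple3", "salmon4", "palevioletred3",
    "navajowhite2", "thistle2", "lavenderblush3", "indianred4", "plum2",
    "lightcoral", "darkseagreen4", "bisque4", "magenta4", "antiquewhite4",
    "coral2")
}

# label n modules, largest first, extending with module<k> if palette runs out
module_labels_for <- function(n) {
  pal <- module_color_palette()
  if (n <= length(pal)) pal[seq_len(n)]
  else c(pal, paste0("module", seq_len(n - length(pal))))
}

star_annotation <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
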