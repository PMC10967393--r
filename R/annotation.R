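#' Construct and validate a gene annotation table
#'
#' Internal coordinates are 0-based half-open throughout the package; GTF
#' on disk is 1-based closed and converted at the I/O boundary.
#'
#' @param df data.frame with columns gene_id, biotype, chrom, start, end;
#'   optional source, strand, length.
#' @return validated data.frame of class \code{gene_annotation}.
#' @export
gene_annotation <- function(df) {
  required <- c("gene_id", "biotype", "chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation missing column(s): ", paste(missing, collapse = ", "))
  if (!all(df$biotype %in% c("lncRNA", "protein_coding")))
    stop("biotype must be lncRNA or protein_coding")
  if (is.null(df$source)) df$source <- rep("synthetic", nrow(df))
  if (!all(df$source %in% c("gencode", "lncipedia", "denovo", "synthetic")))
    stop("unknown annotation source")
  if (is.null(df$strand)) df$strand <- rep(".", nrow(df))
  if (any(df$start >= df$end))
    stop("start must be < end (0-based half-open) for: ",
         paste(head(df$gene_id[df$start >= df$end], 5), collapse = ", "))
  if (is.null(df$length)) df$length <- as.numeric(df$end) - as.numeric(df$start)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id within one source: ",
         paste(head(unique(df$gene_id[duplicated(df$gene_id)]), 5),
               collapse = ", "))
  df <- df[, c("gene_id", "biotype", "source", "chrom", "start", "end",
               "strand", "length")]
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Merge gene annotations from multiple sources into a nonredundant set
#'
#' Builds the union of several annotation collections (e.g. GENCODE-style
#' protein-coding genes, a LNCipedia-style high-confidence lncRNA set, and
#' de novo assembled lncRNAs). Duplicates by gene_id -- and optionally by
#' identical coordinates + strand -- are collapsed, keeping the record from
#' the higher-precedence source (gencode > lncipedia > denovo > synthetic).
#'
#' @param sources list of annotation tables (each internally unique).
#' @param dedup_key "gene_id" (default) or "coordinates" (gene_id first,
#'   then chrom/start/end/strand identity).
#' @return merged \code{gene_annotation}; per-biotype counts in
#'   \code{attr(, "biotype_counts")}.
#' @export
merge_annotations <- function(sources, dedup_key = c("gene_id", "coordinates")) {
  dedup_key <- match.arg(dedup_key)
  sources <- lapply(sources, gene_annotation)
  all <- do.call(rbind, lapply(sources, as.data.frame))

  conflicting <- unique(all$gene_id[
    ave(as.integer(factor(all$biotype)), all$gene_id,
        FUN = function(x) length(unique(x))) > 1])
  if (length(conflicting))
    stop("conflicting biotypes for gene_id(s): ",
         paste(head(conflicting, 10), collapse = ", "))

  precedence <- c(gencode = 1, lncipedia = 2, denovo = 3, synthetic = 4)
  all <- all[order(precedence[all$source]), ]
  all <- all[!duplicated(all$gene_id), ]
  if (dedup_key == "coordinates") {
    key <- paste(all$chrom, all$start, all$end, all$strand)
    all <- all[!duplicated(key), ]
  }
  all <- all[order(all$chrom, all$start, all$gene_id), ]
  rownames(all) <- NULL
  out <- gene_annotation(all)
  attr(out, "biotype_counts") <- table(out$biotype)
  out
}

#' Read/write gene annotations as GTF or BED
#'
#' GTF uses the Ensembl dialect (1-based closed coordinates on disk,
#' \code{gene_id "X";}-style attributes) and is converted to the internal
#' 0-based half-open convention on read. BED6 is already 0-based half-open;
#' biotype and source travel in the name column as
#' \code{gene_id|biotype|source}.
#'
#' @param path file path.
#' @param annotation a \code{gene_annotation}.
#' @return \code{read_*} return a \code{gene_annotation}; \code{write_*}
#'   return \code{path} invisibly.
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) {
    return(gene_annotation(data.frame(
      gene_id = character(0), biotype = character(0), chrom = character(0),
      start = numeric(0), end = numeric(0), source = character(0),
      strand = character(0), stringsAsFactors = FALSE)))
  }
  md <- S4Vectors::mcols(gr)
  gene_annotation(data.frame(
    gene_id = as.character(md$gene_id),
    biotype = as.character(md$gene_biotype),
    source = as.character(md$gene_source %||% rep("synthetic", length(gr))),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE))
}

#' @rdname annotation_io
#' @export
write_gtf <- function(annotation, path) {
  annotation <- gene_annotation(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1,
                              end = annotation$end),
    strand = sub("^\\.$", "*", annotation$strand))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = annotation$source, type = "gene",
    gene_id = annotation$gene_id, gene_biotype = annotation$biotype,
    gene_source = annotation$source)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(gene_annotation(data.frame(
      gene_id = character(0), biotype = character(0), chrom = character(0),
      start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)))
  }
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED file needs >= 4 columns: ", path)
  parts <- strsplit(bed[[4]], "|", fixed = TRUE)
  bad <- which(lengths(parts) < 1)
  if (length(bad)) stop("malformed BED name at line ", bad[1])
  gene_annotation(data.frame(
    gene_id = vapply(parts, `[`, "", 1),
    biotype = vapply(parts, function(p) p[2] %||% "protein_coding", ""),
    source = vapply(parts, function(p) if (length(p) >= 3) p[3] else "synthetic", ""),
    chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
    strand = if (ncol(bed) >= 6) bed[[6]] else ".",
    stringsAsFactors = FALSE))
}

#' @rdname annotation_io
#' @export
write_bed <- function(annotation, path) {
  annotation <- gene_annotation(annotation)
  bed <- data.frame(
    chrom = annotation$chrom, start = annotation$start, end = annotation$end,
    name = paste(annotation$gene_id, annotation$biotype, annotation$source,
                 sep = "|"),
    score = 0, strand = ifelse(annotation$strand == "", ".", annotation$strand))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Generate synthetic annotation fixtures at reference-catalog scale
#'
#' Builds disjoint synthetic stand-ins for the three annotation sources the
#' merged reference combines: a GENCODE-like protein-coding set, a
#' LNCipedia-like high-confidence lncRNA set, and a de novo assembled lncRNA
#' set. Sizes default to the published catalog sizes (19,988 protein-coding;
#' 46,790 + 3,003 lncRNAs). All records are synthetic: ids, coordinates and
#' strands are generated, only the set sizes are meaningful.
#'
#' @param n_coding,n_lncipedia,n_denovo source sizes.
#' @param seed integer seed.
#' @return named list of three \code{gene_annotation} tables.
#' @export
annotation_source_fixtures <- function(n_coding = 19988, n_lncipedia = 46790,
                                       n_denovo = 3003, seed = 1L) {
  set.seed(seed)
  make <- function(prefix, n, biotype, source) {
    chroms <- synthetic_chromosomes()
    chrom <- sample(names(chroms), n, replace = TRUE)
    len <- round(exp(runif(n, log(500), log(20000))))
    start <- floor(runif(n, 0, chroms[chrom] - len - 1))
    gene_annotation(data.frame(
      gene_id = sprintf("%s%06d", prefix, seq_len(n)),
      biotype = biotype, source = source, chrom = chrom,
      start = start, end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  list(gencode = make("ENSG", n_coding, "protein_coding", "gencode"),
       lncipedia = make("LNC", n_lncipedia, "lncRNA", "lncipedia"),
       denovo = make("DNLNC", n_denovo, "lncRNA", "denovo"))
}
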