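# Readers/writers for the plain-text formats the pipeline exchanges.
# BED-family parsing is delegated to rtracklayer; BEDPE (which no
# installed package parses) and simple TSVs are read with base R.
# All files are 0-based half-open; conversion to/from the in-memory
# 1-based GRanges happens in granges_from_bed0()/granges_to_bed0().

#' @rdname sim_io
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes),
                                format(chrom_sizes, scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' @rdname sim_io
#' @export
write_genes_bed12 <- function(genome, path) {
  genes <- genome$genes
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- genome$exons[genome$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(g$chrom, format(g$start, scientific = FALSE),
          format(g$end, scientific = FALSE),
          g$gene_id, 0, g$strand,
          format(g$thick_start, scientific = FALSE),
          format(g$thick_end, scientific = FALSE), "0",
          nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - g$start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  genes <- data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    thick_start = GenomicRanges::start(gr$thick) - 1L,
    thick_end = GenomicRanges::end(gr$thick),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  blocks <- gr$blocks
  exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    data.frame(gene_id = genes$gene_id[i],
               start = genes$start[i] + IRanges::start(b) - 1L,
               end = genes$start[i] + IRanges::end(b),
               stringsAsFactors = FALSE)
  }))
  rownames(exons) <- NULL
  out <- list(chrom_sizes = NULL,
              genes = genes[, c("gene_id", "chrom", "start", "end", "strand",
                                "tss", "thick_start", "thick_end")],
              exons = exons)
  class(out) <- "sim_genome"
  out
}

#' @rdname sim_io
#' @export
write_motifs_bed <- function(motifs, path) {
  df <- if (inherits(motifs, "sim_motifs")) motifs$motifs else motifs
  utils::write.table(
    data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE),
               df$motif_id, trunc(df$score * 1000), df$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_motifs_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(motif_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             score = gr$score / 1000,
             stringsAsFactors = FALSE)
}

#' @rdname sim_io
#' @export
write_narrowpeak <- function(gr, path) {
  df <- granges_to_bed0(gr)
  name <- if (!is.null(df$name)) df$name else "."
  signal <- if (!is.null(df$score)) df$score else 0
  utils::write.table(
    data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE),
               name, 0L, ".", signal, -1, -1, -1),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_narrowpeak <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(signalValue = "numeric",
                                          pValue = "numeric",
                                          qValue = "numeric",
                                          peak = "integer"))
  gr$score <- gr$signalValue
  gr$signalValue <- gr$pValue <- gr$qValue <- gr$peak <- NULL
  gr
}

#' @rdname sim_io
#' @export
write_bedpe <- function(fragments, path) {
  df <- granges_to_bed0(fragments)
  half <- pmax((df$end - df$start) %/% 3, 1)
  utils::write.table(
    data.frame(df$chrom, df$start, df$start + half,
               df$chrom, df$end - half, df$end,
               ".", 0L, "+", "-"),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 6)
  if (!all(df[[1]] == df[[4]]))
    stop("inter-chromosomal BEDPE records are not supported", call. = FALSE)
  gr <- granges_from_bed0(df[[1]], pmin(df[[2]], df[[5]]),
                          pmax(df[[3]], df[[6]]))
  gr$fragment_length <- GenomicRanges::width(gr)
  GenomicRanges::sort(gr)
}

#' @rdname sim_io
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' @rdname sim_io
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' @rdname sim_io
#' @export
write_expression_tsv <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_expression_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname sim_io
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_gene_list <- function(path) {
  readLines(path)
}

#' Read and write the synthetic-data exchange formats
#'
#' Thin wrappers over the standard plain-text genomics formats used by the
#' pipeline: `chrom.sizes` TSV, BED12 gene models, BED6 motifs (score =
#' motif score x 1000, truncated), narrowPeak calls (observed count stored
#' in the signalValue column), BEDPE fragments, bedGraph tracks,
#' expression TSV and one-id-per-line gene lists.  Writers emit 0-based
#' half-open coordinates; readers return the package's in-memory
#' representations (1-based `GRanges` or data.frames in 0-based
#' coordinates matching the generator output).
#'
#' @param chrom_sizes named numeric vector.
#' @param genome a [sim_genome()].
#' @param motifs a [sim_motifs()] or its `$motifs` data.frame.
#' @param gr,fragments,track a `GRanges`.
#' @param expression,genes data.frame / character vector to serialise.
#' @param path file path.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @name sim_io
NULL
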