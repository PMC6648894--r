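#' Genomic feature categories used by peak annotation
#' @export
annotation_categories <- c("promoter_le1kb", "promoter_1to2kb",
                           "promoter_2to3kb", "utr5", "utr3", "exon",
                           "intron", "downstream_le3kb", "distal_intergenic")

#' Annotate peaks with genomic feature categories
#'
#' Assigns each peak to exactly one category by the priority
#' promoter > UTR > exon > intron > downstream > distal intergenic,
#' mirroring the precedence of standard ChIP peak annotators.  The
#' anchor is the peak midpoint (integer floor).  Promoter bins use the
#' strand-aware signed distance to the nearest TSS (negative = upstream):
#' within (-1000, +1000] bp is `promoter_le1kb`, then nested bins out to
#' 2 kb and 3 kb.  Outside the promoter bins, an anchor inside a gene body
#' is classified by the gene's explicit UTR spans, then exons, else
#' intron; an anchor within `downstream_bp` past a gene's 3' end is
#' `downstream_le3kb`; everything else is `distal_intergenic`.  Nearest
#' TSS ties break by smallest absolute distance, then lexicographic gene
#' id.  Peaks on chromosomes absent from the gene models are
#' `distal_intergenic` with a warning.
#'
#' @param peaks `GRanges` of peaks.
#' @param genome a [sim_genome()] (or the structure returned by
#'   [read_genes_bed12()]).
#' @param promoter_bins increasing promoter bin edges in bp (default
#'   `c(1000, 2000, 3000)`).
#' @param downstream_bp downstream window in bp (default 3000).
#' @return `peaks` with metadata columns `annotation` (factor over
#'   [annotation_categories]), `nearest_gene` and `tss_distance` (signed,
#'   strand-aware).
#' @export
annotate_peaks <- function(peaks, genome, promoter_bins = c(1000, 2000, 3000),
                           downstream_bp = 3000) {
  stopifnot(length(promoter_bins) == 3, !is.unsorted(promoter_bins))
  genes <- genome$genes
  exons <- genome$exons
  utrs <- gene_utr_spans(genome)
  anchor <- (GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) %/% 2
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  n <- length(peaks)
  cat_out <- rep("distal_intergenic", n)
  gene_out <- rep(NA_character_, n)
  dist_out <- rep(NA_real_, n)
  missing_chrom <- FALSE

  for (ch in unique(chrom)) {
    pi <- which(chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) { missing_chrom <- TRUE; next }
    # signed strand-aware distance of every anchor to every TSS
    dmat <- outer(anchor[pi], g$tss, "-")
    neg <- g$strand == "-"
    dmat[, neg] <- -dmat[, neg]
    # nearest TSS: min |d|, ties to lexicographically first gene id
    ord <- order(g$gene_id)
    for (k in seq_along(pi)) {
      i <- pi[k]
      a <- anchor[i]
      d <- dmat[k, ]
      best <- ord[which.min(abs(d)[ord])]
      gene_out[i] <- g$gene_id[best]
      dist_out[i] <- d[best]
      db <- d[best]
      bin <- if (db > -promoter_bins[1] && db <= promoter_bins[1]) 1L
      else if (db > -promoter_bins[2] && db <= promoter_bins[2]) 2L
      else if (db > -promoter_bins[3] && db <= promoter_bins[3]) 3L
      else 0L
      if (bin > 0L) {
        cat_out[i] <- c("promoter_le1kb", "promoter_1to2kb",
                        "promoter_2to3kb")[bin]
        next
      }
      inside <- which(g$start <= a & a < g$end)
      if (length(inside)) {
        host <- inside[order(abs(d[inside]), g$gene_id[inside])][1]
        gid <- g$gene_id[host]
        u <- utrs[utrs$gene_id == gid & utrs$start <= a & a < utrs$end, , drop = FALSE]
        if (nrow(u)) {
          cat_out[i] <- u$type[1]
        } else {
          ex <- exons[exons$gene_id == gid, , drop = FALSE]
          cat_out[i] <- if (any(ex$start <= a & a < ex$end)) "exon" else "intron"
        }
        next
      }
      down <- (g$strand == "+" & g$end <= a & a < g$end + downstream_bp) |
        (g$strand == "-" & g$start - downstream_bp <= a & a < g$start)
      if (any(down)) cat_out[i] <- "downstream_le3kb"
    }
  }
  if (missing_chrom)
    warning("peak(s) on chromosome(s) absent from gene models; classified distal_intergenic")
  peaks$annotation <- factor(cat_out, levels = annotation_categories)
  peaks$nearest_gene <- gene_out
  peaks$tss_distance <- dist_out
  peaks
}

#' Genomic-distribution summary per occupancy class
#'
#' Percentage of peaks in each annotation category, for all peaks and for
#' each occupancy class separately.  Percentages within a class sum to
#' 100.  Empty classes are omitted with a warning.
#'
#' @param peaks annotated `GRanges` (needs `annotation`; `occupancy_class`
#'   optional).
#' @return object of class `distribution_summary`: a data.frame with
#'   columns `class`, `category`, `count`, `percentage`, plus a
#'   `class_totals` attribute.
#' @export
distribution_summary <- function(peaks) {
  ann <- peaks$annotation
  if (is.null(ann)) stop("peaks are not annotated", call. = FALSE)
  groups <- list(all = seq_along(peaks))
  if (!is.null(peaks$occupancy_class)) {
    occ <- as.character(peaks$occupancy_class)
    for (cls in c("reduced", "retained", "gained")) {
      idx <- which(occ == cls)
      if (!length(idx)) {
        warning(sprintf("occupancy class '%s' is empty; omitted", cls))
        next
      }
      groups[[cls]] <- idx
    }
  }
  rows <- lapply(names(groups), function(nm) {
    tab <- table(factor(ann[groups[[nm]]], levels = annotation_categories))
    data.frame(class = nm, category = names(tab),
               count = as.integer(tab),
               percentage = 100 * as.integer(tab) / length(groups[[nm]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "class_totals") <- vapply(groups, length, integer(1))
  class(out) <- c("distribution_summary", "data.frame")
  out
}

#' @export
print.distribution_summary <- function(x, ...) {
  totals <- attr(x, "class_totals")
  for (nm in names(totals)) {
    cat(sprintf("%s (n = %d):\n", nm, totals[[nm]]))
    sub <- x[x$class == nm & x$count > 0, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-18s %6.2f%% (%d)\n", sub$category[i],
                  sub$percentage[i], sub$count[i]))
  }
  invisible(x)
}
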