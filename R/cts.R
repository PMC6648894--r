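#' Cluster CTCF motifs into CTSes at a fixed linkage distance
#'
#' Single-linkage clustering per chromosome: two motifs are linked when
#' the gap between them (next start minus previous end, 0-based half-open
#' semantics; overlapping motifs have gap <= 0) is at most `linkage_bp`,
#' inclusive; clusters are the transitive closure of that relation.
#' Cluster order is the number of member motifs: order 1 is a 1XCTS,
#' order 2 a 2XCTS, order >= 3 a 3XCTS.  Strand is ignored; exact
#' duplicate motif records are removed with a warning.
#'
#' @param motifs `GRanges` of motif hits (e.g. [motif_granges()]).
#' @param linkage_bp maximum inter-motif gap in bp (default 40).
#' @return `GRanges` of cluster spans (min start to max end), sorted, with
#'   metadata `order` (integer member count) and `cts_class`
#'   (`1X`/`2X`/`3X`).
#' @examples
#' m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 160), width = 19))
#' cluster_motifs(m)  # gap 40 -> one 2X cluster
#' @export
cluster_motifs <- function(motifs, linkage_bp = 40) {
  stopifnot(linkage_bp >= 0)
  motifs <- GenomicRanges::granges(motifs)
  GenomicRanges::strand(motifs) <- "*"
  dup <- GenomicRanges::duplicated(motifs)
  if (any(dup)) {
    warning(sprintf("removed %d duplicate motif record(s)", sum(dup)))
    motifs <- motifs[!dup]
  }
  motifs <- GenomicRanges::sort(motifs)
  if (!length(motifs)) {
    out <- GenomicRanges::GRanges()
    out$order <- integer()
    out$cts_class <- character()
    return(out)
  }
  # reduce() merges ranges whose gap is strictly below min.gapwidth,
  # so gap <= linkage_bp (inclusive) needs min.gapwidth = linkage_bp + 1
  spans <- GenomicRanges::reduce(motifs, min.gapwidth = linkage_bp + 1)
  spans$order <- GenomicRanges::countOverlaps(spans, motifs)
  spans$cts_class <- c("1X", "2X", "3X")[pmin(spans$order, 3L)]
  spans
}

#' Attach CTS class to consensus peaks
#'
#' A peak overlapping one or more cluster spans by >= 1 bp receives the
#' maximum order among the overlapped clusters; peaks overlapping no
#' cluster keep `cts_order = NA` / `cts_class = "none"` and are excluded
#' from CTS-level analyses while remaining in the peak table.
#'
#' @param peaks `GRanges` of quantified consensus peaks.
#' @param clusters `GRanges` from [cluster_motifs()].
#' @return `peaks` with metadata columns `cts_order` and `cts_class`.
#' @export
assign_peak_cts <- function(peaks, clusters) {
  ord <- rep(NA_integer_, length(peaks))
  hits <- GenomicRanges::findOverlaps(peaks, clusters, ignore.strand = TRUE)
  if (length(hits)) {
    mx <- tapply(clusters$order[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), max)
    ord[as.integer(names(mx))] <- as.integer(mx)
  }
  peaks$cts_order <- ord
  peaks$cts_class <- ifelse(is.na(ord), "none",
                            c("1X", "2X", "3X")[pmin(ord, 3L)])
  peaks
}

#' Classify occupancy change from the log2 fold change
#'
#' The +IAA/-IAA log2 fold change of mean FPKM partitions peaks into
#' `reduced` (log2FC <= -1), `retained` (-1 < log2FC <= 1) and `gained`
#' (log2FC > 1); the boundaries belong to `reduced` and `retained`
#' respectively.
#'
#' @param x either a numeric vector of log2 fold changes or a `GRanges`
#'   with a `log2fc` metadata column (as returned by [quantify_fpkm()]).
#' @param thresholds length-2 numeric: lower and upper class boundary
#'   (default `c(-1, 1)`).
#' @return for numeric input, a factor with levels
#'   `reduced`/`retained`/`gained`; for `GRanges` input, the object with
#'   an added `occupancy_class` column.
#' @examples
#' classify_occupancy(c(-1, -0.5, 1, 1.2))
#' @export
classify_occupancy <- function(x, thresholds = c(-1, 1)) {
  if (inherits(x, "GRanges")) {
    if (is.null(x$log2fc)) stop("peaks have no log2fc column", call. = FALSE)
    x$occupancy_class <- classify_occupancy(x$log2fc, thresholds)
    return(x)
  }
  if (any(!is.finite(x))) stop("log2fc must be finite", call. = FALSE)
  factor(ifelse(x <= thresholds[1], "reduced",
                ifelse(x <= thresholds[2], "retained", "gained")),
         levels = c("reduced", "retained", "gained"))
}

#' MA-style export table for classified peaks
#'
#' One row per peak with the arithmetic mean of all per-sample FPKMs (the
#' MA-plot abscissa), the log2 fold change, and the CTS / occupancy
#' classes when present.
#'
#' @param peaks quantified (and optionally classified) `GRanges`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `mean_fpkm`, `log2fc`, and `cts_class` /
#'   `occupancy_class` when available.
#' @export
ma_table <- function(peaks) {
  if (!length(peaks)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_fpkm = numeric(),
                      log2fc = numeric(), cts_class = character(),
                      occupancy_class = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   mean_fpkm = rowMeans(S4Vectors::mcols(peaks)$fpkm),
                   log2fc = peaks$log2fc,
                   stringsAsFactors = FALSE)
  if (!is.null(peaks$cts_class)) df$cts_class <- peaks$cts_class
  if (!is.null(peaks$occupancy_class))
    df$occupancy_class <- as.character(peaks$occupancy_class)
  df
}
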