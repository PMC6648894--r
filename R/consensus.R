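#' Reproducible peaks across clonal replicates at two confidence levels
#'
#' Implements the dual-confidence reproducibility rule: a merged region is
#' kept when at least one clone has a high-confidence call overlapping it
#' and every other clone supports it with a call at either confidence.
#' Candidate regions are the union-merge of all calls from all clones, so
#' the retained regions are unions of their supporting call intervals.
#' Overlap anywhere (>= 1 bp) counts as support.
#'
#' On ingest each clone's low-confidence set is unioned with its
#' high-confidence set, enforcing the invariant that a high-confidence
#' call is also a (low-confidence) call.
#'
#' @param calls list with one element per clone; each element is a list
#'   with `GRanges` components `high` and `low`.  A clone missing both is
#'   an error.
#' @return sorted, non-overlapping `GRanges` of reproducible regions.
#' @examples
#' r <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
#' calls <- list(a = list(high = r(100, 200), low = r(100, 200)),
#'               b = list(high = r(0, 0)[0], low = r(150, 250)),
#'               c = list(high = r(0, 0)[0], low = r(120, 220)))
#' filter_reproducible(calls)
#' @export
filter_reproducible <- function(calls) {
  if (length(calls) < 2)
    stop("need call sets for at least 2 clones", call. = FALSE)
  calls <- lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    if (is.null(cl$high) && is.null(cl$low))
      stop(sprintf("clone %s is missing both confidence sets",
                   names(calls)[i] %||% i), call. = FALSE)
    high <- cl$high %||% GenomicRanges::GRanges()
    low <- cl$low %||% GenomicRanges::GRanges()
    list(high = high,
         low = GenomicRanges::reduce(c(GenomicRanges::granges(low),
                                       GenomicRanges::granges(high))))
  })
  all_calls <- do.call(c, lapply(calls, function(cl)
    c(GenomicRanges::granges(cl$low), GenomicRanges::granges(cl$high))))
  if (!length(all_calls)) return(GenomicRanges::GRanges())
  candidates <- GenomicRanges::reduce(GenomicRanges::sort(all_calls),
                                      ignore.strand = TRUE)
  any_high <- rep(FALSE, length(candidates))
  all_support <- rep(TRUE, length(candidates))
  for (cl in calls) {
    any_high <- any_high |
      GenomicRanges::countOverlaps(candidates, cl$high, ignore.strand = TRUE) > 0
    all_support <- all_support &
      GenomicRanges::countOverlaps(candidates, cl$low, ignore.strand = TRUE) > 0
  }
  GenomicRanges::sort(candidates[any_high & all_support])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge condition-wise reproducible peaks and drop blacklisted regions
#'
#' Union-merges the reproducible peak sets of the two conditions, then
#' removes entirely any merged region overlapping a blacklist interval by
#' at least 1 bp (peak-level removal, no trimming).
#'
#' @param repro_minus,repro_plus `GRanges` of reproducible regions per
#'   condition.
#' @param blacklist `GRanges` of excluded regions (may be empty).
#' @return sorted, disjoint `GRanges` of consensus regions.
#' @examples
#' r <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
#' merge_and_blacklist(r(101, 200), r(151, 250), r(1000, 2000))
#' @export
merge_and_blacklist <- function(repro_minus, repro_plus,
                                blacklist = GenomicRanges::GRanges()) {
  merged <- GenomicRanges::reduce(
    GenomicRanges::sort(c(GenomicRanges::granges(repro_minus),
                          GenomicRanges::granges(repro_plus))),
    ignore.strand = TRUE)
  if (length(blacklist)) {
    hit <- GenomicRanges::countOverlaps(merged, blacklist,
                                        ignore.strand = TRUE) > 0
    merged <- merged[!hit]
  }
  GenomicRanges::sort(merged)
}

# FPKM for a count matrix: count / ((length/1e3) * (library/1e6)).
fpkm_from_counts <- function(counts, region_lengths, library_sizes) {
  stopifnot(nrow(counts) == length(region_lengths),
            ncol(counts) == length(library_sizes),
            all(library_sizes > 0), all(region_lengths > 0))
  sweep(counts / (region_lengths / 1e3), 2, library_sizes / 1e6, "/")
}

finalize_peaks <- function(regions, counts, fpkm, conditions, pseudocount) {
  stopifnot(all(conditions %in% c("minus", "plus")))
  mean_minus <- rowMeans(fpkm[, conditions == "minus", drop = FALSE])
  mean_plus <- rowMeans(fpkm[, conditions == "plus", drop = FALSE])
  peaks <- GenomicRanges::granges(regions)
  S4Vectors::mcols(peaks)$counts <- counts
  S4Vectors::mcols(peaks)$fpkm <- fpkm
  peaks$mean_fpkm_minus <- mean_minus
  peaks$mean_fpkm_plus <- mean_plus
  peaks$log2fc <- log2((mean_plus + pseudocount) / (mean_minus + pseudocount))
  peaks
}

#' Quantify consensus regions by fragment counts and FPKM
#'
#' Counts, for every sample, the fragments overlapping each region by at
#' least 1 bp (whole-fragment overlap, not midpoints), converts counts to
#' FPKM (`count / ((length/1e3) * (library_size/1e6))`), averages FPKM per
#' condition across clones and computes the pseudocounted log2 fold change
#' `log2((mean_plus + eps) / (mean_minus + eps))`.
#'
#' @param regions `GRanges` of consensus regions.
#' @param fragments named list of `GRanges`, one per sample.
#' @param conditions character vector (`"minus"`/`"plus"`) parallel to
#'   `fragments`, mapping each sample to its condition.
#' @param pseudocount FPKM pseudocount `eps` (default 0.5) keeping the
#'   fold change finite and symmetric.
#' @param library_sizes optional per-sample library sizes; defaults to the
#'   number of fragments per sample.
#' @return the `regions` `GRanges` with metadata columns `counts` and
#'   `fpkm` (matrices, one column per sample), `mean_fpkm_minus`,
#'   `mean_fpkm_plus` and `log2fc`.
#' @seealso [quantify_fpkm_counts()] for the count-matrix entry point.
#' @export
quantify_fpkm <- function(regions, fragments, conditions, pseudocount = 0.5,
                          library_sizes = NULL) {
  stopifnot(length(fragments) == length(conditions))
  if (any(GenomicRanges::width(regions) < 1))
    stop("zero-length region", call. = FALSE)
  if (is.null(library_sizes))
    library_sizes <- vapply(fragments, length, integer(1))
  counts <- vapply(fragments, function(fr)
    GenomicRanges::countOverlaps(regions, fr, ignore.strand = TRUE),
    numeric(length(regions)))
  counts <- matrix(counts, nrow = length(regions),
                   dimnames = list(NULL, names(fragments)))
  fpkm <- fpkm_from_counts(counts, GenomicRanges::width(regions),
                           library_sizes)
  finalize_peaks(regions, counts, fpkm, conditions, pseudocount)
}

#' @rdname quantify_fpkm
#' @param counts numeric matrix (regions x samples) of precomputed
#'   fragment counts, e.g. the `counts` element of [sim_occupancy()].
#' @export
quantify_fpkm_counts <- function(regions, counts, conditions,
                                 pseudocount = 0.5,
                                 library_sizes = colSums(counts)) {
  stopifnot(length(regions) == nrow(counts),
            ncol(counts) == length(conditions))
  if (any(GenomicRanges::width(regions) < 1))
    stop("zero-length region", call. = FALSE)
  fpkm <- fpkm_from_counts(counts, GenomicRanges::width(regions),
                           library_sizes)
  finalize_peaks(regions, counts, fpkm, conditions, pseudocount)
}

#' Split a fragment set by the Cut&Run size windows
#'
#' Size-based quality-control split: `short` keeps fragments under 120 bp
#' (sub-nucleosomal, sharp footprints), `long` keeps fragments strictly
#' between 150 and 2000 bp (nucleosome-scale), and `all_under_2kb` keeps
#' everything under 2000 bp — the set used to build final coverage tracks.
#' Fragments of 120--150 bp fall only in `all_under_2kb`.
#'
#' @param fragments `GRanges` whose widths are the fragment lengths (>= 1).
#' @return named list of `GRanges`: `short`, `long`, `all_under_2kb`.
#' @examples
#' fr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(1, width = c(100, 140, 160, 2500)))
#' lengths(split_fragments_by_size(fr))
#' @export
split_fragments_by_size <- function(fragments) {
  len <- GenomicRanges::width(fragments)
  stopifnot(all(len >= 1))
  list(short = fragments[len < 120],
       long = fragments[len > 150 & len < 2000],
       all_under_2kb = fragments[len < 2000])
}

#' Flatten quantified peaks to an exportable table
#'
#' Expands the matrix columns of a quantified `GRanges` into one
#' `count_<sample>` and `fpkm_<sample>` column per sample, alongside the
#' condition means, fold change and any classification columns — the
#' extended-TSV surface of the consensus peak set.
#'
#' @param peaks quantified (optionally classified/annotated) `GRanges`.
#' @return data.frame in 0-based half-open coordinates.
#' @seealso [write_peak_table()]
#' @export
peak_table <- function(peaks) {
  md <- S4Vectors::mcols(peaks)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   stringsAsFactors = FALSE)
  for (nm in colnames(md)) {
    v <- md[[nm]]
    if (is.matrix(v)) {
      pre <- sub("s$", "", nm)  # counts -> count_, fpkm -> fpkm_
      cols <- as.data.frame(v)
      names(cols) <- paste(pre, colnames(v), sep = "_")
      df <- cbind(df, cols)
    } else {
      df[[nm]] <- if (is.factor(v)) as.character(v) else v
    }
  }
  rownames(df) <- NULL
  df
}

#' Write the consensus peak table as TSV
#'
#' @param peaks quantified `GRanges` (see [peak_table()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(peak_table(peaks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
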