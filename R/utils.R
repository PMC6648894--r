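# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so generators are pure
#' functions of their (config, seed) arguments and never perturb user RNG
#' state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# Per-generator sub-seed; keeps derived seeds within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' All on-disk formats used by the package (BED, narrowPeak, bedGraph,
#' BEDPE) are 0-based half-open; in memory everything is a
#' [GenomicRanges::GRanges], which is 1-based closed.  This constructor and
#' [granges_to_bed0()] are the single conversion point.
#'
#' @param chrom character vector of chromosome names.
#' @param start0,end0 0-based half-open interval bounds.
#' @param strand optional strand vector (`+`, `-` or `*`).
#' @param ... further metadata columns passed to `GRanges`.
#' @return a `GRanges`.
#' @export
granges_from_bed0 <- function(chrom, start0, end0, strand = NULL, ...) {
  stopifnot(all(start0 >= 0), all(end0 > start0))
  if (is.null(strand)) strand <- "*"
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1, end = end0),
                         strand = strand, ...)
}

#' Convert a GRanges back to a 0-based half-open data.frame
#'
#' @param gr a `GRanges`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand` plus
#'   any metadata columns.
#' @export
granges_to_bed0 <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  rownames(df) <- NULL
  df
}

# Largest-remainder apportionment of n items into fractions summing to 1.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Base-pair overlap mass between a scored track and a set of intervals:
# sum of value * overlap-width.  Invariant to interval fragmentation.
weighted_overlap_sum <- function(track, region, value) {
  hits <- GenomicRanges::findOverlaps(track, region)
  if (!length(hits)) return(0)
  q <- track[S4Vectors::queryHits(hits)]
  s <- region[S4Vectors::subjectHits(hits)]
  ov <- IRanges::pintersect(IRanges::ranges(q), IRanges::ranges(s))
  sum(value[S4Vectors::queryHits(hits)] * IRanges::width(ov))
}

stop_if_missing_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
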