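#' Generate a synthetic genome annotation
#'
#' Places non-overlapping multi-exon gene models on the configured
#' chromosomes.  Each gene carries an explicit coding span
#' (`thick_start`/`thick_end`, BED12 semantics), so 5'/3' UTR intervals are
#' well defined: they are the exonic base pairs outside the coding span at
#' the 5' and 3' ends respectively.  All coordinates are 0-based
#' half-open.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_genome`: a list with
#'   \describe{
#'     \item{chrom_sizes}{named numeric vector of chromosome lengths.}
#'     \item{genes}{data.frame: `gene_id`, `chrom`, `start`, `end`,
#'       `strand`, `tss`, `thick_start`, `thick_end`.}
#'     \item{exons}{data.frame: `gene_id`, `start`, `end`, sorted and
#'       non-overlapping within each gene.}
#'   }
#'   The TSS equals the gene start on `+` and `end - 1` on `-`.
#' @examples
#' g <- sim_genome(sim_config(n_genes = 10))
#' head(g$genes)
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_genes
    chrom_sizes <- config$chrom_sizes
    genes <- list()
    exons <- list()
    if (n > 0) {
      # apportion genes across chromosomes by length
      per_chrom <- apportion(n, chrom_sizes / sum(chrom_sizes))
      gid <- 0L
      for (ci in seq_along(chrom_sizes)) {
        chrom <- names(chrom_sizes)[ci]
        len <- chrom_sizes[[ci]]
        cursor <- sample(500:2000, 1)
        for (k in seq_len(per_chrom[ci])) {
          gid <- gid + 1L
          n_ex <- sample(3:8, 1)
          widths <- sample(400:800, n_ex, replace = TRUE)
          introns <- if (n_ex > 1) sample(100:1000, n_ex - 1, replace = TRUE) else integer()
          glen <- sum(widths) + sum(introns)
          if (cursor + glen >= len - 500)
            stop(sprintf(
              "genome too small: cannot place gene %d on %s (need %d bp at %d, length %d)",
              gid, chrom, glen, cursor, len), call. = FALSE)
          ex_start <- cursor + c(0, cumsum(widths[-n_ex] + introns))
          ex_end <- ex_start + widths
          strand <- sample(c("+", "-"), 1)
          gstart <- cursor
          gend <- cursor + glen
          # coding span leaves ~200 bp 5' UTR and ~300 bp 3' UTR exonic margin
          if (strand == "+") {
            thick_start <- ex_start[1] + sample(150:250, 1)
            thick_end <- ex_end[n_ex] - sample(250:350, 1)
            tss <- gstart
          } else {
            thick_start <- ex_start[1] + sample(250:350, 1)
            thick_end <- ex_end[n_ex] - sample(150:250, 1)
            tss <- gend - 1
          }
          gene_id <- sprintf("G%04d", gid)
          genes[[gid]] <- data.frame(
            gene_id = gene_id, chrom = chrom, start = gstart, end = gend,
            strand = strand, tss = tss,
            thick_start = thick_start, thick_end = thick_end,
            stringsAsFactors = FALSE)
          exons[[gid]] <- data.frame(gene_id = gene_id,
                                     start = ex_start, end = ex_end,
                                     stringsAsFactors = FALSE)
          cursor <- gend + sample(200:1500, 1)
        }
      }
    }
    out <- list(chrom_sizes = chrom_sizes,
                genes = if (length(genes)) do.call(rbind, genes) else
                  data.frame(gene_id = character(), chrom = character(),
                             start = numeric(), end = numeric(),
                             strand = character(), tss = numeric(),
                             thick_start = numeric(), thick_end = numeric(),
                             stringsAsFactors = FALSE),
                exons = if (length(exons)) do.call(rbind, exons) else
                  data.frame(gene_id = character(), start = numeric(),
                             end = numeric(), stringsAsFactors = FALSE))
    rownames(out$genes) <- NULL
    rownames(out$exons) <- NULL
    class(out) <- "sim_genome"
    out
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d chromosome(s), %.3g Mb, %d gene model(s)\n",
              length(x$chrom_sizes), sum(x$chrom_sizes) / 1e6, nrow(x$genes)))
  invisible(x)
}

#' Exonic UTR spans of a synthetic genome
#'
#' 5' UTR = exonic bases between the gene's 5' end and the coding span;
#' 3' UTR = exonic bases past the coding span, strand-aware.
#'
#' @param genome a [sim_genome()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `type`
#'   (`utr5`/`utr3`), 0-based half-open.
#' @export
gene_utr_spans <- function(genome) {
  genes <- genome$genes
  exons <- genome$exons
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    # exonic bases left of thick_start / right of thick_end
    left <- ex[ex$start < g$thick_start, , drop = FALSE]
    left$end <- pmin(left$end, g$thick_start)
    right <- ex[ex$end > g$thick_end, , drop = FALSE]
    right$start <- pmax(right$start, g$thick_end)
    left$type <- if (g$strand == "+") "utr5" else "utr3"
    right$type <- if (g$strand == "+") "utr3" else "utr5"
    both <- rbind(left, right)
    if (nrow(both)) {
      both <- both[both$end > both$start, , drop = FALSE]
      both$chrom <- g$chrom
      out[[length(out) + 1L]] <- both[, c("gene_id", "chrom", "start", "end", "type")]
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      type = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
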