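#' Generate a clustered CTCF motif landscape with known cluster order
#'
#' Emits `config$n_sites` CTS clusters.  Within a cluster, consecutive
#' motifs are separated by gaps of 0--40 bp (so the cluster links at the
#' 40-bp rule); distinct clusters are separated by more than 40 bp from
#' every other motif.  Truth order (1, 2 or >=3 motifs) is therefore equal
#' to the clustered order by construction.
#'
#' @param genome a [sim_genome()]; motifs are placed on its chromosomes.
#' @param config a [sim_config()].
#' @param linkage_bp the linkage distance the clusters are built to
#'   respect (default 40).
#' @return an object of class `sim_motifs`: a list with
#'   \describe{
#'     \item{motifs}{data.frame `motif_id`, `chrom`, `start`, `end`,
#'       `strand`, `score`, `site_id` (0-based half-open).}
#'     \item{sites}{data.frame `site_id`, `chrom`, `start`, `end`
#'       (cluster span), `order`, `cts_class` (`1X`/`2X`/`3X`).}
#'   }
#' @examples
#' cfg <- sim_config(n_sites = 20)
#' m <- sim_motifs(sim_genome(cfg), cfg)
#' table(m$sites$cts_class)
#' @export
sim_motifs <- function(genome, config, linkage_bp = 40) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 2L), {
    n <- config$n_sites
    w <- config$motif_width
    orders_n <- apportion(n, config$cluster_fractions)
    orders <- rep(c(1L, 2L, 3L), orders_n)
    if (length(orders) && orders_n[3] > 0) {
      # ">=3" class: mix of 3 and 4 motif clusters
      idx3 <- which(orders == 3L)
      orders[idx3] <- sample(c(3L, 4L), length(idx3), replace = TRUE,
                             prob = c(0.8, 0.2))
    }
    orders <- sample(orders)  # shuffle placement order

    chrom_sizes <- config$chrom_sizes
    per_chrom <- apportion(n, chrom_sizes / sum(chrom_sizes))
    motifs <- list(); sites <- list()
    sid <- 0L; mid <- 0L; oi <- 0L
    min_sep <- linkage_bp + 1L
    for (ci in seq_along(chrom_sizes)) {
      chrom <- names(chrom_sizes)[ci]
      len <- chrom_sizes[[ci]]
      cursor <- sample(200:1000, 1)
      for (k in seq_len(per_chrom[ci])) {
        oi <- oi + 1L; sid <- sid + 1L
        ord <- orders[oi]
        gaps <- if (ord > 1) sample(0:linkage_bp, ord - 1, replace = TRUE) else integer()
        span <- ord * w + sum(gaps)
        if (cursor + span >= len - min_sep)
          stop(sprintf(
            "genome too small to place %d motif clusters > %d bp apart on %s",
            per_chrom[ci], linkage_bp, chrom), call. = FALSE)
        starts <- cursor + c(0, cumsum(rep(w, ord - 1) + gaps))
        site_id <- sprintf("S%05d", sid)
        for (j in seq_len(ord)) {
          mid <- mid + 1L
          motifs[[mid]] <- data.frame(
            motif_id = sprintf("M%06d", mid), chrom = chrom,
            start = starts[j], end = starts[j] + w,
            strand = sample(c("+", "-"), 1),
            score = round(stats::runif(1, 5, 30), 3),
            site_id = site_id, stringsAsFactors = FALSE)
        }
        sites[[sid]] <- data.frame(
          site_id = site_id, chrom = chrom,
          start = starts[1], end = starts[ord] + w,
          order = ord,
          cts_class = c("1X", "2X", "3X")[pmin(ord, 3L)],
          stringsAsFactors = FALSE)
        cursor <- starts[ord] + w + min_sep + sample(0:2000, 1)
      }
    }
    out <- list(
      motifs = if (length(motifs)) do.call(rbind, motifs) else
        data.frame(motif_id = character(), chrom = character(),
                   start = numeric(), end = numeric(), strand = character(),
                   score = numeric(), site_id = character(),
                   stringsAsFactors = FALSE),
      sites = if (length(sites)) do.call(rbind, sites) else
        data.frame(site_id = character(), chrom = character(),
                   start = numeric(), end = numeric(), order = integer(),
                   cts_class = character(), stringsAsFactors = FALSE))
    rownames(out$motifs) <- NULL
    rownames(out$sites) <- NULL
    class(out) <- "sim_motifs"
    out
  })
}

#' @export
print.sim_motifs <- function(x, ...) {
  cat(sprintf("Synthetic motif landscape: %d motifs in %d clusters (%s)\n",
              nrow(x$motifs), nrow(x$sites),
              paste(sprintf("%s=%d", names(table(x$sites$cts_class)),
                            table(x$sites$cts_class)), collapse = ", ")))
  invisible(x)
}

#' Motifs as a GRanges
#'
#' @param motifs a `sim_motifs` object (or its `$motifs` data.frame).
#' @return `GRanges` with `motif_id`, `score`, `site_id` metadata.
#' @export
motif_granges <- function(motifs) {
  df <- if (inherits(motifs, "sim_motifs")) motifs$motifs else motifs
  granges_from_bed0(df$chrom, df$start, df$end, strand = df$strand,
                    motif_id = df$motif_id, score = df$score,
                    site_id = df$site_id)
}
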