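#' Simulate a Cut&Run occupancy experiment over CTS sites
#'
#' Draws a per-site baseline occupancy (log-normal around
#' `depth / n_sites`), applies the occupancy-class effect multiplier to
#' the +IAA expectation (optionally scaled further by CTS order via
#' `order_depletion`), samples observed fragment counts per clone with
#' negative-binomial noise, and derives per-clone peak calls at the two
#' confidence thresholds with independent dropout.
#'
#' Counts are sampled as NB(mean = mu, size = 1/dispersion); with
#' `dispersion = 0` the draw is Poisson, and with `exact_counts = TRUE`
#' counts equal `round(mu)` (the noise-free limit used by recovery tests).
#' A site is called in a clone at low confidence when its observed count
#' reaches `call_threshold_low`, and at high confidence when it reaches
#' `call_threshold_high`; high-confidence calls are by construction a
#' subset of low-confidence calls.  Dropout removes a site from both call
#' sets of a clone/condition.
#'
#' @param motifs a [sim_motifs()] result (sites define the truth units).
#' @param config a [sim_config()].
#' @return an object of class `sim_occupancy`: list with
#'   \describe{
#'     \item{sites}{truth table: site coordinates, `order`, `cts_class`,
#'       `occupancy_class`, effective `multiplier`, `baseline`.}
#'     \item{counts}{numeric matrix sites x samples of observed fragment
#'       counts; sample names are `<condition>_<clone>`.}
#'     \item{samples}{data.frame `sample`, `condition`
#'       (`minus`/`plus`), `clone`.}
#'     \item{peak_calls}{nested list `[[condition]][[clone]]` with
#'       elements `high` and `low`, each a `GRanges` of called peaks
#'       (site span padded by `peak_pad`, score = observed count).}
#'     \item{library_sizes}{named per-sample sequenced library sizes
#'       (all equal to `depth`): FPKM is computed against total sequenced
#'       fragments, not the in-site mass, which is what keeps the
#'       +IAA/-IAA ratio interpretable under global depletion.}
#'   }
#' @examples
#' cfg <- sim_config(n_sites = 50, depth = 5e4)
#' occ <- sim_occupancy(sim_motifs(sim_genome(cfg), cfg), cfg)
#' head(occ$samples)
#' @export
sim_occupancy <- function(motifs, config) {
  stopifnot(inherits(motifs, "sim_motifs"), inherits(config, "sim_config"))
  sites <- motifs$sites
  n <- nrow(sites)
  with_seed(derive_seed(config$seed, 3L), {
    cls_n <- apportion(n, config$occupancy_fractions)
    cls <- sample(rep(names(config$occupancy_fractions), cls_n))
    mult <- unname(config$class_multipliers[cls]) *
      config$order_depletion[pmin(sites$order, 3L)]
    baseline <- stats::rlnorm(n,
                              meanlog = log(config$frip * config$depth / max(n, 1)) -
                                config$baseline_sdlog^2 / 2,
                              sdlog = config$baseline_sdlog)

    clones <- sprintf("c%02d", seq_len(config$n_clones))
    samples <- expand.grid(clone = clones, condition = c("minus", "plus"),
                           stringsAsFactors = FALSE)[, 2:1]
    samples$sample <- paste(samples$condition, samples$clone, sep = "_")
    samples <- samples[, c("sample", "condition", "clone")]

    draw <- function(mu) {
      if (config$exact_counts) return(round(mu))
      if (config$dispersion > 0)
        stats::rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
      else stats::rpois(length(mu), mu)
    }
    counts <- sapply(seq_len(nrow(samples)), function(i) {
      mu <- if (samples$condition[i] == "minus") baseline else baseline * mult
      draw(mu)
    })
    counts <- matrix(counts, nrow = n,
                     dimnames = list(sites$site_id, samples$sample))

    pad <- config$peak_pad
    peak_gr <- function(idx, score) {
      if (!length(idx))
        return(GenomicRanges::GRanges())
      chrom_len <- config$chrom_sizes[sites$chrom[idx]]
      granges_from_bed0(sites$chrom[idx],
                        pmax(sites$start[idx] - pad, 0),
                        pmin(sites$end[idx] + pad, chrom_len),
                        name = sites$site_id[idx], score = score)
    }
    peak_calls <- list()
    for (cond in c("minus", "plus")) {
      peak_calls[[cond]] <- list()
      for (cl in clones) {
        smp <- paste(cond, cl, sep = "_")
        cnt <- counts[, smp]
        keep <- stats::runif(n) >= config$dropout
        hi <- which(cnt >= config$call_threshold_high & keep)
        lo <- which(cnt >= config$call_threshold_low & keep)
        peak_calls[[cond]][[cl]] <- list(high = peak_gr(hi, cnt[hi]),
                                         low = peak_gr(lo, cnt[lo]))
      }
    }

    truth <- sites
    truth$occupancy_class <- cls
    truth$multiplier <- mult
    truth$baseline <- baseline
    out <- list(sites = truth, counts = counts, samples = samples,
                peak_calls = peak_calls,
                library_sizes = stats::setNames(rep(config$depth,
                                                    nrow(samples)),
                                                samples$sample))
    class(out) <- "sim_occupancy"
    out
  })
}

#' @export
print.sim_occupancy <- function(x, ...) {
  tb <- table(x$sites$occupancy_class)
  cat(sprintf("Synthetic occupancy experiment: %d sites x %d samples (%s)\n",
              nrow(x$sites), ncol(x$counts),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Materialise per-sample fragment sets from simulated counts
#'
#' Turns the count matrix of a [sim_occupancy()] result into explicit
#' fragment intervals, the input shape consumed by [quantify_fpkm()] and
#' writable as BEDPE.  Fragment lengths follow a two-component mixture
#' emulating sub-nucleosomal (~80 bp) and nucleosomal (~200 bp) Cut&Run
#' fragments; fragment centres scatter around the site centre.  Each
#' sample is padded with uniformly scattered background fragments up to
#' its library size (`depth`), so fragment-based and count-based FPKM
#' quantification see the same libraries.
#'
#' @param occ a [sim_occupancy()] result.
#' @param config the [sim_config()] used to generate it.
#' @return named list of `GRanges` (one per sample), each with a
#'   `fragment_length` metadata column equal to its width.
#' @export
sim_fragments <- function(occ, config) {
  stopifnot(inherits(occ, "sim_occupancy"), inherits(config, "sim_config"))
  sites <- occ$sites
  chroms <- config$chrom_sizes
  with_seed(derive_seed(config$seed, 4L), {
    frag_lengths <- function(k) {
      sub <- stats::runif(k) < 0.5
      len <- ifelse(sub,
                    round(stats::rnorm(k, 80, 15)),
                    round(stats::rnorm(k, 200, 40)))
      pmax(pmin(len, 1900L), 30L)
    }
    out <- lapply(seq_len(nrow(occ$samples)), function(si) {
      cnt <- occ$counts[, si]
      total <- sum(cnt)
      idx <- rep.int(seq_len(nrow(sites)), cnt)
      len <- frag_lengths(total)
      centre <- round((sites$start[idx] + sites$end[idx]) / 2 +
                        stats::rnorm(total, 0, 40))
      n_bg <- max(0, round(config$depth) - total)
      bg_chrom <- sample(names(chroms), n_bg, replace = TRUE,
                         prob = chroms / sum(chroms))
      bg_len <- frag_lengths(n_bg)
      bg_centre <- round(stats::runif(n_bg, 0, chroms[bg_chrom]))
      chrom <- c(sites$chrom[idx], bg_chrom)
      centre <- c(centre, bg_centre)
      len <- c(len, bg_len)
      if (!length(chrom)) return(GenomicRanges::GRanges())
      start <- pmax(centre - len %/% 2, 0)
      end <- start + len
      chrom_len <- chroms[chrom]
      end <- pmin(end, chrom_len)
      start <- pmax(pmin(start, end - 1), 0)
      gr <- granges_from_bed0(chrom, start, end)
      gr$fragment_length <- GenomicRanges::width(gr)
      GenomicRanges::sort(gr)
    })
    names(out) <- occ$samples$sample
    out
  })
}
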