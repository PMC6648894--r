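#' Simulate Capture-C coverage tracks with a planted loop effect
#'
#' Builds piecewise-constant (bedGraph-style) tracks for each condition
#' and replicate on a dedicated viewpoint chromosome.  Signal over the
#' capture-probe interval has height `cc_probe_height`; each loop window
#' has height `height * cc_multipliers[condition]`; everywhere else the
#' track sits at `cc_baseline`.  Noise is multiplicative log-normal per
#' bin (`cc_noise_sd = 0` gives deterministic tracks), so a planted
#' multiplier of 0 yields exactly zero loop signal.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_capturec`: list with
#'   \describe{
#'     \item{tracks}{nested list `[[condition]][[replicate]]`, each a
#'       `GRanges` with a `score` column (disjoint, sorted bins).}
#'     \item{probe}{`GRanges` of the capture-probe interval.}
#'     \item{windows}{`GRanges` of loop windows with `loop_id`.}
#'     \item{truth}{data.frame `loop_id`, `multiplier_minus`,
#'       `multiplier_plus`, `height`.}
#'   }
#' @examples
#' cc <- sim_capturec(sim_config(cc_noise_sd = 0))
#' names(cc$tracks)
#' @export
sim_capturec <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 5L), {
    bin <- config$cc_bin
    n_bins <- ceiling(config$cc_length / bin)
    starts <- (seq_len(n_bins) - 1) * bin
    ends <- pmin(starts + bin, config$cc_length)
    probe <- granges_from_bed0(config$cc_chrom, config$cc_probe[1],
                               config$cc_probe[2])
    loops <- config$cc_loops
    windows <- granges_from_bed0(rep(config$cc_chrom, nrow(loops)),
                                 loops$start, loops$end,
                                 loop_id = loops$loop_id)
    in_probe <- starts < config$cc_probe[2] & ends > config$cc_probe[1]
    loop_idx <- rep(NA_integer_, n_bins)
    for (i in seq_len(nrow(loops)))
      loop_idx[starts < loops$end[i] & ends > loops$start[i]] <- i

    base_height <- function(mult) {
      h <- rep(config$cc_baseline, n_bins)
      h[!is.na(loop_idx)] <- loops$height[loop_idx[!is.na(loop_idx)]] * mult
      h[in_probe] <- config$cc_probe_height
      h
    }
    tracks <- list()
    for (cond in c("minus", "plus")) {
      mult <- config$cc_multipliers[[cond]]
      h <- base_height(mult)
      tracks[[cond]] <- lapply(seq_len(config$cc_replicates), function(r) {
        noise <- if (config$cc_noise_sd > 0)
          exp(stats::rnorm(n_bins, -config$cc_noise_sd^2 / 2, config$cc_noise_sd))
        else rep(1, n_bins)
        granges_from_bed0(config$cc_chrom, starts, ends, score = h * noise)
      })
      names(tracks[[cond]]) <- sprintf("rep%d", seq_len(config$cc_replicates))
    }
    out <- list(tracks = tracks, probe = probe, windows = windows,
                truth = data.frame(loop_id = loops$loop_id,
                                   multiplier_minus = config$cc_multipliers[["minus"]],
                                   multiplier_plus = config$cc_multipliers[["plus"]],
                                   height = loops$height,
                                   stringsAsFactors = FALSE))
    class(out) <- "sim_capturec"
    out
  })
}

#' @export
print.sim_capturec <- function(x, ...) {
  cat(sprintf("Synthetic Capture-C: %d loop window(s), %d x %d tracks\n",
              length(x$windows), length(x$tracks),
              length(x$tracks[[1]])))
  invisible(x)
}
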