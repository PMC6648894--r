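#' Normalise a Capture-C track by its probe-region signal
#'
#' Divides every track value by the total signal mass over the capture
#' probe, where mass is the base-pair-weighted sum
#' `sum(value * overlap_bp)`.  After normalisation the probe-region mass
#' is exactly 1, making interaction frequencies comparable across samples
#' and invariant to how the bedGraph intervals are fragmented.
#'
#' @param track `GRanges` with a numeric `score` column (bedGraph
#'   semantics: disjoint intervals, piecewise-constant values).
#' @param probe `GRanges` of the capture-probe interval.
#' @param sample optional sample label used in error messages.
#' @return the track with `score` divided by the probe mass.
#' @export
probe_normalize <- function(track, probe, sample = NULL) {
  stopifnot(!is.null(track$score))
  s <- weighted_overlap_sum(track, probe, track$score)
  if (s <= 0)
    stop(sprintf("probe-region signal is zero%s: cannot normalise",
                 if (is.null(sample)) "" else sprintf(" in sample '%s'", sample)),
         call. = FALSE)
  track$score <- track$score / s
  track
}

#' Relative interaction frequency over loop windows
#'
#' For each loop window and each probe-normalised replicate track, the
#' interaction frequency is the base-pair-weighted signal mass
#' `sum(value * overlap_bp)` over the window.  Condition means, the
#' +IAA/-IAA ratio, and a two-tailed two-sample t-test across replicates
#' (equal-variance by default, matching 2--3 biological replicates;
#' Welch optional) are reported.  The P value is omitted (NA) unless both
#' conditions have at least two replicates.  A window on a chromosome
#' absent from a track contributes frequency 0 with a warning.
#'
#' @param tracks nested list `[[condition]][[replicate]]` of normalised
#'   tracks; conditions must be named `minus` and `plus`.
#' @param windows `GRanges` of loop windows with a `loop_id` column.
#' @param welch use the Welch (unequal-variance) t-test.
#' @return object of class `interaction_result`: list with
#'   `frequencies` (long data.frame: `loop_id`, `condition`, `replicate`,
#'   `frequency`) and `summary` (data.frame: `loop_id`, `mean_minus`,
#'   `mean_plus`, `ratio`, `t_stat`, `p_value`).
#' @export
relative_interaction <- function(tracks, windows, welch = FALSE) {
  stopifnot(all(c("minus", "plus") %in% names(tracks)),
            !is.null(windows$loop_id))
  freq_rows <- list()
  for (cond in c("minus", "plus")) {
    reps <- tracks[[cond]]
    if (!length(reps)) stop("each condition needs >= 1 replicate", call. = FALSE)
    for (r in seq_along(reps)) {
      tr <- reps[[r]]
      for (w in seq_along(windows)) {
        win <- windows[w]
        if (!as.character(GenomicRanges::seqnames(win)) %in%
            GenomeInfoDb::seqlevels(tr)) {
          warning(sprintf("window %s on chromosome absent from a %s track; frequency 0",
                          win$loop_id, cond))
          f <- 0
        } else {
          f <- weighted_overlap_sum(tr, win, tr$score)
        }
        freq_rows[[length(freq_rows) + 1L]] <- data.frame(
          loop_id = win$loop_id, condition = cond,
          replicate = names(reps)[r] %||% sprintf("rep%d", r),
          frequency = f, stringsAsFactors = FALSE)
      }
    }
  }
  freq <- do.call(rbind, freq_rows)
  summ <- lapply(unique(freq$loop_id), function(id) {
    fm <- freq$frequency[freq$loop_id == id & freq$condition == "minus"]
    fp <- freq$frequency[freq$loop_id == id & freq$condition == "plus"]
    tt <- if (length(fm) >= 2 && length(fp) >= 2)
      two_sample_t(fp, fm, welch = welch)
    else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(loop_id = id, mean_minus = mean(fm), mean_plus = mean(fp),
               ratio = mean(fp) / mean(fm), t_stat = tt$statistic,
               p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  out <- list(frequencies = freq, summary = do.call(rbind, summ))
  rownames(out$summary) <- NULL
  class(out) <- "interaction_result"
  out
}

# Two-tailed two-sample t-test.  Implemented directly so that degenerate
# replicate sets have defined behaviour: zero pooled variance gives t = 0,
# P = 1 when the means agree and P = 0 otherwise (stats::t.test errors on
# constant data).
two_sample_t <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  if (welch) {
    se2 <- stats::var(x) / n1 + stats::var(y) / n2
    df <- se2^2 / ((stats::var(x) / n1)^2 / (n1 - 1) +
                     (stats::var(y) / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (!is.finite(se2) || se2 <= 0) {
    if (abs(d) < .Machine$double.eps^0.5)
      return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(d) * Inf, p_value = 0))
  }
  t <- d / sqrt(se2)
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("Relative interaction frequencies (probe-normalised)\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: -IAA %.4g, +IAA %.4g, ratio %.3f, P = %s\n",
                s$loop_id, s$mean_minus, s$mean_plus, s$ratio,
                if (is.na(s$p_value)) "NA" else sprintf("%.3g", s$p_value)))
  }
  invisible(x)
}
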