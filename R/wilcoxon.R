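#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' For small groups the two-sided P value is computed by exhaustive
#' enumeration of all group assignments of the pooled sample (handling
#' ties exactly): P is the fraction of assignments whose U statistic is at
#' least as extreme, around its null mean, as the observed one.  For
#' larger groups the tie-corrected normal approximation with continuity
#' correction is used (the same formula as `stats::wilcox.test` with
#' `correct = TRUE`).
#'
#' The exact branch is taken when both groups have fewer than
#' `approx_min` observations and the number of assignments
#' `choose(n1 + n2, n1)` does not exceed `exact_limit`.
#'
#' @param x,y numeric vectors.
#' @param approx_min per-group size at which the normal approximation
#'   takes over (default 20).
#' @param exact_limit largest number of enumerated assignments (default
#'   2e5).
#' @return list with `statistic` (U for the first group), `p_value` and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcox_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
wilcox_rank_sum <- function(x, y, approx_min = 20, exact_limit = 2e5) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  exact_ok <- n1 < approx_min && n2 < approx_min &&
    choose(n1 + n2, n1) <= exact_limit
  if (exact_ok) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(statistic = u_obs, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0)  # all observations identical
    return(list(statistic = u_obs, p_value = 1, method = "normal"))
  z <- u_obs - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u_obs, p_value = p, method = "normal")
}

#' Compare binding change between CTS classes
#'
#' Pairwise two-sided Wilcoxon rank-sum tests on the per-peak log2 fold
#' changes of the 1X/2X/3X CTS groups, with per-group sizes and medians.
#' Peaks without a CTS assignment (`cts_class == "none"`) are excluded.
#' Pairs involving an empty group are skipped with a warning.
#'
#' @param peaks classified `GRanges` (needs `log2fc` and `cts_class`), or
#'   a data.frame with those columns.
#' @param ... passed to [wilcox_rank_sum()].
#' @return object of class `cts_comparison`: list with `groups`
#'   (data.frame `cts_class`, `n`, `median_log2fc`) and `pairs`
#'   (data.frame `group1`, `group2`, `statistic`, `p_value`, `method`).
#' @export
compare_cts_groups <- function(peaks, ...) {
  df <- if (inherits(peaks, "GRanges"))
    data.frame(log2fc = peaks$log2fc, cts_class = peaks$cts_class,
               stringsAsFactors = FALSE)
  else peaks
  stop_if_missing_cols(df, c("log2fc", "cts_class"), "peak table")
  df <- df[df$cts_class != "none" & !is.na(df$cts_class), , drop = FALSE]
  classes <- intersect(c("1X", "2X", "3X"), unique(df$cts_class))
  if (length(classes) < 2)
    stop("need at least 2 non-empty CTS groups", call. = FALSE)
  vals <- split(df$log2fc, factor(df$cts_class, levels = classes))
  groups <- data.frame(cts_class = classes,
                       n = vapply(vals, length, integer(1)),
                       median_log2fc = vapply(vals, stats::median, numeric(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(classes, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (!length(vals[[a]]) || !length(vals[[b]])) {
      warning(sprintf("skipping %s vs %s: empty group", a, b))
      return(NULL)
    }
    w <- wilcox_rank_sum(vals[[a]], vals[[b]], ...)
    data.frame(group1 = a, group2 = b, statistic = w$statistic,
               p_value = w$p_value, method = w$method,
               stringsAsFactors = FALSE)
  })
  out <- list(groups = groups, pairs = do.call(rbind, res))
  rownames(out$pairs) <- NULL
  class(out) <- "cts_comparison"
  out
}

#' @export
print.cts_comparison <- function(x, ...) {
  cat("CTS group comparison (two-sided Wilcoxon rank-sum on log2FC)\n")
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: n = %d, median log2FC = %.3f\n",
                x$groups$cts_class[i], x$groups$n[i],
                x$groups$median_log2fc[i]))
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  %s vs %s: P = %.3g (%s)\n",
                x$pairs$group1[i], x$pairs$group2[i], x$pairs$p_value[i],
                x$pairs$method[i]))
  invisible(x)
}
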