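#' Simulate an expression table with planted DEG / loop-gene structure
#'
#' Generates a differential-expression table (gene, log2FC of depleted vs
#' control, adjusted P, FPKM per condition) in which
#' \itemize{
#'   \item exactly `n_deg` planted DEGs satisfy |log2FC| >= `deg_lfc`,
#'     adjusted P <= `deg_padj` and max-condition FPKM >= `deg_fpkm`,
#'     while every other gene has |log2FC| drawn strictly below the
#'     threshold, so threshold filtering recovers the planted set exactly;
#'   \item a loop-disrupted gene list of size `n_loop_genes` shares exactly
#'     `loop_overlap` genes with the DEG set;
#'   \item an ordered target signature of `n_targets` genes contains
#'     `targets_excluded` genes planted below the FPKM floor and
#'     `targets_decreased` evaluable genes with log2FC < 0;
#'   \item enhancer-docking cohorts overlap the DEG set by the configured
#'     counts, with a single high-expression (FPKM >= 10) DEG shared by
#'     all cohorts.
#' }
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_expression`: list with
#'   \describe{
#'     \item{expression}{data.frame `gene_id`, `log2fc`, `padj`,
#'       `fpkm_minus`, `fpkm_plus`.}
#'     \item{loop_genes}{character vector (loop-disrupted list).}
#'     \item{targets}{ordered character vector (target signature).}
#'     \item{docking}{named list of character vectors (cohorts).}
#'     \item{truth}{data.frame `gene_id`, `deg`, `loop_disrupted`,
#'       `target_status` (`none`/`excluded`/`decreased`/`increased`),
#'       `docking_shared`.}
#'   }
#' @examples
#' ex <- sim_expression(sim_config())
#' nrow(ex$expression)
#' @export
sim_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 6L), {
    n <- config$n_genes_expr
    ids <- sprintf("EG%05d", seq_len(n))
    deg_idx <- sample(n, config$n_deg)
    non_deg <- setdiff(seq_len(n), deg_idx)

    # background genes: sub-threshold fold changes, free P values; the
    # dispersion is set so the global transcriptome correlation between
    # conditions sits near the ~0.95 Spearman r of an acute depletion
    # time course
    lfc <- stats::rnorm(n, 0, 0.38)
    lfc <- pmin(pmax(lfc, -(config$deg_lfc - 1e-3)), config$deg_lfc - 1e-3)
    padj <- stats::runif(n)
    fpkm_minus <- stats::rlnorm(n, meanlog = log(5), sdlog = 1.0)

    # planted DEGs: above every threshold (60% down, matching a depletion
    # experiment where the perturbed factor's targets drop)
    sgn <- ifelse(stats::runif(config$n_deg) < 0.6, -1, 1)
    lfc[deg_idx] <- sgn * (config$deg_lfc + stats::rexp(config$n_deg, 1.5))
    padj[deg_idx] <- stats::runif(config$n_deg, 0, config$deg_padj)
    fpkm_minus[deg_idx] <- config$deg_fpkm + stats::rlnorm(config$n_deg,
                                                           log(10), 1)

    # loop-disrupted list: planted overlap with DEGs, rest background
    loop_idx <- c(sample(deg_idx, config$loop_overlap),
                  sample(non_deg, config$n_loop_genes - config$loop_overlap))

    # target signature: drawn from background so its planted fold-change
    # signs are free of the DEG constraints
    pool <- setdiff(non_deg, loop_idx)
    tgt_idx <- sample(pool, config$n_targets)
    n_exc <- config$targets_excluded
    n_dec <- config$targets_decreased
    n_inc <- config$n_targets - n_exc - n_dec
    status <- c(rep("excluded", n_exc), rep("decreased", n_dec),
                rep("increased", n_inc))
    status <- sample(status)  # interleave along the signature order
    exc <- tgt_idx[status == "excluded"]
    dec <- tgt_idx[status == "decreased"]
    inc <- tgt_idx[status == "increased"]
    # excluded: both conditions under the FPKM floor
    lfc[exc] <- stats::runif(length(exc), -0.6, 0.6)
    fpkm_minus[exc] <- stats::runif(length(exc), 0.05, 0.6)
    lfc[dec] <- -stats::runif(length(dec), 0.1, 0.95)
    fpkm_minus[dec] <- 1.5 + stats::rlnorm(length(dec), log(8), 0.8)
    lfc[inc] <- stats::runif(length(inc), 0.1, 0.95)
    fpkm_minus[inc] <- 1.5 + stats::rlnorm(length(inc), log(8), 0.8)

    # docking cohorts: per-cohort DEG overlaps, one shared FPKM>=10 gene
    shared <- sample(deg_idx, 1)
    lfc[shared] <- (config$deg_lfc + stats::runif(1, 0.2, 1)) *
      sample(c(-1, 1), 1)
    fpkm_minus[shared] <- 50
    other_deg <- setdiff(deg_idx, shared)
    docking <- list()
    used <- integer()
    for (nm in names(config$docking_sizes)) {
      k <- config$docking_overlaps[[nm]]
      ov <- sample(setdiff(other_deg, used), k - 1)
      used <- c(used, ov)  # keep cohort-specific DEGs disjoint
      # cap these genes' expression below the high-FPKM cutoff so the
      # shared gene is the only all-cohort survivor at FPKM >= 10
      lfc[ov] <- sign(lfc[ov]) * (config$deg_lfc + stats::runif(k - 1, 0, 0.3))
      fpkm_minus[ov] <- stats::runif(k - 1, 1.2, 3.5)
      filler <- sample(setdiff(pool, tgt_idx),
                       config$docking_sizes[[nm]] - k)
      docking[[nm]] <- ids[c(shared, ov, filler)]
    }

    fpkm_plus <- fpkm_minus * 2^lfc
    expression <- data.frame(gene_id = ids, log2fc = lfc, padj = padj,
                             fpkm_minus = fpkm_minus, fpkm_plus = fpkm_plus,
                             stringsAsFactors = FALSE)
    truth <- data.frame(
      gene_id = ids,
      deg = seq_len(n) %in% deg_idx,
      loop_disrupted = seq_len(n) %in% loop_idx,
      target_status = "none",
      docking_shared = seq_len(n) == shared,
      stringsAsFactors = FALSE)
    truth$target_status[tgt_idx] <- status
    out <- list(expression = expression,
                loop_genes = ids[loop_idx],
                targets = ids[tgt_idx],
                docking = docking,
                truth = truth)
    class(out) <- "sim_expression"
    out
  })
}

#' @export
print.sim_expression <- function(x, ...) {
  cat(sprintf(
    "Synthetic expression tables: %d genes, %d planted DEGs, %d loop genes, %d targets\n",
    nrow(x$expression), sum(x$truth$deg), length(x$loop_genes),
    length(x$targets)))
  invisible(x)
}
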