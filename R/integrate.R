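#' Filter an expression table to differentially expressed genes
#'
#' A gene is kept when |log2FC| >= `lfc_threshold`, adjusted P <=
#' `padj_threshold` (inclusive), and its FPKM — combined over the two
#' conditions by `fpkm_mode` (default: the maximum) — is at least
#' `fpkm_threshold`.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `padj`,
#'   `fpkm_minus`, `fpkm_plus`.
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @param padj_threshold adjusted-P cutoff (default 0.05).
#' @param fpkm_threshold expression cutoff (default 1).
#' @param fpkm_mode how the two condition FPKMs enter the cutoff:
#'   `"max"` (default; expressed in either state), `"min"` or `"mean"`.
#' @return the kept rows of `table`.
#' @examples
#' tb <- data.frame(gene_id = c("a", "b"), log2fc = c(1.2, 0.9),
#'                  padj = c(0.01, 0.001), fpkm_minus = c(5, 100),
#'                  fpkm_plus = c(11, 80))
#' filter_degs(tb)$gene_id  # only "a": "b" fails the fold-change cutoff
#' @export
filter_degs <- function(table, lfc_threshold = 1, padj_threshold = 0.05,
                        fpkm_threshold = 1,
                        fpkm_mode = c("max", "min", "mean")) {
  fpkm_mode <- match.arg(fpkm_mode)
  stop_if_missing_cols(table, c("gene_id", "log2fc", "padj", "fpkm_minus",
                                "fpkm_plus"), "expression table")
  fpkm <- combine_fpkm(table, fpkm_mode)
  keep <- abs(table$log2fc) >= lfc_threshold &
    table$padj <= padj_threshold & fpkm >= fpkm_threshold
  table[keep & !is.na(keep), , drop = FALSE]
}

combine_fpkm <- function(table, fpkm_mode) {
  switch(fpkm_mode,
         max = pmax(table$fpkm_minus, table$fpkm_plus),
         min = pmin(table$fpkm_minus, table$fpkm_plus),
         mean = (table$fpkm_minus + table$fpkm_plus) / 2)
}

#' Exact overlap between two gene sets
#'
#' Case-normalised exact intersection; duplicate identifiers are removed
#' with a warning.
#'
#' @param a,b character vectors of gene identifiers.
#' @return object of class `overlap_result`: list with `n_a`, `n_b`,
#'   `n_overlap` and `members` (sorted intersection).
#' @examples
#' overlap_sets(c("a", "b", "c"), c("B", "c", "d"))$n_overlap
#' @export
overlap_sets <- function(a, b) {
  norm <- function(x, nm) {
    x <- toupper(x)
    if (anyDuplicated(x)) {
      warning(sprintf("deduplicated %d identifier(s) in set %s",
                      sum(duplicated(x)), nm))
      x <- unique(x)
    }
    x
  }
  a <- norm(a, "A"); b <- norm(b, "B")
  members <- sort(intersect(a, b))
  out <- list(n_a = length(a), n_b = length(b),
              n_overlap = length(members), members = members)
  class(out) <- "overlap_result"
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Gene-set overlap: |A| = %d, |B| = %d, intersection = %d\n",
              x$n_a, x$n_b, x$n_overlap))
  invisible(x)
}

#' Overlap DEGs with enhancer-docking gene cohorts at an expression cutoff
#'
#' Restricts the DEG set to genes whose combined-condition FPKM reaches
#' `fpkm_cutoff`, intersects it with each docking cohort, and reports the
#' genes shared by every comparison.
#'
#' @param deg_set character vector of DEG identifiers.
#' @param docking_sets named list of character vectors (one per cohort).
#' @param expression expression table resolving the FPKM values.
#' @param fpkm_cutoff expression cutoff (0 disables the filter).
#' @param fpkm_mode see [filter_degs()].
#' @return list with `per_set` (named list of [overlap_sets()] results)
#'   and `shared` (genes in every cohort intersection).
#' @export
docking_overlap <- function(deg_set, docking_sets, expression,
                            fpkm_cutoff = 10,
                            fpkm_mode = c("max", "min", "mean")) {
  fpkm_mode <- match.arg(fpkm_mode)
  stopifnot(length(docking_sets) >= 1)
  stop_if_missing_cols(expression, c("gene_id", "fpkm_minus", "fpkm_plus"),
                       "expression table")
  if (fpkm_cutoff > 0) {
    fpkm <- combine_fpkm(expression, fpkm_mode)
    expressed <- toupper(expression$gene_id[fpkm >= fpkm_cutoff])
    deg_set <- deg_set[toupper(deg_set) %in% expressed]
  }
  per_set <- lapply(names(docking_sets), function(nm) {
    if (!length(docking_sets[[nm]]))
      warning(sprintf("docking set '%s' is empty", nm))
    overlap_sets(deg_set, docking_sets[[nm]])
  })
  names(per_set) <- names(docking_sets)
  shared <- Reduce(intersect, lapply(per_set, function(x) x$members))
  list(per_set = per_set, shared = sort(shared))
}

#' Concordance of a target signature with the expression response
#'
#' Of `target_genes`, those resolvable in the table and expressed above
#' `fpkm_exclude` (strictly, combined over conditions by `fpkm_mode`) are
#' evaluable; of these, the decreased genes are those with log2FC < 0 (a
#' descriptive criterion, no significance requirement).  The reported
#' fraction uses the full target-list size as denominator.
#'
#' @param target_genes character vector (ordered signature).
#' @param expression expression table.
#' @param fpkm_exclude expression floor below which targets are not
#'   evaluable (default 1).
#' @param fpkm_mode see [filter_degs()].
#' @return object of class `concordance_result`: list with `n_targets`,
#'   `n_unresolved`, `n_evaluable`, `n_decreased`, `fraction` and
#'   `decreased` (gene ids).
#' @export
signature_concordance <- function(target_genes, expression, fpkm_exclude = 1,
                                  fpkm_mode = c("max", "min", "mean")) {
  fpkm_mode <- match.arg(fpkm_mode)
  if (!length(target_genes)) stop("empty target list", call. = FALSE)
  stop_if_missing_cols(expression, c("gene_id", "log2fc", "fpkm_minus",
                                     "fpkm_plus"), "expression table")
  idx <- match(toupper(target_genes), toupper(expression$gene_id))
  unresolved <- sum(is.na(idx))
  hit <- expression[idx[!is.na(idx)], , drop = FALSE]
  evaluable <- combine_fpkm(hit, fpkm_mode) > fpkm_exclude
  decreased <- evaluable & hit$log2fc < 0
  out <- list(n_targets = length(target_genes),
              n_unresolved = unresolved,
              n_evaluable = sum(evaluable),
              n_decreased = sum(decreased),
              fraction = sum(decreased) / length(target_genes),
              decreased = hit$gene_id[decreased])
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Signature concordance: %d/%d targets decreased (%d evaluable, %d unresolved)\n",
    x$n_decreased, x$n_targets, x$n_evaluable, x$n_unresolved))
  invisible(x)
}

#' Spearman correlation between condition-wise transcriptomes
#'
#' Rank correlation of log2(FPKM + 1) between the two conditions, after
#' excluding genes below the expression floor in both conditions.  Ties
#' receive average ranks.
#'
#' @param fpkm_minus,fpkm_plus paired non-negative FPKM vectors.
#' @param floor genes with both values < `floor` are excluded (default 1).
#' @return list with `r` (Spearman correlation, NA with a message if a
#'   filtered vector is constant) and `n_used`.
#' @export
transcriptome_correlation <- function(fpkm_minus, fpkm_plus, floor = 1) {
  stopifnot(length(fpkm_minus) == length(fpkm_plus))
  keep <- !(fpkm_minus < floor & fpkm_plus < floor) &
    is.finite(fpkm_minus) & is.finite(fpkm_plus)
  x <- log2(fpkm_minus[keep] + 1)
  y <- log2(fpkm_plus[keep] + 1)
  if (length(x) < 3) stop("need >= 3 gene pairs after filtering", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("constant expression vector: correlation undefined")
    return(list(r = NA_real_, n_used = length(x)))
  }
  list(r = stats::cor(x, y, method = "spearman"), n_used = length(x))
}
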