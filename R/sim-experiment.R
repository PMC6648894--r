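#' Run every synthetic-data generator and optionally write all inputs
#'
#' Convenience wrapper chaining [sim_genome()], [sim_motifs()],
#' [sim_occupancy()], [sim_capturec()] and [sim_expression()] under one
#' config, and assembling the combined ground truth.  With `outdir` set,
#' all pipeline input files are written in their standard on-disk formats
#' (see [sim_io]).
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @param write_fragments also materialise and write per-sample BEDPE
#'   fragment files (only sensible at modest `depth`).
#' @return an object of class `sim_experiment`: list with elements
#'   `genome`, `motifs`, `occupancy`, `capturec`, `expression` and
#'   `truth` (list of `sites`, `genes`, `loops` truth tables).
#' @examples
#' ex <- sim_experiment(sim_config(n_sites = 30, depth = 1e4, n_genes = 20))
#' names(ex)
#' @export
sim_experiment <- function(config, outdir = NULL, write_fragments = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim_genome(config)
  motifs <- sim_motifs(genome, config)
  occupancy <- sim_occupancy(motifs, config)
  capturec <- sim_capturec(config)
  expression <- sim_expression(config)
  truth <- list(
    sites = occupancy$sites[, c("site_id", "chrom", "start", "end", "order",
                                "cts_class", "occupancy_class", "multiplier")],
    genes = expression$truth,
    loops = capturec$truth)
  out <- list(genome = genome, motifs = motifs, occupancy = occupancy,
              capturec = capturec, expression = expression, truth = truth)
  class(out) <- "sim_experiment"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(outdir, ...)
    write_chrom_sizes(genome$chrom_sizes, fp("chrom.sizes"))
    write_genes_bed12(genome, fp("genes.bed"))
    write_motifs_bed(motifs, fp("motifs.bed"))
    for (cond in names(occupancy$peak_calls))
      for (cl in names(occupancy$peak_calls[[cond]]))
        for (conf in c("high", "low"))
          write_narrowpeak(occupancy$peak_calls[[cond]][[cl]][[conf]],
                           fp(sprintf("peaks_%s_%s_%s.narrowPeak",
                                      cond, cl, conf)))
    if (write_fragments) {
      frags <- sim_fragments(occupancy, config)
      for (smp in names(frags))
        write_bedpe(frags[[smp]], fp(sprintf("fragments_%s.bedpe", smp)))
    }
    for (cond in names(capturec$tracks))
      for (rep in names(capturec$tracks[[cond]]))
        write_bedgraph(capturec$tracks[[cond]][[rep]],
                       fp(sprintf("capturec_%s_%s.bedGraph", cond, rep)))
    rtracklayer::export(capturec$probe, fp("probe.bed"), format = "BED")
    win <- capturec$windows
    win$name <- win$loop_id
    rtracklayer::export(win, fp("loop_windows.bed"), format = "BED")
    write_expression_tsv(expression$expression, fp("expression.tsv"))
    write_gene_list(expression$loop_genes, fp("loop_genes.txt"))
    write_gene_list(expression$targets, fp("targets.txt"))
    for (nm in names(expression$docking))
      write_gene_list(expression$docking[[nm]],
                      fp(sprintf("docking_%s.txt", nm)))
    jsonlite::write_json(truth, fp("truth.json"), digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Synthetic depletion experiment\n")
  print(x$genome); print(x$motifs); print(x$occupancy)
  print(x$capturec); print(x$expression)
  invisible(x)
}
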