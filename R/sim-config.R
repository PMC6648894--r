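#' Configuration for the synthetic depletion experiment
#'
#' Bundles every tunable of the synthetic-data generators into one
#' validated object.  The defaults describe the study conditions the
#' package is designed around: three single-cell-derived clones profiled
#' with and without auxin (IAA), CTCF target sites (CTSes) in isolated
#' (1X), paired (2X) and clustered (3X) motif configurations, occupancy
#' classes in roughly the proportions observed for an acute CTCF degron
#' (about 48\% reduced, 51\% retained, 1\% gained), depletion effect
#' multipliers of 0.25/1.0/2.5 on the +IAA expectation, a Capture-C loop
#' that drops to a quarter of its contact frequency on depletion, and an
#' expression scenario with 330 planted differentially expressed genes, a
#' 664-gene loop-disrupted list sharing 10 genes with the DEG set, and a
#' 100-gene downregulated target signature of which 6 genes fall below the
#' FPKM floor and 92 decrease.
#'
#' @param seed integer master seed; every generator derives its stream
#'   from it, so a fixed config is fully deterministic.
#' @param n_sites number of CTS clusters to simulate.
#' @param cluster_fractions named fractions of sites of motif order 1, 2
#'   and >=3 (`x1`, `x2`, `x3`); must sum to 1.
#' @param occupancy_fractions named fractions of `reduced`, `retained`,
#'   `gained` sites; must sum to 1.
#' @param class_multipliers expected +IAA/-IAA count ratio per occupancy
#'   class; all > 0.
#' @param order_depletion extra multiplier applied to the +IAA expectation
#'   by CTS order (length 3, orders 1/2/>=3); default no order effect.
#'   Values below 1 model stronger depletion at clustered sites.
#' @param depth sequenced fragments per sample (library size).
#' @param frip expected fraction of a library's fragments falling in CTS
#'   sites in the untreated condition; the remainder is genomic
#'   background.  Keeping library sizes fixed at `depth` while the in-site
#'   mass shrinks on depletion reproduces how FPKM is computed against
#'   total sequenced reads.
#' @param dispersion negative-binomial dispersion of observed counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param exact_counts if `TRUE`, observed counts are the rounded
#'   expectations (the noise-free limit).
#' @param baseline_sdlog log-normal spread of per-site baseline occupancy.
#' @param n_clones number of clonal replicates per condition (>= 2).
#' @param call_threshold_high,call_threshold_low observed-count thresholds
#'   above which a site is "called" in a clone at high / low confidence
#'   (high confidence is the stricter cutoff, so `high > low`).
#' @param dropout probability that a truly occupied site is missing from a
#'   clone's call set (applied independently per site, clone, condition).
#' @param motif_width width in bp of a single motif occurrence.
#' @param peak_pad padding in bp added to each side of a site span when
#'   emitting peak calls.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_genes number of gene models to place on the genome.
#' @param cc_chrom,cc_length chromosome name and length for the Capture-C
#'   locus.
#' @param cc_bin bedGraph bin width in bp.
#' @param cc_probe numeric length-2 (start, end), 0-based half-open span of
#'   the capture probe.
#' @param cc_probe_height raw signal height over the probe.
#' @param cc_baseline background signal height outside probe and loops.
#' @param cc_loops data.frame with columns `loop_id`, `start`, `end`,
#'   `height`: loop windows and their -IAA signal heights.  Windows must
#'   not overlap the probe (probe normalisation would be degenerate).
#' @param cc_multipliers named (`minus`, `plus`) multipliers applied to
#'   loop-window signal per condition.
#' @param cc_replicates replicates per condition for Capture-C.
#' @param cc_noise_sd standard deviation of multiplicative log-normal
#'   track noise; 0 gives deterministic tracks.
#' @param n_genes_expr number of genes in the expression table.
#' @param n_deg number of planted differentially expressed genes.
#' @param n_loop_genes size of the loop-disrupted gene list.
#' @param loop_overlap planted overlap between DEG set and loop-disrupted
#'   list; must not exceed either set size.
#' @param deg_lfc,deg_padj,deg_fpkm the DEG thresholds the planted genes
#'   are generated to satisfy (|log2FC| >= `deg_lfc`, adjusted P <=
#'   `deg_padj`, FPKM >= `deg_fpkm`).
#' @param n_targets size of the downregulated target signature.
#' @param targets_excluded how many signature genes are planted below the
#'   FPKM floor (not evaluable).
#' @param targets_decreased how many evaluable signature genes decrease.
#' @param docking_sizes named sizes of enhancer-docking gene cohorts.
#' @param docking_overlaps per-cohort planted overlap with the DEG set
#'   (same names as `docking_sizes`); exactly one high-FPKM DEG is shared
#'   by all cohorts.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_sites = 50, depth = 1e4)
#' cfg$class_multipliers
#' @export
sim_config <- function(seed = 20190525,
                       n_sites = 2000,
                       cluster_fractions = c(x1 = 0.70, x2 = 0.20, x3 = 0.10),
                       occupancy_fractions = c(reduced = 0.481,
                                               retained = 0.507,
                                               gained = 0.012),
                       class_multipliers = c(reduced = 0.25,
                                             retained = 1.0,
                                             gained = 2.5),
                       order_depletion = c(1, 1, 1),
                       depth = 1e6,
                       frip = 0.8,
                       dispersion = 0.1,
                       exact_counts = FALSE,
                       baseline_sdlog = 0.5,
                       n_clones = 3,
                       call_threshold_high = 50,
                       call_threshold_low = 10,
                       dropout = 0.05,
                       motif_width = 19L,
                       peak_pad = 100L,
                       chrom_sizes = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                       n_genes = 150,
                       cc_chrom = "chrCC",
                       cc_length = 2e5,
                       cc_bin = 500,
                       cc_probe = c(1e5, 102000),
                       cc_probe_height = 100,
                       cc_baseline = 1,
                       cc_loops = data.frame(
                         loop_id = c("Loop1", "Loop2"),
                         start = c(150000, 180000),
                         end = c(155000, 185000),
                         height = c(30, 20)),
                       cc_multipliers = c(minus = 1, plus = 0.25),
                       cc_replicates = 2,
                       cc_noise_sd = 0.05,
                       n_genes_expr = 12000,
                       n_deg = 330,
                       n_loop_genes = 664,
                       loop_overlap = 10,
                       deg_lfc = 1,
                       deg_padj = 0.05,
                       deg_fpkm = 1,
                       n_targets = 100,
                       targets_excluded = 6,
                       targets_decreased = 92,
                       docking_sizes = c(HCT116 = 400, K562 = 350,
                                         Jurkat = 300),
                       docking_overlaps = c(HCT116 = 21, K562 = 15,
                                            Jurkat = 11)) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed must be a single number")
  chk(abs(sum(cfg$cluster_fractions) - 1) < 1e-8,
      "cluster_fractions must sum to 1")
  chk(abs(sum(cfg$occupancy_fractions) - 1) < 1e-8,
      "occupancy_fractions must sum to 1")
  chk(all(cfg$cluster_fractions >= 0) && all(cfg$occupancy_fractions >= 0),
      "fractions must be non-negative")
  chk(all(cfg$class_multipliers > 0), "class multipliers must be > 0")
  chk(all(cfg$order_depletion > 0) && length(cfg$order_depletion) == 3,
      "order_depletion must be 3 positive multipliers")
  chk(cfg$depth > 0, "depth must be > 0")
  chk(cfg$frip > 0 && cfg$frip <= 1, "frip must be in (0, 1]")
  chk(cfg$dispersion >= 0, "dispersion must be >= 0")
  chk(cfg$n_clones >= 2, "n_clones must be >= 2")
  chk(cfg$call_threshold_high > cfg$call_threshold_low,
      "high-confidence threshold must exceed the low-confidence threshold")
  chk(cfg$dropout >= 0 && cfg$dropout <= 1, "dropout must be in [0, 1]")
  chk(all(cfg$chrom_sizes > 0), "chromosome sizes must be positive")
  chk(cfg$cc_probe[2] > cfg$cc_probe[1], "probe interval must be non-empty")
  if (nrow(cfg$cc_loops)) {
    ov <- cfg$cc_loops$start < cfg$cc_probe[2] & cfg$cc_loops$end > cfg$cc_probe[1]
    chk(!any(ov), "loop windows must not overlap the probe interval")
    chk(all(cfg$cc_loops$end > cfg$cc_loops$start), "loop windows must be non-empty")
  }
  chk(all(cfg$cc_multipliers >= 0), "loop multipliers must be >= 0")
  chk(cfg$loop_overlap <= min(cfg$n_deg, cfg$n_loop_genes),
      "planted overlap cannot exceed either gene-set size")
  chk(cfg$n_deg + cfg$n_loop_genes - cfg$loop_overlap <= cfg$n_genes_expr,
      "expression table too small for the requested gene sets")
  chk(cfg$targets_excluded + cfg$targets_decreased <= cfg$n_targets,
      "excluded + decreased targets cannot exceed n_targets")
  chk(identical(sort(names(cfg$docking_sizes)), sort(names(cfg$docking_overlaps))),
      "docking_sizes and docking_overlaps must share names")
  chk(all(cfg$docking_overlaps <= pmin(cfg$docking_sizes[names(cfg$docking_overlaps)],
                                       cfg$n_deg)),
      "docking overlaps cannot exceed cohort or DEG size")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic depletion-experiment configuration\n")
  cat(sprintf("  seed %s | %d CTS sites | %d clones x 2 conditions | depth %.3g\n",
              format(x$seed), x$n_sites, x$n_clones, x$depth))
  cat(sprintf("  cluster fractions 1X/2X/3X: %s\n",
              paste(format(x$cluster_fractions), collapse = "/")))
  cat(sprintf("  occupancy fractions red/ret/gain: %s (multipliers %s)\n",
              paste(format(x$occupancy_fractions), collapse = "/"),
              paste(format(x$class_multipliers), collapse = "/")))
  cat(sprintf("  Capture-C: %d loops, +IAA multiplier %.3g, %d reps, noise sd %.3g\n",
              nrow(x$cc_loops), x$cc_multipliers[["plus"]], x$cc_replicates,
              x$cc_noise_sd))
  cat(sprintf("  expression: %d genes, %d DEGs, %d loop genes (overlap %d), %d targets\n",
              x$n_genes_expr, x$n_deg, x$n_loop_genes, x$loop_overlap, x$n_targets))
  invisible(x)
}
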