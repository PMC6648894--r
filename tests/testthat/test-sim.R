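# Synthetic-data generators: determinism, construction guarantees,
# planted effects.

small_cfg <- function(...) {
  sim_config(n_sites = 60, depth = 2e4, n_genes = 20,
             chrom_sizes = c(chr1 = 5e5, chr2 = 5e5), ...)
}

test_that("generators are deterministic for a fixed config", {
  cfg <- small_cfg()
  a <- sim_experiment(cfg)
  b <- sim_experiment(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$motifs, b$motifs)
  expect_identical(a$occupancy$counts, b$occupancy$counts)
  expect_identical(a$expression$expression, b$expression$expression)
  expect_identical(lapply(a$capturec$tracks$minus, granges_to_bed0),
                   lapply(b$capturec$tracks$minus, granges_to_bed0))
  # different seed gives different draws
  c2 <- sim_experiment(small_cfg(seed = 42))
  expect_false(identical(a$occupancy$counts, c2$occupancy$counts))
})

test_that("written outputs are byte-identical across runs of one config", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim_experiment(cfg, outdir = d1, write_fragments = TRUE)
  sim_experiment(cfg, outdir = d2, write_fragments = TRUE)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sim_genome(small_cfg())); after <- runif(1)
  expect_identical(before, after)
})

test_that("gene placement stays within chromosome bounds", {
  cfg <- sim_config(n_genes = 100, chrom_sizes = c(chr1 = 1e6),
                    n_sites = 10)
  g <- sim_genome(cfg)
  expect_equal(nrow(g$genes), 100)
  # exhaustive scan of every gene and exon span
  for (i in seq_len(nrow(g$genes))) {
    expect_true(g$genes$start[i] >= 0 && g$genes$end[i] <= 1e6)
    ex <- g$exons[g$exons$gene_id == g$genes$gene_id[i], ]
    expect_true(all(ex$start >= g$genes$start[i] & ex$end <= g$genes$end[i]))
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
  }
  expect_equal(anyDuplicated(g$genes$gene_id), 0L)
})

test_that("zero genes gives an empty gene list with valid chrom sizes", {
  g <- sim_genome(sim_config(n_genes = 0, n_sites = 5))
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$exons), 0)
  expect_true(all(g$chrom_sizes > 0))
})

test_that("a genome too small for the request errors", {
  expect_error(sim_genome(sim_config(n_genes = 100,
                                     chrom_sizes = c(chr1 = 5e4),
                                     n_sites = 5)),
               "too small")
  expect_error(sim_motifs(sim_genome(small_cfg()),
                          sim_config(n_sites = 1e5,
                                     chrom_sizes = c(chr1 = 5e4))),
               "too small")
})

test_that("pure 1X landscapes keep every motif > 40 bp from every other", {
  cfg <- small_cfg(cluster_fractions = c(x1 = 1, x2 = 0, x3 = 0))
  m <- sim_motifs(sim_genome(cfg), cfg)
  df <- m$motifs
  # brute-force all-pairs distance scan
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (i >= j || df$chrom[i] != df$chrom[j]) next
    gap <- max(df$start[i] - df$end[j], df$start[j] - df$end[i])
    expect_gt(gap, 40)
  }
})

test_that("pure 2X landscapes produce order-2 clusters by construction", {
  cfg <- sim_config(n_sites = 10, cluster_fractions = c(x1 = 0, x2 = 1, x3 = 0),
                    chrom_sizes = c(chr1 = 1e5), n_genes = 0)
  m <- sim_motifs(sim_genome(cfg), cfg)
  expect_equal(nrow(m$motifs), 20)
  expect_equal(nrow(m$sites), 10)
  expect_true(all(m$sites$order == 2))
  # intra-cluster gaps <= 40
  for (s in m$sites$site_id) {
    mm <- m$motifs[m$motifs$site_id == s, ]
    mm <- mm[order(mm$start), ]
    expect_true(all(mm$start[-1] - mm$end[-nrow(mm)] <= 40))
  }
})

test_that("truth records are complete and exclusive", {
  m <- sim_motifs(sim_genome(small_cfg()), small_cfg())
  expect_equal(sort(unique(m$motifs$site_id)), sort(m$sites$site_id))
  expect_equal(sum(m$sites$order), nrow(m$motifs))
  expect_equal(anyDuplicated(m$sites$site_id), 0L)
})

test_that("identity multipliers with exact counts give equal conditions", {
  cfg <- small_cfg(class_multipliers = c(reduced = 1, retained = 1, gained = 1),
                   exact_counts = TRUE, dropout = 0)
  occ <- sim_occupancy(sim_motifs(sim_genome(cfg), cfg), cfg)
  minus <- occ$counts[, occ$samples$condition == "minus"]
  plus <- occ$counts[, occ$samples$condition == "plus"]
  expect_identical(unname(minus), unname(plus))
})

test_that("dropout 1 empties every per-clone peak set", {
  cfg <- small_cfg(dropout = 1)
  occ <- sim_occupancy(sim_motifs(sim_genome(cfg), cfg), cfg)
  for (cond in names(occ$peak_calls))
    for (cl in names(occ$peak_calls[[cond]])) {
      expect_length(occ$peak_calls[[cond]][[cl]]$high, 0)
      expect_length(occ$peak_calls[[cond]][[cl]]$low, 0)
    }
})

test_that("high-confidence calls are a subset of low-confidence calls", {
  cfg <- small_cfg()
  occ <- sim_occupancy(sim_motifs(sim_genome(cfg), cfg), cfg)
  for (cond in names(occ$peak_calls))
    for (cl in names(occ$peak_calls[[cond]])) {
      pc <- occ$peak_calls[[cond]][[cl]]
      expect_true(all(pc$high$name %in% pc$low$name))
    }
})

test_that("planted 4-fold depletion yields mean log2 ratio near -2", {
  cfg <- sim_config(n_sites = 300, depth = 2e5, n_genes = 0,
                    chrom_sizes = c(chr1 = 2e6))
  occ <- sim_occupancy(sim_motifs(sim_genome(cfg), cfg), cfg)
  red <- occ$sites$occupancy_class == "reduced"
  # Monte-Carlo expectation recomputed directly from the count matrix
  m_minus <- rowMeans(occ$counts[red, occ$samples$condition == "minus"])
  m_plus <- rowMeans(occ$counts[red, occ$samples$condition == "plus"])
  expect_lt(abs(mean(log2(m_plus / m_minus)) - (-2)), 0.3)
})

test_that("degenerate occupancy configs are rejected", {
  expect_error(sim_config(class_multipliers = c(reduced = 0, retained = 1,
                                                gained = 2.5)),
               "> 0")
  expect_error(sim_config(call_threshold_high = 5, call_threshold_low = 10),
               "threshold")
  expect_error(sim_config(occupancy_fractions = c(reduced = 0.5,
                                                  retained = 0.4,
                                                  gained = 0.3)),
               "sum to 1")
})

test_that("capture-C identity and null multipliers behave exactly", {
  cfg <- small_cfg(cc_multipliers = c(minus = 1, plus = 1), cc_noise_sd = 0)
  cc <- sim_capturec(cfg)
  expect_identical(granges_to_bed0(cc$tracks$minus$rep1),
                   granges_to_bed0(cc$tracks$plus$rep1))
  cfg0 <- small_cfg(cc_multipliers = c(minus = 1, plus = 0), cc_noise_sd = 0)
  cc0 <- sim_capturec(cfg0)
  tr <- cc0$tracks$plus$rep1
  in_loop <- IRanges::overlapsAny(tr, cc0$windows)
  expect_true(all(tr$score[in_loop] == 0))
  expect_true(all(tr$score[!in_loop] > 0))
})

test_that("replicate tracks share structure and differ only by noise", {
  cc <- sim_capturec(small_cfg())
  all_tracks <- c(cc$tracks$minus, cc$tracks$plus)
  for (tr in all_tracks) {
    expect_gt(bf_mass(tr, GenomicRanges::start(cc$probe) - 1,
                      GenomicRanges::end(cc$probe)), 0)
  }
  r1 <- cc$tracks$minus$rep1; r2 <- cc$tracks$minus$rep2
  expect_identical(GenomicRanges::granges(r1), GenomicRanges::granges(r2))
  expect_false(identical(r1$score, r2$score))
})

test_that("loop windows overlapping the probe are rejected", {
  expect_error(sim_config(cc_loops = data.frame(loop_id = "L", start = 101000,
                                                end = 103000, height = 10)),
               "probe")
})

test_that("expression generator plants the configured structure", {
  cfg <- small_cfg()
  ex <- sim_expression(cfg)
  tb <- ex$expression
  truth <- ex$truth
  deg <- truth$gene_id[truth$deg]
  expect_length(deg, cfg$n_deg)
  # every planted DEG passes all three thresholds; no other gene passes lfc
  expect_true(all(abs(tb$log2fc[truth$deg]) >= cfg$deg_lfc))
  expect_true(all(tb$padj[truth$deg] <= cfg$deg_padj))
  expect_true(all(pmax(tb$fpkm_minus, tb$fpkm_plus)[truth$deg] >= cfg$deg_fpkm))
  expect_true(all(abs(tb$log2fc[!truth$deg]) < cfg$deg_lfc))
  expect_length(intersect(deg, ex$loop_genes), cfg$loop_overlap)
  expect_length(ex$loop_genes, cfg$n_loop_genes)
  expect_length(ex$targets, cfg$n_targets)
  expect_error(sim_config(n_deg = 5, n_loop_genes = 100, loop_overlap = 10),
               "overlap")
})

test_that("zero planted overlap gives disjoint DEG and loop sets", {
  ex <- sim_expression(small_cfg(loop_overlap = 0))
  deg <- ex$truth$gene_id[ex$truth$deg]
  expect_length(intersect(deg, ex$loop_genes), 0)
})
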