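# Reproducibility rule, consensus merging, FPKM quantification,
# fragment-size QC split.

test_that("dual-confidence rule keeps exactly the supported patterns", {
  # quoted rule: called at least once at high confidence, and at either
  # confidence in the other two replicates
  expect_length(filter_reproducible(calls_from_pattern(c("high", "low", "low"))), 1)
  expect_length(filter_reproducible(calls_from_pattern(c("high", "low", "absent"))), 0)
  expect_length(filter_reproducible(calls_from_pattern(c("low", "low", "low"))), 0)
  expect_length(filter_reproducible(calls_from_pattern(c("high", "high", "high"))), 1)
})

test_that("all 27 support patterns match the brute-force rule", {
  levels <- c("absent", "low", "high")
  grid <- expand.grid(a = levels, b = levels, c = levels,
                      stringsAsFactors = FALSE)
  kept <- logical(nrow(grid))
  expected <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- unlist(grid[i, ])
    kept[i] <- length(filter_reproducible(calls_from_pattern(p))) > 0
    # independent evaluation of the quoted rule
    expected[i] <- any(p == "high") && !any(p == "absent")
  }
  expect_identical(kept, expected)
  expect_equal(sum(kept), 7)
})

test_that("reproducible regions are unions of supporting calls", {
  calls <- list(
    a = list(high = gr0("chr1", 100, 200), low = gr0("chr1", 100, 200)),
    b = list(high = gr0("chr1", 900, 950)[0], low = gr0("chr1", 150, 250)),
    c = list(high = gr0("chr1", 900, 950)[0], low = gr0("chr1", 120, 220)))
  out <- filter_reproducible(calls)
  expect_equal(granges_to_bed0(out)[, c("start", "end")],
               data.frame(start = 100L, end = 250L))
})

test_that("a clone missing both confidence sets is an input error", {
  calls <- list(a = list(high = gr0("chr1", 1, 10), low = gr0("chr1", 1, 10)),
                b = list())
  expect_error(filter_reproducible(calls), "missing both")
  expect_error(filter_reproducible(list(a = list(high = gr0("chr1", 1, 10),
                                                 low = gr0("chr1", 1, 10)))),
               "at least 2")
})

test_that("adding calls never removes reproducible coverage", {
  set.seed(11)
  for (rep in 1:20) {
    mk <- function(n) {
      s <- sort(sample(0:5000, n))
      gr0("chr1", s, s + sample(50:300, n, replace = TRUE))
    }
    calls <- lapply(1:3, function(i) {
      low <- mk(sample(3:8, 1))
      list(high = low[sample(length(low), sample(0:length(low), 1))], low = low)
    })
    base <- filter_reproducible(calls)
    calls2 <- calls
    calls2[[2]]$low <- c(calls2[[2]]$low, mk(2))
    more <- filter_reproducible(calls2)
    uncovered <- GenomicRanges::setdiff(base, more)
    expect_length(uncovered, 0)
  }
})

test_that("merge_and_blacklist union-merges and drops on >= 1 bp overlap", {
  out <- merge_and_blacklist(gr0("chr1", 100, 200), gr0("chr1", 150, 250))
  expect_equal(granges_to_bed0(out)[, c("start", "end")],
               data.frame(start = 100L, end = 250L))
  out <- merge_and_blacklist(gr0("chr1", 100, 200), gr0("chr1", 150, 250),
                             blacklist = gr0("chr1", 240, 260))
  expect_length(out, 0)  # whole region removed, not trimmed
  # 1-bp overlap is enough; adjacency is not
  expect_length(merge_and_blacklist(gr0("chr1", 100, 250),
                                    GenomicRanges::GRanges(),
                                    gr0("chr1", 249, 300)), 0)
  expect_length(merge_and_blacklist(gr0("chr1", 100, 250),
                                    GenomicRanges::GRanges(),
                                    gr0("chr1", 250, 300)), 1)
})

test_that("blacklist filtering matches the quadratic oracle on random data", {
  set.seed(7)
  for (rep in 1:5) {
    s <- sample(0:20000, 50)
    regions <- GenomicRanges::reduce(gr0("chr1", s, s + sample(50:500, 50, TRUE)))
    bs <- sample(0:20000, 5)
    blacklist <- gr0("chr1", bs, bs + sample(100:800, 5, TRUE))
    got <- merge_and_blacklist(regions, GenomicRanges::GRanges(), blacklist)
    want <- GenomicRanges::sort(bf_blacklist(regions, blacklist))
    expect_equal(granges_to_bed0(got), granges_to_bed0(want))
  }
})

test_that("merge_and_blacklist is idempotent", {
  set.seed(8)
  s <- sample(0:10000, 30)
  a <- gr0("chr1", s, s + 100)
  bl <- gr0("chr1", c(500, 5000), c(700, 5400))
  once <- merge_and_blacklist(a, GenomicRanges::GRanges(), bl)
  twice <- merge_and_blacklist(once, GenomicRanges::GRanges(), bl)
  expect_equal(granges_to_bed0(once), granges_to_bed0(twice))
})

test_that("FPKM follows its closed form and scale invariance", {
  region <- gr0("chr1", 1000, 1500)  # 500 bp
  counts <- matrix(200, 1, 1, dimnames = list(NULL, "s1"))
  q <- quantify_fpkm_counts(region, cbind(counts, counts), c("minus", "plus"),
                            library_sizes = c(1e7, 1e7))
  expect_equal(unname(S4Vectors::mcols(q)$fpkm[1, 1]), 40)  # 200/(0.5*10)
  # joint doubling of counts and library sizes leaves FPKM unchanged
  q2 <- quantify_fpkm_counts(region, cbind(counts, counts) * 2,
                             c("minus", "plus"), library_sizes = c(2e7, 2e7))
  expect_equal(S4Vectors::mcols(q2)$fpkm, S4Vectors::mcols(q)$fpkm)
})

test_that("log2 fold change uses the pseudocount on condition means", {
  region <- gr0("chr1", 0, 1000)  # FPKM == count at library 1e6
  counts <- matrix(c(8, 8, 8, 2, 2, 2), nrow = 1)
  q <- quantify_fpkm_counts(region, counts,
                            c("minus", "minus", "minus", "plus", "plus", "plus"),
                            pseudocount = 0.5,
                            library_sizes = rep(1e6, 6))
  expect_equal(q$mean_fpkm_minus, 8)
  expect_equal(q$mean_fpkm_plus, 2)
  expect_equal(q$log2fc, log2(2.5 / 8.5))  # ~ -1.766
})

test_that("fragment counting uses >= 1 bp whole-fragment overlap", {
  regions <- gr0("chr1", c(100, 1000), c(300, 1200))
  frags <- list(
    s1 = gr0("chr1", c(50, 250, 299, 300, 2000), c(150, 350, 400, 400, 2100)),
    s2 = gr0("chr1", c(1100), c(1150)))
  q <- quantify_fpkm(regions, frags, c("minus", "plus"),
                     library_sizes = c(1e6, 1e6))
  expect_equal(unname(S4Vectors::mcols(q)$counts[, "s1"]), c(3, 0))
  expect_equal(unname(S4Vectors::mcols(q)$counts[, "s2"]), c(0, 1))
  expect_error(quantify_fpkm(regions, frags, c("minus", "plus"),
                             library_sizes = c(0, 1e6)))
})

test_that("counts over disjoint regions never exceed the library size", {
  cfg <- sim_config(n_sites = 50, depth = 5e3, n_genes = 0,
                    chrom_sizes = c(chr1 = 5e5))
  occ <- sim_occupancy(sim_motifs(sim_genome(cfg), cfg), cfg)
  frags <- sim_fragments(occ, cfg)
  regions <- GenomicRanges::reduce(
    granges_from_bed0(occ$sites$chrom, occ$sites$start, occ$sites$end))
  q <- quantify_fpkm(regions, frags, occ$samples$condition)
  totals <- colSums(S4Vectors::mcols(q)$counts)
  expect_true(all(totals <= vapply(frags, length, integer(1))))
})

test_that("fragment-size split follows the Cut&Run QC windows", {
  fr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1, width = c(100, 140, 160, 2500)))
  sp <- split_fragments_by_size(fr)
  expect_equal(GenomicRanges::width(sp$short), 100)
  expect_equal(GenomicRanges::width(sp$long), 160)
  expect_equal(GenomicRanges::width(sp$all_under_2kb), c(100, 140, 160))
  # strict boundaries: 120 and 150 fall only in the < 2 kb set
  for (w in c(120, 150)) {
    sp <- split_fragments_by_size(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(1, width = w)))
    expect_length(sp$short, 0)
    expect_length(sp$long, 0)
    expect_length(sp$all_under_2kb, 1)
  }
  sp <- split_fragments_by_size(GenomicRanges::GRanges())
  expect_true(all(lengths(sp) == 0))
})

test_that("random fragment lengths partition as a direct filter says", {
  set.seed(5)
  len <- sample(1:3000, 1000, replace = TRUE)
  fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, width = len))
  sp <- split_fragments_by_size(fr)
  expect_length(sp$short, sum(len < 120))
  expect_length(sp$long, sum(len > 150 & len < 2000))
  expect_length(sp$all_under_2kb, sum(len < 2000))
})

test_that("the peak table flattens per-sample matrices and round-trips", {
  regions <- gr0("chr1", c(0, 2000), c(1000, 2600))
  counts <- matrix(c(8, 4, 2, 1), nrow = 2,
                   dimnames = list(NULL, c("minus_c01", "plus_c01")))
  q <- classify_occupancy(
    quantify_fpkm_counts(regions, counts, c("minus", "plus"),
                         library_sizes = c(1e6, 1e6)))
  tab <- peak_table(q)
  expect_true(all(c("count_minus_c01", "fpkm_plus_c01", "log2fc",
                    "occupancy_class") %in% names(tab)))
  expect_equal(tab$count_plus_c01, c(2, 1))
  expect_equal(tab$fpkm_minus_c01, c(8, 4) / c(1, 0.6))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(q, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$log2fc, tab$log2fc, tolerance = 1e-10)
  expect_equal(back$occupancy_class, tab$occupancy_class)
})
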