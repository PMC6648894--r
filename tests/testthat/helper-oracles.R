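# Brute-force reference implementations used as independent oracles.
# These deliberately use naive O(n^2)/enumeration algorithms and never
# call the package functions they check.

gr0 <- function(chrom, start0, end0, ...) {
  granges_from_bed0(chrom, start0, end0, ...)
}

# one-region call sets for a per-clone support pattern in
# {"absent", "low", "high"}
calls_from_pattern <- function(pattern, region = c(101, 200)) {
  r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(region[1], region[2]))
  empty <- r[0]
  lapply(pattern, function(p)
    switch(p,
           absent = list(high = empty, low = empty),
           low = list(high = empty, low = r),
           high = list(high = r, low = r)))
}

# all-pairs single-linkage transitive closure over motif intervals
# (0-based half-open data.frame: chrom, start, end); returns cluster
# membership labels in input order
bf_cluster_labels <- function(df, linkage = 40) {
  n <- nrow(df)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || df$chrom[i] != df$chrom[j]) next
      gap <- max(df$start[i] - df$end[j], df$start[j] - df$end[i])
      if (gap <= linkage && lab[i] != lab[j]) {
        new <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# naive pairwise-overlap blacklist filter on merged regions
bf_blacklist <- function(regions, blacklist) {
  keep <- rep(TRUE, length(regions))
  for (i in seq_along(regions)) for (j in seq_along(blacklist)) {
    same <- as.character(GenomicRanges::seqnames(regions[i])) ==
      as.character(GenomicRanges::seqnames(blacklist[j]))
    if (same &&
        GenomicRanges::start(regions[i]) <= GenomicRanges::end(blacklist[j]) &&
        GenomicRanges::start(blacklist[j]) <= GenomicRanges::end(regions[i]))
      keep[i] <- FALSE
  }
  regions[keep]
}

# exhaustive two-sided rank-sum P: statistic computed by direct pairwise
# counting (not via ranks), extremeness measured around the null mean
bf_wilcox_p <- function(x, y) {
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b)
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  mu <- n1 * n2 / 2
  obs <- u_of(x, y)
  combs <- utils::combn(n1 + n2, n1)
  stats <- apply(combs, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# per-peak scan over all genes reproducing the annotation priority rules
bf_annotate_one <- function(anchor, chrom, genome, bins = c(1000, 2000, 3000),
                            down = 3000) {
  g <- genome$genes[genome$genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return("distal_intergenic")
  d <- ifelse(g$strand == "+", anchor - g$tss, g$tss - anchor)
  ord <- order(abs(d), g$gene_id)
  db <- d[ord[1]]
  for (k in 1:3)
    if (db > -bins[k] && db <= bins[k])
      return(c("promoter_le1kb", "promoter_1to2kb", "promoter_2to3kb")[k])
  inside <- which(g$start <= anchor & anchor < g$end)
  if (length(inside)) {
    host <- inside[order(abs(d[inside]), g$gene_id[inside])][1]
    gid <- g$gene_id[host]
    utr <- gene_utr_spans(genome)
    u <- utr[utr$gene_id == gid, , drop = FALSE]
    for (r in seq_len(nrow(u)))
      if (u$start[r] <= anchor && anchor < u$end[r]) return(u$type[r])
    ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
    for (r in seq_len(nrow(ex)))
      if (ex$start[r] <= anchor && anchor < ex$end[r]) return("exon")
    return("intron")
  }
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+" && g$end[i] <= anchor && anchor < g$end[i] + down)
      return("downstream_le3kb")
    if (g$strand[i] == "-" && g$start[i] - down <= anchor && anchor < g$start[i])
      return("downstream_le3kb")
  }
  "distal_intergenic"
}

# random disjoint-bin signal track
random_track <- function(n_bins = 40, bin = 100, chrom = "chrT") {
  starts <- (seq_len(n_bins) - 1) * bin
  gr0(chrom, starts, starts + bin, score = stats::runif(n_bins, 0.1, 10))
}

# direct summation of value * overlap-bp of a track over one interval,
# written as an explicit loop
bf_mass <- function(track, start0, end0) {
  df <- granges_to_bed0(track)
  total <- 0
  for (i in seq_len(nrow(df))) {
    ov <- min(df$end[i], end0) - max(df$start[i], start0)
    if (ov > 0) total <- total + df$score[i] * ov
  }
  total
}
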