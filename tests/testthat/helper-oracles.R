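# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (adjacency matrices, full enumeration) so that they
# cannot share a defect with the implementation they check.

# Connected components of the <=gap proximity graph, by breadth-first
# search over an explicit adjacency matrix.
cc_cluster_oracle <- function(positions, gap = 500) {
  p <- sort(positions)
  n <- length(p)
  adj <- abs(outer(p, p, "-")) <= gap
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    comp[i] <- k
    while (length(frontier) > 0L) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & is.na(comp))
      comp[nb] <- k
      frontier <- nb
    }
  }
  unname(split(p, comp))
}

# Two-sided Fisher p by direct hypergeometric mass summation (dhyper),
# point-probability rule with the 1e-7 relative tolerance.
fisher_oracle <- function(a, b, cc, d, alternative = "two_sided") {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  k <- max(0, c1 - r2):min(c1, r1)
  dk <- dhyper(k, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  switch(alternative,
    two_sided = sum(dk[dk <= obs * (1 + 1e-7)]),
    greater = sum(dk[k >= a]),
    less = sum(dk[k <= a]))
}

# Exact two-sided rank-sum p by full enumeration of all C(N, m) rank
# assignments (tie-free samples only).
wilcox_enum_oracle <- function(x, y, alternative = "two_sided") {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  sums <- combn(seq_len(N), m, sum)
  ple <- mean(sums <= W); pge <- mean(sums >= W)
  switch(alternative,
    two_sided = min(1, 2 * min(ple, pge)),
    greater = pge,
    less = ple)
}

# Random multi-exon transcript model in the read_bed12() shape.
random_transcript <- function(gene_id = "G1", tx_id = paste0(gene_id, ".t1"),
                              strand = sample(c("+", "-"), 1L)) {
  ne <- sample(1:6, 1L)
  exon_sizes <- sample(50:400, ne, replace = TRUE)
  intron_sizes <- if (ne > 1L) sample(60:2000, ne - 1L, replace = TRUE) else integer(0)
  tx_start <- sample(1000:100000, 1L)
  es <- tx_start + cumsum(c(0L, head(exon_sizes, -1L) + intron_sizes))
  ee <- es + exon_sizes
  spliced <- sum(exon_sizes)
  u_left <- sample(0:(spliced %/% 3), 1L)
  u_right <- sample(0:((spliced - u_left - 1L) %/% 2), 1L)
  to_genomic <- function(off) {
    cum <- cumsum(exon_sizes)
    i <- which(off <= cum)[1L]
    prev <- if (i == 1L) 0L else cum[i - 1L]
    es[i] + (off - prev)
  }
  out <- data.frame(tx_id = tx_id, gene_id = gene_id, chrom = "chr1",
                    strand = strand, tx_start = es[1L], tx_end = ee[ne],
                    cds_start = to_genomic(u_left),
                    cds_end = to_genomic(spliced - u_right),
                    stringsAsFactors = FALSE)
  out$exon_starts <- list(es)
  out$exon_ends <- list(ee)
  out
}

# Reflect a transcript about a coordinate C and flip its strand: the
# biological object is unchanged except for orientation bookkeeping.
reflect_transcript <- function(t, C = 1e7) {
  out <- t
  out$strand <- ifelse(t$strand == "+", "-", "+")
  out$tx_start <- C - t$tx_end
  out$tx_end <- C - t$tx_start
  out$cds_start <- C - t$cds_end
  out$cds_end <- C - t$cds_start
  out$exon_starts <- lapply(seq_len(nrow(t)), function(i) rev(C - t$exon_ends[[i]]))
  out$exon_ends <- lapply(seq_len(nrow(t)), function(i) rev(C - t$exon_starts[[i]]))
  out
}

# Small default cohort for pipeline tests.
small_cohort <- function(seed = 5, dir = tempfile("cohort")) {
  cfg <- synthetic_config(seed = seed, class_sizes = c(50L, 40L, 30L, 20L),
                          n_datasets = 40L)
  list(config = cfg, paths = generate_cohort(cfg, dir))
}
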