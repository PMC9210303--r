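# Brute-force oracles and small fixture builders, independent of the package
# implementations they check.

# O(n^2) transitive-closure merge: connect peaks (same chrom) whose gap is
# <= merge_gap, take connected components, span each component.
oracle_merge <- function(peaks, merge_gap = 10) {
  if (is.null(peaks$sample)) peaks$sample <- "sample1"
  n <- nrow(peaks)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      if (peaks$chrom[i] != peaks$chrom[j]) next
      gap <- max(peaks$start[i], peaks$start[j]) -
        min(peaks$end[i], peaks$end[j])
      if (gap <= merge_gap && comp[i] != comp[j]) {
        old <- comp[j]; comp[comp == old] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cp) {
    rows <- which(comp == cp)
    data.frame(chrom = peaks$chrom[rows[1]],
               start = min(peaks$start[rows]),
               end = max(peaks$end[rows]),
               support = length(unique(peaks$sample[rows])),
               n_members = length(rows))
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# All-pairs >=1 bp overlap counting of fragments per peak.
oracle_overlap_counts <- function(peaks, frags) {
  vapply(seq_len(nrow(peaks)), function(i) {
    sum(frags$chrom == peaks$chrom[i] &
          frags$start < peaks$end[i] & frags$end > peaks$start[i])
  }, 1L)
}

# Definitional BH: padj_i = min over j with p_(j) >= p_i of min(1, m p_(j)/j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  rank_of <- match(seq_len(m), ord)
  vapply(seq_len(m), function(i) {
    js <- which(p[ord] >= p[i])
    min(pmin(1, m * p[ord][js] / js))
  }, 1)
}

# Random interval fixture.
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         max_len = 300, samples = paste0("s", 1:3)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             sample = sample(samples, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Fragment fixture with clean QC flags.
make_frag_df <- function(chrom, start, end, mapq = 60L, flags = 2L,
                         sample = "s1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             mapq = mapq, flags = flags, sample = sample,
             stringsAsFactors = FALSE)
}

# d fragments exactly tiling [start, end) at uniform depth d.
stack_frags <- function(chrom, start, end, depth) {
  make_frag_df(rep(chrom, depth), rep(start, depth), rep(end, depth))
}

# Mixture CDF of the fragment-length model (normal components).
mixture_cdf <- function(q, mix) {
  rowSums(vapply(seq_len(nrow(mix)), function(k)
    mix$weight[k] * pnorm(q, mix$mean[k], mix$sd[k]), numeric(length(q))))
}
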