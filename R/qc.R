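# ATAC library QC: fragment filtering, fragment-size distribution, TSS
# enrichment score, FRiP, library complexity (NRF/PBC), NFR score, binned
# coverage correlation, and a per-sample report.

# SAM flag bits used by the quality filter (samtools view -f2 -F1548).
FLAG_PROPER_PAIR <- 2L
FLAG_EXCLUDE <- 1548L  # unmapped(4) + mate unmapped(8) + qcfail(512) + dup(1024)

#' Filter fragments on mapping quality, SAM flags and chromosome
#'
#' Retains fragments with `mapq >= min_mapq`, the proper-pair bit set, none of
#' the unmapped / mate-unmapped / QC-fail / duplicate bits set, and a
#' chromosome outside `exclude_chroms` (mitochondrial reads are excluded by
#' default). Equivalent to `samtools view -f2 -q10 -F1548` plus the
#' mitochondrial exclusion.
#'
#' @param fragments fragment data frame with columns `chrom`, `start`, `end`,
#'   `mapq`, `flags` (and optionally `sample`).
#' @param min_mapq minimum mapping quality kept (default 10; a fragment with
#'   mapq 10 is kept, mapq 9 is dropped).
#' @param exclude_chroms chromosomes removed entirely (default `"MT"`).
#' @return the retained fragment rows.
#' @export
filter_fragments <- function(fragments, min_mapq = 10,
                             exclude_chroms = "MT") {
  check_intervals(fragments, "fragments")
  stopifnot(!is.null(fragments$mapq), !is.null(fragments$flags))
  keep <- fragments$mapq >= min_mapq &
    bitwAnd(fragments$flags, FLAG_PROPER_PAIR) == FLAG_PROPER_PAIR &
    bitwAnd(fragments$flags, FLAG_EXCLUDE) == 0L &
    !(fragments$chrom %in% exclude_chroms)
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragment-size distribution with log-density transform
#'
#' Histograms fragment lengths and reports the normalized read-count density
#' `log2(count / max(count))` per bin (so the modal bin always maps to 0).
#' Fragments are also classified into nucleosome-free (< 100 bp),
#' mono-nucleosome (180-247 bp) and di-nucleosome (315-473 bp) bins.
#'
#' @param fragments fragment data frame (`start`, `end`).
#' @param binwidth histogram bin width in bp (default 10).
#' @return list with `mids`, `count`, `log2_density` (per histogram bin) and
#'   `class_counts` (named vector: nfr / mono / di / other).
#' @export
fragment_size_distribution <- function(fragments, binwidth = 10) {
  check_intervals(fragments, "fragments")
  if (nrow(fragments) == 0L) stop("no fragments supplied")
  len <- fragments$end - fragments$start
  breaks <- seq(0, max(len) + binwidth, by = binwidth)
  bin <- findInterval(len, breaks, rightmost.closed = FALSE)
  count <- tabulate(bin, nbins = length(breaks) - 1L)
  mids <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  class_counts <- c(
    nfr = sum(len < 100),
    mono = sum(len >= 180 & len <= 247),
    di = sum(len >= 315 & len <= 473)
  )
  class_counts <- c(class_counts, other = length(len) - sum(class_counts))
  list(mids = mids, count = count,
       log2_density = log2(count / max(count)),
       class_counts = class_counts)
}

# Pooled per-base depth profile around TSSs, strand-oriented, length 2*flank.
tss_depth_profile <- function(fragments, tss, flank = 1000) {
  prof <- numeric(2 * flank)
  frag_by_chrom <- split(fragments, fragments$chrom)
  cov_by_chrom <- lapply(frag_by_chrom, function(f)
    IRanges::coverage(IRanges::IRanges(start = f$start + 1L, end = f$end)))
  for (i in seq_len(nrow(tss))) {
    cv <- cov_by_chrom[[as.character(tss$chrom[i])]]
    win <- numeric(2 * flank)
    if (!is.null(cv)) {
      lo <- tss$pos[i] - flank      # 0-based window [lo, lo + 2*flank)
      pos1 <- (lo + 1L):(lo + 2L * flank)  # 1-based
      ok <- pos1 >= 1L & pos1 <= length(cv)
      if (any(ok)) win[ok] <- as.numeric(cv[pos1[ok]])
    }
    if (!is.null(tss$strand) && tss$strand[i] == "-") win <- rev(win)
    prof <- prof + win
  }
  prof
}

#' TSS enrichment score
#'
#' Tiles the `[TSS - flank, TSS + flank)` region into `2*flank/window`
#' windows (20 windows of 100 bp by default), pools fragment-overlap depth
#' across all TSSs (strand-oriented), and scores each window as its mean
#' depth divided by the mean depth of the two outermost (flank-end) windows.
#' The library's TSS enrichment score (TSS-ES) is the maximum window score.
#' Uniform coverage therefore scores 1 in every window.
#'
#' @param fragments filtered fragment data frame.
#' @param tss data frame of TSS positions: `chrom`, `pos` (0-based),
#'   optionally `strand`.
#' @param window window width in bp (default 100).
#' @param flank half-width of the profiled region in bp (default 1000).
#' @return list with `window_scores` (length `2*flank/window`), `tss_es`, and
#'   the pooled per-base `profile`.
#' @export
tss_enrichment <- function(fragments, tss, window = 100, flank = 1000) {
  check_intervals(fragments, "fragments")
  stopifnot(is.data.frame(tss), nrow(tss) >= 1L,
            all(c("chrom", "pos") %in% names(tss)))
  stopifnot(flank %% window == 0)
  prof <- tss_depth_profile(fragments, tss, flank = flank)
  nwin <- as.integer(2 * flank / window)
  win_mean <- colMeans(matrix(prof, nrow = window, ncol = nwin))
  flank_depth <- mean(win_mean[c(1L, nwin)])
  if (flank_depth == 0)
    stop("zero depth in flank windows: TSS enrichment score undefined")
  scores <- win_mean / flank_depth
  list(window_scores = scores, tss_es = max(scores), profile = prof)
}

#' Fraction of fragments in peaks (FRiP)
#'
#' @param fragments filtered fragment data frame.
#' @param peaks peak interval data frame.
#' @return proportion in \[0, 1\] of fragments overlapping any peak by >= 1 bp.
#' @export
frip <- function(fragments, peaks) {
  check_intervals(fragments, "fragments")
  check_intervals(peaks, "peaks")
  if (nrow(fragments) == 0L) stop("no fragments supplied")
  if (nrow(peaks) == 0L) return(0)
  mean(IRanges::overlapsAny(as_granges0(fragments), as_granges0(peaks)))
}

#' Library complexity: NRF and PCR bottlenecking coefficients
#'
#' Computed over distinct fragment positions, i.e. `(chrom, start, end)`
#' triples (paired-end convention): NRF = distinct/total, PBC1 = positions
#' seen exactly once / distinct, PBC2 = positions seen exactly once /
#' positions seen exactly twice. PBC2 is `Inf` (flagged) when no position is
#' seen twice.
#'
#' @param fragments fragment data frame.
#' @return list `nrf`, `pbc1`, `pbc2`, `pbc2_defined`.
#' @export
library_complexity <- function(fragments) {
  check_intervals(fragments, "fragments")
  if (nrow(fragments) == 0L) stop("no fragments supplied")
  pos <- paste(fragments$chrom, fragments$start, fragments$end)
  mult <- table(pos)
  total <- length(pos)
  distinct <- length(mult)
  once <- sum(mult == 1L)
  twice <- sum(mult == 2L)
  list(nrf = distinct / total,
       pbc1 = once / distinct,
       pbc2 = if (twice == 0L) Inf else once / twice,
       pbc2_defined = twice > 0L)
}

#' Nucleosome-free region score
#'
#' `log2` ratio of nucleosome-free fragments (< 100 bp) to mono-nucleosome
#' fragments (180-247 bp). Both bins must be non-empty.
#'
#' @param fragments fragment data frame.
#' @return the NFR score (0 when the two bins are equally populated).
#' @export
nfr_score <- function(fragments) {
  check_intervals(fragments, "fragments")
  len <- fragments$end - fragments$start
  n_nfr <- sum(len < 100)
  n_mono <- sum(len >= 180 & len <= 247)
  if (n_nfr == 0L || n_mono == 0L)
    stop("NFR score undefined: empty nucleosome-free or mono-nucleosome bin")
  log2(n_nfr / n_mono)
}

#' Pairwise sample correlation of binned genome coverage
#'
#' Tiles the genome into fixed-width bins, counts fragments per bin per
#' sample (a fragment is counted in every bin it overlaps), and returns the
#' Pearson correlation matrix of the per-sample bin vectors.
#'
#' @param fragments_by_sample named list of fragment data frames.
#' @param bin bin width in bp (default 100).
#' @param chrom_sizes named vector of chromosome lengths; inferred from the
#'   fragments when missing.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
binned_correlation <- function(fragments_by_sample, bin = 100,
                               chrom_sizes = NULL) {
  stopifnot(is.list(fragments_by_sample), length(fragments_by_sample) >= 2L)
  samples <- names(fragments_by_sample)
  if (is.null(chrom_sizes)) {
    all_f <- do.call(rbind, lapply(fragments_by_sample,
                                   function(f) f[, c("chrom", "end")]))
    chrom_sizes <- vapply(split(all_f$end, all_f$chrom), max, 1)
  }
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0L, chrom_sizes[[ch]] - 1L, by = bin)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin, chrom_sizes[[ch]]))
  }))
  bin_gr <- as_granges0(bins)
  m <- vapply(fragments_by_sample, function(f) {
    check_intervals(f, "fragments")
    if (nrow(f) == 0L) numeric(nrow(bins))
    else as.numeric(GenomicRanges::countOverlaps(bin_gr, as_granges0(f)))
  }, numeric(nrow(bins)))
  colnames(m) <- samples
  r <- stats::cor(m)
  diag(r) <- 1
  r
}

#' Per-sample QC report
#'
#' Assembles the library validation metrics for each sample: TSS enrichment
#' score, FRiP, NRF, PBC1/PBC2, NFR score and mean autosomal coverage.
#' Metrics are computed on the quality-filtered fragments
#' (see [filter_fragments()]).
#'
#' @param fragments_by_sample named list of *raw* fragment data frames.
#' @param peaks peak set used for FRiP (per-sample calls or consensus).
#' @param tss TSS table (`chrom`, `pos`, `strand`).
#' @param chrom_sizes named chromosome lengths (autosomes + "MT").
#' @param min_mapq,exclude_chroms passed to [filter_fragments()].
#' @return data frame, one row per sample, columns `sample`, `n_raw`,
#'   `n_filtered`, `tss_es`, `frip`, `nrf`, `pbc1`, `pbc2`, `nfr_score`,
#'   `mean_autosome_cov`.
#' @export
qc_report <- function(fragments_by_sample, peaks, tss, chrom_sizes,
                      min_mapq = 10, exclude_chroms = "MT") {
  stopifnot(is.list(fragments_by_sample), !is.null(names(fragments_by_sample)))
  autosomes <- setdiff(names(chrom_sizes), exclude_chroms)
  auto_len <- sum(unlist(chrom_sizes[autosomes]))
  rows <- lapply(names(fragments_by_sample), function(s) {
    raw <- fragments_by_sample[[s]]
    f <- filter_fragments(raw, min_mapq = min_mapq,
                          exclude_chroms = exclude_chroms)
    lc <- library_complexity(f)
    auto <- f[f$chrom %in% autosomes, , drop = FALSE]
    data.frame(
      sample = s, n_raw = nrow(raw), n_filtered = nrow(f),
      tss_es = tss_enrichment(f, tss)$tss_es,
      frip = frip(f, peaks),
      nrf = lc$nrf, pbc1 = lc$pbc1, pbc2 = lc$pbc2,
      nfr_score = nfr_score(f),
      mean_autosome_cov = sum(auto$end - auto$start) / auto_len,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
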