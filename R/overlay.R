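# Signed peak-to-gene distances and the size-specific peak / DE gene overlay.

#' Signed start distance from a gene to peaks
#'
#' Strand-aware coordinate linking a peak to a gene: the magnitude is the
#' distance from the gene's 5' end (TSS) to the peak's 5'-most boundary; the
#' sign is positive when the peak lies within the gene or in the 5' upstream
#' window, and negative when it lies within `window` bp past the gene's 3'
#' end. Peaks outside `[5' end - window, 3' end + window]` return `NA`.
#'
#' @param gene single-row data frame (or list) with `chrom`, `strand`,
#'   `start`, `end` (0-based half-open; TSS = `start` on "+", `end` on "-").
#' @param peaks peak data frame (`chrom`, `start`, `end`).
#' @param window vicinity window in bp (default 10000).
#' @return numeric vector of signed distances (NA outside the window), one
#'   per peak.
#' @examples
#' g <- data.frame(chrom = "chr1", strand = "+", start = 10000, end = 20000)
#' signed_start_distance(g, data.frame(chrom = "chr1", start = 8000, end = 8400))
#' @export
signed_start_distance <- function(gene, peaks, window = 10000) {
  stopifnot(window > 0)
  gene <- as.list(gene)
  check_intervals(peaks, "peaks")
  glen <- gene$end - gene$start
  tss <- if (gene$strand == "+") gene$start else gene$end
  # strand-aware offset of the peak's 5'-most boundary relative to the TSS:
  # negative = upstream of the TSS, 0..glen = within the gene, > glen = past
  # the 3' end
  raw <- if (gene$strand == "+") peaks$start - tss else tss - peaks$end
  out <- ifelse(raw <= glen, abs(raw), -abs(raw))
  out[peaks$chrom != gene$chrom | raw < -window | raw > glen + window] <- NA_real_
  out
}

#' Overlay size-class-specific peaks onto differentially expressed genes
#'
#' For every (gene, peak) pair in which the peak lies within `window` bp of
#' the gene (see [signed_start_distance()]), emits one record carrying the
#' signed start distance, the peak width, the peak's size-class specificity
#' and the gene's differential-expression status. Output order is
#' deterministic (by gene then distance), independent of peak input order.
#'
#' @param genes data frame of gene models (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`), typically `ann$genes`.
#' @param peaksets named list of peak data frames keyed by specificity label
#'   (e.g. `shared`, `small_only`, `large_only`, `average_only`).
#' @param de_genes character vector of differentially expressed gene ids (or
#'   data frame with `feature`/`gene_id` and `significant` columns).
#' @param window vicinity window in bp (default 10000).
#' @param de_only when TRUE keep only records of DE genes (default FALSE:
#'   all genes are tabulated and DE genes flagged).
#' @return data frame: `gene_id`, `peak`, `start_dist`, `peak_width`,
#'   `specificity`, `de_status`.
#' @export
overlay_table <- function(genes, peaksets, de_genes, window = 10000,
                          de_only = FALSE) {
  stopifnot(is.data.frame(genes), is.list(peaksets),
            !is.null(names(peaksets)))
  if (is.data.frame(de_genes)) {
    idc <- intersect(c("gene_id", "feature"), names(de_genes))[1L]
    ids <- de_genes[[idc]]
    if (!is.null(de_genes$significant))
      ids <- ids[de_genes$significant %in% TRUE]
    de_genes <- ids
  }
  rows <- list()
  for (spec in names(peaksets)) {
    p <- peaksets[[spec]]
    if (is.null(p) || nrow(p) == 0L) next
    for (i in seq_len(nrow(genes))) {
      d <- signed_start_distance(genes[i, ], p, window = window)
      hit <- which(!is.na(d))
      if (!length(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i],
        peak = peak_id(p[hit, , drop = FALSE]),
        start_dist = d[hit],
        peak_width = p$end[hit] - p$start[hit],
        specificity = spec,
        de_status = genes$gene_id[i] %in% de_genes,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), peak = character(),
                      start_dist = numeric(), peak_width = integer(),
                      specificity = character(), de_status = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$start_dist, out$specificity, out$peak), ,
             drop = FALSE]
  if (de_only) out <- out[out$de_status, , drop = FALSE]
  rownames(out) <- NULL
  out
}
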