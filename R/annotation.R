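# Gene-model container, GTF-style serialization, peak-to-feature
# classification and category summaries.

#' Construct a gene annotation
#'
#' Container for strand-aware gene models: per-gene extent and TSS, exons in
#' transcription order, and 5'/3' UTR intervals. All coordinates 0-based
#' half-open; the TSS is the gene's 5' end on its strand (`start` on "+",
#' `end` on "-").
#'
#' @param genes data frame: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (`tss` is derived when absent).
#' @param exons data frame: `gene_id`, `rank` (1 = 5'-most exon), `start`,
#'   `end`.
#' @param utr5,utr3 data frames: `gene_id`, `start`, `end` (may be empty).
#' @return object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, utr5 = NULL, utr3 = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (nrow(genes)) {
    check_intervals(genes, "genes")
    stopifnot(all(genes$strand %in% c("+", "-")))
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  empty_iv <- function() data.frame(gene_id = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE)
  if (is.null(utr5)) utr5 <- empty_iv()
  if (is.null(utr3)) utr3 <- empty_iv()
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Extract the TSS table of an annotation
#'
#' @param ann a [gene_annotation()].
#' @return data frame `gene_id`, `chrom`, `pos` (0-based TSS), `strand`.
#' @export
tss_table <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  data.frame(gene_id = ann$genes$gene_id, chrom = ann$genes$chrom,
             pos = ann$genes$tss, strand = ann$genes$strand,
             stringsAsFactors = FALSE)
}

#' Write an annotation as GTF
#'
#' One `gene` row plus `exon`, `five_prime_utr` and `three_prime_utr` rows per
#' gene, 1-based closed coordinates per the GTF convention.
#'
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  row <- function(chrom, feat, start, end, strand, gid)
    sprintf("%s\tpeakforge\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            chrom, feat, start + 1L, end, strand, gid, gid)
  g <- ann$genes
  strand_of <- setNames(g$strand, g$gene_id)
  chrom_of <- setNames(g$chrom, g$gene_id)
  lines <- character(0)
  if (nrow(g))
    lines <- row(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id)
  feat_lines <- function(df, feat) {
    if (is.null(df) || nrow(df) == 0L) return(character(0))
    row(chrom_of[df$gene_id], feat, df$start, df$end,
        strand_of[df$gene_id], df$gene_id)
  }
  lines <- c(lines,
             feat_lines(ann$exons, "exon"),
             feat_lines(ann$utr5, "five_prime_utr"),
             feat_lines(ann$utr3, "three_prime_utr"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation written by [write_annotation_gtf()]
#'
#' @param path GTF path.
#' @return a [gene_annotation()] (coordinates converted back to 0-based
#'   half-open).
#' @export
read_annotation_gtf <- function(path) {
  tab <- utils::read.table(path, sep = "\t", quote = "",
                           col.names = c("chrom", "source", "feature", "start",
                                         "end", "score", "strand", "frame",
                                         "attr"),
                           stringsAsFactors = FALSE)
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", tab$attr)
  tab$start <- tab$start - 1L  # back to 0-based half-open
  pick <- function(feat) {
    z <- tab[tab$feature == feat, , drop = FALSE]
    data.frame(gene_id = gid[tab$feature == feat], chrom = z$chrom,
               strand = z$strand, start = z$start, end = z$end,
               stringsAsFactors = FALSE)
  }
  genes <- pick("gene")
  ex <- pick("exon")
  # restore transcription-order exon rank
  ex <- ex[order(ex$gene_id, ex$start), , drop = FALSE]
  rk <- unlist(lapply(split(seq_len(nrow(ex)), ex$gene_id), function(idx) {
    if (ex$strand[idx[1L]] == "+") seq_along(idx) else rev(seq_along(idx))
  }), use.names = FALSE)
  ex$rank <- rk
  gene_annotation(genes[, c("gene_id", "chrom", "strand", "start", "end")],
                  ex[, c("gene_id", "rank", "start", "end")],
                  pick("five_prime_utr")[, c("gene_id", "start", "end")],
                  pick("three_prime_utr")[, c("gene_id", "start", "end")])
}

FEATURE_CATEGORIES <- c("Promoter (<=1kb)", "Promoter (1-2kb)",
                        "Promoter (2-3kb)", "5' UTR", "3' UTR", "1st exon",
                        "Other exon", "1st intron", "Other intron",
                        "Downstream (<=3kb)", "Distal intergenic")

#' Classify peaks into genomic feature categories
#'
#' Each peak receives exactly one category by fixed precedence, anchored at
#' the peak midpoint: promoter windows by absolute distance to the nearest
#' TSS (<= 1 kb, 1-2 kb, 2-3 kb), then within-gene features of the covering
#' gene (5' UTR > 3' UTR > 1st exon > other exon > 1st intron > other
#' intron), then downstream (<= 3 kb past the 3' end, strand-aware), else
#' distal intergenic. Peaks on chromosomes absent from the annotation are
#' distal intergenic with a warning.
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`).
#' @param ann a [gene_annotation()].
#' @param promoter_windows increasing promoter window bounds in bp (default
#'   `c(1000, 2000, 3000)`).
#' @param downstream downstream window in bp (default 3000).
#' @return data frame: `peak` (id), `category` (factor over the 11
#'   categories), `gene_id`, `tss_dist` (signed midpoint-to-TSS distance of
#'   the nearest TSS, strand-aware: negative = upstream).
#' @export
classify_peaks <- function(peaks, ann, promoter_windows = c(1000, 2000, 3000),
                           downstream = 3000) {
  check_intervals(peaks, "peaks")
  stopifnot(inherits(ann, "gene_annotation"))
  g <- ann$genes
  mid <- floor((peaks$start + peaks$end) / 2)
  n <- nrow(peaks)
  category <- character(n)
  gene_id <- rep(NA_character_, n)
  tss_dist <- rep(NA_real_, n)
  missing_chrom <- FALSE
  exons_by_gene <- split(ann$exons, ann$exons$gene_id)
  utr5_by_gene <- split(ann$utr5, ann$utr5$gene_id)
  utr3_by_gene <- split(ann$utr3, ann$utr3$gene_id)
  in_iv <- function(df, m) !is.null(df) && nrow(df) > 0 &&
    any(df$start <= m & m < df$end)
  for (i in seq_len(n)) {
    m <- mid[i]
    gi <- which(g$chrom == peaks$chrom[i])
    if (!length(gi)) {
      category[i] <- "Distal intergenic"
      missing_chrom <- missing_chrom || !(peaks$chrom[i] %in% g$chrom)
      next
    }
    dists <- abs(g$tss[gi] - m)
    near <- gi[which.min(dists)]
    dmin <- min(dists)
    tss_dist[i] <- (m - g$tss[near]) * ifelse(g$strand[near] == "+", 1, -1)
    if (dmin <= promoter_windows[1L]) {
      category[i] <- "Promoter (<=1kb)"; gene_id[i] <- g$gene_id[near]; next
    }
    if (dmin <= promoter_windows[2L]) {
      category[i] <- "Promoter (1-2kb)"; gene_id[i] <- g$gene_id[near]; next
    }
    if (dmin <= promoter_windows[3L]) {
      category[i] <- "Promoter (2-3kb)"; gene_id[i] <- g$gene_id[near]; next
    }
    cover <- gi[g$start[gi] <= m & m < g$end[gi]]
    if (length(cover)) {
      cg <- cover[1L]
      cid <- g$gene_id[cg]
      gene_id[i] <- cid
      if (in_iv(utr5_by_gene[[cid]], m)) { category[i] <- "5' UTR"; next }
      if (in_iv(utr3_by_gene[[cid]], m)) { category[i] <- "3' UTR"; next }
      ex <- exons_by_gene[[cid]]
      hit <- which(ex$start <= m & m < ex$end)
      if (length(hit)) {
        category[i] <- if (ex$rank[hit[1L]] == 1L) "1st exon" else "Other exon"
        next
      }
      # intron index: number of exons whose 5' end precedes the midpoint
      # in transcription order
      if (g$strand[cg] == "+") {
        idx <- sum(ex$end <= m)
      } else {
        idx <- sum(ex$start > m)
      }
      category[i] <- if (idx <= 1L) "1st intron" else "Other intron"
      next
    }
    # strand-aware downstream distance past the 3' end
    down <- ifelse(g$strand[gi] == "+", m - g$end[gi], g$start[gi] - m)
    cand <- which(down > 0 & down <= downstream)
    if (length(cand)) {
      near_d <- cand[which.min(down[cand])]
      category[i] <- "Downstream (<=3kb)"
      gene_id[i] <- g$gene_id[gi[near_d]]
      next
    }
    category[i] <- "Distal intergenic"
  }
  if (missing_chrom)
    warning("some peaks lie on chromosomes absent from the annotation; ",
            "classified as distal intergenic")
  data.frame(peak = peak_id(peaks),
             category = factor(category, levels = FEATURE_CATEGORIES),
             gene_id = gene_id, tss_dist = tss_dist,
             stringsAsFactors = FALSE)
}

#' Summarize feature category frequencies
#'
#' Counts per category and percentages (`100 * count / total`, printed to 3
#' significant figures); the percentages sum to 100 up to rounding.
#'
#' @param calls a character/factor vector of category labels, the data frame
#'   returned by [classify_peaks()], or a named count vector/table.
#' @return data frame `category`, `count`, `percent` (3 significant figures).
#' @export
summarize_features <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$category
  if (is.table(calls) || (!is.null(names(calls)) && is.numeric(calls))) {
    counts <- as.numeric(calls)
    cats <- names(calls)
  } else {
    tab <- table(calls)
    counts <- as.numeric(tab)
    cats <- names(tab)
  }
  total <- sum(counts)
  if (total == 0) stop("no feature calls supplied")
  data.frame(category = cats, count = counts,
             percent = signif(100 * counts / total, 3),
             stringsAsFactors = FALSE)
}

#' Collapse detailed feature categories onto the broad vocabulary
#'
#' Surjection from the 11-category promoter/UTR/exon/intron system onto the
#' broad labels used for differential-peak summaries (Intronic, Intergenic,
#' Promoter, 3' UTR, Proximal, 5' UTR, CDS, Exonic). "Proximal" additionally
#' captures distal-intergenic calls whose midpoint lies within 2-10 kb of the
#' nearest TSS.
#'
#' @param calls data frame from [classify_peaks()] (needs `category` and
#'   `tss_dist`).
#' @return character vector of broad labels, one per call.
#' @export
collapse_to_broad <- function(calls) {
  stopifnot(is.data.frame(calls), !is.null(calls$category))
  map <- c("Promoter (<=1kb)" = "Promoter", "Promoter (1-2kb)" = "Promoter",
           "Promoter (2-3kb)" = "Proximal", "5' UTR" = "5' UTR",
           "3' UTR" = "3' UTR", "1st exon" = "CDS", "Other exon" = "Exonic",
           "1st intron" = "Intronic", "Other intron" = "Intronic",
           "Downstream (<=3kb)" = "Intergenic",
           "Distal intergenic" = "Intergenic")
  out <- unname(map[as.character(calls$category)])
  if (!is.null(calls$tss_dist)) {
    prox <- out == "Intergenic" & !is.na(calls$tss_dist) &
      abs(calls$tss_dist) > 2000 & abs(calls$tss_dist) <= 10000
    out[prox] <- "Proximal"
  }
  out
}
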