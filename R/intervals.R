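# Consensus-peak construction: peak I/O, gap merging with sample support,
# support filtering, shared/size-specific separation, fragment counting.

#' Read peak calls from a BED or narrowPeak file
#'
#' Accepts BED3, BED6 and 10-column narrowPeak. Coordinates are kept 0-based
#' half-open as stored in the file. Malformed lines (wrong field count,
#' non-numeric or inverted coordinates) raise an error naming the line number.
#'
#' @param path path to a tab-separated BED/narrowPeak file.
#' @param sample optional sample label attached to every interval (defaults to
#'   the file name without extension).
#' @return a data frame with columns `chrom`, `start`, `end`, `sample` and,
#'   when present in the file, `name` and `score`.
#' @seealso [write_peaks()], [merge_with_support()]
#' @export
read_peaks <- function(path, sample = NULL) {
  if (is.null(sample))
    sample <- sub("\\.(bed|narrowPeak)$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      sample = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d in '%s': fewer than 3 fields",
                 lineno[which(nf < 3L)[1L]], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in '%s': non-numeric coordinates",
                 lineno[bad[1L]], path))
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop(sprintf("malformed BED line %d in '%s': start >= end (or negative)",
                 lineno[bad[1L]], path))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    sample = sample, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L))
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  out
}

#' Write intervals as BED
#'
#' Writes BED3 (or BED6 when `name`/`score` columns are present; strand is
#' reported as "."). Round-trips with [read_peaks()] on `chrom`, `start`,
#' `end`, `name`, `score`.
#'
#' @param x interval data frame (`chrom`, `start`, `end`, optionally `name`,
#'   `score`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  check_intervals(x, "peaks")
  cols <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                     stringsAsFactors = FALSE)
  if (!is.null(x$name) || !is.null(x$score)) {
    cols$name <- if (is.null(x$name)) "." else x$name
    cols$score <- if (is.null(x$score)) 0 else x$score
    cols$strand <- "."
  }
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge per-sample peaks into consensus peaks with sample support
#'
#' Collapses the transitive closure of the relation "inter-peak gap is at most
#' `merge_gap` bases" (overlapping and book-ended peaks always merge) into
#' spanning consensus intervals. Each consensus peak carries a `support`
#' value: the number of distinct sample labels among its member peaks (a
#' sample contributing several member peaks counts once).
#'
#' @param peaks data frame of intervals over samples: `chrom`, `start`, `end`,
#'   `sample` (missing `sample` treats every row as one anonymous sample).
#' @param merge_gap non-negative merge distance in bp (default 10: peaks
#'   within <= 10 nucleotides of one another are merged).
#' @return data frame of class `consensus_peaks` with columns `chrom`,
#'   `start`, `end`, `support`, `n_members` and a list-column `members`
#'   holding each member's `(chrom, start, end, sample)`.
#' @examples
#' p <- data.frame(chrom = "chr1", start = c(100, 205), end = c(200, 300),
#'                 sample = c("sA", "sB"))
#' merge_with_support(p, merge_gap = 10)
#' @export
merge_with_support <- function(peaks, merge_gap = 10) {
  if (!is.numeric(merge_gap) || length(merge_gap) != 1L || merge_gap < 0)
    stop("merge_gap must be a single non-negative number")
  check_intervals(peaks, "peaks")
  if (is.null(peaks$sample)) peaks$sample <- "sample1"
  if (nrow(peaks) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      support = integer(), n_members = integer())
    out$members <- list()
    class(out) <- c("consensus_peaks", "data.frame")
    return(out)
  }
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[ord, , drop = FALSE]
  res <- lapply(split(seq_len(nrow(p)), p$chrom), function(idx) {
    s <- p$start[idx]; e <- p$end[idx]
    cme <- cummax(e)
    # new cluster when this start lies more than merge_gap past everything seen
    newgrp <- c(TRUE, s[-1L] > cme[-length(cme)] + merge_gap)
    grp <- cumsum(newgrp)
    lapply(split(seq_along(idx), grp), function(g) {
      rows <- idx[g]
      list(chrom = p$chrom[rows[1L]], start = min(s[g]), end = max(e[g]),
           members = p[rows, c("chrom", "start", "end", "sample")],
           support = length(unique(p$sample[rows])))
    })
  })
  res <- unlist(res, recursive = FALSE, use.names = FALSE)
  out <- data.frame(
    chrom = vapply(res, `[[`, "", "chrom"),
    start = vapply(res, function(z) as.integer(z$start), 1L),
    end = vapply(res, function(z) as.integer(z$end), 1L),
    support = vapply(res, function(z) as.integer(z$support), 1L),
    n_members = vapply(res, function(z) nrow(z$members), 1L),
    stringsAsFactors = FALSE
  )
  out$members <- lapply(res, `[[`, "members")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_peaks", "data.frame")
  out
}

#' Filter consensus peaks by sample support
#'
#' Retains consensus peaks present in at least `min_support` distinct samples,
#' preserving input order. With the defaults of the pipeline, peaks with a
#' support value below 3 are removed before differential analysis.
#'
#' @param consensus output of [merge_with_support()].
#' @param min_support minimum number of contributing samples (>= 1).
#' @return the filtered consensus data frame.
#' @export
filter_support <- function(consensus, min_support = 3) {
  stopifnot(is.data.frame(consensus), !is.null(consensus$support))
  if (!is.numeric(min_support) || length(min_support) != 1L || min_support < 1)
    stop("min_support must be a single number >= 1")
  out <- consensus[consensus$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Separate peaks shared across all size classes from class-specific peaks
#'
#' A peak is *shared* when it overlaps (by at least 1 bp) a peak in every
#' other size class; *specific* to its class when it overlaps no peak of any
#' other class. Peaks overlapping some but not all other classes are reported
#' separately as *partial* and belong to neither set.
#'
#' @param peaksets named list (one element per size class) of interval data
#'   frames.
#' @return list with elements `shared` (data frame with a `class` column
#'   recording the contributing class), `specific` (named list per class) and
#'   `partial` (data frame with `class` column).
#' @export
separate_size_specific <- function(peaksets) {
  stopifnot(is.list(peaksets), length(peaksets) >= 2L,
            !is.null(names(peaksets)), all(nzchar(names(peaksets))))
  for (nm in names(peaksets)) check_intervals(peaksets[[nm]], nm)
  grs <- lapply(peaksets, as_granges0)
  classes <- names(peaksets)
  shared <- list(); partial <- list()
  specific <- setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    x <- peaksets[[cl]]
    others <- setdiff(classes, cl)
    if (nrow(x) == 0L) {
      specific[[cl]] <- x
      next
    }
    hits <- vapply(others, function(o) {
      if (nrow(peaksets[[o]]) == 0L) rep(FALSE, nrow(x))
      else IRanges::overlapsAny(grs[[cl]], grs[[o]])
    }, logical(nrow(x)))
    if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(x))
    nhit <- rowSums(hits)
    is_shared <- nhit == length(others)
    is_spec <- nhit == 0L
    specific[[cl]] <- x[is_spec, , drop = FALSE]
    sh <- x[is_shared, , drop = FALSE]
    pa <- x[!is_shared & !is_spec, , drop = FALSE]
    if (nrow(sh)) { sh$class <- cl; shared[[cl]] <- sh }
    if (nrow(pa)) { pa$class <- cl; partial[[cl]] <- pa }
  }
  empty <- function() {
    z <- data.frame(chrom = character(), start = integer(), end = integer(),
                    class = character(), stringsAsFactors = FALSE)
    z
  }
  list(
    shared = if (length(shared)) do.call(rbind, c(shared, make.row.names = FALSE)) else empty(),
    specific = lapply(specific, function(z) { rownames(z) <- NULL; z }),
    partial = if (length(partial)) do.call(rbind, c(partial, make.row.names = FALSE)) else empty()
  )
}

#' Count fragments over a disjoint consensus peak set
#'
#' `count[i, j]` is the number of sample-`j` fragments overlapping peak `i` by
#' at least 1 bp (unstranded). The consensus set must be pairwise disjoint
#' (guaranteed by [merge_with_support()]); overlapping input is an error.
#' Per-sample library sizes (total fragments supplied, assumed pre-filtered
#' with [filter_fragments()]) are recorded alongside the counts.
#'
#' @param consensus consensus peak data frame (`chrom`, `start`, `end`).
#' @param fragments fragment data frame with a `sample` column, or a named
#'   list of per-sample fragment data frames.
#' @return a `count_matrix`: list with `counts` (features x samples integer
#'   matrix, rownames `chrom:start-end`), `library_sizes`, and the `features`
#'   data frame.
#' @export
count_fragments <- function(consensus, fragments) {
  check_intervals(consensus, "consensus")
  if (is.data.frame(fragments)) {
    stopifnot(!is.null(fragments$sample))
    fragments <- split(fragments, fragments$sample)
  }
  cons <- as.data.frame(consensus[, c("chrom", "start", "end")])
  ord <- order(cons$chrom, cons$start)
  cons <- cons[ord, , drop = FALSE]
  # disjointness check within chromosome
  for (idx in split(seq_len(nrow(cons)), cons$chrom)) {
    if (length(idx) > 1L) {
      s <- cons$start[idx]; e <- cons$end[idx]
      if (any(s[-1L] < e[-length(e)]))
        stop("consensus peaks overlap; merge them first with merge_with_support()")
    }
  }
  gr <- as_granges0(cons)
  samples <- names(fragments)
  counts <- matrix(0L, nrow = nrow(cons), ncol = length(samples),
                   dimnames = list(peak_id(cons), samples))
  lib <- setNames(integer(length(samples)), samples)
  for (j in seq_along(samples)) {
    f <- fragments[[j]]
    check_intervals(f, sprintf("fragments[%s]", samples[j]))
    lib[j] <- nrow(f)
    if (nrow(f))
      counts[, j] <- GenomicRanges::countOverlaps(gr, as_granges0(f))
  }
  count_matrix(counts, library_sizes = lib, features = cons)
}

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param library_sizes per-sample totals used for normalization; defaults to
#'   the column sums.
#' @param features optional feature annotation data frame (one row per count
#'   row).
#' @return list of class `count_matrix` with elements `counts`,
#'   `library_sizes`, `features`.
#' @export
count_matrix <- function(counts, library_sizes = colSums(counts),
                         features = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%d", seq_len(ncol(counts)))
  library_sizes <- setNames(as.numeric(library_sizes), colnames(counts))
  structure(list(counts = counts, library_sizes = library_sizes,
                 features = features),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes: ",
      paste(utils::head(sprintf("%s=%g", names(x$library_sizes),
                                x$library_sizes), 4L),
            collapse = ", "),
      if (ncol(x$counts) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Write a consensus peak set as BED6+ (support in the score column)
#'
#' @param consensus output of [merge_with_support()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  df <- data.frame(chrom = consensus$chrom, start = consensus$start,
                   end = consensus$end, name = peak_id(consensus),
                   score = consensus$support,
                   strand = rep(".", nrow(consensus)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
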