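# Internal helpers shared across modules.

# Validate a peak/interval data frame (0-based half-open).
check_intervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("%s missing column(s): %s", what, paste(miss, collapse = ", ")))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    stop(sprintf("%s: non-finite coordinates", what))
  if (any(x$start < 0))
    stop(sprintf("%s: negative start coordinate", what))
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(sprintf("%s: start >= end at row %d", what, bad[1L]))
  invisible(x)
}

# Convert a 0-based half-open interval data frame to GRanges (1-based closed).
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

peak_id <- function(x) sprintf("%s:%d-%d", x$chrom, x$start, x$end)

# Restore-on-exit seeded evaluation so generators never disturb the caller's RNG.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
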