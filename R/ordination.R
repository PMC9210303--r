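# Count normalization and sample ordination: the stated log normalization,
# Manhattan distances, Kruskal non-metric MDS, and PCA of expression.

#' Normalize raw counts by library size for ordination
#'
#' Elementwise `log2(raw / library_size * 1e8 + 1)`. A raw count of 0 maps to
#' 0 for any library size; the transform is monotone in the raw count and
#' non-negative.
#'
#' @param counts integer matrix (features x samples) or a [count_matrix()].
#' @param library_sizes per-sample totals (ignored when `counts` is a
#'   `count_matrix`).
#' @return numeric matrix of normalized counts, same dimensions as `counts`.
#' @examples
#' normalize_counts(matrix(c(0, 100), 1), library_sizes = c(5e7, 1e8))
#' @export
normalize_counts <- function(counts, library_sizes = NULL) {
  if (inherits(counts, "count_matrix")) {
    library_sizes <- counts$library_sizes
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts))
  if (is.null(library_sizes)) stop("library_sizes required")
  if (length(library_sizes) != ncol(counts))
    stop("one library size per sample required")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  log2(sweep(counts, 2L, library_sizes, "/") * 1e8 + 1)
}

#' Manhattan distance matrix between samples
#'
#' `d(i, j) = sum_f |x[f, i] - x[f, j]|` over features, computed between the
#' columns of a normalized count matrix.
#'
#' @param x numeric matrix, features x samples.
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
manhattan_distance <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  as.matrix(stats::dist(t(x), method = "manhattan"))
}

# Pool-adjacent-violators: weighted least-squares isotonic (non-decreasing)
# fit to y. Returns the fitted values in input order.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  # block representation: value, weight, size
  val <- y; wt <- w; sz <- rep(1L, n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; sz[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      tw <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) / tw
      wt[nb - 1L] <- tw
      sz[nb - 1L] <- sz[nb - 1L] + sz[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], times = sz[seq_len(nb)])
}

# Kruskal stress-1 of a configuration against dissimilarities d (vectors over
# pairs): sqrt(sum((D - dhat)^2) / sum(D^2)), dhat the isotonic fit of D on
# the rank order of d (primary approach to ties: within tied d, pairs are
# ordered by D so ties never add stress).
stress1 <- function(dvec, Dvec) {
  ord <- order(dvec, Dvec)
  dhat <- numeric(length(Dvec))
  dhat[ord] <- pava(Dvec[ord])
  sqrt(sum((Dvec - dhat)^2) / sum(Dvec^2))
}

#' Non-metric multidimensional scaling (Kruskal)
#'
#' Embeds samples in `k` dimensions by minimizing Kruskal's stress-1,
#' `sqrt(sum((D - dhat)^2) / sum(D^2))`, where `D` are configuration
#' distances and `dhat` is the isotonic (monotone non-decreasing) regression
#' of `D` on the rank order of the input dissimilarities (pool-adjacent
#' violators; ties in the input are handled by the primary approach). The
#' configuration is initialized from classical (Torgerson) scaling and
#' updated by alternating the isotonic fit with a Guttman-transform
#' (majorization) step, which makes the recorded stress sequence monotone
#' non-increasing; iteration stops when the stress improvement falls below
#' `tol` or a step fails to improve.
#'
#' @param d symmetric non-negative dissimilarity matrix (zero diagonal) or a
#'   `dist` object.
#' @param k embedding dimension (default 2; use 3 to inspect components 1-3).
#' @param max_iter maximum number of iterations (default 200).
#' @param tol convergence tolerance on the stress decrease (default 1e-6).
#' @param seed integer seed used only to break degenerate (rank-deficient)
#'   classical-scaling starts with small jitter.
#' @return object of class `nmds`: `points` (n x k), `stress`,
#'   `stress_history`, `n_iter`, `converged`.
#' @export
nmds <- function(d, k = 2, max_iter = 200, tol = 1e-6, seed = 1L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  if (n <= k + 1L) stop("need more points than dimensions + 1")
  labs <- rownames(d)
  lower <- which(lower.tri(d))
  dvec <- d[lower]

  X <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(X) < k || any(!is.finite(X))) {
    pad <- with_seed(seed, matrix(stats::rnorm(n * k, sd = 1e-4), n, k))
    Xf <- pad
    if (ncol(X) > 0) Xf[, seq_len(ncol(X))] <- Xf[, seq_len(ncol(X))] + X
    X <- Xf
  }

  conf_dist <- function(X) as.matrix(stats::dist(X))[lower]
  Dvec <- conf_dist(X)
  stress <- stress1(dvec, Dvec)
  history <- stress
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # isotonic targets for the current configuration
    ord <- order(dvec, Dvec)
    dhat <- numeric(length(Dvec))
    dhat[ord] <- pava(Dvec[ord])
    # Guttman transform toward the targets
    B <- matrix(0, n, n)
    ratio <- ifelse(Dvec > 0, dhat / Dvec, 0)
    B[lower] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    Xnew <- (B %*% X) / n
    Dnew <- conf_dist(Xnew)
    snew <- stress1(dvec, Dnew)
    if (snew > stress) break  # keep the monotone sequence; stop here
    improved <- (stress - snew) > tol
    X <- Xnew; Dvec <- Dnew; stress <- snew
    history <- c(history, snew)
    if (!improved) { converged <- TRUE; break }
  }
  if (!is.null(labs)) rownames(X) <- labs
  colnames(X) <- sprintf("MDS%d", seq_len(k))
  structure(list(points = X, stress = stress, stress_history = history,
                 n_iter = length(history) - 1L, converged = converged),
            class = "nmds")
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("Non-metric MDS: %d points in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  cat(sprintf("Kruskal stress-1: %.6f after %d iterations (%s)\n",
              x$stress, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
plot.nmds <- function(x, dims = c(1, 2), col = 1, pch = 19, ...) {
  p <- x$points[, dims, drop = FALSE]
  graphics::plot(p, col = col, pch = pch,
                 xlab = colnames(p)[1], ylab = colnames(p)[2], ...)
  invisible(x)
}

#' Principal component analysis of samples
#'
#' SVD-based PCA of the sample columns of an expression (or normalized count)
#' matrix, reporting per-component variance shares.
#'
#' @param x numeric matrix, features x samples.
#' @param center,scale. passed to [stats::prcomp()] (defaults: center, no
#'   scaling).
#' @return object of class `sample_pca`: `scores` (samples x components),
#'   `var_share` (sums to 1), `sdev`.
#' @export
sample_pca <- function(x, center = TRUE, scale. = FALSE) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  keep <- apply(x, 1L, function(r) stats::var(r) > 0)
  p <- stats::prcomp(t(x[keep, , drop = FALSE]), center = center,
                     scale. = scale.)
  structure(list(scores = p$x,
                 var_share = p$sdev^2 / sum(p$sdev^2),
                 sdev = p$sdev),
            class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat(sprintf("PCA of %d samples; variance shares: %s\n",
              nrow(x$scores),
              paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(x$var_share))),
                            100 * x$var_share[seq_len(min(4, length(x$var_share)))]),
                    collapse = ", ")))
  invisible(x)
}
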