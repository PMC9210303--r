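# Differential accessibility/expression: median-of-ratios size factors,
# method-of-moments dispersion with trend shrinkage, negative-binomial GLM
# likelihood-ratio tests, Benjamini-Hochberg adjustment, and the two study
# pipelines (time-course differential peaks; day-90 size-class DE).

#' Median-of-ratios size factors
#'
#' For each sample, the median over features (restricted to features with
#' all-positive counts) of the ratio of its count to the feature's geometric
#' mean across samples.
#'
#' @param counts integer matrix (features x samples) or [count_matrix()].
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("size factors undefined: no feature has all-positive counts")
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cnt)
    exp(stats::median(log(cnt) - loggeo[use])))
  setNames(sf, colnames(counts))
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per feature, on size-factor-normalized counts, the raw dispersion is
#' `max(0, (s^2 - mu) / mu^2)` (so Poisson-like features get 0). A
#' mean-dispersion trend `a0 + a1/mu` is fitted across features and each raw
#' estimate is shrunk halfway toward the trend; estimates are floored at
#' 1e-8.
#'
#' @param counts integer matrix or [count_matrix()].
#' @param sf size factors (defaults to [size_factors()] of `counts`).
#' @return named non-negative numeric vector, one dispersion per feature.
#' @export
estimate_dispersion <- function(counts, sf = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  araw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  fit_ok <- mu > 0 & is.finite(araw)
  trend <- rep(mean(araw[fit_ok]), length(mu))
  if (sum(fit_ok) >= 10L) {
    co <- tryCatch(stats::coef(stats::lm(araw[fit_ok] ~ I(1 / mu[fit_ok]))),
                   error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co))) {
      a0 <- max(co[1L], 0); a1 <- max(co[2L], 0)
      trend <- ifelse(mu > 0, a0 + a1 / mu, a0)
    }
  }
  alpha <- pmax(0.5 * araw + 0.5 * trend, 1e-8)
  setNames(alpha, rownames(counts))
}

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

fit_nb_one <- function(X, y, offset, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = offset,
                   control = list(maxit = 50))
  )
  list(coef = fit$coefficients,
       ll = nb_loglik(y, fit$fitted.values, alpha),
       converged = isTRUE(fit$converged))
}

#' Negative-binomial GLM likelihood-ratio test per feature
#'
#' Fits, for every feature, a log-link negative-binomial GLM (iteratively
#' reweighted least squares) under a full and a nested reduced design with
#' fixed per-feature dispersion and log size-factor offsets. The LRT
#' statistic `2 * (ll_full - ll_reduced)` is referred to a chi-square
#' distribution with degrees of freedom equal to the difference in parameter
#' count. Unshrunk maximum-likelihood log2 fold changes are reported for the
#' full-design coefficients absent from the reduced design. Non-converged
#' features are flagged and their p-value set missing (they are excluded from
#' the Benjamini-Hochberg denominator downstream).
#'
#' @param counts integer matrix or [count_matrix()].
#' @param design data frame of per-sample factors (rows aligned to the count
#'   columns; a `sample` column, if present, is matched against column
#'   names).
#' @param full,reduced model formulas over columns of `design`, e.g.
#'   `~ size + time` and `~ size`; the reduced design must be nested in the
#'   full one.
#' @param sf size factors (default: computed from `counts`).
#' @param dispersions per-feature dispersions (default:
#'   [estimate_dispersion()]).
#' @return data frame: `feature`, `stat`, `df`, `pvalue`, `converged`, plus
#'   one `log2fc_<coef>` column per tested coefficient.
#' @export
nb_lrt <- function(counts, design, full, reduced, sf = NULL,
                   dispersions = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(is.matrix(counts), is.data.frame(design))
  if (!is.null(design$sample)) {
    stopifnot(!is.null(colnames(counts)),
              setequal(design$sample, colnames(counts)))
    design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  } else stopifnot(nrow(design) == ncol(counts))
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, sf)
  stopifnot(length(dispersions) == nrow(counts), all(dispersions > 0))
  Xf <- stats::model.matrix(full, design)
  Xr <- stats::model.matrix(reduced, design)
  if (!all(colnames(Xr) %in% colnames(Xf)))
    stop("reduced design is not nested in the full design")
  if (qr(Xf)$rank < ncol(Xf)) stop("full design is not of full rank")
  df_test <- ncol(Xf) - ncol(Xr)
  if (df_test < 1L) stop("full and reduced designs have equal dimension")
  test_coefs <- setdiff(colnames(Xf), colnames(Xr))
  offset <- log(sf)
  nfeat <- nrow(counts)
  stat <- pval <- rep(NA_real_, nfeat)
  conv <- rep(FALSE, nfeat)
  lfc <- matrix(NA_real_, nfeat, length(test_coefs),
                dimnames = list(NULL, test_coefs))
  for (i in seq_len(nfeat)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    ff <- fit_nb_one(Xf, y, offset, dispersions[i])
    fr <- fit_nb_one(Xr, y, offset, dispersions[i])
    if (!ff$converged || !fr$converged || any(!is.finite(ff$coef))) next
    s <- 2 * (ff$ll - fr$ll)
    stat[i] <- max(0, s)
    pval[i] <- stats::pchisq(stat[i], df = df_test, lower.tail = FALSE)
    conv[i] <- TRUE
    lfc[i, ] <- ff$coef[test_coefs] / log(2)
  }
  out <- data.frame(
    feature = if (is.null(rownames(counts)))
      sprintf("feature%d", seq_len(nfeat)) else rownames(counts),
    stat = stat, df = df_test, pvalue = pval, converged = conv,
    stringsAsFactors = FALSE
  )
  colnames(lfc) <- paste0("log2fc_", gsub("[^A-Za-z0-9_.]", "_", test_coefs))
  cbind(out, as.data.frame(lfc))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `padj[i] = min over j with p_(j) >= p_(i) of min(1, m * p_(j) / j)` where
#' `m` is the number of non-missing p-values; equivalently the standard
#' step-up procedure with enforced monotonicity. Missing p-values stay
#' missing and do not count toward `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  ord <- order(pv, decreasing = TRUE)
  # cummin from the largest p downwards enforces step-up monotonicity
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[ord]))
  res <- rep(NA_real_, length(p))
  res[which(ok)[ord]] <- adj
  res
}

#' Differential accessibility of peaks across timepoints
#'
#' The study's time-course test: size factors, dispersion estimation, an
#' NB-GLM likelihood-ratio test of `~ size + time` against `~ size` (litter
#' may be added as a covariate), Benjamini-Hochberg adjustment, and a dual
#' significance rule: `padj < fdr` *and* maximum absolute time log2 fold
#' change `> lfc_min`.
#'
#' @param counts integer matrix or [count_matrix()] over consensus peaks.
#' @param design data frame with `sample`, `timepoint`, `size` (and
#'   optionally `litter`) columns.
#' @param fdr false-discovery-rate threshold (default 0.10).
#' @param lfc_min absolute log2 fold-change threshold on the time contrasts
#'   (default 2).
#' @param covariates extra fixed covariates added to both designs (e.g.
#'   `"litter"`).
#' @return data frame of class `peakforge_diff`: per-feature LRT results plus
#'   `padj`, `max_abs_log2fc`, `significant`.
#' @export
diff_peaks <- function(counts, design, fdr = 0.10, lfc_min = 2.0,
                       covariates = character()) {
  stopifnot(all(c("sample", "timepoint", "size") %in% names(design)))
  base <- c("size", covariates)
  full <- stats::as.formula(paste("~", paste(c(base, "timepoint"), collapse = " + ")))
  reduced <- stats::as.formula(paste("~", paste(base, collapse = " + ")))
  res <- nb_lrt(counts, design, full, reduced)
  res$padj <- bh_adjust(res$pvalue)
  lfc_cols <- grep("^log2fc_", names(res), value = TRUE)
  res$max_abs_log2fc <- apply(abs(res[, lfc_cols, drop = FALSE]), 1L,
                              function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
  res$significant <- !is.na(res$padj) & res$padj < fdr &
    !is.na(res$max_abs_log2fc) & res$max_abs_log2fc > lfc_min
  attr(res, "fdr") <- fdr
  attr(res, "lfc_min") <- lfc_min
  class(res) <- c("peakforge_diff", "data.frame")
  res
}

#' @export
print.peakforge_diff <- function(x, ...) {
  cat(sprintf(
    "Differential test over %d features: %d significant (FDR < %g%s)\n",
    nrow(x), sum(x$significant, na.rm = TRUE), attr(x, "fdr"),
    if (!is.null(attr(x, "lfc_min")) && is.finite(attr(x, "lfc_min")))
      sprintf(", |log2FC| > %g", attr(x, "lfc_min")) else ""))
  invisible(x)
}

#' @export
summary.peakforge_diff <- function(object, ...) {
  cat(sprintf("features tested: %d (converged %d)\n",
              nrow(object), sum(object$converged)))
  cat(sprintf("significant: %d at FDR < %g\n",
              sum(object$significant, na.rm = TRUE), attr(object, "fdr")))
  pv <- object$pvalue[!is.na(object$pvalue)]
  cat(sprintf("p-value quartiles: %s\n",
              paste(signif(stats::quantile(pv, c(.25, .5, .75)), 3),
                    collapse = " / ")))
  invisible(object)
}

#' Day-90 differential expression between piglet size classes
#'
#' Restricted to samples at one timepoint (day 90 of gestation by default),
#' tests `~ size` against the intercept-only model with an NB-GLM LRT, small
#' size as the reference level (denominator of every log2 fold change).
#' Per-contrast log2 fold changes are reported for large vs small and
#' average vs small; average vs large is their difference on the log2 scale.
#' Significance is `padj < fdr`; `reportable_*` flags additionally require
#' `|log2FC| >= lfc_report` (a reporting threshold, not a test).
#'
#' @param counts transcript/gene count matrix or [count_matrix()].
#' @param design data frame with `sample`, `timepoint`, `size`.
#' @param timepoint label of the tested timepoint (default `"D90"`).
#' @param fdr FDR threshold (default 0.10).
#' @param lfc_report reporting threshold on |log2FC| (default 0.1).
#' @return data frame of class `peakforge_diff` with columns
#'   `log2fc_large_vs_small`, `log2fc_average_vs_small`,
#'   `log2fc_average_vs_large`, `stat`, `df`, `pvalue`, `padj`,
#'   `significant`, and per-contrast `reportable_*` flags.
#' @export
diff_genes_day90 <- function(counts, design, timepoint = "D90", fdr = 0.10,
                             lfc_report = 0.1) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(all(c("sample", "timepoint", "size") %in% names(design)))
  keep <- design$timepoint == timepoint
  if (!any(keep)) stop(sprintf("no samples at timepoint '%s'", timepoint))
  design <- design[keep, , drop = FALSE]
  design$size <- factor(as.character(design$size),
                        levels = c("small", "average", "large"))
  counts <- counts[, match(design$sample, colnames(counts)), drop = FALSE]
  res <- nb_lrt(counts, design, ~size, ~1)
  lvs <- res$log2fc_sizelarge
  avs <- res$log2fc_sizeaverage
  out <- data.frame(
    feature = res$feature,
    log2fc_large_vs_small = lvs,
    log2fc_average_vs_small = avs,
    log2fc_average_vs_large = avs - lvs,
    stat = res$stat, df = res$df, pvalue = res$pvalue,
    converged = res$converged,
    stringsAsFactors = FALSE
  )
  out$padj <- bh_adjust(out$pvalue)
  out$significant <- !is.na(out$padj) & out$padj < fdr
  for (ct in c("large_vs_small", "average_vs_small", "average_vs_large")) {
    lfc <- out[[paste0("log2fc_", ct)]]
    out[[paste0("reportable_", ct)]] <-
      out$significant & !is.na(lfc) & abs(lfc) >= lfc_report
  }
  attr(out, "fdr") <- fdr
  attr(out, "lfc_min") <- NA_real_
  class(out) <- c("peakforge_diff", "data.frame")
  out
}
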