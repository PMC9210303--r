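# Synthetic-data generator: toy genome/annotation, per-sample fragments with
# a tri-modal size mixture, per-sample peak calls with planted core /
# sample-specific / size-class-specific peaks, and NB count and expression
# matrices with planted time and size effects. Every generator is
# deterministic given the config seed and never disturbs the caller's RNG.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study design: an unbalanced
#' 24-sample layout over five developmental timepoints (gestational days
#' 45/60/90, 1 week, 6 weeks) and three piglet size classes
#' (small/average/large, small = reference), a tri-modal ATAC fragment-size
#' mixture with modes near 50/180/350 bp (nucleosome-free, mono- and
#' di-nucleosome), TSS-proximal peak placement, and negative-binomial counts
#' with log-normal library-size factors and planted effects.
#'
#' @param seed integer seed; identical configs (including seed) produce
#'   byte-identical outputs.
#' @param timepoints ordered timepoint labels (5 by default).
#' @param sizes size-class labels; the first is the reference level.
#' @param n_samples number of ATAC samples (default 24).
#' @param chrom_sizes named chromosome lengths in bp; the default includes
#'   two autosomes and "MT" so the mitochondrial exclusion filter is
#'   exercisable.
#' @param n_genes number of non-overlapping gene models to place.
#' @param frag_mixture data frame `mean`, `sd`, `weight` (weights sum to 1)
#'   of the fragment-length mixture components.
#' @param tss_peak_fraction proportion of peaks (and of fragment centers)
#'   placed within 1 kb of a TSS.
#' @param frag_fail_fraction fraction of fragments built to fail the quality
#'   filter (low mapq, duplicate or QC-fail flags).
#' @param mt_fraction fraction of fragments placed on "MT".
#' @param n_core_peaks shared ("core") peaks present in (almost) every
#'   sample.
#' @param core_presence per-sample inclusion probability of each core peak.
#' @param peak_jitter max boundary jitter (bp) applied per sample to shared
#'   peaks.
#' @param n_sample_specific extra peaks private to each sample.
#' @param n_size_specific peaks present in every sample of exactly one size
#'   class.
#' @param merge_gap consensus merge distance the placement respects (planted
#'   peaks are separated by more than `merge_gap + 2 * peak_jitter` so the
#'   consensus set recovers them exactly).
#' @param nb_dispersion negative-binomial dispersion of the counts (> 0).
#' @param effect_log2fc magnitude of the planted log2 fold change.
#' @param effect_fraction fraction of features carrying a planted effect.
#' @param libsize_lsd log-sd of the log-normal library-size factors.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       timepoints = c("D45", "D60", "D90", "W1", "W6"),
                       sizes = c("small", "average", "large"),
                       n_samples = 24L,
                       chrom_sizes = c(chr1 = 1e6, chr2 = 1e6, MT = 16000),
                       n_genes = 100L,
                       frag_mixture = data.frame(
                         mean = c(50, 180, 350),
                         sd = c(15, 25, 40),
                         weight = c(0.5, 0.35, 0.15)),
                       tss_peak_fraction = 0.55,
                       frag_fail_fraction = 0.1,
                       mt_fraction = 0.05,
                       n_core_peaks = 150L,
                       core_presence = 0.9,
                       peak_jitter = 20L,
                       n_sample_specific = 10L,
                       n_size_specific = 5L,
                       merge_gap = 10L,
                       nb_dispersion = 0.1,
                       effect_log2fc = 2.5,
                       effect_fraction = 0.1,
                       libsize_lsd = 0.3) {
  stopifnot(abs(sum(frag_mixture$weight) - 1) < 1e-8,
            all(frag_mixture$sd > 0),
            nb_dispersion > 0,
            tss_peak_fraction >= 0, tss_peak_fraction <= 1,
            effect_fraction >= 0, effect_fraction <= 1,
            n_samples >= 1, all(chrom_sizes > 0))
  structure(
    list(seed = as.integer(seed), timepoints = timepoints, sizes = sizes,
         n_samples = as.integer(n_samples), chrom_sizes = chrom_sizes,
         n_genes = as.integer(n_genes), frag_mixture = frag_mixture,
         tss_peak_fraction = tss_peak_fraction,
         frag_fail_fraction = frag_fail_fraction, mt_fraction = mt_fraction,
         n_core_peaks = as.integer(n_core_peaks),
         core_presence = core_presence,
         peak_jitter = as.integer(peak_jitter),
         n_sample_specific = as.integer(n_sample_specific),
         n_size_specific = as.integer(n_size_specific),
         merge_gap = as.integer(merge_gap),
         nb_dispersion = nb_dispersion, effect_log2fc = effect_log2fc,
         effect_fraction = effect_fraction, libsize_lsd = libsize_lsd),
    class = "sim_config")
}

#' Sample design table of the synthetic study
#'
#' With the default 24 samples, reproduces the unbalanced layout of the
#' emulated study: one complete litter at day 45 and day 60 (3 samples
#' each), four day-90 litters (12 samples), smallest + largest from one
#' litter at 1 week (2), and two partial litters at 6 weeks (4). Other
#' sample counts are allocated round-robin over timepoint x size cells.
#'
#' @param config a [sim_config()].
#' @return data frame `sample`, `timepoint`, `size`, `litter` (factors;
#'   `size` reference level is the first configured size class).
#' @export
make_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$timepoints; sz <- config$sizes
  if (config$n_samples == 24L && length(tp) == 5L && length(sz) == 3L) {
    cells <- rbind(
      data.frame(timepoint = tp[1], size = sz, litter = "L01"),
      data.frame(timepoint = tp[2], size = sz, litter = "L02"),
      do.call(rbind, lapply(1:4, function(k)
        data.frame(timepoint = tp[3], size = sz,
                   litter = sprintf("L%02d", 2 + k)))),
      data.frame(timepoint = tp[4], size = sz[c(1, 3)], litter = "L07"),
      data.frame(timepoint = tp[5], size = sz[c(1, 2)], litter = "L08"),
      data.frame(timepoint = tp[5], size = sz[c(1, 2)], litter = "L09")
    )
  } else {
    grid <- expand.grid(size = sz, timepoint = tp,
                        stringsAsFactors = FALSE)[, c(2, 1)]
    idx <- rep(seq_len(nrow(grid)), length.out = config$n_samples)
    cells <- data.frame(timepoint = grid$timepoint[idx],
                        size = grid$size[idx],
                        litter = sprintf("L%02d", ((seq_along(idx) - 1) %/%
                                                     length(sz)) + 1))
  }
  cells$sample <- sprintf("%s_%s_%s", cells$timepoint,
                          toupper(substr(cells$size, 1, 1)), cells$litter)
  cells$sample <- make.unique(cells$sample, sep = "_")
  data.frame(sample = cells$sample,
             timepoint = factor(cells$timepoint, levels = tp),
             size = factor(cells$size, levels = sz),
             litter = factor(cells$litter),
             stringsAsFactors = FALSE)
}

#' Generate a toy genome with non-overlapping gene models
#'
#' Places `n_genes` genes (uniform lengths 2-10 kb, random strand) on the
#' non-mitochondrial chromosomes with at least 200 bp between neighbours, so
#' genes never overlap by construction. Each gene gets 1-4 exons in
#' transcription order and 5'/3' UTRs carved from its outermost exons. An
#' explicit error is raised when the requested genes do not fit the genome.
#'
#' @param config a [sim_config()].
#' @return list of class `toy_genome`: `chrom_sizes` and `annotation` (a
#'   [gene_annotation()]).
#' @export
make_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    autos <- setdiff(names(config$chrom_sizes), "MT")
    sizes <- config$chrom_sizes[autos]
    n <- config$n_genes
    if (n == 0L) {
      ann <- gene_annotation(
        data.frame(gene_id = character(), chrom = character(),
                   strand = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE),
        data.frame(gene_id = character(), rank = integer(),
                   start = integer(), end = integer(), stringsAsFactors = FALSE))
      return(structure(list(chrom_sizes = config$chrom_sizes,
                            annotation = ann), class = "toy_genome"))
    }
    n_per <- as.vector(stats::setNames(
      table(sample(autos, n, replace = TRUE, prob = sizes / sum(sizes)))[autos],
      autos))
    n_per[is.na(n_per)] <- 0L
    genes <- list(); exons <- list(); u5 <- list(); u3 <- list()
    gid <- 0L
    min_gap <- 200
    for (ci in seq_along(autos)) {
      nc <- n_per[ci]
      if (nc == 0L) next
      L <- sizes[[ci]]
      len <- as.integer(round(stats::runif(nc, 2000, 10000)))
      free <- L - sum(len) - min_gap * (nc + 1)
      if (free < 0)
        stop(sprintf("cannot place %d genes on %s (%g bp): genome too small",
                     nc, autos[ci], L))
      gaps <- stats::runif(nc + 1)
      gaps <- gaps / sum(gaps) * free + min_gap
      starts <- as.integer(round(cumsum(gaps[seq_len(nc)]) +
                                         cumsum(c(0, len[-nc]))))
      for (k in seq_len(nc)) {
        gid <- gid + 1L
        id <- sprintf("gene%03d", gid)
        gs <- starts[k]; ge <- gs + len[k]
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample(1:4, 1L)
        # alternate exon/intron segments spanning the gene
        nseg <- 2L * n_ex - 1L
        w <- stats::runif(nseg, 0.5, 1.5)
        w <- w / sum(w) * len[k]
        bounds <- as.integer(round(gs + cumsum(c(0, w))))
        bounds[length(bounds)] <- ge
        ex_idx <- seq(1L, nseg, by = 2L)
        ex <- data.frame(gene_id = id,
                         start = bounds[ex_idx],
                         end = bounds[ex_idx + 1L],
                         stringsAsFactors = FALSE)
        ex <- ex[ex$end > ex$start, , drop = FALSE]
        ex$rank <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
        first <- ex[ex$rank == 1L, ]
        last <- ex[ex$rank == nrow(ex), ]
        ulen5 <- max(1, round(0.3 * (first$end - first$start)))
        ulen3 <- max(1, round(0.3 * (last$end - last$start)))
        u5[[length(u5) + 1L]] <- data.frame(
          gene_id = id,
          start = if (strand == "+") first$start else first$end - ulen5,
          end = if (strand == "+") first$start + ulen5 else first$end,
          stringsAsFactors = FALSE)
        u3[[length(u3) + 1L]] <- data.frame(
          gene_id = id,
          start = if (strand == "+") last$end - ulen3 else last$start,
          end = if (strand == "+") last$end else last$start + ulen3,
          stringsAsFactors = FALSE)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = id, chrom = autos[ci], strand = strand,
          start = gs, end = ge, stringsAsFactors = FALSE)
        exons[[length(exons) + 1L]] <-
          cbind(ex[, c("gene_id", "rank")],
                ex[, c("start", "end")], chrom = autos[ci])
      }
    }
    ann <- gene_annotation(do.call(rbind, genes),
                           do.call(rbind, exons)[, c("gene_id", "rank",
                                                     "start", "end")],
                           do.call(rbind, u5), do.call(rbind, u3))
    structure(list(chrom_sizes = config$chrom_sizes, annotation = ann),
              class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %s; %d genes\n",
              paste(sprintf("%s (%g bp)", names(x$chrom_sizes),
                            x$chrom_sizes), collapse = ", "),
              nrow(x$annotation$genes)))
  invisible(x)
}

# Draw n fragment lengths from the configured mixture.
draw_frag_lengths <- function(n, mix) {
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  len <- round(stats::rnorm(n, mix$mean[comp], mix$sd[comp]))
  pmax(len, 1L)
}

#' Generate per-sample ATAC fragment records
#'
#' Fragment lengths are drawn from the configured tri-modal mixture. A
#' `tss_peak_fraction` share of fragments is centered near a TSS (normal
#' spread, sd 300 bp, so coverage piles up within the +/- 1 kb flank);
#' `mt_fraction` lands on "MT"; the rest is uniform over the autosomes. A
#' `frag_fail_fraction` share is marked to fail the quality filter (low
#' mapping quality, duplicate or QC-fail flag); everything else carries the
#' proper-pair flag and high mapq.
#'
#' @param genome a [make_annotation()] result.
#' @param config a [sim_config()].
#' @param per_sample_depth fragments per sample (> 0).
#' @param samples sample names (default: the configured design's samples).
#' @return named list of fragment data frames (`chrom`, `start`, `end`,
#'   `mapq`, `flags`, `sample`).
#' @export
make_fragments <- function(genome, config, per_sample_depth = 20000L,
                           samples = NULL) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"),
            per_sample_depth > 0)
  if (is.null(samples)) samples <- make_design(config)$sample
  autos <- setdiff(names(genome$chrom_sizes), "MT")
  auto_sizes <- unlist(genome$chrom_sizes[autos])
  tss <- tss_table(genome$annotation)
  out <- setNames(vector("list", length(samples)), samples)
  for (si in seq_along(samples)) {
    out[[si]] <- with_seed(config$seed + 200L + si, {
      n <- as.integer(per_sample_depth)
      len <- draw_frag_lengths(n, config$frag_mixture)
      u <- stats::runif(n)
      on_mt <- u < config$mt_fraction
      near_tss <- !on_mt & nrow(tss) > 0 &
        u < config$mt_fraction + (1 - config$mt_fraction) * config$tss_peak_fraction
      chrom <- character(n); center <- numeric(n)
      n_mt <- sum(on_mt)
      if (n_mt) {
        chrom[on_mt] <- "MT"
        center[on_mt] <- stats::runif(n_mt, 0, genome$chrom_sizes[["MT"]])
      }
      n_tss <- sum(near_tss)
      if (n_tss) {
        pick <- sample.int(nrow(tss), n_tss, replace = TRUE)
        chrom[near_tss] <- tss$chrom[pick]
        center[near_tss] <- tss$pos[pick] + stats::rnorm(n_tss, 0, 450)
      }
      rest <- !on_mt & !near_tss
      n_rest <- sum(rest)
      if (n_rest) {
        ci <- sample(seq_along(autos), n_rest, replace = TRUE,
                     prob = auto_sizes / sum(auto_sizes))
        chrom[rest] <- autos[ci]
        center[rest] <- stats::runif(n_rest, 0, auto_sizes[ci])
      }
      limit <- unlist(genome$chrom_sizes)[chrom]
      start <- pmin(pmax(round(center - len / 2), 0), pmax(limit - len, 0))
      end <- pmin(start + len, limit)
      start <- pmin(start, end - 1)
      mapq <- rep(60L, n); flags <- rep(FLAG_PROPER_PAIR, n)
      fail <- stats::runif(n) < config$frag_fail_fraction
      n_fail <- sum(fail)
      if (n_fail) {
        mode <- sample.int(3L, n_fail, replace = TRUE)
        idx <- which(fail)
        mapq[idx[mode == 1L]] <- sample(0:9, sum(mode == 1L), replace = TRUE)
        flags[idx[mode == 2L]] <- bitwOr(FLAG_PROPER_PAIR, 1024L)  # duplicate
        flags[idx[mode == 3L]] <- bitwOr(FLAG_PROPER_PAIR, 512L)   # QC fail
      }
      data.frame(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), mapq = mapq, flags = flags,
                 sample = samples[si], stringsAsFactors = FALSE)
    })
  }
  out
}

# Place n intervals of the given widths on the autosomes, keeping at least
# min_sep bp away from every interval in `occupied` and from one another.
# Positions may be tied to TSSs (within 1 kb) for a configured fraction.
place_intervals <- function(n, widths, genome, config, occupied,
                            tss_fraction = 0) {
  autos <- setdiff(names(genome$chrom_sizes), "MT")
  auto_sizes <- unlist(genome$chrom_sizes[autos])
  tss <- tss_table(genome$annotation)
  min_sep <- config$merge_gap + 2L * config$peak_jitter + 2L
  res <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  occ <- occupied
  placed <- 0L; tries <- 0L
  while (placed < n && tries < n * 200L) {
    tries <- tries + 1L
    w <- widths[placed + 1L]
    if (nrow(tss) > 0 && stats::runif(1) < tss_fraction) {
      k <- sample.int(nrow(tss), 1L)
      ch <- tss$chrom[k]
      s <- round(tss$pos[k] + stats::runif(1, -1000, 1000 - w))
    } else {
      ci <- sample(seq_along(autos), 1L, prob = auto_sizes / sum(auto_sizes))
      ch <- autos[ci]
      s <- round(stats::runif(1, 0, auto_sizes[ci] - w))
    }
    s <- max(0L, as.integer(s))
    e <- s + as.integer(w)
    if (e > genome$chrom_sizes[[ch]]) next
    clash <- occ$chrom == ch & occ$start < e + min_sep & occ$end > s - min_sep
    if (any(clash)) next
    row <- data.frame(chrom = ch, start = s, end = e,
                      stringsAsFactors = FALSE)
    res <- rbind(res, row)
    occ <- rbind(occ, row)
    placed <- placed + 1L
  }
  if (placed < n)
    stop("could not place the requested peaks without collisions; ",
         "reduce peak counts or enlarge the genome")
  list(intervals = res, occupied = occ)
}

#' Generate per-sample peak calls with planted structure
#'
#' Builds a shared "core" peak set (a `tss_peak_fraction` share placed within
#' 1 kb of TSSs), present in each sample with probability `core_presence` and
#' with boundaries jittered by up to `peak_jitter` bp; adds `n_size_specific`
#' peaks present in every sample of exactly one size class, and
#' `n_sample_specific` peaks private to each sample. All planted peaks are
#' separated by more than `merge_gap + 2 * peak_jitter`, so
#' [merge_with_support()] recovers exactly the planted regions.
#'
#' @param genome a [make_annotation()] result.
#' @param config a [sim_config()].
#' @param design design table (default [make_design()]).
#' @return list with `peaks` (named list of per-sample data frames) and
#'   `truth` (`core`, `size_specific` per class, `sample_specific` per
#'   sample).
#' @export
make_peak_calls <- function(genome, config, design = NULL) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  if (is.null(design)) design <- make_design(config)
  with_seed(config$seed + 301L, {
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    pc <- place_intervals(config$n_core_peaks,
                          round(stats::runif(config$n_core_peaks, 150, 500)),
                          genome, config, empty,
                          tss_fraction = config$tss_peak_fraction)
    core <- pc$intervals; occ <- pc$occupied
    size_specific <- list()
    for (cl in config$sizes) {
      ps <- place_intervals(config$n_size_specific,
                            round(stats::runif(config$n_size_specific, 150, 400)),
                            genome, config, occ)
      size_specific[[cl]] <- ps$intervals; occ <- ps$occupied
    }
    sample_specific <- list()
    peaks <- setNames(vector("list", nrow(design)), design$sample)
    for (si in seq_len(nrow(design))) {
      s <- design$sample[si]
      keep <- stats::runif(nrow(core)) < config$core_presence
      p <- core[keep, , drop = FALSE]
      p <- rbind(p, size_specific[[as.character(design$size[si])]])
      if (config$n_sample_specific > 0) {
        ps <- place_intervals(config$n_sample_specific,
                              round(stats::runif(config$n_sample_specific,
                                                 150, 400)),
                              genome, config, occ)
        sample_specific[[s]] <- ps$intervals; occ <- ps$occupied
        p <- rbind(p, ps$intervals)
      }
      if (config$peak_jitter > 0) {
        j <- config$peak_jitter
        p$start <- pmax(0L, p$start +
                          sample(seq.int(-j, j), nrow(p), replace = TRUE))
        p$end <- p$end + sample(seq.int(-j, j), nrow(p), replace = TRUE)
        p$end <- pmax(p$end, p$start + 50L)
      }
      p$sample <- s
      p <- p[order(p$chrom, p$start), , drop = FALSE]
      rownames(p) <- NULL
      peaks[[si]] <- p
    }
    list(peaks = peaks,
         truth = list(core = core, size_specific = size_specific,
                      sample_specific = sample_specific))
  })
}

#' Generate a consensus-peak count matrix with planted time effects
#'
#' Counts are `NegativeBinomial(mean = libfactor_j * base_i * 2^effect,
#' dispersion = nb_dispersion)`: per-feature base means are log-normal,
#' per-sample library factors log-normal (log-sd `libsize_lsd`). A fraction
#' `effect_fraction` of features carries a true time effect: all samples of
#' one randomly chosen non-reference timepoint are shifted by
#' `+/- effect_log2fc` log2 units. Everything else is null with respect to
#' time.
#'
#' @param peaks consensus peak data frame whose rows name the features, or a
#'   single integer (number of features).
#' @param design design table ([make_design()]).
#' @param config a [sim_config()].
#' @return a [count_matrix()] with attribute `truth`: data frame `feature`,
#'   `affected`, `timepoint`, `log2fc`.
#' @export
make_count_matrix <- function(peaks, design, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$effect_log2fc != 0 && config$effect_fraction > 0 &&
      length(unique(design$timepoint)) < 2L)
    stop("planted time effects require at least two timepoints")
  nfeat <- if (is.numeric(peaks) && length(peaks) == 1L) as.integer(peaks)
           else nrow(peaks)
  feat_ids <- if (is.data.frame(peaks)) peak_id(peaks)
              else sprintf("peak%04d", seq_len(nfeat))
  with_seed(config$seed + 401L, {
    nsamp <- nrow(design)
    base <- stats::rlnorm(nfeat, log(80), 1)
    libf <- stats::rlnorm(nsamp, 0, config$libsize_lsd)
    n_aff <- round(config$effect_fraction * nfeat)
    affected <- sort(sample.int(nfeat, n_aff))
    tp_lvls <- levels(design$timepoint)
    tp_pick <- sample(tp_lvls[-1L], n_aff, replace = TRUE)
    sign <- sample(c(-1, 1), n_aff, replace = TRUE)
    lfc <- numeric(nfeat)
    shift <- matrix(0, nfeat, nsamp)
    for (k in seq_len(n_aff)) {
      cols <- design$timepoint == tp_pick[k]
      shift[affected[k], cols] <- sign[k] * config$effect_log2fc
      lfc[affected[k]] <- sign[k] * config$effect_log2fc
    }
    mu <- outer(base, libf) * 2^shift
    counts <- matrix(stats::rnbinom(nfeat * nsamp, mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nfeat, nsamp,
                     dimnames = list(feat_ids, design$sample))
    cm <- count_matrix(counts)
    attr(cm, "truth") <- data.frame(
      feature = feat_ids,
      affected = seq_len(nfeat) %in% affected,
      timepoint = {
        z <- rep(NA_character_, nfeat); z[affected] <- tp_pick; z
      },
      log2fc = lfc, stringsAsFactors = FALSE)
    cm
  })
}

#' Generate a transcript-level expression matrix with planted size effects
#'
#' Same count model as [make_count_matrix()], but the planted effects are
#' size-class effects (constant across timepoints): an affected gene is
#' shifted by `effect_log2fc` log2 units in the large class and by half that
#' in the average class, relative to small — the structure probed by the
#' day-90 differential-expression test.
#'
#' @param genome a [make_annotation()] result (features = its genes), or an
#'   integer number of transcripts.
#' @param design design table.
#' @param config a [sim_config()].
#' @return a [count_matrix()] with attribute `truth`: `feature`, `affected`,
#'   `log2fc_large_vs_small`, `log2fc_average_vs_small`.
#' @export
make_expression_matrix <- function(genome, design, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(genome, "toy_genome")) {
    feat_ids <- genome$annotation$genes$gene_id
  } else {
    feat_ids <- sprintf("gene%03d", seq_len(as.integer(genome)))
  }
  nfeat <- length(feat_ids)
  with_seed(config$seed + 501L, {
    nsamp <- nrow(design)
    base <- stats::rlnorm(nfeat, log(200), 1)
    libf <- stats::rlnorm(nsamp, 0, config$libsize_lsd)
    n_aff <- round(config$effect_fraction * nfeat)
    affected <- sort(sample.int(nfeat, n_aff))
    sign <- sample(c(-1, 1), n_aff, replace = TRUE)
    shift <- matrix(0, nfeat, nsamp)
    lfc_l <- numeric(nfeat); lfc_a <- numeric(nfeat)
    is_large <- design$size == "large"
    is_avg <- design$size == "average"
    for (k in seq_len(n_aff)) {
      b <- sign[k] * config$effect_log2fc
      shift[affected[k], is_large] <- b
      shift[affected[k], is_avg] <- b / 2
      lfc_l[affected[k]] <- b
      lfc_a[affected[k]] <- b / 2
    }
    mu <- outer(base, libf) * 2^shift
    counts <- matrix(stats::rnbinom(nfeat * nsamp, mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nfeat, nsamp,
                     dimnames = list(feat_ids, design$sample))
    cm <- count_matrix(counts)
    attr(cm, "truth") <- data.frame(
      feature = feat_ids,
      affected = seq_len(nfeat) %in% affected,
      log2fc_large_vs_small = lfc_l,
      log2fc_average_vs_small = lfc_a,
      stringsAsFactors = FALSE)
    cm
  })
}
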