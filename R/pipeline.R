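# End-to-end orchestration: one config drives simulate/ingest -> consensus ->
# QC -> ordination -> differential -> annotation -> overlay, with stage logs
# and a checksummed output manifest.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed forwarded to the simulation config.
#' @param merge_gap consensus merge distance in bp.
#' @param min_support minimum consensus support kept.
#' @param fdr FDR threshold for both differential tests.
#' @param lfc_min |log2FC| threshold for differential peaks.
#' @param overlay_window peak-to-gene vicinity window in bp.
#' @param per_sample_depth simulated fragments per sample.
#' @param sim extra arguments forwarded to [sim_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("peakforge_run"), seed = 1L,
                       merge_gap = 10, min_support = 3, fdr = 0.10,
                       lfc_min = 2.0, overlay_window = 10000,
                       per_sample_depth = 20000L, sim = list()) {
  stopifnot(merge_gap >= 0, min_support >= 1, fdr > 0, overlay_window > 0,
            per_sample_depth > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 merge_gap = merge_gap, min_support = min_support,
                 fdr = fdr, lfc_min = lfc_min,
                 overlay_window = overlay_window,
                 per_sample_depth = as.integer(per_sample_depth), sim = sim),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys map to [run_config()] arguments; a nested `sim:` block maps
#' to [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "sim")
  args <- y[intersect(names(y), known)]
  args$sim <- if (is.null(y$sim)) list() else y$sim
  do.call(run_config, args)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates the study inputs at the configured seed, then runs every
#' analysis stage: consensus peak construction and support filtering,
#' per-sample QC, fragment counting, normalization, NMDS ordination,
#' time-course differential peaks, day-90 differential expression,
#' size-class separation of the day-90 peak sets, feature annotation and the
#' signed-distance overlay. Every artifact is written under
#' `config$out_dir` as plain text, and a manifest (file, bytes, md5) plus
#' per-stage survivor counts are returned. Identical configs (including
#' seed) produce identical manifests.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage logging (default FALSE; logs go to stderr).
#' @return invisibly, list of class `peakforge_run` with `manifest`
#'   (data frame), `stage_counts` (named vector) and the in-memory stage
#'   results.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  outfile <- function(name) file.path(config$out_dir, name)
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))

  say("stage 1/8: simulating inputs (seed %d)", config$seed)
  genome <- make_annotation(scfg)
  design <- make_design(scfg)
  frags <- make_fragments(genome, scfg, config$per_sample_depth,
                          samples = design$sample)
  calls <- make_peak_calls(genome, scfg, design)
  write_annotation_gtf(genome$annotation, outfile("annotation.gtf"))
  write.table(design, outfile("design.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  say("stage 2/8: consensus peaks (gap %g, min support %g)",
      config$merge_gap, config$min_support)
  all_calls <- do.call(rbind, calls$peaks)
  consensus <- merge_with_support(all_calls, merge_gap = config$merge_gap)
  kept <- filter_support(consensus, min_support = config$min_support)
  write_consensus(kept, outfile("consensus.bed"))
  say("  %d input peaks -> %d consensus -> %d support-filtered",
      nrow(all_calls), nrow(consensus), nrow(kept))

  say("stage 3/8: per-sample QC")
  qc <- qc_report(frags, kept, tss_table(genome$annotation),
                  genome$chrom_sizes)
  write.table(qc, outfile("qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  qcj <- qc
  qcj$pbc2[!is.finite(qcj$pbc2)] <- NA  # JSON has no Inf
  writeLines(jsonlite::toJSON(qcj, dataframe = "rows", pretty = TRUE,
                              na = "null"),
             outfile("qc.json"))

  say("stage 4/8: fragment counting over %d consensus peaks", nrow(kept))
  filt <- lapply(frags, filter_fragments)
  cm <- if (nrow(kept)) count_fragments(kept, filt) else NULL
  if (!is.null(cm))
    write.table(cm$counts, outfile("counts.tsv"), sep = "\t", quote = FALSE)

  say("stage 5/8: normalization + NMDS ordination")
  ord <- NULL
  if (!is.null(cm) && nrow(cm$counts) >= 3L) {
    norm <- normalize_counts(cm)
    ord <- nmds(manhattan_distance(norm), k = 3, seed = config$seed)
    write.table(ord$points, outfile("nmds.tsv"), sep = "\t", quote = FALSE)
  }

  say("stage 6/8: differential peaks (~ size + time vs ~ size)")
  dp <- NULL
  if (!is.null(cm) && nrow(cm$counts) >= 2L) {
    dp <- diff_peaks(cm, design, fdr = config$fdr, lfc_min = config$lfc_min)
    write.table(as.data.frame(dp), outfile("diff_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("  %d/%d peaks significant (FDR < %g, |log2FC| > %g)",
        sum(dp$significant, na.rm = TRUE), nrow(dp), config$fdr,
        config$lfc_min)
  }

  say("stage 7/8: day-90 expression and differential genes")
  expr <- make_expression_matrix(genome, design, scfg)
  write.table(expr$counts, outfile("expression.tsv"), sep = "\t",
              quote = FALSE)
  dg <- diff_genes_day90(expr, design, timepoint = levels(design$timepoint)[3],
                         fdr = config$fdr)
  write.table(as.data.frame(dg), outfile("diff_genes_day90.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  say("stage 8/8: size-class separation + annotation + overlay")
  d90 <- design$timepoint == levels(design$timepoint)[3]
  by_class <- lapply(split(design$sample[d90], design$size[d90]),
                     function(s) {
                       m <- merge_with_support(
                         do.call(rbind, calls$peaks[s]),
                         merge_gap = config$merge_gap)
                       m[, c("chrom", "start", "end")]
                     })
  split_sets <- separate_size_specific(by_class)
  ann_calls <- if (nrow(kept))
    classify_peaks(kept, genome$annotation) else NULL
  if (!is.null(ann_calls)) {
    write.table(ann_calls, outfile("feature_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summarize_features(ann_calls), outfile("feature_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  overlay_sets <- c(list(shared = split_sets$shared),
                    setNames(split_sets$specific,
                             paste0(names(split_sets$specific), "_only")))
  ov <- overlay_table(genome$annotation$genes, overlay_sets, dg,
                      window = config$overlay_window)
  write.table(ov, outfile("overlay.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- data.frame(
    file = basename(files),
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  write.table(manifest, outfile("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_counts <- c(
    input_peaks = nrow(all_calls), consensus = nrow(consensus),
    support_filtered = nrow(kept),
    tested = if (is.null(dp)) 0L else sum(!is.na(dp$pvalue)),
    significant_peaks = if (is.null(dp)) 0L else
      sum(dp$significant, na.rm = TRUE),
    significant_genes = sum(dg$significant, na.rm = TRUE),
    overlay_records = nrow(ov)
  )
  invisible(structure(
    list(manifest = manifest, stage_counts = stage_counts,
         consensus = kept, qc = qc, counts = cm, nmds = ord,
         diff_peaks = dp, diff_genes = dg, overlay = ov,
         size_split = split_sets, design = design),
    class = "peakforge_run"))
}

#' @export
print.peakforge_run <- function(x, ...) {
  cat("peakforge pipeline run\n")
  cat("stage counts:\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-18s %d\n", nm, x$stage_counts[[nm]]))
  cat(sprintf("%d artifacts in manifest\n", nrow(x$manifest)))
  invisible(x)
}
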