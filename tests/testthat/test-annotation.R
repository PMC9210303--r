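# Feature classification, category summaries, signed distances and the
# peak-to-gene overlay.

# A hand-built two-gene annotation used throughout:
# gene up: chr1 +, [10000, 20000), exon1 [10000,10300), exon2 [14000,15000),
#          exon3 [19000,20000); UTR5 [10000,10100), UTR3 [19900,20000)
# gene dn: chr2 -, [40000, 50000), single exon
# gene lu: chr1 +, [70000, 80000), with a long (3.5 kb) 5' UTR so a UTR hit
#          can outrank the promoter windows by distance
toy_ann <- function() {
  genes <- data.frame(
    gene_id = c("gUP", "gDN", "gLU"), chrom = c("chr1", "chr2", "chr1"),
    strand = c("+", "-", "+"), start = c(10000L, 40000L, 70000L),
    end = c(20000L, 50000L, 80000L))
  exons <- data.frame(
    gene_id = c("gUP", "gUP", "gUP", "gDN", "gLU", "gLU"),
    rank = c(1L, 2L, 3L, 1L, 1L, 2L),
    start = c(10000L, 14000L, 19000L, 40000L, 70000L, 79000L),
    end = c(10300L, 15000L, 20000L, 50000L, 74000L, 80000L))
  utr5 <- data.frame(gene_id = c("gUP", "gDN", "gLU"),
                     start = c(10000L, 49900L, 70000L),
                     end = c(10100L, 50000L, 73500L))
  utr3 <- data.frame(gene_id = c("gUP", "gDN", "gLU"),
                     start = c(19900L, 40000L, 79900L),
                     end = c(20000L, 40100L, 80000L))
  gene_annotation(genes, exons, utr5, utr3)
}

pk <- function(chrom, start, end)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end))

test_that("peak classification follows the promoter/genic precedence rules", {
  ann <- toy_ann()
  cls <- function(s, e, chrom = "chr1")
    as.character(classify_peaks(pk(chrom, s, e), ann)$category)
  # midpoint 500 bp upstream of the + strand TSS
  expect_equal(cls(9400, 9600), "Promoter (<=1kb)")
  # midpoint 1.5 kb / 2.5 kb away
  expect_equal(cls(8400, 8600), "Promoter (1-2kb)")
  expect_equal(cls(7400, 7600), "Promoter (2-3kb)")
  # inside the 1st intron, 3.5 kb from the TSS: intron wins over nothing else
  expect_equal(cls(13400, 13600), "1st intron")
  # intron between exon 2 and 3 (midpoint 17 kb)
  expect_equal(cls(16900, 17100), "Other intron")
  # exon hits: rank-2 exon midpoint
  expect_equal(cls(14400, 14600), "Other exon")
  # UTR3 beats exon (midpoint 19950 inside utr3 and exon3)
  expect_equal(cls(19900, 20000), "3' UTR")
  # downstream <= 3 kb past the 3' end
  expect_equal(cls(21950, 22050), "Downstream (<=3kb)")
  # far from any gene
  expect_equal(cls(99900, 100100), "Distal intergenic")
  # minus-strand gene: promoter upstream means coordinates above gene end
  expect_equal(cls(50400, 50600, "chr2"), "Promoter (<=1kb)")
  # a midpoint in a long 5' UTR beyond the promoter windows is a UTR call
  expect_equal(cls(73200, 73400), "5' UTR")
  # promoter distance outranks the UTR when the midpoint is within 1 kb of
  # the TSS
  expect_equal(cls(70400, 70600), "Promoter (<=1kb)")
  # unknown chromosome: distal intergenic with a warning
  expect_warning(out <- classify_peaks(pk("chrUn", 100, 200), ann), "absent")
  expect_equal(as.character(out$category), "Distal intergenic")
})

test_that("every peak gets exactly one category and percents sum to 100", {
  cfg <- sim_config(seed = 23)
  g <- make_annotation(cfg)
  calls <- make_peak_calls(g, cfg, make_design(cfg))
  cons <- filter_support(merge_with_support(do.call(rbind, calls$peaks)), 3)
  fc <- classify_peaks(cons, g$annotation)
  expect_equal(nrow(fc), nrow(cons))
  expect_false(any(is.na(fc$category)))
  sm <- summarize_features(fc)
  expect_equal(sum(sm$count), nrow(cons))
  expect_true(abs(sum(sm$percent) - 100) <= 0.1)
  # with TSS-proximal placement, most peaks should be promoter-proximal
  expect_gt(sm$percent[sm$category == "Promoter (<=1kb)"], 40)
})

test_that("category summaries reproduce printed frequencies from counts", {
  counts <- c(Intronic = 185, Intergenic = 109, Promoter = 42, `3' UTR` = 12,
              Proximal = 10, `5' UTR` = 8, CDS = 8, Exonic = 3)
  sm <- summarize_features(counts)
  expect_equal(sm$percent[sm$category == "Promoter"], 11.1)
  expect_equal(sm$percent[sm$category == "Intronic"], 49.1)
  expect_equal(sm$percent[sm$category == "Intergenic"], 28.9)
  expect_equal(sm$percent[sm$category == "3' UTR"], 3.18)
  # single category -> 100%
  expect_equal(summarize_features(c(Promoter = 7))$percent, 100)
  # a label vector works the same way
  labs <- rep(names(counts), counts)
  expect_equal(sort(summarize_features(labs)$percent), sort(sm$percent))
})

test_that("broad-category collapse maps the detailed system sensibly", {
  ann <- toy_ann()
  fc <- classify_peaks(rbind(pk("chr1", 9400, 9600),    # promoter <=1kb
                             pk("chr1", 13400, 13600),  # 1st intron
                             pk("chr1", 16900, 17100),  # other intron
                             pk("chr1", 99900, 100100), # distal
                             pk("chr1", 15000 + 0, 15100)), ann)
  broad <- collapse_to_broad(fc)
  expect_equal(broad[1], "Promoter")
  expect_equal(broad[2], "Intronic")
  expect_equal(broad[3], "Intronic")
  expect_equal(broad[4], "Intergenic")
})

test_that("signed start distance follows the upstream-positive convention", {
  gplus <- data.frame(chrom = "chr1", strand = "+", start = 10000L,
                      end = 20000L)
  # peak 2 kb upstream -> positive, magnitude 2000
  expect_equal(signed_start_distance(gplus, pk("chr1", 8000, 8400)), 2000)
  # peak inside the gene -> positive
  expect_equal(signed_start_distance(gplus, pk("chr1", 12000, 12400)), 2000)
  # peak past the 3' end within 10 kb -> negative
  expect_equal(signed_start_distance(gplus, pk("chr1", 22000, 22400)), -12000)
  # 11 kb upstream -> outside the window
  gfar <- data.frame(chrom = "chr1", strand = "+", start = 30000L,
                     end = 40000L)
  expect_true(is.na(signed_start_distance(gfar, pk("chr1", 18500, 18900))))
  # exactly 10 kb upstream is still inside
  expect_equal(signed_start_distance(gfar, pk("chr1", 20000, 20400)), 10000)
  # other chromosome -> NA
  expect_true(is.na(signed_start_distance(gplus, pk("chr2", 8000, 8400))))
})

test_that("signed start distance is strand-mirror symmetric", {
  L <- 100000L
  gplus <- data.frame(chrom = "chr1", strand = "+", start = 10000L,
                      end = 20000L)
  gminus <- data.frame(chrom = "chr1", strand = "-", start = L - 20000L,
                       end = L - 10000L)
  set.seed(31)
  for (rep in 1:50) {
    s <- sample(0:35000, 1)
    w <- sample.int(500L, 1) + 50L
    d_plus <- signed_start_distance(gplus, pk("chr1", s, s + w))
    d_minus <- signed_start_distance(gminus, pk("chr1", L - s - w, L - s))
    expect_equal(d_plus, d_minus)
  }
})

test_that("overlay links size-specific peaks to DE genes within the window", {
  # planted: small-only peak 8769 bp upstream of a down-regulated gene
  gene <- data.frame(gene_id = "gMYO", chrom = "chr1", strand = "+",
                     start = 50000L, end = 60000L)
  peak <- pk("chr1", 50000 - 8769 - 315, 50000 - 8769)  # 315 bp wide
  ov <- overlay_table(gene, list(small_only = peak), de_genes = "gMYO")
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$start_dist, 8769 + 315)
  expect_gt(ov$start_dist, 0)
  expect_equal(ov$peak_width, 315L)
  expect_equal(ov$specificity, "small_only")
  expect_true(ov$de_status)
  # no peaks within 10 kb -> gene absent
  far <- pk("chr1", 200000, 200400)
  expect_equal(nrow(overlay_table(gene, list(small_only = far), "gMYO")), 0L)
})

test_that("overlay equals a brute-force all-pairs window scan and ignores order", {
  cfg <- sim_config(seed = 37, n_genes = 30L)
  g <- make_annotation(cfg)
  genes <- g$annotation$genes
  set.seed(2)
  peaks <- random_peaks(80, chroms = c("chr1", "chr2"),
                        max_pos = 900000)[, c("chrom", "start", "end")]
  ov <- overlay_table(genes, list(anyset = peaks), de_genes = character(0))
  # brute force over all (gene, peak) pairs
  expected <- 0L
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(peaks))) {
    gn <- genes[i, ]
    tssp <- if (gn$strand == "+") gn$start else gn$end
    raw <- if (gn$strand == "+") peaks$start[j] - tssp else tssp - peaks$end[j]
    if (peaks$chrom[j] == gn$chrom && raw >= -10000 &&
        raw <= (gn$end - gn$start) + 10000)
      expected <- expected + 1L
  }
  expect_equal(nrow(ov), expected)
  # permuting the peak rows leaves the table unchanged
  ov2 <- overlay_table(genes, list(anyset = peaks[sample(nrow(peaks)), ]),
                       de_genes = character(0))
  expect_equal(ov, ov2)
})

test_that("GTF serialization round-trips the annotation", {
  cfg <- sim_config(seed = 41, n_genes = 20L)
  ann <- make_annotation(cfg)$annotation
  tf <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann, tf)
  back <- read_annotation_gtf(tf)
  ord <- function(df) { df <- df[order(df$gene_id, df$start), ]
                        rownames(df) <- NULL; df }
  expect_equal(ord(back$genes), ord(ann$genes))
  expect_equal(ord(back$exons)[, c("gene_id", "start", "end", "rank")],
               ord(ann$exons)[, c("gene_id", "start", "end", "rank")])
  expect_equal(ord(back$utr5), ord(ann$utr5))
  expect_equal(ord(back$utr3), ord(ann$utr3))
})
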