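test_that("peak sets rank by score with positional tie-break and validate", {
  ps <- peak_set(chrom = c("chr2", "chr1", "chr1"),
                 start = c(100, 500, 50), end = c(200, 600, 150),
                 score = c(9, 7, 7))
  expect_identical(ps$rank, c(1L, 3L, 2L))  # ties by chrom then start
  expect_error(peak_set("chr1", 100, 100), "start >= end")
  expect_error(peak_set("chr1", 100, 200, score = -1), "non-negative")
})

test_that("BED peaks round-trip and malformed lines name their line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t110\tp1\t50", "chr2\t500\t700\tp2\t80"), path)
  ps <- read_peaks(path)
  expect_equal(nrow(ps), 2)
  expect_equal(ps$start, c(10, 500))
  expect_identical(ps$rank, c(2L, 1L))
  writeLines(c("chr1\t10\t110\tp1\t50", "chr1\t300\t300"), path)
  expect_error(read_peaks(path), "line 2.*start >= end")
  writeLines("chr1\t10", path)
  expect_error(read_peaks(path), "fewer than 3 fields")
  # 3-column BED gets uniform scores and positional ranks
  writeLines(c("chr1\t10\t110", "chr1\t200\t300"), path)
  expect_identical(read_peaks(path)$rank, c(1L, 2L))
})

test_that("peaks annotate to the nearest TSS within the window", {
  genes <- gene_models(
    gene = c("NEAR", "FAR", "OTHER"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "+", "-"),
    span_start = c(60000, 100000, 5000),
    span_end = c(62000, 102000, 40001))
  # peak midpoint 50,000: 10 kb from NEAR's TSS, 50 kb from FAR's
  pk <- peak_set("chr1", 49850, 50150, 10)
  ann <- annotate_peaks(pk, genes)$annotations
  expect_identical(ann$gene, "NEAR")
  expect_equal(ann$distance, -10000)  # upstream of a + strand TSS
  # beyond the window: unassigned
  pk2 <- peak_set("chr1", 249850, 250150, 10)
  expect_true(is.na(annotate_peaks(pk2, genes)$annotations$gene))
  # minus-strand orientation: peak left of a - strand TSS is downstream
  pk3 <- peak_set("chr2", 29850, 30150, 10)
  ann3 <- annotate_peaks(pk3, genes)$annotations
  expect_identical(ann3$gene, "OTHER")
  expect_equal(ann3$distance, 40000 - 30000)  # TSS at 40000, oriented
  # equidistant TSSs break ties lexically
  tie <- gene_models(c("BBB", "AAA"), c("chr1", "chr1"), c("+", "+"),
                     c(40000, 60000), c(42000, 62000))
  ann4 <- annotate_peaks(peak_set("chr1", 49850, 50150, 1), tie)$annotations
  expect_identical(ann4$gene, "AAA")
})

test_that("annotation equals a brute-force search and shrinks with the window", {
  for (seed in 1:4) {
    set.seed(seed)
    ng <- sample(5:20, 1); np <- sample(5:20, 1)
    genes <- gene_models(
      gene = sprintf("g%02d", seq_len(ng)),
      chrom = sample(c("c1", "c2"), ng, replace = TRUE),
      strand = sample(c("+", "-"), ng, replace = TRUE),
      span_start = (st <- sort(sample(1000:300000, ng))),
      span_end = st + 2000)
    mid <- sample(1000:300000, np)
    peaks <- peak_set(sample(c("c1", "c2"), np, replace = TRUE),
                      mid - 100, mid + 100, runif(np, 0, 100))
    res <- annotate_peaks(peaks, genes, window = 50000)$annotations
    ref <- floor((peaks$start + peaks$end) / 2)
    for (i in seq_len(np)) {
      d <- abs(ref[i] - genes$tss)
      d[genes$chrom != peaks$chrom[i] | d > 50000] <- NA
      if (all(is.na(d))) {
        expect_true(is.na(res$gene[i]))
      } else {
        best <- which(d == min(d, na.rm = TRUE))
        expect_identical(res$gene[i], sort(genes$gene[best])[1])
        expect_lte(abs(res$distance[i]), 50000)
      }
    }
    # shrinking the window never assigns more peaks
    n_small <- sum(!is.na(
      annotate_peaks(peaks, genes, window = 10000)$annotations$gene))
    expect_lte(n_small, sum(!is.na(res$gene)))
  }
})

test_that("gene -> best peak rank keeps the strongest associated peak", {
  genes <- gene_models("TGT", "chr1", "+", 50000, 52000)
  pk <- peak_set(rep("chr1", 3), c(48000, 51000, 60000),
                 c(48300, 51300, 60300), score = c(10, 90, 50))
  gpr <- annotate_peaks(pk, genes)$gene_peak_rank
  expect_identical(gpr$gene, "TGT")
  expect_identical(gpr$peak_rank, 1L)  # the score-90 peak
})

test_that("TSS distance histogram uses half-open bins summing to assigned peaks", {
  ann <- data.frame(peak_id = paste0("p", 1:4), chrom = "c",
                    rank = 1:4, gene = c("a", "b", "c", NA),
                    distance = c(-500, 500, 1500, NA))
  h <- tss_distance_profile(ann, 1000)
  expect_equal(h$count, c(1L, 1L, 1L))
  expect_equal(h$bin_start, c(-1000, 0, 1000))
  expect_equal(sum(h$count), sum(!is.na(ann$gene)))
  expect_error(tss_distance_profile(ann, 0), "positive")
  empty <- ann[is.na(ann$gene), ]
  expect_equal(nrow(tss_distance_profile(empty, 1000)), 0)
  # random tallies equal a brute-force count
  set.seed(3)
  d <- round(rnorm(50, 0, 3000))
  ann2 <- data.frame(peak_id = paste0("p", 1:50), chrom = "c", rank = 1:50,
                     gene = "g", distance = d)
  h2 <- tss_distance_profile(ann2, 500)
  for (k in seq_len(nrow(h2))) {
    expect_equal(h2$count[k],
                 sum(d >= h2$bin_start[k] & d < h2$bin_end[k]))
  }
})

test_that("peak windows are centered, clipped, uppercased substrings", {
  genome <- Biostrings::DNAStringSet(c(
    tiny = paste(rep("acgt", 25), collapse = ""),                # 100 bp
    big = paste(rep("ACGTACGTTG", 60), collapse = "")))          # 600 bp
  genes <- gene_models(c("g1", "g2"), c("tiny", "big"), c("+", "+"),
                       c(10, 100), c(50, 400))
  pk <- peak_set(c("tiny", "big", "big"), c(0, 250, 290),
                 c(100, 350, 390), score = c(5, 9, 7))
  ann <- annotate_peaks(pk, genes, window = 1e5)
  win <- extract_peak_windows(pk, ann$annotations, genome, width = 100)
  expect_equal(length(win), 3)
  # clipped at the contig end: the 100-bp contig comes back whole, uppercased
  expect_identical(as.character(win[["tiny:0-100"]]),
                   toupper(paste(rep("acgt", 25), collapse = "")))
  # interior window equals a direct substring oracle (midpoint 300, 100 bp)
  big <- paste(rep("ACGTACGTTG", 60), collapse = "")
  expect_identical(as.character(win[["big:250-350"]]),
                   substr(big, 300 - 50 + 1, 300 + 50))
  # top limits how many windows come back, by rank
  win1 <- extract_peak_windows(pk, ann$annotations, genome, width = 100,
                               top = 1)
  expect_identical(names(win1), "big:250-350")  # rank 1 (score 9)
  expect_error(
    extract_peak_windows(peak_set("missing", 1, 50, 1),
                         data.frame(peak_id = "missing:1-50", chrom = "missing",
                                    rank = 1, gene = "g", distance = 0),
                         genome),
    "missing")
})

test_that("IUPAC motif scanning honors degeneracy, strand and overlap", {
  hits <- scan_motif(c(s1 = "AACACTCAA"), "CACTY", both_strands = TRUE)
  expect_equal(nrow(hits$hits), 1)
  expect_equal(hits$hits$offset, 2)
  expect_identical(hits$hits$strand, "+")
  expect_identical(hits$hits$matched, "CACTC")
  expect_equal(unname(hits$counts["s1"]), 1L)

  expect_equal(nrow(scan_motif(c(a = "GGGGG"), "CACTY")$hits), 0)

  # reverse complement of CACTC reported on the minus strand at plus offset
  rc <- scan_motif(c(a = "GAGTG"), "CACTY", both_strands = TRUE)
  expect_equal(nrow(rc$hits), 1)
  expect_identical(rc$hits$strand, "-")
  expect_equal(rc$hits$offset, 0)
  expect_false(nrow(scan_motif(c(a = "GAGTG"), "CACTY",
                               both_strands = FALSE)$hits) > 0)

  # overlapping matches are all reported
  ov <- scan_motif(c(a = "CACTCACTC"), "CACTY", both_strands = FALSE)
  expect_equal(ov$hits$offset, c(0, 4))

  expect_error(scan_motif(c(a = "ACGT"), "CACTZ"), "invalid IUPAC")

  # scanning the reverse complement swaps strands but preserves hit counts
  set.seed(7)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
    rcs <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    h1 <- scan_motif(c(x = s), "CHCTY")$hits
    h2 <- scan_motif(c(x = rcs), "CHCTY")$hits
    expect_equal(nrow(h1), nrow(h2))
    expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
  }
})

test_that("shuffle enrichment separates motif-rich windows from background", {
  # absent pattern: fold 0, p at the resolution ceiling
  none <- motif_enrichment(c(a = "GGGGGGGG", b = "GGGGAGGG"), "CACTY",
                           n_shuffles = 20, seed = 1)
  expect_equal(none$fold, 0)
  expect_equal(none$p_value, 1)
  # motif-dense sequences beat their composition-preserving shuffles
  dense <- motif_enrichment(
    setNames(rep(paste(rep("CACTC", 6), collapse = ""), 5),
             paste0("x", 1:5)),
    "CACTY", n_shuffles = 50, seed = 2)
  expect_gt(dense$fold, 1)
  expect_lt(dense$p_value, 0.05)
  expect_gte(dense$p_value, 1 / 51)  # add-one floor
  expect_error(motif_enrichment(character(), "CACTY", 10, 1), "empty")
  expect_error(motif_enrichment(c(a = "ACGT"), "CACTY", 0, 1), ">= 1")
})
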