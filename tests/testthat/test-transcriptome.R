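test_that("expression tables validate input and round-trip through TSV", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(tab, path)
  back <- read_expression(path, cell_line = "L1")
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_identical(attr(back, "cell_line"), "L1")

  expect_error(expression_table(c("EGFR", "EGFR"), c(1, 2), c(1, 2)),
               "duplicate.*EGFR")
  expect_error(expression_table("A", -1, 2), "negative abundance")
  expect_error(expression_table("A", NaN, 2), "non-finite")

  writeLines(c("gene\tknockdown\tcontrol", "EGFR\t1\t2", "EGFR\t3\t4"), path)
  expect_error(read_expression(path), "duplicate")
  writeLines(c("gene\tkd\tcontrol", "EGFR\t1\t2"), path)
  expect_error(read_expression(path), "missing required column 'knockdown'")
  writeLines(c("gene\tknockdown\tcontrol", "EGFR\tx\t2"), path)
  expect_error(read_expression(path), "non-numeric")
})

test_that("well_measured applies the inclusive abundance filter to both conditions", {
  tab <- toy_table()
  # hand enumeration: A (2,2) kept; B (0.9,5) out; C (1,3) boundary kept;
  # D (5,0.2) out; E (7,7) kept
  expect_identical(well_measured(tab), c("A", "C", "E"))
  expect_true("C" %in% well_measured(tab))          # kd exactly at 1
  expect_false("B" %in% well_measured(tab, 1))      # fails one condition
  expect_identical(well_measured(tab, 0), tab$gene) # zero floor keeps all
})

test_that("response calls follow the inclusive 25% ratio thresholds", {
  tab <- expression_table(
    gene = c("EGFR", "FLAT", "EDGE_DN", "EDGE_UP", "LOW"),
    knockdown = c(0.349 * 10, 5, 7.5, 12.5, 0.5),
    control = c(10, 5, 10, 10, 10))
  resp <- compute_response(tab)
  calls <- setNames(resp$call, resp$gene)
  expect_identical(calls[["EGFR"]], "down")      # ratio 0.349
  expect_identical(calls[["FLAT"]], "unchanged") # ratio 1.0
  expect_identical(calls[["EDGE_DN"]], "down")   # exactly 0.75
  expect_identical(calls[["EDGE_UP"]], "up")     # exactly 1.25
  expect_identical(calls[["LOW"]], "not_measured")
  expect_equal(resp$ratio[resp$gene == "EGFR"], 0.349)

  # rank_down: ascending ratio, ties by gene id, present iff call == down
  expect_equal(resp$rank_down[resp$gene == "EGFR"], 1L)
  expect_equal(resp$rank_down[resp$gene == "EDGE_DN"], 2L)
  expect_true(all(is.na(resp$rank_down[resp$call != "down"])))

  # ctrl = 0 with a zero filter floor falls back to not_measured
  tab0 <- expression_table(c("Z", "Y"), c(2, 2), c(0, 2))
  r0 <- compute_response(tab0, min_abundance = 0)
  expect_identical(r0$call[r0$gene == "Z"], "not_measured")
})

test_that("calls partition the gene universe and are monotone in threshold", {
  for (seed in 1:5) {
    tab <- random_table(seed, n = 40)
    r <- compute_response(tab)
    expect_identical(sort(r$gene), sort(tab$gene))
    expect_true(all(r$call %in% c("down", "up", "unchanged", "not_measured")))
    # lowering the threshold never shrinks the down or up sets
    r_loose <- compute_response(tab, threshold = 0.10)
    expect_true(all(r$gene[r$call == "down"] %in%
                      r_loose$gene[r_loose$call == "down"]))
    expect_true(all(r$gene[r$call == "up"] %in%
                      r_loose$gene[r_loose$call == "up"]))
  }
})

test_that("response classification matches a naive per-row oracle", {
  for (seed in 11:14) {
    tab <- random_table(seed, n = 50)
    r <- compute_response(tab, min_abundance = 1, threshold = 0.25)
    for (i in seq_len(nrow(tab))) {
      kd <- tab$knockdown[i]; ct <- tab$control[i]
      expected <- if (kd < 1 || ct < 1) "not_measured"
        else if (kd / ct <= 0.75) "down"
        else if (kd / ct >= 1.25) "up"
        else "unchanged"
      expect_identical(r$call[r$gene == tab$gene[i]], expected)
    }
  }
})

test_that("consistent_genes intersects calls across lines", {
  mk <- function(down) data.frame(
    gene = down, ratio = rep(0.5, length(down)),
    call = rep("down", length(down)), rank_down = seq_along(down),
    stringsAsFactors = FALSE)
  resp <- list(L1 = mk(c("A", "B", "C")), L2 = mk(c("B", "C")),
               L3 = mk(c("C", "D")))
  cs <- consistent_genes(resp, "down", min_lines = 2)
  expect_identical(cs$genes, c("B", "C"))
  expect_identical(rownames(cs$membership), c("A", "B", "C", "D"))
  expect_identical(unname(cs$membership["B", ]), c(TRUE, TRUE, FALSE))

  expect_identical(consistent_genes(resp, "down", min_lines = 3)$genes, "C")
  # anti-monotone in min_lines
  for (k in 1:2) {
    expect_true(all(consistent_genes(resp, "down", k + 1)$genes %in%
                      consistent_genes(resp, "down", k)$genes))
  }
  expect_error(consistent_genes(resp, "down", min_lines = 4), "exceeds")
  # a line with an empty down list empties the full intersection
  resp$L4 <- mk(character())
  expect_length(consistent_genes(resp, "down", min_lines = 4)$genes, 0)
})

test_that("top_genes ranks by response strength with lexical tie-break", {
  r <- data.frame(gene = c("A", "C", "B", "D"),
                  ratio = c(0.3, 0.5, 0.5, 0.7),
                  call = c("down", "down", "down", "down"),
                  rank_down = NA, stringsAsFactors = FALSE)
  expect_identical(top_genes(r, n = 2, "down"), c("A", "B"))
  expect_identical(top_genes(r, n = 100, "down"), c("A", "B", "C", "D"))
  r_up <- data.frame(gene = c("X", "Y"), ratio = c(1.5, 2),
                     call = "up", rank_down = NA, stringsAsFactors = FALSE)
  expect_identical(top_genes(r_up, n = 1, "up"), "Y")
})

test_that("cross-line correlation recovers exact profiles and hand-computed r", {
  mk <- function(genes, ratios, line) {
    data.frame(gene = genes, ratio = ratios,
               call = ifelse(ratios <= 0.75, "down",
                             ifelse(ratios >= 1.25, "up", "unchanged")),
               rank_down = NA, stringsAsFactors = FALSE)
  }
  ratios <- c(0.3, 0.5, 0.6, 1.4, 2.0)
  genes <- c("A", "B", "C", "D", "E")
  r1 <- mk(genes, ratios)
  # identical profiles correlate at exactly 1
  cc <- cross_line_correlation(list(L1 = r1, L2 = r1), n = 5)
  expect_equal(unname(cc$r["L1", "L2"]), 1)
  # inverted profiles in log space correlate at exactly -1
  r2 <- mk(genes, 2^(-log2(ratios)))
  cc2 <- cross_line_correlation(list(L1 = r1, L2 = r2), n = 5)
  expect_equal(unname(cc2$r["L1", "L2"]), -1)
  # general profiles match a direct Pearson evaluation on the log2 ratios
  ratios_b <- c(0.7, 0.4, 1.6, 0.5, 1.3)
  r3 <- mk(genes, ratios_b)
  cc3 <- cross_line_correlation(list(L1 = r1, L2 = r3), n = 5)
  expect_equal(unname(cc3$r["L1", "L2"]),
               cor(log2(ratios), log2(ratios_b)))
  ct <- cor.test(log2(ratios), log2(ratios_b))
  expect_equal(unname(cc3$p_adj["L1", "L2"]), min(1, ct$p.value))
  # structural invariants: symmetry, unit diagonal
  expect_identical(cc3$r, t(cc3$r))
  expect_equal(unname(diag(cc3$r)), c(1, 1))
  # permuting gene order leaves the result unchanged
  perm <- c(3, 1, 5, 2, 4)
  cc4 <- cross_line_correlation(
    list(L1 = r1[perm, ], L2 = r3[perm, ]), n = 5)
  expect_equal(cc4$r, cc3$r)
  # a pair sharing under 3 genes is undefined, not an error
  r5 <- mk(c("A", "Z1"), c(0.5, 0.6))
  cc5 <- cross_line_correlation(list(L1 = r1, L2 = r5), n = 5)
  expect_true(is.na(cc5$r["L1", "L2"]))
})
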