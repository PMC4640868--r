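#' Intersect the three evidence layers into a prioritized candidate table
#'
#' A gene becomes a candidate direct target in a given cell line when it
#' (1) responds to factor knockdown in the requested direction in that
#' line, (2) has a binding peak annotated to it, and (3) is significantly
#' overexpressed in the amplified tumor-cohort group (`d > 0`, `q` at or
#' below `fdr_threshold`). All three evidence values — knockdown/control
#' ratio, best peak rank, cohort FDR — are carried through unchanged, so
#' the output rows can be rendered directly into a candidate table.
#'
#' @param responses Named list (per cell line) of [compute_response()]
#'   data frames.
#' @param peak_ranks Named list (per cell line) of `gene_peak_rank` data
#'   frames from [annotate_peaks()] (columns `gene`, `peak_rank`).
#' @param cohort A [sam_two_class()] result, or any data frame with columns
#'   `gene`, `d`, `q`.
#' @param direction Knockdown response direction; `"down"` (default) selects
#'   genes the factor sustains (reduced on knockdown, overexpressed with
#'   amplification).
#' @param fdr_threshold Cohort FDR bound (default 0.10).
#' @param mode `"per_line"` (default) requires the peak in the same cell
#'   line as the expression response; `"cross_line"` accepts a peak from any
#'   supplied line (reporting the best rank across lines).
#' @return Data frame with columns `cell_line`, `gene`, `ratio`,
#'   `peak_rank`, `cohort_fdr`, sorted within line by response strength.
#' @export
integrate_candidates <- function(responses, peak_ranks, cohort,
                                 direction = c("down", "up"),
                                 fdr_threshold = 0.10,
                                 mode = c("per_line", "cross_line")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (is.null(names(responses))) {
    names(responses) <- paste0("line", seq_along(responses))
  }
  if (is.null(names(peak_ranks))) names(peak_ranks) <- names(responses)
  cohort <- as.data.frame(cohort)
  stopifnot(all(c("gene", "d", "q") %in% names(cohort)))
  cohort_pass <- if (direction == "down") {
    cohort[cohort$d > 0 & cohort$q <= fdr_threshold, , drop = FALSE]
  } else {
    cohort[cohort$d < 0 & cohort$q <= fdr_threshold, , drop = FALSE]
  }
  resp_genes <- unique(unlist(lapply(responses, `[[`, "gene")))
  peak_genes <- unique(unlist(lapply(peak_ranks, `[[`, "gene")))
  if (length(intersect(resp_genes, cohort$gene)) == 0 ||
      length(intersect(resp_genes, peak_genes)) == 0) {
    stop("gene identifier namespaces do not overlap across evidence layers")
  }
  if (mode == "cross_line") {
    all_pk <- do.call(rbind, unname(peak_ranks))
    best <- vapply(split(all_pk$peak_rank, all_pk$gene), min, numeric(1))
    union_pk <- data.frame(gene = names(best),
                           peak_rank = as.integer(best),
                           stringsAsFactors = FALSE)
  }
  rows <- lapply(names(responses), function(ln) {
    r <- responses[[ln]]
    pk <- if (mode == "per_line") peak_ranks[[ln]] else union_pk
    hit <- r[r$call == direction & r$gene %in% pk$gene &
               r$gene %in% cohort_pass$gene, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    data.frame(cell_line = ln, gene = hit$gene, ratio = hit$ratio,
               peak_rank = pk$peak_rank[match(hit$gene, pk$gene)],
               cohort_fdr = cohort_pass$q[match(hit$gene, cohort_pass$gene)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(cell_line = character(), gene = character(),
                      ratio = numeric(), peak_rank = integer(),
                      cohort_fdr = numeric(), stringsAsFactors = FALSE))
  }
  ord <- if (direction == "down") {
    order(out$cell_line, out$ratio, out$gene)
  } else {
    order(out$cell_line, -out$ratio, out$gene)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-line overlap of regulated and peak-associated genes
#'
#' For each cell line, counts the genes substantially regulated by the
#' knockdown (down or up), the genes with an annotated binding peak, and
#' their intersection, reporting the fraction both ways (what share of
#' regulated genes have a peak, and what share of peak-associated genes are
#' regulated).
#'
#' @param responses Named list of [compute_response()] data frames.
#' @param peak_genes Named list (same names) of peak-associated gene
#'   identifier vectors, or `gene_peak_rank` data frames.
#' @return Data frame with one row per line: `cell_line`, `n_regulated`,
#'   `n_peak`, `n_both`, `frac_regulated_with_peak`, `frac_peak_regulated`.
#' @export
overlap_summary <- function(responses, peak_genes) {
  if (is.null(names(responses))) {
    names(responses) <- paste0("line", seq_along(responses))
  }
  rows <- lapply(names(responses), function(ln) {
    r <- responses[[ln]]
    reg <- unique(r$gene[r$call %in% c("down", "up")])
    pg <- peak_genes[[ln]]
    if (is.data.frame(pg)) pg <- pg$gene
    pg <- unique(pg)
    both <- length(intersect(reg, pg))
    data.frame(cell_line = ln, n_regulated = length(reg),
               n_peak = length(pg), n_both = both,
               frac_regulated_with_peak =
                 if (length(reg) > 0) both / length(reg) else 0,
               frac_peak_regulated =
                 if (length(pg) > 0) both / length(pg) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sided hypergeometric gene-set overlap test
#'
#' Probability of observing at least the realized overlap between two gene
#' sets when the query is drawn at random from a universe of
#' `universe_size` genes containing the reference set — the standard
#' "compute overlap" enrichment test, evaluated by exact summation of the
#' hypergeometric tail.
#'
#' @param query,reference Character vectors of gene identifiers (both
#'   subsets of the universe).
#' @param universe_size Number of genes in the universe; must be at least
#'   `|query union reference|`.
#' @return A list with `overlap`, `p_value`, and the input sizes.
#' @export
hypergeometric_overlap <- function(query, reference, universe_size) {
  query <- unique(query); reference <- unique(reference)
  nq <- length(query); nr <- length(reference)
  k <- length(intersect(query, reference))
  if (universe_size < length(union(query, reference))) {
    stop("universe_size smaller than |query union reference|")
  }
  # P(X >= k), X ~ Hypergeometric(universe, reference, draws = query)
  support <- k:min(nq, nr)
  p <- sum(stats::dhyper(support, nr, universe_size - nr, nq))
  p <- min(1, p)
  list(overlap = k, p_value = p, n_query = nq, n_reference = nr,
       universe_size = universe_size)
}
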