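#' Construct a validated expression table
#'
#' An expression table holds per-gene abundances (RPKM-like units) for one
#' cell line under two conditions: a factor knockdown and a non-targeting
#' control. All downstream response classification starts from this object.
#'
#' @param gene Character vector of unique gene identifiers.
#' @param knockdown,control Non-negative, finite abundance vectors, parallel
#'   to `gene`.
#' @param cell_line Single string identifying the cell line.
#'
#' @return A data frame of class `expression_table` with columns `gene`,
#'   `knockdown`, `control` and a `cell_line` attribute.
#' @export
expression_table <- function(gene, knockdown, control, cell_line = "line") {
  gene <- as.character(gene)
  if (length(gene) != length(knockdown) || length(gene) != length(control)) {
    stop("gene, knockdown and control must have equal length")
  }
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  for (nm in c("knockdown", "control")) {
    v <- get(nm)
    if (!is.numeric(v)) stop("non-numeric abundance in column '", nm, "'")
    if (anyNA(v) || any(!is.finite(v))) {
      stop("non-finite abundance in column '", nm, "'")
    }
    if (any(v < 0)) {
      bad <- gene[which(v < 0)[1L]]
      stop("negative abundance for gene '", bad, "' in column '", nm, "'")
    }
  }
  out <- data.frame(gene = gene, knockdown = as.numeric(knockdown),
                    control = as.numeric(control), stringsAsFactors = FALSE)
  attr(out, "cell_line") <- as.character(cell_line)[1L]
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Read an expression table from TSV
#'
#' The file must have a header row; one column holds gene identifiers and two
#' further columns hold the knockdown and control abundances. Duplicate genes,
#' negative or non-numeric abundances, and missing condition columns are
#' rejected with an error naming the offender.
#'
#' @param path Path to a tab-separated file.
#' @param cell_line Cell-line identifier stored on the returned table.
#' @param gene_col,kd_col,ctrl_col Column names in the file header.
#' @return An [expression_table()].
#' @export
read_expression <- function(path, cell_line = "line", gene_col = "gene",
                            kd_col = "knockdown", ctrl_col = "control") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(gene_col, kd_col, ctrl_col)) {
    if (!col %in% names(raw)) {
      stop("missing required column '", col, "' in ", path)
    }
  }
  for (col in c(kd_col, ctrl_col)) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))[1L]
      stop("non-numeric abundance in column '", col, "', row ", bad)
    }
  }
  expression_table(raw[[gene_col]], raw[[kd_col]], raw[[ctrl_col]],
                   cell_line = cell_line)
}

#' Write an expression table to TSV
#' @param table An [expression_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genes adequately measured in both conditions
#'
#' A gene is well measured when its abundance reaches `min_abundance` in both
#' the knockdown and the control condition; the comparison is inclusive, so a
#' gene sitting exactly on the cutoff is kept. The default of 1 RPKM is the
#' conventional floor below which ratio estimates are dominated by sampling
#' noise.
#'
#' @param table An [expression_table()].
#' @param min_abundance Non-negative abundance cutoff (default 1).
#' @return Character vector of gene identifiers, in table order.
#' @export
well_measured <- function(table, min_abundance = 1) {
  stopifnot(inherits(table, "expression_table"), min_abundance >= 0)
  keep <- table$knockdown >= min_abundance & table$control >= min_abundance
  table$gene[keep]
}

#' Classify per-gene knockdown response
#'
#' For every well-measured gene the knockdown/control abundance ratio is
#' computed and the gene is called `down` when the ratio is at most
#' `1 - threshold`, `up` when it is at least `1 + threshold` (both bounds
#' inclusive: a change of "at least 25%" includes exactly 25%), and
#' `unchanged` otherwise. Genes failing the [well_measured()] filter are
#' called `not_measured`. Down-regulated genes additionally receive
#' `rank_down`, 1 for the most strongly reduced gene, with ties broken by
#' gene identifier so output is byte-reproducible.
#'
#' @inheritParams well_measured
#' @param threshold Fractional change defining a substantial response
#'   (default 0.25).
#' @return A data frame with columns `gene`, `ratio`, `call`
#'   (`down`/`up`/`unchanged`/`not_measured`) and `rank_down` (NA unless
#'   `call == "down"`), carrying the table's `cell_line` attribute.
#' @export
compute_response <- function(table, min_abundance = 1, threshold = 0.25) {
  stopifnot(inherits(table, "expression_table"),
            threshold > 0, threshold < 1)
  wm <- table$gene %in% well_measured(table, min_abundance)
  ratio <- ifelse(table$control > 0, table$knockdown / table$control, NA_real_)
  wm <- wm & !is.na(ratio)  # ctrl = 0 (possible when min_abundance = 0)
  call <- rep("not_measured", nrow(table))
  call[wm & ratio <= 1 - threshold] <- "down"
  call[wm & ratio >= 1 + threshold] <- "up"
  call[wm & call == "not_measured"] <- "unchanged"
  out <- data.frame(gene = table$gene, ratio = ratio, call = call,
                    rank_down = NA_integer_, stringsAsFactors = FALSE)
  is_down <- call == "down"
  if (any(is_down)) {
    ord <- order(out$ratio[is_down], out$gene[is_down])
    out$rank_down[is_down][ord] <- seq_len(sum(is_down))
  }
  attr(out, "cell_line") <- attr(table, "cell_line")
  out
}

#' Genes responding consistently across cell lines
#'
#' Given response classifications for several cell lines, returns the genes
#' called in the requested direction in at least `min_lines` of them, along
#' with the full per-line membership matrix. Genes absent from a line's table
#' are `not_measured` there, never silently `unchanged`.
#'
#' @param responses Named list of response data frames from
#'   [compute_response()], one per cell line.
#' @param direction `"down"` or `"up"`.
#' @param min_lines Minimum number of lines in which a gene must carry the
#'   call; must not exceed the number of supplied lines.
#' @return A list with `direction`, `min_lines`, `genes` (sorted character
#'   vector) and `membership` (gene-by-line logical matrix over the union of
#'   all genes).
#' @export
consistent_genes <- function(responses, direction = c("down", "up"),
                             min_lines = length(responses)) {
  direction <- match.arg(direction)
  if (is.null(names(responses)) || any(names(responses) == "")) {
    names(responses) <- paste0("line", seq_along(responses))
  }
  if (min_lines > length(responses)) {
    stop("min_lines (", min_lines, ") exceeds number of lines (",
         length(responses), ")")
  }
  universe <- sort(unique(unlist(lapply(responses, `[[`, "gene"))))
  membership <- vapply(responses, function(r) {
    m <- r$call[match(universe, r$gene)] == direction
    m[is.na(m)] <- FALSE
    m
  }, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(responses)))
  genes <- universe[rowSums(membership) >= min_lines]
  list(direction = direction, min_lines = min_lines, genes = genes,
       membership = membership)
}

#' Most strongly regulated genes in one cell line
#'
#' For `direction = "down"` the `n` genes with the smallest knockdown/control
#' ratio among those called down; for `"up"` the largest ratios among those
#' called up. Ties are broken by ascending gene identifier. Fewer than `n`
#' genes are returned when fewer qualify.
#'
#' @param response Response data frame from [compute_response()].
#' @param n Number of genes requested (default 100).
#' @param direction `"down"` or `"up"`.
#' @return Character vector of gene identifiers, strongest response first.
#' @export
top_genes <- function(response, n = 100, direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(n >= 1)
  sub <- response[response$call == direction, , drop = FALSE]
  ord <- if (direction == "down") {
    order(sub$ratio, sub$gene)
  } else {
    order(-sub$ratio, sub$gene)
  }
  utils::head(sub$gene[ord], n)
}

#' Cross-cell-line correlation of knockdown response profiles
#'
#' Builds a shared gene universe from the union of each line's top-`n`
#' down- and up-regulated genes, represents each line by the log2 of its
#' knockdown/control ratios over that universe (genes not measured in a line
#' are missing there), and computes all pairwise Pearson correlations over
#' genes measured in both lines of a pair. P-values come from the standard
#' Pearson test and are adjusted across the line pairs (Bonferroni by
#' default, the most conservative choice). Pairs sharing fewer than 3 genes
#' are reported as `NA` rather than raising an error.
#'
#' @param responses Named list of response data frames, one per line
#'   (at least 2).
#' @param n Per-direction top-gene count defining the universe (default 100).
#' @param adjust Multiplicity adjustment method passed to
#'   [stats::p.adjust()]; default `"bonferroni"`.
#' @return A list with `lines`, `r` and `p_adj` (symmetric matrices with unit
#'   and zero diagonal respectively), `n_shared` (genes per pair) and
#'   `gene_universe`.
#' @export
cross_line_correlation <- function(responses, n = 100,
                                   adjust = "bonferroni") {
  if (length(responses) < 2) stop("need at least 2 cell lines")
  if (is.null(names(responses)) || any(names(responses) == "")) {
    names(responses) <- paste0("line", seq_along(responses))
  }
  lines <- names(responses)
  universe <- sort(unique(unlist(lapply(responses, function(r) {
    c(top_genes(r, n, "down"), top_genes(r, n, "up"))
  }))))
  profiles <- vapply(responses, function(r) {
    idx <- match(universe, r$gene)
    v <- log2(r$ratio[idx])
    v[is.na(idx) | r$call[idx] == "not_measured"] <- NA_real_
    v
  }, numeric(length(universe)))
  profiles <- matrix(profiles, nrow = length(universe),
                     dimnames = list(universe, lines))

  k <- length(lines)
  r <- diag(1, k); dimnames(r) <- list(lines, lines)
  p <- matrix(NA_real_, k, k, dimnames = list(lines, lines))
  nsh <- matrix(0L, k, k, dimnames = list(lines, lines))
  pairs <- utils::combn(k, 2)
  praw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ok <- stats::complete.cases(profiles[, c(i1, i2)])
    nsh[i1, i2] <- nsh[i2, i1] <- sum(ok)
    if (sum(ok) < 3) {
      r[i1, i2] <- r[i2, i1] <- NA_real_
      praw[j] <- NA_real_
      next
    }
    ct <- stats::cor.test(profiles[ok, i1], profiles[ok, i2],
                          method = "pearson")
    r[i1, i2] <- r[i2, i1] <- unname(ct$estimate)
    praw[j] <- ct$p.value
  }
  padj <- stats::p.adjust(praw, method = adjust)
  for (j in seq_len(ncol(pairs))) {
    p[pairs[1, j], pairs[2, j]] <- p[pairs[2, j], pairs[1, j]] <- padj[j]
  }
  diag(p) <- 0
  list(lines = lines, r = r, p_adj = p, n_shared = nsh,
       gene_universe = universe, profiles = profiles)
}
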