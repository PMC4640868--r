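#' Construct a validated peak set
#'
#' Peaks are genomic intervals in BED convention (0-based, half-open) with a
#' non-negative score. Ranks (1 = strongest) are assigned by descending
#' score, ties broken by chromosome then start, and are unique within the
#' set. An optional summit coordinate may be carried for use as the peak
#' reference point.
#'
#' @param chrom,start,end Parallel vectors defining the intervals.
#' @param score Non-negative peak scores (default all 1).
#' @param summit Optional summit coordinates (absolute, 0-based), or `NULL`.
#' @return A data frame of class `peak_set` with columns `chrom`, `start`,
#'   `end`, `score`, `rank`, `summit` and a `peak_id` of the form
#'   `chrom:start-end`.
#' @export
peak_set <- function(chrom, start, end, score = NULL, summit = NULL) {
  n <- length(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start < 0)) {
    stop("peak coordinates must be finite and non-negative")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop("peak ", bad, " has start >= end (", start[bad], " >= ", end[bad],
         "); intervals are 0-based half-open")
  }
  if (is.null(score)) score <- rep(1, n)
  score <- as.numeric(score)
  if (any(!is.finite(score)) || any(score < 0)) {
    stop("peak scores must be finite and non-negative")
  }
  ord <- order(-score, as.character(chrom), start)
  rank <- integer(n); rank[ord] <- seq_len(n)
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    score = score, rank = rank,
                    summit = if (is.null(summit)) NA_real_
                             else as.numeric(summit),
                    stringsAsFactors = FALSE)
  out$peak_id <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                         as.integer(out$end))
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Read called peaks from a BED file
#'
#' Requires at least 3 columns (chrom, start, end); column 5, when present,
#' is taken as the score (BED convention). Malformed lines are reported with
#' their line number.
#'
#' @param path Path to a BED(-like) file; `track`/`browser`/`#` lines are
#'   skipped.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0) stop("no peak records in ", path)
  chrom <- character(length(fields)); start <- end <- score <-
    numeric(length(fields))
  has_score <- any(lengths(fields) >= 5)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stop("malformed BED line ", lineno[i], " in ", path,
           ": fewer than 3 fields")
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      stop("malformed BED line ", lineno[i], " in ", path,
           ": non-numeric coordinates")
    }
    if (s >= e) {
      stop("malformed BED line ", lineno[i], " in ", path,
           ": start >= end")
    }
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    score[i] <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 1
  }
  if (anyNA(score)) stop("non-numeric score in ", path)
  peak_set(chrom, start, end, if (has_score) score else NULL)
}

#' Construct a validated gene-model table
#'
#' Each gene carries its chromosome, strand, transcription start site (TSS)
#' and span in 0-based half-open coordinates. For `+` strand genes the TSS is
#' `span_start`; for `-` strand genes it is `span_end - 1`.
#'
#' @param gene Unique gene identifiers.
#' @param chrom,strand,span_start,span_end Parallel vectors; strand is
#'   `"+"` or `"-"`.
#' @return A data frame of class `gene_models` with columns `gene`, `chrom`,
#'   `strand`, `tss`, `span_start`, `span_end`.
#' @export
gene_models <- function(gene, chrom, strand, span_start, span_end) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) {
    stop("duplicate gene identifier(s) in gene models: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  span_start <- as.numeric(span_start); span_end <- as.numeric(span_end)
  if (any(span_start >= span_end)) stop("gene span_start must be < span_end")
  tss <- ifelse(strand == "+", span_start, span_end - 1)
  out <- data.frame(gene = gene, chrom = as.character(chrom),
                    strand = strand, tss = tss,
                    span_start = span_start, span_end = span_end,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read gene models from BED6 or GTF
#'
#' BED6 input (`gene` in column 4, strand in column 6) is used as is; GTF
#' input (detected by extension, 1-based inclusive coordinates) is converted
#' to 0-based half-open on load, keeping one record per `gene_id` (the union
#' span of its `gene`/`transcript`/`exon` features).
#'
#' @param path Path to a `.bed` or `.gtf` file.
#' @return A [gene_models()] table.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    gtf <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(gtf) < 9) stop("malformed GTF: fewer than 9 columns")
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?;?.*', "\\1", gtf[[9]])
    # GTF is 1-based inclusive; convert to 0-based half-open
    df <- data.frame(gene = gid, chrom = gtf[[1]], strand = gtf[[7]],
                     start = gtf[[4]] - 1, end = gtf[[5]],
                     stringsAsFactors = FALSE)
    agg <- do.call(rbind, lapply(split(df, df$gene), function(d) {
      data.frame(gene = d$gene[1], chrom = d$chrom[1], strand = d$strand[1],
                 span_start = min(d$start), span_end = max(d$end),
                 stringsAsFactors = FALSE)
    }))
    agg <- agg[order(agg$gene), ]
    gene_models(agg$gene, agg$chrom, agg$strand, agg$span_start,
                agg$span_end)
  } else {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 6) stop("gene-model BED needs 6 columns (name, strand)")
    gene_models(bed[[4]], bed[[1]], bed[[6]], bed[[2]], bed[[3]])
  }
}

#' Annotate peaks to the nearest gene within a window
#'
#' Each peak is assigned to the gene whose TSS lies closest to the peak's
#' reference point (midpoint by default; summit when available and
#' requested), restricted to genes on the same chromosome within `window`
#' base pairs. Distances are signed and strand-oriented: positive means the
#' peak lies downstream of the TSS in the gene's direction of transcription.
#' Ties are broken by ascending gene identifier. The reverse map from gene to
#' its best (lowest, i.e. strongest) associated peak rank is returned
#' alongside.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_models()] table.
#' @param window Maximum absolute TSS distance in bp (default 100000).
#' @param reference `"midpoint"` (default) or `"summit"`; summit falls back
#'   to the midpoint for peaks without one.
#' @param distance_to `"tss"` (default) or `"body"`; with `"body"` a peak
#'   overlapping the gene span has distance measured as 0 from the span and
#'   proximity is judged by distance to the span, though the reported signed
#'   distance is still TSS-relative.
#' @return A list with `annotations` (one row per peak: `peak_id`, `chrom`,
#'   `rank`, `gene` — `NA` when unassigned — and signed `distance`) and
#'   `gene_peak_rank` (per assigned gene, its best peak rank).
#' @export
annotate_peaks <- function(peaks, genes, window = 100000,
                           reference = c("midpoint", "summit"),
                           distance_to = c("tss", "body")) {
  reference <- match.arg(reference)
  distance_to <- match.arg(distance_to)
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_models"),
            window > 0)
  ref <- floor((peaks$start + peaks$end) / 2)
  if (reference == "summit") {
    ref <- ifelse(is.na(peaks$summit), ref, peaks$summit)
  }
  gene <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    if (distance_to == "tss") {
      prox <- abs(ref[i] - g$tss)
    } else {
      prox <- pmax(0, pmax(g$span_start - ref[i], ref[i] - g$span_end + 1))
    }
    cand <- which(prox <= window)
    if (length(cand) == 0) next
    best <- cand[order(prox[cand], g$gene[cand])][1L]
    gene[i] <- g$gene[best]
    raw <- ref[i] - g$tss[best]
    dist[i] <- if (g$strand[best] == "+") raw else -raw
  }
  ann <- data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
                    rank = peaks$rank, gene = gene, distance = dist,
                    stringsAsFactors = FALSE)
  assigned <- ann[!is.na(ann$gene), , drop = FALSE]
  if (nrow(assigned) > 0) {
    best_rank <- vapply(split(assigned$rank, assigned$gene), min, numeric(1))
    gpr <- data.frame(gene = names(best_rank),
                      peak_rank = as.integer(best_rank),
                      stringsAsFactors = FALSE)
    gpr <- gpr[order(gpr$gene), , drop = FALSE]
    rownames(gpr) <- NULL
  } else {
    gpr <- data.frame(gene = character(), peak_rank = integer(),
                      stringsAsFactors = FALSE)
  }
  list(annotations = ann, gene_peak_rank = gpr)
}

#' Histogram of peak-to-TSS distances
#'
#' Tallies the signed TSS distances of assigned peaks into half-open bins
#' `[k * bin_width, (k + 1) * bin_width)`. Unassigned peaks are excluded, so
#' the counts sum to the number of assigned peaks.
#'
#' @param annotations The `annotations` element of [annotate_peaks()].
#' @param bin_width Positive bin width in bp.
#' @return Data frame with `bin_start`, `bin_end`, `count`, covering only
#'   occupied bins.
#' @export
tss_distance_profile <- function(annotations, bin_width) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be a positive number")
  }
  d <- annotations$distance[!is.na(annotations$gene)]
  if (length(d) == 0) {
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  }
  bin <- floor(d / bin_width)
  tab <- table(bin)
  bs <- as.numeric(names(tab)) * bin_width
  data.frame(bin_start = bs, bin_end = bs + bin_width,
             count = as.integer(tab))
}

#' Extract fixed-width sequence windows around top gene-associated peaks
#'
#' Selects the `top` strongest (lowest rank) peaks that were assigned a gene
#' and returns an uppercased window of `width` bp centered on each peak's
#' reference point, clipped at chromosome ends. This is the input for
#' consensus-motif scanning of the strongest binding sites.
#'
#' @param peaks A [peak_set()].
#' @param annotations The `annotations` element of [annotate_peaks()] for the
#'   same peaks.
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param width Window width in bp (default 100).
#' @param top Number of top-ranked gene-associated peaks (default 500).
#' @return A named [Biostrings::DNAStringSet]; names are peak ids.
#' @export
extract_peak_windows <- function(peaks, annotations, genome, width = 100,
                                 top = 500) {
  stopifnot(width >= 1, top >= 1)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  assigned <- annotations$peak_id[!is.na(annotations$gene)]
  sel <- peaks[peaks$peak_id %in% assigned, , drop = FALSE]
  sel <- sel[order(sel$rank), , drop = FALSE]
  sel <- utils::head(sel, top)
  missing <- setdiff(unique(sel$chrom), names(genome))
  if (length(missing) > 0) {
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "))
  }
  if (nrow(sel) == 0) return(Biostrings::DNAStringSet())
  ref <- floor((sel$start + sel$end) / 2)
  ref <- ifelse(is.na(sel$summit), ref, sel$summit)
  # FASTA substring coordinates are 1-based inclusive
  from <- pmax(1, ref - floor(width / 2) + 1)
  lens <- Biostrings::width(genome)[match(sel$chrom, names(genome))]
  to <- pmin(lens, from + width - 1)
  from <- pmax(1, pmin(from, to - width + 1))
  from <- pmax(1, from)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(sel)), function(i) {
    toupper(as.character(Biostrings::subseq(genome[[sel$chrom[i]]],
                                            start = from[i], end = to[i])))
  }, character(1)))
  names(seqs) <- sel$peak_id
  seqs
}
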