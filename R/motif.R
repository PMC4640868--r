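#' Scan sequences for an IUPAC consensus motif
#'
#' Finds every exact match of a degenerate IUPAC pattern (e.g. the Nkx2
#' homeodomain consensus `CACTY`, or the extended `CHCTY`) in a set of DNA
#' sequences. Minus-strand matches are located by scanning with the reverse
#' complement of the pattern and are reported at their plus-strand offset
#' with `strand = "-"`; overlapping matches are all reported.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @param pattern IUPAC consensus string (default `"CACTY"`).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return A list with `hits` (data frame: `sequence_id`, `offset` (0-based),
#'   `strand`, `matched` plus-strand text) and `counts` (named integer vector
#'   of hits per sequence, zeros included).
#' @export
scan_motif <- function(sequences, pattern = "CACTY", both_strands = TRUE) {
  pattern <- toupper(pattern)
  valid <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  bad <- setdiff(strsplit(pattern, "")[[1]], valid)
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s) in pattern: ", paste(bad, collapse = ""))
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- paste0("seq", seq_along(sequences))
    }
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids <- make.unique(ids)
  pat <- Biostrings::DNAString(pattern)
  rcpat <- Biostrings::reverseComplement(pat)
  rows <- list()
  for (i in seq_along(sequences)) {
    subj <- sequences[[i]]
    m <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
    if (length(m) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = ids[i], offset = Biostrings::start(m) - 1L,
        strand = "+", matched = as.character(m), stringsAsFactors = FALSE)
    }
    if (both_strands) {
      m2 <- Biostrings::matchPattern(rcpat, subj, fixed = FALSE)
      if (length(m2) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = ids[i], offset = Biostrings::start(m2) - 1L,
          strand = "-", matched = as.character(m2), stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows) > 0) {
    h <- do.call(rbind, rows)
    h <- h[order(match(h$sequence_id, ids), h$offset, h$strand), ,
           drop = FALSE]
    rownames(h) <- NULL
    h
  } else {
    data.frame(sequence_id = character(), offset = integer(),
               strand = character(), matched = character(),
               stringsAsFactors = FALSE)
  }
  counts <- table(factor(hits$sequence_id, levels = ids))
  counts <- stats::setNames(as.integer(counts), ids)
  list(hits = hits, counts = counts)
}

#' Shuffle-based enrichment of a consensus motif in peak windows
#'
#' Compares the total motif count observed in the supplied sequences with
#' counts in per-sequence mononucleotide shuffles (which preserve each
#' window's base composition and length). Fold enrichment is the observed
#' total over the mean shuffled total; the empirical p-value uses the
#' add-one convention and therefore can never fall below
#' `1 / (n_shuffles + 1)`.
#'
#' @inheritParams scan_motif
#' @param n_shuffles Number of shuffled replicates (default 100, minimum 1).
#' @param seed Integer seed making the shuffles reproducible.
#' @return A list with `observed`, `fold`, `p_value`, and the vector of
#'   `shuffled` totals.
#' @export
motif_enrichment <- function(sequences, pattern = "CACTY", n_shuffles = 100,
                             seed = 1, both_strands = TRUE) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0) stop("empty sequence set")
  observed <- sum(scan_motif(sequences, pattern, both_strands)$counts)
  chars <- lapply(sequences, function(s) strsplit(toupper(s), "")[[1]])
  set.seed(seed)
  shuffled <- vapply(seq_len(n_shuffles), function(b) {
    shuf <- vapply(chars, function(ch) paste(sample(ch), collapse = ""),
                   character(1))
    sum(scan_motif(shuf, pattern, both_strands)$counts)
  }, numeric(1))
  mu <- mean(shuffled)
  fold <- if (mu == 0) {
    if (observed == 0) 0 else Inf
  } else {
    observed / mu
  }
  if (observed == 0) fold <- 0
  p <- (1 + sum(shuffled >= observed)) / (n_shuffles + 1)
  list(observed = observed, fold = fold, p_value = p, shuffled = shuffled)
}
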