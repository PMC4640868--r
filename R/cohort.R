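#' Construct a tumor-cohort study object
#'
#' Bundles a gene-by-sample expression matrix with the per-sample
#' copy-number tumor/normal ratio at a single index locus (the amplified
#' transcription-factor gene). Expression declared `"linear"` is
#' log2-transformed with a +1 offset on construction, since the downstream
#' two-class statistic assumes a roughly additive scale.
#'
#' @param expression Numeric gene-by-sample matrix with dimnames.
#' @param cn_ratio Positive numeric vector, one tumor/normal copy-number
#'   ratio per sample (named or in column order).
#' @param index_gene Identifier of the amplified locus; must be a row of
#'   `expression`.
#' @param scale `"log2"` (default) or `"linear"`.
#' @return A list of class `cohort_study` with elements `expression`
#'   (log2 scale), `cn_ratio`, `index_gene`.
#' @export
cohort_study <- function(expression, cn_ratio, index_gene,
                         scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(expression) || is.null(rownames(expression)) ||
      is.null(colnames(expression))) {
    stop("expression must be a matrix with gene rownames and sample colnames")
  }
  if (anyNA(expression) || any(!is.finite(expression))) {
    stop("expression must be finite")
  }
  if (length(cn_ratio) != ncol(expression)) {
    stop("cn_ratio length must equal the number of samples")
  }
  if (any(cn_ratio <= 0)) stop("cn_ratio must be positive")
  if (!index_gene %in% rownames(expression)) {
    stop("index_gene '", index_gene, "' not in expression rows")
  }
  if (is.null(names(cn_ratio))) names(cn_ratio) <- colnames(expression)
  cn_ratio <- cn_ratio[colnames(expression)]
  if (scale == "linear") expression <- log2(expression + 1)
  structure(list(expression = expression, cn_ratio = cn_ratio,
                 index_gene = index_gene),
            class = "cohort_study")
}

#' Call copy-number amplification status from a tumor/normal ratio
#'
#' Amplified when the ratio strictly exceeds `amp_threshold`; non-amplified
#' when strictly below `nonamp_threshold`; the zone in between is
#' indeterminate and excluded from downstream group comparisons.
#'
#' @param cn_ratio Positive numeric vector of tumor/normal ratios.
#' @param amp_threshold Lower bound (exclusive) for amplification
#'   (default 1.5).
#' @param nonamp_threshold Upper bound (exclusive) for confident absence of
#'   amplification (default 1.1).
#' @return Character vector in `{"amplified", "non_amplified",
#'   "indeterminate"}`.
#' @export
call_amplification <- function(cn_ratio, amp_threshold = 1.5,
                               nonamp_threshold = 1.1) {
  if (nonamp_threshold > amp_threshold) {
    stop("nonamp_threshold must not exceed amp_threshold")
  }
  if (any(cn_ratio <= 0)) stop("cn_ratio must be positive")
  out <- rep("indeterminate", length(cn_ratio))
  out[cn_ratio > amp_threshold] <- "amplified"
  out[cn_ratio < nonamp_threshold] <- "non_amplified"
  names(out) <- names(cn_ratio)
  out
}

#' Samples in the top expression percentile for the index gene
#'
#' "High expression" is membership in the top `100 - percentile` percent of
#' the cohort distribution: samples at or above the `percentile`-th
#' percentile (linear-interpolation quantile, the R type-7 default) are
#' selected; the comparison is inclusive.
#'
#' @param expr Named numeric vector of index-gene expression across samples.
#' @param percentile Percentile cut in `[0, 100]` (default 75, i.e. the top
#'   quartile).
#' @return Character vector of selected sample names.
#' @export
high_expression_gate <- function(expr, percentile = 75) {
  if (length(expr) < 4) stop("need at least 4 samples")
  if (is.null(names(expr))) names(expr) <- paste0("s", seq_along(expr))
  cut <- stats::quantile(expr, probs = percentile / 100, type = 7,
                         names = FALSE)
  names(expr)[expr >= cut]
}

#' Derive comparison-group labels for a cohort study
#'
#' Composes amplification calling with the high-expression gate:
#' `amplified_high` samples are amplified at the index locus and in the top
#' expression percentile for the index gene; `nonamplified_high` samples are
#' confidently non-amplified yet still highly expressing; all other samples
#' (indeterminate copy number, or below the expression gate) are `excluded`.
#'
#' @param study A [cohort_study()].
#' @inheritParams call_amplification
#' @inheritParams high_expression_gate
#' @return Named character vector of labels per sample, with the
#'   amplification calls attached as attribute `amp_call`.
#' @export
define_groups <- function(study, amp_threshold = 1.5, nonamp_threshold = 1.1,
                          percentile = 75) {
  stopifnot(inherits(study, "cohort_study"))
  amp <- call_amplification(study$cn_ratio, amp_threshold, nonamp_threshold)
  high <- colnames(study$expression) %in%
    high_expression_gate(study$expression[study$index_gene, ], percentile)
  labels <- rep("excluded", ncol(study$expression))
  labels[amp == "amplified" & high] <- "amplified_high"
  labels[amp == "non_amplified" & high] <- "nonamplified_high"
  names(labels) <- colnames(study$expression)
  attr(labels, "amp_call") <- amp
  labels
}

# Relative difference d = (mean_A - mean_B) / (s + s0) with pooled-variance
# gene-wise standard error s. Returns list(r, s) for one label assignment.
.sam_stats <- function(x, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(x[, idx_a, drop = FALSE])
  mb <- rowMeans(x[, idx_b, drop = FALSE])
  ssa <- rowSums((x[, idx_a, drop = FALSE] - ma)^2)
  ssb <- rowSums((x[, idx_b, drop = FALSE] - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  list(r = ma - mb, s = s)
}

# Tusher-style fudge-factor selection: pick the percentile of {s_i} that
# minimizes the coefficient of variation of the median absolute deviation of
# d across quantile windows of s.
.sam_select_s0 <- function(r, s, alphas = seq(0, 1, by = 0.05)) {
  qs <- stats::quantile(s, probs = alphas, names = FALSE)
  n_bins <- min(100L, max(2L, floor(length(s) / 5)))
  breaks <- unique(stats::quantile(s, probs = seq(0, 1, length.out =
                                                    n_bins + 1),
                                   names = FALSE))
  if (length(breaks) < 3) return(stats::quantile(s, 0.5, names = FALSE))
  bins <- cut(s, breaks = breaks, include.lowest = TRUE)
  cvs <- vapply(qs, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, bins, stats::mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  qs[which.min(cvs)]
}

#' Two-class SAM analysis with permutation-based FDR
#'
#' The significance-analysis-of-microarrays statistic for a two-group
#' comparison: per gene, `d = (mean_A - mean_B) / (s + s0)` where `s` is the
#' pooled-variance standard error of the mean difference and `s0` is a fudge
#' constant chosen from candidate percentiles of the `s` distribution to
#' minimize the coefficient of variation of `d`'s spread across the range of
#' `s`. Significance is assessed against expected order statistics from
#' seeded whole-label permutations: for a threshold `Delta`, genes whose
#' sorted `d` departs from the permutation-average sorted `d` by more than
#' `Delta` define data-driven cut points in `d`, the median number of
#' permuted statistics beyond those cut points estimates false calls, and
#' each gene's `q` is the minimum estimated FDR over all `Delta` at which it
#' is called. The null proportion `pi0` is estimated from the fraction of
#' observed `d` inside the central 50% of the pooled permuted statistics.
#'
#' The contrast is group A minus group B, where A is the first factor level
#' of `labels` (for character labels, the alphabetically first; with
#' [define_groups()] output, `amplified_high` minus `nonamplified_high`), so
#' `d > 0` means higher expression in group A.
#'
#' @param expression Gene-by-sample numeric matrix (log2 scale).
#' @param labels Per-sample group labels; samples with labels other than the
#'   two compared groups (e.g. `"excluded"`) are dropped.
#' @param groups Optional length-2 character vector fixing (A, B); defaults
#'   to the first two factor levels present.
#' @param n_perm Number of label permutations (default 200, minimum 10).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param s0 Fudge constant; `NULL` (default) selects it automatically,
#'   `0` recovers the unmoderated statistic.
#' @return A data frame (class `sam_result`) with columns `gene`, `d`, `s`,
#'   `q`, and attributes `s0`, `pi0`, `n_perm`, `seed`, `groups`, `n_a`,
#'   `n_b`.
#' @export
sam_two_class <- function(expression, labels, groups = NULL, n_perm = 200,
                          seed, s0 = NULL) {
  if (missing(seed)) stop("seed is required")
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (length(labels) != ncol(expression)) {
    stop("labels length must equal the number of samples")
  }
  labels <- as.character(labels)
  if (is.null(groups)) {
    groups <- setdiff(sort(unique(labels)), "excluded")[1:2]
  }
  if (length(groups) != 2 || anyNA(groups)) {
    stop("need exactly two comparison groups")
  }
  keep <- labels %in% groups
  x <- expression[, keep, drop = FALSE]
  lab <- labels[keep]
  idx_a <- which(lab == groups[1]); idx_b <- which(lab == groups[2])
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    stop("both groups need at least 2 samples (got ", length(idx_a), " and ",
         length(idx_b), ")")
  }
  m <- nrow(x); n <- ncol(x); na <- length(idx_a)
  obs <- .sam_stats(x, idx_a, idx_b)
  if (all(obs$s == 0) && (!is.null(s0) && s0 == 0)) {
    stop("zero within-group variance for every gene with s0 = 0")
  }
  if (is.null(s0)) s0 <- .sam_select_s0(obs$r, obs$s)
  denom <- obs$s + s0
  d <- ifelse(obs$r == 0 & denom == 0, 0, obs$r / denom)

  set.seed(seed)
  d_perm <- matrix(NA_real_, m, n_perm)
  for (b in seq_len(n_perm)) {
    pa <- sample.int(n, na)
    pstat <- .sam_stats(x, pa, setdiff(seq_len(n), pa))
    pden <- pstat$s + s0
    d_perm[, b] <- ifelse(pstat$r == 0 & pden == 0, 0, pstat$r / pden)
  }
  d_perm_sorted <- apply(d_perm, 2, sort)
  dbar <- rowMeans(d_perm_sorted)

  ord <- order(d)
  d_sorted <- d[ord]
  gaps <- abs(d_sorted - dbar)

  central <- stats::quantile(d_perm, probs = c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d >= central[1] & d <= central[2]) / (0.5 * m))

  deltas <- sort(unique(c(0, gaps)))
  n_delta <- length(deltas)
  cutup_at <- rep(Inf, n_delta); cutlow_at <- rep(-Inf, n_delta)
  n_called_at <- integer(n_delta)
  delta_max <- rep(-1, m)   # per sorted position: largest delta still called
  for (k in seq_len(n_delta)) {
    delta <- deltas[k]
    up <- d_sorted - dbar > delta & d_sorted > 0
    lo <- dbar - d_sorted > delta & d_sorted < 0
    cutup <- if (any(up)) min(d_sorted[up]) else Inf
    cutlow <- if (any(lo)) max(d_sorted[lo]) else -Inf
    called <- d_sorted >= cutup | d_sorted <= cutlow
    cutup_at[k] <- cutup; cutlow_at[k] <- cutlow
    n_called_at[k] <- sum(called)
    delta_max[called] <- delta
  }
  # median false calls per delta: count permuted d beyond the cut points,
  # via binary search in each permutation's sorted statistics
  false_counts <- vapply(seq_len(n_perm), function(b) {
    sc <- d_perm_sorted[, b]
    up_n <- m - findInterval(cutup_at, sc, left.open = TRUE)
    lo_n <- findInterval(cutlow_at, sc)
    up_n + lo_n
  }, numeric(n_delta))
  false_counts <- matrix(false_counts, nrow = n_delta)
  med_false <- apply(false_counts, 1, stats::median)
  fdr_at <- pmin(1, pi0 * med_false / pmax(1, n_called_at))
  # calls are nested (cut points tighten as delta grows): each gene is
  # called on an interval [0, delta_max], so its q is the prefix-minimum
  # FDR over the ascending delta grid up to its ceiling
  pref <- cummin(fdr_at)
  q_sorted <- rep(1, m)
  has <- delta_max >= 0
  if (any(has)) {
    k_idx <- findInterval(delta_max[has], deltas)
    q_sorted[has] <- pref[k_idx]
  }
  q <- numeric(m); q[ord] <- q_sorted

  genes <- rownames(expression)
  if (is.null(genes)) genes <- paste0("g", seq_len(m))
  out <- data.frame(gene = genes, d = d, s = obs$s, q = q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "s0") <- s0
  attr(out, "pi0") <- pi0
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "groups") <- groups
  attr(out, "n_a") <- length(idx_a)
  attr(out, "n_b") <- length(idx_b)
  class(out) <- c("sam_result", "data.frame")
  out
}

#' Genes significantly overexpressed in the amplified group
#'
#' Positive-direction calls from a SAM result: genes with `d > 0` (higher in
#' group A, the amplified/highly-expressing group under [define_groups()]
#' labels) and `q` at or below the FDR threshold. The default threshold of
#' 0.10 matches a candidate-table use; 0.05 is the stricter conventional
#' choice.
#'
#' @param sam A [sam_two_class()] result.
#' @param fdr_threshold Maximum estimated FDR (default 0.10).
#' @return Character vector of gene identifiers, sorted.
#' @export
overexpressed_in_amplified <- function(sam, fdr_threshold = 0.10) {
  sort(sam$gene[sam$d > 0 & sam$q <= fdr_threshold])
}
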