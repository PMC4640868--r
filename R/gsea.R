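#' Read gene-set collections from a GMT file
#'
#' Each GMT line holds a set name, a description, then the member genes,
#' tab-separated. Duplicate members are collapsed; sets left with no members
#' are skipped with a warning. Size filtering against the measured genes
#' happens downstream in [gsea_two_class()], not at load time.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets, each `list(name, description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) {
      stop("malformed GMT line ", i, ": need at least name and description")
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      warning("skipping empty gene set '", f[1], "' (line ", i, ")")
      next
    }
    sets[[f[1]]] <- list(name = f[1], description = f[2], genes = genes)
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene sets as returned by [read_gmt()], or a
#'   named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    genes <- if (is.list(s)) s$genes else s
    desc <- if (is.list(s) && !is.null(s$description)) s$description else "na"
    paste(c(nm, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Signal-to-noise gene ranking for a two-class comparison
#'
#' The per-gene metric is `(mu_A - mu_B) / (sd_A + sd_B)`, with each class
#' standard deviation floored at `max(0.2 * |class mean|, eps)` — the
#' convention of the reference GSEA implementation, which prevents
#' near-constant genes from dominating the ranking. Genes are returned in
#' descending metric order with ties broken by gene identifier.
#'
#' @param expression Gene-by-sample numeric matrix.
#' @param labels Per-sample class labels (exactly the two compared classes
#'   after dropping others).
#' @param groups Optional length-2 vector fixing (A, B); defaults to the
#'   alphabetically first two labels.
#' @param sd_floor_frac Fraction of `|mean|` flooring each sd (default 0.2).
#' @param eps Absolute sd floor (default 1e-8).
#' @return Data frame with columns `gene` and `metric`, ranked.
#' @export
rank_signal_to_noise <- function(expression, labels, groups = NULL,
                                 sd_floor_frac = 0.2, eps = 1e-8) {
  labels <- as.character(labels)
  if (is.null(groups)) groups <- setdiff(sort(unique(labels)), "excluded")[1:2]
  keep <- labels %in% groups
  x <- expression[, keep, drop = FALSE]
  lab <- labels[keep]
  a <- x[, lab == groups[1], drop = FALSE]
  b <- x[, lab == groups[2], drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    stop("each class needs at least 2 samples")
  }
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  sd_a <- pmax(apply(a, 1, stats::sd), sd_floor_frac * abs(mu_a), eps)
  sd_b <- pmax(apply(b, 1, stats::sd), sd_floor_frac * abs(mu_b), eps)
  metric <- (mu_a - mu_b) / (sd_a + sd_b)
  genes <- rownames(expression)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(expression)))
  ord <- order(-metric, genes)
  data.frame(gene = genes[ord], metric = metric[ord],
             stringsAsFactors = FALSE)
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked gene list accumulating `|metric|^weight`
#' (normalized to sum to 1 over in-set genes) at every set member and
#' subtracting `1 / (N - N_hit)` at every non-member. The enrichment score
#' is the signed maximum deviation of this running sum from zero; with
#' `weight = 0` it reduces to the classic Kolmogorov-Smirnov statistic on
#' the set's rank positions. The leading edge contains the set members at or
#' before the score's extremum (after it, for negative scores).
#'
#' @param ranked Data frame from [rank_signal_to_noise()] (columns `gene`,
#'   `metric`), best-to-worst order.
#' @param gene_set Character vector of member genes (or a [read_gmt()] set).
#' @param weight Exponent on `|metric|` (default 1).
#' @return A list with `es`, `running` (length-N profile), and
#'   `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  if (is.list(gene_set) && !is.null(gene_set$genes)) {
    gene_set <- gene_set$genes
  }
  hit <- ranked$gene %in% gene_set
  n <- nrow(ranked); nh <- sum(hit)
  if (nh == 0) stop("gene set shares no genes with the ranked list")
  if (nh == n) stop("gene set covers every ranked gene")
  w <- abs(ranked$metric)^weight
  w[!hit] <- 0
  tot <- sum(w)
  incr <- if (tot > 0) w / tot else ifelse(hit, 1 / nh, 0)
  decr <- ifelse(hit, 0, 1 / (n - nh))
  running <- cumsum(incr - decr)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) {
    ranked$gene[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    ranked$gene[i_max:n][hit[i_max:n]]
  }
  list(es = es, running = running, leading_edge = leading)
}

#' Two-class GSEA with permutation-based significance
#'
#' For every gene set passing the in-data size filters, computes the
#' weighted running-sum enrichment score over the signal-to-noise ranking,
#' then assesses significance against a seeded null. The null is built by
#' phenotype (label) permutation — re-ranking all genes under each permuted
#' labeling — or, when either class has fewer than `min_phenotype` samples
#' (where label permutations are too few to resolve small p-values), by gene
#' permutation of set memberships; the choice is recorded in the output.
#'
#' The normalized score is `NES = ES / mean(|permuted ES of the same
#' sign|)`; the nominal p-value is the one-sided empirical tail among
#' same-sign permuted scores with add-one smoothing; the FDR for a set with
#' `NES >= 0` compares the fraction of pooled permuted NES at or above it
#' with the fraction of observed NES at or above it (mirrored for negative
#' scores) and is clipped to `[0, 1]`.
#'
#' @inheritParams rank_signal_to_noise
#' @param sets Named list of gene sets ([read_gmt()] output or character
#'   vectors).
#' @param n_perm Number of permutations (default 200, minimum 10).
#' @param seed Integer seed; mandatory.
#' @param weight Running-sum exponent (default 1).
#' @param min_size,max_size Bounds on members present in the data
#'   (defaults 15 and 500).
#' @param perm_type `"auto"` (default), `"phenotype"`, or `"gene"`.
#' @param min_phenotype Minimum per-class size for phenotype permutation
#'   under `"auto"` (default 7).
#' @return Data frame with one row per retained set: `set_name`, `size`,
#'   `es`, `nes`, `p_nominal`, `fdr`, `leading_edge` (list column), sorted
#'   by descending `nes`; attributes `perm_type`, `n_perm`, `seed`.
#' @export
gsea_two_class <- function(expression, labels, sets, n_perm = 200, seed,
                           groups = NULL, weight = 1, min_size = 15,
                           max_size = 500, perm_type = c("auto", "phenotype",
                                                         "gene"),
                           min_phenotype = 7) {
  if (missing(seed)) stop("seed is required")
  if (n_perm < 10) stop("n_perm must be >= 10")
  perm_type <- match.arg(perm_type)
  labels <- as.character(labels)
  if (is.null(groups)) groups <- setdiff(sort(unique(labels)), "excluded")[1:2]
  keep <- labels %in% groups
  x <- expression[, keep, drop = FALSE]
  lab <- labels[keep]
  n_a <- sum(lab == groups[1]); n_b <- sum(lab == groups[2])
  if (perm_type == "auto") {
    perm_type <- if (min(n_a, n_b) >= min_phenotype) "phenotype" else "gene"
    if (perm_type == "gene") {
      warning("fewer than ", min_phenotype, " samples in a class; ",
              "falling back to gene permutation")
    }
  }

  members <- lapply(sets, function(s) if (is.list(s)) s$genes else s)
  if (is.null(names(members))) {
    names(members) <- paste0("set", seq_along(members))
  }
  measured <- rownames(x)
  in_data <- lapply(members, intersect, measured)
  sizes <- lengths(in_data)
  retain <- sizes >= min_size & sizes <= max_size & sizes < length(measured)
  if (!any(retain)) stop("no gene set passes the size filters")
  in_data <- in_data[retain]
  sizes <- sizes[retain]
  n_sets <- length(in_data)

  ranked <- rank_signal_to_noise(x, lab, groups)
  es_obs <- vapply(in_data, function(g) {
    enrichment_score(ranked, g, weight)$es
  }, numeric(1))
  leading <- lapply(in_data, function(g) {
    enrichment_score(ranked, g, weight)$leading_edge
  })

  set.seed(seed)
  es_perm <- matrix(NA_real_, n_sets, n_perm)
  if (perm_type == "phenotype") {
    for (b in seq_len(n_perm)) {
      plab <- sample(lab)
      pranked <- rank_signal_to_noise(x, plab, groups)
      es_perm[, b] <- vapply(in_data, function(g) {
        enrichment_score(pranked, g, weight)$es
      }, numeric(1))
    }
  } else {
    for (b in seq_len(n_perm)) {
      pgenes <- sample(measured)
      es_perm[, b] <- vapply(seq_len(n_sets), function(s) {
        enrichment_score(ranked, pgenes[seq_len(sizes[s])], weight)$es
      }, numeric(1))
    }
  }

  nes <- p_nom <- rep(NA_real_, n_sets)
  nes_perm <- matrix(NA_real_, n_sets, n_perm)
  for (s in seq_len(n_sets)) {
    perm <- es_perm[s, ]
    pos <- perm[perm >= 0]; neg <- perm[perm < 0]
    mean_pos <- if (length(pos) > 0) mean(pos) else mean(abs(perm))
    mean_neg <- if (length(neg) > 0) mean(abs(neg)) else mean(abs(perm))
    if (es_obs[s] >= 0) {
      nes[s] <- es_obs[s] / mean_pos
      p_nom[s] <- (1 + sum(pos >= es_obs[s])) / (1 + length(pos))
    } else {
      nes[s] <- -abs(es_obs[s]) / mean_neg
      p_nom[s] <- (1 + sum(neg <= es_obs[s])) / (1 + length(neg))
    }
    nes_perm[s, ] <- ifelse(perm >= 0, perm / mean_pos, perm / mean_neg)
  }

  pool <- as.vector(nes_perm)
  fdr <- vapply(seq_len(n_sets), function(s) {
    v <- nes[s]
    if (v >= 0) {
      num <- sum(pool >= v) / max(1, sum(pool >= 0))
      den <- sum(nes >= v) / max(1, sum(nes >= 0))
    } else {
      num <- sum(pool <= v) / max(1, sum(pool < 0))
      den <- sum(nes <= v) / max(1, sum(nes < 0))
    }
    if (den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(set_name = names(in_data), size = as.integer(sizes),
                    es = es_obs, nes = nes, p_nominal = p_nom, fdr = fdr,
                    stringsAsFactors = FALSE)
  out$leading_edge <- I(unname(leading))
  out <- out[order(-out$nes, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "perm_type") <- perm_type
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}
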