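#' Configuration for the synthetic-data generator
#'
#' Collects every parameter of the planted-truth simulation with defaults
#' chosen to emulate the statistical regime the analysis assumes: a few
#' thousand measured genes per cell line, a planted minority of
#' knockdown-responsive genes whose ratio effects straddle the 25%
#' threshold, multiplicative log-normal measurement noise on RPKM-like
#' abundances, binding peaks placed promoter-proximally at direct-target
#' TSSs among uniform decoys, and a tumor cohort in which amplified samples
#' carry a log2 expression shift at the planted direct targets and at the
#' index gene itself.
#'
#' @param seed Integer seed (mandatory); drives every random draw.
#' @param n_genes Total genes (default 2000).
#' @param n_lines Number of knockdown cell lines (default 3).
#' @param n_direct_targets Genes planted with both a knockdown response and
#'   a nearby peak and a cohort shift (default 50).
#' @param n_indirect_targets Genes planted with a knockdown response only
#'   (default 100).
#' @param direct_ratio_range,indirect_ratio_range Knockdown/control ratio
#'   ranges for planted genes (defaults `c(0.2, 0.7)` and `c(0.4, 0.9)`;
#'   the indirect range deliberately straddles the 0.75 call threshold).
#' @param expression_noise_sigma Standard deviation of the per-condition
#'   natural-log multiplicative noise (default 0.15).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   RPKM (defaults 3 and 1.2, median about 20 RPKM).
#' @param fraction_below_filter Fraction of null genes forced below the
#'   1-RPKM filter in the knockdown condition, exercising the
#'   `not_measured` path (default 0.05).
#' @param n_contigs,contig_length Synthetic genome shape (defaults 3 and
#'   4e6, so 100-kb windows are meaningful at toy scale).
#' @param peak_width Width of simulated peaks in bp (default 300).
#' @param true_peak_distance_range Absolute TSS distance range for planted
#'   peaks, bp (default `c(200, 2000)`; promoter-proximal so nearest-TSS
#'   annotation is unambiguous at the simulated gene density).
#' @param n_decoy_peaks Uniformly placed decoy peaks per line (default 500).
#' @param motif Consensus instance inserted into true-peak windows
#'   (default `"CACTC"`).
#' @param motif_insertion_rate Per-true-peak insertion probability
#'   (default 0.8).
#' @param n_amplified,n_nonamplified,n_indeterminate Cohort group sizes
#'   (defaults 30, 60, 30).
#' @param cn_amplified_range,cn_nonamplified_range,cn_indeterminate_range
#'   Copy-number tumor/normal ratio ranges per group.
#' @param cohort_baseline_mean,cohort_baseline_sd Normal parameters of
#'   per-gene log2 baselines (defaults 6 and 1).
#' @param cohort_noise_sd Per-sample log2 noise (default 0.8).
#' @param amplified_effect_log2 Expression shift at planted direct targets
#'   in amplified samples (default 1.5).
#' @param amplified_index_shift_log2 Shift of the index gene itself in
#'   amplified samples (default 1.0).
#' @param planted_set_size Members of the planted gene set drawn from the
#'   direct targets (default 20).
#' @param n_decoy_sets Decoy gene sets in the GMT (default 10).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 2000,
                              n_lines = 3,
                              n_direct_targets = 50,
                              n_indirect_targets = 100,
                              direct_ratio_range = c(0.2, 0.7),
                              indirect_ratio_range = c(0.4, 0.9),
                              expression_noise_sigma = 0.15,
                              baseline_meanlog = 3,
                              baseline_sdlog = 1.2,
                              fraction_below_filter = 0.05,
                              n_contigs = 3,
                              contig_length = 4e6,
                              peak_width = 300,
                              true_peak_distance_range = c(200, 2000),
                              n_decoy_peaks = 500,
                              motif = "CACTC",
                              motif_insertion_rate = 0.8,
                              n_amplified = 30,
                              n_nonamplified = 60,
                              n_indeterminate = 30,
                              cn_amplified_range = c(1.6, 4.0),
                              cn_nonamplified_range = c(0.7, 1.09),
                              cn_indeterminate_range = c(1.1, 1.5),
                              cohort_baseline_mean = 6,
                              cohort_baseline_sd = 1,
                              cohort_noise_sd = 0.8,
                              amplified_effect_log2 = 1.5,
                              amplified_index_shift_log2 = 1.0,
                              planted_set_size = 20,
                              n_decoy_sets = 10) {
  if (missing(seed)) stop("seed is required")
  cfg <- as.list(environment())
  if (cfg$n_direct_targets + cfg$n_indirect_targets > cfg$n_genes) {
    stop("planted targets exceed n_genes")
  }
  if (cfg$planted_set_size > cfg$n_direct_targets) {
    stop("planted_set_size exceeds n_direct_targets")
  }
  stopifnot(cfg$n_genes >= 1, cfg$n_lines >= 1,
            all(cfg$direct_ratio_range > 0),
            all(cfg$indirect_ratio_range > 0),
            cfg$expression_noise_sigma >= 0,
            cfg$motif_insertion_rate >= 0, cfg$motif_insertion_rate <= 1)
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a seeded synthetic input bundle with planted ground truth
#'
#' Writes every input the pipeline consumes — per-line expression TSVs,
#' per-line peak BEDs, a gene-model BED on a synthetic genome, the genome
#' FASTA (with consensus-motif instances inserted into true-peak windows),
#' a cohort expression matrix and sample metadata, a GMT with one planted
#' and several decoy sets — plus a truth table recording what was planted,
#' and a manifest listing all files. Identical seeds yield byte-identical
#' files; all draws happen in a fixed documented order (gene roles, planted
#' ratios, expression noise per line, genome, peaks per line, motif
#' insertions, cohort, gene sets).
#'
#' Control abundance is `baseline * lognormal noise`; knockdown abundance is
#' `baseline * planted ratio * lognormal noise`. True peaks are centered at
#' a signed strand-oriented distance from their target's TSS; decoys are
#' uniform. Amplified cohort samples get `amplified_effect_log2` added at
#' direct targets.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list with `config`, `paths` (named file paths), `truth` (data
#'   frame), `lines`, and in-memory objects: `tables` (expression tables),
#'   `peaks`, `genes` (gene models), `genome`, `study`
#'   ([cohort_study()]), `sets`.
#' @export
simulate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  set.seed(cfg$seed)
  lines <- sprintf("LINE%d", seq_len(cfg$n_lines))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))

  ## 1. gene roles -----------------------------------------------------
  roles <- rep("null", cfg$n_genes)
  planted <- sample.int(cfg$n_genes,
                        cfg$n_direct_targets + cfg$n_indirect_targets)
  direct_idx <- planted[seq_len(cfg$n_direct_targets)]
  indirect_idx <- setdiff(planted, direct_idx)
  roles[direct_idx] <- "direct"
  roles[indirect_idx] <- "indirect"
  null_idx <- which(roles == "null")
  n_below <- round(cfg$fraction_below_filter * length(null_idx))
  below_idx <- if (n_below > 0) sample(null_idx, n_below) else integer()

  ## 2. planted ratios per line ----------------------------------------
  ratio <- matrix(1, cfg$n_genes, cfg$n_lines,
                  dimnames = list(gene_ids, lines))
  for (l in seq_len(cfg$n_lines)) {
    ratio[direct_idx, l] <- stats::runif(length(direct_idx),
                                         cfg$direct_ratio_range[1],
                                         cfg$direct_ratio_range[2])
    ratio[indirect_idx, l] <- stats::runif(length(indirect_idx),
                                           cfg$indirect_ratio_range[1],
                                           cfg$indirect_ratio_range[2])
  }

  ## 3. gene models on the synthetic genome ----------------------------
  per_contig <- ceiling(cfg$n_genes / cfg$n_contigs)
  contig <- sprintf("chr%d", ((seq_len(cfg$n_genes) - 1) %/% per_contig) + 1)
  within <- ((seq_len(cfg$n_genes) - 1) %% per_contig) + 1
  spacing <- floor(cfg$contig_length / (per_contig + 1))
  tss <- within * spacing
  strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  span_len <- 2000
  span_start <- ifelse(strand == "+", tss, tss - span_len + 1)
  span_end <- ifelse(strand == "+", tss + span_len, tss + 1)
  span_start <- pmax(0, span_start)
  genes <- gene_models(gene_ids, contig, strand, span_start, span_end)

  ## 4. expression tables per line -------------------------------------
  baseline <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                            cfg$baseline_sdlog)
  baseline <- pmax(baseline, 1.5)  # keep null genes above the RPKM filter
  # planted responsive genes are modeled as adequately expressed, so their
  # knockdown values stay measurable even at the strongest planted ratios
  baseline[planted] <- pmax(baseline[planted], 8)
  tables <- list()
  for (l in seq_len(cfg$n_lines)) {
    noise_kd <- stats::rlnorm(cfg$n_genes, 0, cfg$expression_noise_sigma)
    noise_ct <- stats::rlnorm(cfg$n_genes, 0, cfg$expression_noise_sigma)
    kd <- baseline * ratio[, l] * noise_kd
    ct <- baseline * noise_ct
    kd[below_idx] <- kd[below_idx] * 0.02 / baseline[below_idx]
    tables[[lines[l]]] <- expression_table(gene_ids, kd, ct,
                                           cell_line = lines[l])
  }

  ## 5. genome sequence -------------------------------------------------
  genome_chr <- lapply(seq_len(cfg$n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$contig_length, replace = TRUE),
          collapse = "")
  })
  names(genome_chr) <- sprintf("chr%d", seq_len(cfg$n_contigs))

  ## 6. peaks per line (+ motif insertions at true peaks) ---------------
  half <- floor(cfg$peak_width / 2)
  peaks <- list()
  truth_dist <- matrix(NA_real_, cfg$n_genes, cfg$n_lines,
                       dimnames = list(gene_ids, lines))
  for (l in seq_len(cfg$n_lines)) {
    dmag <- stats::runif(length(direct_idx),
                         cfg$true_peak_distance_range[1],
                         cfg$true_peak_distance_range[2])
    dsign <- sample(c(-1, 1), length(direct_idx), replace = TRUE)
    dist <- round(dmag * dsign)
    truth_dist[direct_idx, l] <- dist
    gdir <- ifelse(genes$strand[direct_idx] == "+", 1, -1)
    mid_true <- genes$tss[direct_idx] + dist * gdir
    chrom_true <- genes$chrom[direct_idx]
    mid_dec <- round(stats::runif(cfg$n_decoy_peaks, half + 1,
                                  cfg$contig_length - half - 1))
    chrom_dec <- sprintf("chr%d", sample.int(cfg$n_contigs,
                                             cfg$n_decoy_peaks,
                                             replace = TRUE))
    # true binding sites tend to rank above decoys, with overlap
    score_true <- stats::runif(length(direct_idx), 50, 100)
    score_dec <- stats::runif(cfg$n_decoy_peaks, 0, 90)
    mid <- c(mid_true, mid_dec)
    chrom <- c(chrom_true, chrom_dec)
    peaks[[lines[l]]] <- peak_set(chrom, mid - half, mid + half,
                                  c(score_true, score_dec))
    insert <- stats::runif(length(direct_idx)) < cfg$motif_insertion_rate
    for (j in which(insert)) {
      pos <- mid_true[j] + 1  # 1-based insert position at window center
      chr <- chrom_true[j]
      if (pos + nchar(cfg$motif) - 1 <= cfg$contig_length && pos >= 1) {
        substr(genome_chr[[chr]], pos, pos + nchar(cfg$motif) - 1) <-
          cfg$motif
      }
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(genome_chr))

  ## 7. tumor cohort -----------------------------------------------------
  n_samp <- cfg$n_amplified + cfg$n_nonamplified + cfg$n_indeterminate
  samples <- sprintf("S%03d", seq_len(n_samp))
  group <- rep(c("amp", "nonamp", "indet"),
               c(cfg$n_amplified, cfg$n_nonamplified, cfg$n_indeterminate))
  cn <- numeric(n_samp)
  cn[group == "amp"] <- stats::runif(cfg$n_amplified,
                                     cfg$cn_amplified_range[1],
                                     cfg$cn_amplified_range[2])
  cn[group == "nonamp"] <- stats::runif(cfg$n_nonamplified,
                                        cfg$cn_nonamplified_range[1],
                                        cfg$cn_nonamplified_range[2])
  cn[group == "indet"] <- stats::runif(cfg$n_indeterminate,
                                       cfg$cn_indeterminate_range[1],
                                       cfg$cn_indeterminate_range[2])
  names(cn) <- samples
  index_gene <- "TFX"
  mu_g <- stats::rnorm(cfg$n_genes, cfg$cohort_baseline_mean,
                       cfg$cohort_baseline_sd)
  expr <- matrix(stats::rnorm(cfg$n_genes * n_samp, mean = mu_g,
                              sd = cfg$cohort_noise_sd),
                 cfg$n_genes, n_samp, dimnames = list(gene_ids, samples))
  expr[direct_idx, group == "amp"] <-
    expr[direct_idx, group == "amp"] + cfg$amplified_effect_log2
  tf_expr <- stats::rnorm(n_samp, cfg$cohort_baseline_mean,
                          cfg$cohort_noise_sd)
  tf_expr[group == "amp"] <- tf_expr[group == "amp"] +
    cfg$amplified_index_shift_log2
  expr <- rbind(expr, matrix(tf_expr, 1, n_samp,
                             dimnames = list(index_gene, samples)))
  study <- cohort_study(expr, cn, index_gene, scale = "log2")

  ## 8. gene sets --------------------------------------------------------
  planted_set <- sort(gene_ids[sample(direct_idx, cfg$planted_set_size)])
  sets <- list(PLANTED_DIRECT = planted_set)
  for (k in seq_len(cfg$n_decoy_sets)) {
    sets[[sprintf("DECOY%02d", k)]] <-
      sort(gene_ids[sample(null_idx, cfg$planted_set_size)])
  }

  ## 9. truth table ------------------------------------------------------
  truth <- data.frame(gene = gene_ids, role = roles,
                      is_direct = roles == "direct",
                      is_indirect = roles == "indirect",
                      below_filter = seq_len(cfg$n_genes) %in% below_idx,
                      cohort_shift = ifelse(roles == "direct",
                                            cfg$amplified_effect_log2, 0),
                      stringsAsFactors = FALSE)
  for (l in seq_len(cfg$n_lines)) {
    truth[[paste0("ratio_", lines[l])]] <- ratio[, l]
    truth[[paste0("peak_dist_", lines[l])]] <- truth_dist[, l]
  }

  ## 10. write files ------------------------------------------------------
  paths <- list()
  for (ln in lines) {
    p <- file.path(out_dir, paste0("expression_", ln, ".tsv"))
    write_expression(tables[[ln]], p)
    paths[[paste0("expression_", ln)]] <- p
    pk <- peaks[[ln]]
    p2 <- file.path(out_dir, paste0("peaks_", ln, ".bed"))
    bed <- data.frame(pk$chrom, as.integer(pk$start), as.integer(pk$end),
                      pk$peak_id, pk$score)
    utils::write.table(bed, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[[paste0("peaks_", ln)]] <- p2
  }
  p <- file.path(out_dir, "genes.bed")
  utils::write.table(
    data.frame(genes$chrom, as.integer(genes$span_start),
               as.integer(genes$span_end), genes$gene, 0, genes$strand),
    p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths$genes <- p
  p <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, p)
  paths$genome <- p
  p <- file.path(out_dir, "cohort_expression.tsv")
  utils::write.table(data.frame(gene = rownames(expr), expr,
                                check.names = FALSE),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$cohort_expression <- p
  p <- file.path(out_dir, "cohort_samples.tsv")
  utils::write.table(data.frame(sample = samples, cn_ratio = cn),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$cohort_samples <- p
  p <- file.path(out_dir, "sets.gmt")
  write_gmt(sets, p)
  paths$sets <- p
  p <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth <- p
  manifest <- data.frame(name = names(paths),
                         file = basename(unlist(paths)),
                         stringsAsFactors = FALSE)
  p <- file.path(out_dir, "MANIFEST.tsv")
  utils::write.table(manifest, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$manifest <- p

  list(config = cfg, paths = paths, truth = truth, lines = lines,
       tables = tables, peaks = peaks, genes = genes, genome = genome,
       study = study, sets = sets)
}

#' Score recovered candidates against the planted truth
#'
#' Precision is the fraction of distinct candidate genes that are planted
#' direct targets; recall is the fraction of planted direct targets
#' recovered by at least one candidate row. With no candidates, precision is
#' undefined (`NA`) and recall is 0.
#'
#' @param candidates [integrate_candidates()] output (or any data frame
#'   with a `gene` column).
#' @param truth Truth table from [simulate_bundle()].
#' @return A list with `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `n_candidates`.
#' @export
evaluate_recovery <- function(candidates, truth) {
  if (nrow(truth) == 0) stop("empty truth table")
  cand <- unique(candidates$gene)
  planted <- truth$gene[truth$is_direct]
  tp <- length(intersect(cand, planted))
  fp <- length(setdiff(cand, planted))
  fn <- length(setdiff(planted, cand))
  list(precision = if (length(cand) > 0) tp / length(cand) else NA_real_,
       recall = if (length(planted) > 0) tp / length(planted) else NA_real_,
       tp = tp, fp = fp, fn = fn, n_candidates = length(cand))
}

#' Run the full integrative pipeline on a simulated (or equivalent) bundle
#'
#' Convenience driver: classifies knockdown responses per line, annotates
#' peaks to nearest TSSs, stratifies the cohort and runs the two-class SAM
#' test, then intersects all three evidence layers into the candidate table.
#'
#' @param bundle A [simulate_bundle()] result (in-memory objects are used
#'   directly).
#' @param seed Seed for the SAM permutations.
#' @param min_abundance,threshold Response-classification parameters.
#' @param window Peak annotation window in bp.
#' @param n_perm SAM permutations.
#' @param fdr_threshold Cohort FDR bound for candidacy.
#' @return A list with `responses`, `annotations`, `peak_ranks`, `labels`,
#'   `sam`, `candidates`, `recovery` (when the bundle carries a truth
#'   table).
#' @export
run_pipeline <- function(bundle, seed, min_abundance = 1, threshold = 0.25,
                         window = 100000, n_perm = 200,
                         fdr_threshold = 0.10) {
  responses <- lapply(bundle$tables, compute_response,
                      min_abundance = min_abundance, threshold = threshold)
  ann <- lapply(bundle$peaks, annotate_peaks, genes = bundle$genes,
                window = window)
  peak_ranks <- lapply(ann, `[[`, "gene_peak_rank")
  labels <- define_groups(bundle$study)
  sam <- sam_two_class(bundle$study$expression, labels, n_perm = n_perm,
                       seed = seed)
  candidates <- integrate_candidates(responses, peak_ranks, sam,
                                     direction = "down",
                                     fdr_threshold = fdr_threshold)
  out <- list(responses = responses, annotations = ann,
              peak_ranks = peak_ranks, labels = labels, sam = sam,
              candidates = candidates)
  if (!is.null(bundle$truth)) {
    out$recovery <- evaluate_recovery(candidates, bundle$truth)
  }
  out
}

#' Read a simulated bundle back from disk
#'
#' Loads the files written by [simulate_bundle()] from a directory via its
#' manifest, returning the same in-memory structure (minus the truth table
#' unless present).
#'
#' @param dir Directory containing `MANIFEST.tsv` and the bundle files.
#' @return A bundle list usable with [run_pipeline()].
#' @export
read_bundle <- function(dir) {
  man <- utils::read.delim(file.path(dir, "MANIFEST.tsv"),
                           stringsAsFactors = FALSE)
  get_path <- function(nm) file.path(dir, man$file[man$name == nm])
  lines <- sub("^expression_", "",
               man$name[grepl("^expression_", man$name)])
  tables <- lapply(stats::setNames(lines, lines), function(ln) {
    read_expression(get_path(paste0("expression_", ln)), cell_line = ln)
  })
  peaks <- lapply(stats::setNames(lines, lines), function(ln) {
    read_peaks(get_path(paste0("peaks_", ln)))
  })
  genes <- read_gene_models(get_path("genes"))
  genome <- Biostrings::readDNAStringSet(get_path("genome"))
  names(genome) <- sub("\\s.*", "", names(genome))
  ce <- utils::read.delim(get_path("cohort_expression"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(ce[, -1, drop = FALSE])
  rownames(expr) <- ce[[1]]
  cs <- utils::read.delim(get_path("cohort_samples"),
                          stringsAsFactors = FALSE)
  cn <- stats::setNames(cs$cn_ratio, cs$sample)
  study <- cohort_study(expr, cn, index_gene = "TFX", scale = "log2")
  sets <- read_gmt(get_path("sets"))
  truth <- if ("truth" %in% man$name) {
    utils::read.delim(get_path("truth"), stringsAsFactors = FALSE)
  } else NULL
  list(paths = NULL, truth = truth, lines = lines, tables = tables,
       peaks = peaks, genes = genes, genome = genome, study = study,
       sets = sets)
}
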