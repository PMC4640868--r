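# Small in-code fixtures shared across test files.

toy_table <- function(cell_line = "L1") {
  # genes straddling the RPKM filter and both response thresholds
  expression_table(
    gene      = c("A",  "B",  "C",  "D",  "E"),
    knockdown = c(2,    0.9,  1,    5,    7),
    control   = c(2,    5,    3,    0.2,  7),
    cell_line = cell_line
  )
}

random_table <- function(seed, n = 30, cell_line = "R") {
  set.seed(seed)
  expression_table(
    gene = sprintf("g%03d", seq_len(n)),
    knockdown = stats::rlnorm(n, 1, 1.2),
    control = stats::rlnorm(n, 1, 1.2),
    cell_line = cell_line
  )
}

# a fast-but-complete simulation configuration for pipeline tests
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         n_genes = 300, n_lines = 2,
         n_direct_targets = 15, n_indirect_targets = 20,
         n_contigs = 2, contig_length = 5e5,
         n_decoy_peaks = 80,
         n_amplified = 15, n_nonamplified = 30, n_indeterminate = 10,
         planted_set_size = 10, n_decoy_sets = 4),
    list(...))
  do.call(simulation_config, args)
}

random_cohort <- function(seed, m = 100, na = 10, nb = 20, shift = 0,
                          shifted = integer()) {
  set.seed(seed)
  x <- matrix(stats::rnorm(m * (na + nb)), m, na + nb,
              dimnames = list(sprintf("g%03d", seq_len(m)),
                              sprintf("s%02d", seq_len(na + nb))))
  if (length(shifted) > 0) x[shifted, seq_len(na)] <-
      x[shifted, seq_len(na)] + shift
  list(x = x, labels = rep(c("A", "B"), c(na, nb)))
}
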