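# Small in-code fixtures shared across test files.

make_track <- function(starts, ends, chrom = "chr1", sample_id = "s1",
                       tumor_type = "T01") {
  sample_track(sample_id, tumor_type,
               data.frame(chrom = chrom, start = as.integer(starts),
                          end = as.integer(ends)))
}

make_tss <- function(pos, genes = NULL, chrom = "chr1", strand = "+") {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_along(pos))
  data.frame(gene_id = genes, gene_symbol = genes,
             chrom = rep_len(chrom, length(pos)),
             tss = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             stringsAsFactors = FALSE)
}

# PWM with the given consensus: count 17 for the consensus base, 1
# elsewhere (0.75 vs 1/12 probabilities after a +1-equivalent smoothing)
make_pwm <- function(consensus, id = "MX0001", tf = "TFX") {
  b <- c("A", "C", "G", "T")
  mot <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, length(mot), 4, dimnames = list(NULL, b))
  counts[cbind(seq_along(mot), match(mot, b))] <- 17
  structure(list(motif_id = id, tf_name = tf,
                 matrix = counts / rowSums(counts),
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
            class = "secrc_pwm")
}

# exact-match PWM (probability-1 rows), as in controlled scanning tests
make_exact_pwm <- function(consensus, id = "MEX", tf = "TFEX") {
  b <- c("A", "C", "G", "T")
  mot <- strsplit(consensus, "")[[1]]
  mat <- matrix(0, length(mot), 4, dimnames = list(NULL, b))
  mat[cbind(seq_along(mot), match(mot, b))] <- 1
  structure(list(motif_id = id, tf_name = tf, matrix = mat,
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
            class = "secrc_pwm")
}

rand_seqs <- function(n, len) {
  s <- paste(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
             collapse = "")
  substring(s, seq(1, n * len, len), seq(len, n * len, len))
}

# small, fast synthetic study used by module tests
small_config <- function(seed = 11, n_specific_ses_per_type = 1,
                         constituent_signal_fold = 8) {
  synthetic_config(n_tumor_types = 3, cell_lines_per_type = 2,
                   genome_length = 2e6, n_shared_ses = 4,
                   n_specific_ses_per_type = n_specific_ses_per_type,
                   n_typical = 10, fragments_per_sample = 8000,
                   se_constituents = 3,
                   constituent_signal_fold = constituent_signal_fold,
                   seed = seed)
}
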