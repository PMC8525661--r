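#' Configuration for the synthetic ChIP-seq data generator
#'
#' Describes a toy study: one chromosome, several tumor types with a few
#' cell lines each, planted super-enhancers (clusters of high-signal
#' constituent peaks) shared across all types or specific to one, isolated
#' typical enhancers, and a fully interconnected autoregulated TF triad
#' whose SE nucleosome-free regions carry all three TF motifs.
#'
#' @param n_tumor_types Number of tumor types (default 8).
#' @param cell_lines_per_type Cell lines per tumor type (default 3).
#' @param genome_length Length of the single synthetic chromosome
#'   (default 5e6).
#' @param n_shared_ses SEs present in every tumor type (default 8).
#' @param n_specific_ses_per_type SEs present in exactly one type
#'   (default 2).
#' @param n_typical Isolated typical enhancers, present in all samples
#'   (default 30).
#' @param fragments_per_sample Sequencing depth per sample (default 5e4).
#' @param se_constituents Constituent peaks per SE (default 4).
#' @param constituent_signal_fold Fragment rate of an SE constituent
#'   relative to a typical enhancer (default 8; must exceed 1).
#' @param n_clique_tfs Size of the planted autoregulated TF clique
#'   (default 3, mirroring a bladder-cancer style SMAD3/ETS1/HOXB2 triad).
#' @param background_fraction Fraction of fragments placed uniformly on the
#'   genome (default 0.1).
#' @param fragment_length Fixed fragment length in bp (default 200).
#' @param fragment_sd SD of fragment centers around an enhancer center
#'   (default 500).
#' @param seed RNG seed; the generator is fully deterministic given the
#'   seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_tumor_types = 8, cell_lines_per_type = 3,
                             genome_length = 5e6, n_shared_ses = 8,
                             n_specific_ses_per_type = 2, n_typical = 30,
                             fragments_per_sample = 50000,
                             se_constituents = 4,
                             constituent_signal_fold = 8,
                             n_clique_tfs = 3,
                             background_fraction = 0.1,
                             fragment_length = 200, fragment_sd = 500,
                             seed = 1) {
  cfg <- list(
    n_tumor_types = as.integer(n_tumor_types),
    cell_lines_per_type = as.integer(cell_lines_per_type),
    genome_length = as.integer(genome_length),
    n_shared_ses = as.integer(n_shared_ses),
    n_specific_ses_per_type = as.integer(n_specific_ses_per_type),
    n_typical = as.integer(n_typical),
    fragments_per_sample = as.integer(fragments_per_sample),
    se_constituents = as.integer(se_constituents),
    constituent_signal_fold = as.numeric(constituent_signal_fold),
    n_clique_tfs = as.integer(n_clique_tfs),
    background_fraction = as.numeric(background_fraction),
    fragment_length = as.integer(fragment_length),
    fragment_sd = as.numeric(fragment_sd),
    seed = as.integer(seed)
  )
  counts <- cfg[c("n_tumor_types", "cell_lines_per_type", "genome_length",
                  "n_shared_ses", "n_typical", "fragments_per_sample",
                  "se_constituents", "n_clique_tfs", "fragment_length")]
  if (any(unlist(counts) <= 0L)) {
    stop("all synthetic_config counts must be positive", call. = FALSE)
  }
  if (cfg$n_specific_ses_per_type < 0L) {
    stop("n_specific_ses_per_type must be >= 0", call. = FALSE)
  }
  if (cfg$constituent_signal_fold <= 1) {
    stop("constituent_signal_fold must exceed 1", call. = FALSE)
  }
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1) {
    stop("background_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# planted motif consensus sequences for the TF triad (extended if
# n_clique_tfs > 5)
.clique_motif_consensus <- function(k) {
  base <- c("ACCGGAAGTG", "CATGCCTAAG", "GTACGTCAGC", "TTGACCGATA",
            "CGGATATCCT")
  if (k <= length(base)) return(base[seq_len(k)])
  extra <- vapply(seq_len(k - length(base)), function(i)
    paste(c("A", "C", "G", "T")[1 + (i + 0:9) %% 4], collapse = ""),
    character(1))
  c(base, extra)
}

#' Generate a synthetic study with planted ground truth
#'
#' Writes every input format the pipeline reads - genome FASTA,
#' chrom.sizes, TSS BED6, per-sample narrowPeak and fragment BED files, NFR
#' BED, JASPAR PFM motif library, sample sheet, expression matrix - plus the
#' planted truth tables. Planted SEs are clusters of constituent peaks
#' (3 kb apart, so well within the 12.5 kb stitching distance) with fragment
#' rate `constituent_signal_fold` times the typical-enhancer rate; typical
#' enhancers are isolated. Shared SEs (and the TF-clique SEs) appear in all
#' tumor types, specific SEs in exactly one. Decoy significant peaks are
#' placed within 2.5 kb of every TSS to exercise the TSS-distance filter,
#' and a few sub-threshold peaks exercise the significance filter. Every NFR
#' of a TF-clique SE carries the consensus of all clique TF motifs, making
#' the triad fully interconnected and autoregulated. Output is byte-for-byte
#' deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `paths` (named file paths),
#'   `truth` (planted SEs, typical enhancers, clique, motif placements) and
#'   `config`.
#' @export
generate_synthetic <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_loci <- cfg$n_shared_ses + cfg$n_clique_tfs +
    cfg$n_tumor_types * cfg$n_specific_ses_per_type + cfg$n_typical
  spacing <- cfg$genome_length %/% (n_loci + 1L)
  cluster_half <- ((cfg$se_constituents - 1L) * 3000L) %/% 2L
  if (spacing < max(36000L, 2L * (cluster_half + 5500L) + 13000L)) {
    stop(sprintf(
      "genome too small: %d loci need spacing >= 36 kb, got %d bp",
      n_loci, spacing), call. = FALSE)
  }
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "fragments"), showWarnings = FALSE)

  types <- sprintf("T%02d", seq_len(cfg$n_tumor_types))
  tf_names <- paste0("TF", LETTERS[seq_len(cfg$n_clique_tfs)])

  # --- locus table -------------------------------------------------------
  loci <- data.frame(
    class = c(rep("shared", cfg$n_shared_ses),
              rep("tf", cfg$n_clique_tfs),
              rep("specific",
                  cfg$n_tumor_types * cfg$n_specific_ses_per_type),
              rep("typical", cfg$n_typical)),
    stringsAsFactors = FALSE
  )
  loci$tumor_type <- NA_character_
  spec_rows <- which(loci$class == "specific")
  if (length(spec_rows) > 0L) {
    loci$tumor_type[spec_rows] <- rep(types,
                                      each = cfg$n_specific_ses_per_type)
  }
  loci$gene <- NA_character_
  loci$gene[loci$class == "shared"] <-
    sprintf("GENES%02d", seq_len(cfg$n_shared_ses))
  loci$gene[loci$class == "tf"] <- tf_names
  if (length(spec_rows) > 0L) {
    loci$gene[spec_rows] <- sprintf(
      "GENEX_%s_%d", loci$tumor_type[spec_rows],
      rep(seq_len(cfg$n_specific_ses_per_type), times = cfg$n_tumor_types))
  }
  loci$gene[loci$class == "typical"] <-
    sprintf("GENET%02d", seq_len(cfg$n_typical))
  # shuffle locus order along the chromosome
  loci <- loci[sample.int(nrow(loci)), , drop = FALSE]
  loci$center <- spacing * seq_len(nrow(loci))
  rownames(loci) <- NULL

  # constituent peak midpoints per locus (single peak for typical)
  const_mids <- lapply(seq_len(nrow(loci)), function(i) {
    if (loci$class[i] == "typical") return(loci$center[i])
    k <- cfg$se_constituents
    loci$center[i] + as.integer((seq_len(k) - (k + 1) / 2) * 3000)
  })

  # --- TSS annotation (BED6) --------------------------------------------
  tss_pos <- loci$center + 15000L
  tss_df <- data.frame(chrom = "chr1", start = tss_pos,
                       end = tss_pos + 1000L, name = loci$gene,
                       score = 0L, strand = "+")
  tss_df <- tss_df[order(tss_df$start), ]
  p_tss <- file.path(out_dir, "tss.bed")
  write.table(tss_df, p_tss, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # --- genome with planted motifs in TF-SE NFRs -------------------------
  bases <- c("A", "C", "G", "T")
  genome_chars <- sample(bases, cfg$genome_length, replace = TRUE)
  consensus <- .clique_motif_consensus(cfg$n_clique_tfs)
  motif_ids <- sprintf("MA%04d", seq_len(cfg$n_clique_tfs))
  nfr_rows <- list()
  placements <- list()
  for (i in seq_len(nrow(loci))) {
    if (loci$class[i] == "typical") next
    for (mid in const_mids[[i]]) {
      nfr_s <- mid - 60L
      nfr_e <- mid + 60L
      nfr_rows[[length(nfr_rows) + 1L]] <-
        data.frame(chrom = "chr1", start = nfr_s, end = nfr_e,
                   name = sprintf("nfr_%s", loci$gene[i]),
                   stringsAsFactors = FALSE)
      if (loci$class[i] == "tf") {
        # all clique motifs in every NFR of every TF SE
        for (m in seq_len(cfg$n_clique_tfs)) {
          off <- nfr_s + 5L + (m - 1L) * 15L
          mot <- strsplit(consensus[m], "")[[1L]]
          genome_chars[(off + 1L):(off + length(mot))] <- mot
          placements[[length(placements) + 1L]] <-
            data.frame(pwm_id = motif_ids[m], chrom = "chr1",
                       start = off, end = off + length(mot),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chr1"
  p_genome <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, p_genome, width = 80L)
  p_sizes <- file.path(out_dir, "chrom.sizes")
  writeLines(sprintf("chr1\t%d", cfg$genome_length), p_sizes)

  nfr_df <- do.call(rbind, nfr_rows)
  p_nfr <- file.path(out_dir, "nfr.bed")
  write.table(nfr_df, p_nfr, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # --- PFM library -------------------------------------------------------
  p_pfm <- file.path(out_dir, "motifs.pfm")
  pfm_lines <- character(0)
  for (m in seq_len(cfg$n_clique_tfs)) {
    mot <- strsplit(consensus[m], "")[[1L]]
    counts <- matrix(1L, nrow = length(mot), ncol = 4L,
                     dimnames = list(NULL, bases))
    counts[cbind(seq_along(mot), match(mot, bases))] <- 17L
    pfm_lines <- c(pfm_lines, sprintf(">%s %s", motif_ids[m], tf_names[m]),
                   vapply(seq_len(4L), function(b)
                     sprintf("%s [ %s ]", bases[b],
                             paste(counts[, b], collapse = " ")),
                     character(1)))
  }
  writeLines(pfm_lines, p_pfm)

  # --- per-sample peaks and fragments -----------------------------------
  samples <- data.frame(
    sample_id = as.vector(t(outer(types, seq_len(cfg$cell_lines_per_type),
                                  function(t, i) sprintf("%s_CL%d", t, i)))),
    tumor_type = rep(types, each = cfg$cell_lines_per_type),
    stringsAsFactors = FALSE
  )
  p_sheet <- file.path(out_dir, "sample_sheet.tsv")
  write.table(samples, p_sheet, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)

  frag_half <- cfg$fragment_length %/% 2L
  peak_paths <- character(nrow(samples))
  frag_paths <- character(nrow(samples))
  for (s in seq_len(nrow(samples))) {
    tt <- samples$tumor_type[s]
    active <- which(loci$class %in% c("shared", "tf", "typical") |
                    (loci$class == "specific" & loci$tumor_type == tt))
    # element table: one row per constituent peak
    el_mid <- unlist(const_mids[active], use.names = FALSE)
    el_class <- rep(loci$class[active],
                    times = lengths(const_mids[active]))
    el_gene <- rep(loci$gene[active], times = lengths(const_mids[active]))
    el_weight <- ifelse(el_class == "typical", 1,
                        cfg$constituent_signal_fold)

    # fragments: multinomial allocation over elements + uniform background
    n_bg <- as.integer(round(cfg$background_fraction *
                             cfg$fragments_per_sample))
    n_enh <- cfg$fragments_per_sample - n_bg
    alloc <- as.vector(rmultinom(1L, n_enh, el_weight / sum(el_weight)))
    centers <- unlist(lapply(seq_along(el_mid), function(e)
      rnorm(alloc[e], mean = el_mid[e], sd = cfg$fragment_sd)),
      use.names = FALSE)
    bg_centers <- runif(n_bg, min = frag_half,
                        max = cfg$genome_length - frag_half)
    centers <- round(c(centers, bg_centers))
    fs <- pmax(0L, as.integer(centers) - frag_half)
    fe <- pmin(cfg$genome_length, fs + cfg$fragment_length)
    frag <- data.frame(chrom = "chr1", start = fs, end = fe)
    frag <- frag[order(frag$start), ]
    frag_paths[s] <- file.path(out_dir, "fragments",
                               paste0(samples$sample_id[s], ".bed"))
    write.table(frag, frag_paths[s], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)

    # peaks: planted constituents, decoys near each TSS, sub-threshold decoys
    pk <- data.frame(
      chrom = "chr1", start = el_mid - 500L, end = el_mid + 500L,
      name = sprintf("%s_pk%d", el_gene, seq_along(el_mid)),
      score = 1000L, strand = ".",
      signal = round(el_weight * 10, 2),
      neg_log10_p = round(runif(length(el_mid), 30, 120), 2),
      neg_log10_q = round(runif(length(el_mid), 20, 100), 2),
      summit = 500L, stringsAsFactors = FALSE
    )
    decoy <- data.frame(
      chrom = "chr1", start = tss_pos - 1200L, end = tss_pos - 200L,
      name = sprintf("decoy_%s", loci$gene), score = 1000L, strand = ".",
      signal = 10, neg_log10_p = 50, neg_log10_q = 40, summit = 500L,
      stringsAsFactors = FALSE
    )
    weak_at <- head(loci$center[loci$class == "typical"], 3L)
    weak <- data.frame(
      chrom = rep("chr1", length(weak_at)),
      start = weak_at + 20000L, end = weak_at + 21000L,
      name = sprintf("weak_%d", seq_along(weak_at)), score = 100L,
      strand = ".", signal = 2, neg_log10_p = 5, neg_log10_q = 3,
      summit = 500L, stringsAsFactors = FALSE
    )
    pk <- rbind(pk, decoy, weak)
    pk <- pk[order(pk$start), ]
    peak_paths[s] <- file.path(out_dir, "peaks",
                               paste0(samples$sample_id[s], ".narrowPeak"))
    write.table(pk, peak_paths[s], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }

  # --- expression matrix (FPKM-like) ------------------------------------
  genes <- sort(loci$gene)
  base_expr <- runif(length(genes), 3, 8)
  names(base_expr) <- genes
  expr <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  se_in_type <- function(gene, tt) {
    cls <- loci$class[loci$gene == gene]
    cls %in% c("shared", "tf") ||
      (cls == "specific" && loci$tumor_type[loci$gene == gene] == tt)
  }
  for (s in seq_len(nrow(samples))) {
    tt <- samples$tumor_type[s]
    boost <- vapply(genes, se_in_type, logical(1), tt = tt)
    expr[, s] <- round(pmax(0, base_expr + 40 * boost +
                              rnorm(length(genes), 0, 1)), 3)
  }
  p_expr <- file.path(out_dir, "expression.tsv")
  write.table(data.frame(gene = rownames(expr), expr,
                         check.names = FALSE),
              p_expr, sep = "\t", quote = FALSE, row.names = FALSE)

  # --- truth -------------------------------------------------------------
  se_rows <- which(loci$class != "typical")
  se_span <- data.frame(
    chrom = "chr1",
    start = vapply(const_mids[se_rows], min, numeric(1)) - 5000L,
    end = vapply(const_mids[se_rows], max, numeric(1)) + 5000L,
    gene = loci$gene[se_rows],
    class = loci$class[se_rows],
    tumor_type = loci$tumor_type[se_rows],
    stringsAsFactors = FALSE
  )
  planted_ses <- do.call(rbind, lapply(types, function(tt) {
    rows <- se_span$class %in% c("shared", "tf") |
      (!is.na(se_span$tumor_type) & se_span$tumor_type == tt)
    out <- se_span[rows, c("chrom", "start", "end", "gene", "class")]
    out$tumor_type <- tt
    out
  }))
  rownames(planted_ses) <- NULL
  typ_rows <- which(loci$class == "typical")
  planted_typical <- data.frame(
    chrom = "chr1",
    start = vapply(const_mids[typ_rows], min, numeric(1)) - 5000L,
    end = vapply(const_mids[typ_rows], max, numeric(1)) + 5000L,
    gene = loci$gene[typ_rows], stringsAsFactors = FALSE
  )
  truth <- list(
    planted_ses = planted_ses,
    planted_typical = planted_typical,
    planted_clique = tf_names,
    motif_placements = do.call(rbind, placements),
    seed = cfg$seed
  )
  p_truth <- file.path(out_dir, "truth_ses.tsv")
  write.table(planted_ses, p_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(
    dir = out_dir,
    paths = list(genome = p_genome, chrom_sizes = p_sizes, tss = p_tss,
                 nfr = p_nfr, pwm = p_pfm, sample_sheet = p_sheet,
                 expression = p_expr,
                 peaks = setNames(peak_paths, samples$sample_id),
                 fragments = setNames(frag_paths, samples$sample_id)),
    truth = truth,
    config = cfg
  ))
}

#' Compare pipeline output against planted synthetic truth
#'
#' SE calls match a planted SE of the same tumor type under reciprocal
#' overlap of at least `overlap_fraction`. Gene categories and the TF clique
#' are compared as sets. Precision with zero calls is reported as `NA`
#' (undefined), never as an error.
#'
#' @param calls List with any of: `merged_ses` ([merge_ses()] output),
#'   `gene_freq` ([gene_frequency_table()] output), `top_cliques` (list of
#'   character vectors, the top-scored clique per tumor type).
#' @param truth The `truth` element of [generate_synthetic()]'s return.
#' @param overlap_fraction Reciprocal overlap required for an SE match
#'   (default 0.5).
#' @param n_tumor_types Number of tumor types in the study (used for the
#'   conservative-gene truth threshold; default 8).
#' @return `data.frame` with one row per layer: `layer`, `precision`,
#'   `recall`, `n_called`, `n_truth`.
#' @export
truth_compare <- function(calls, truth, overlap_fraction = 0.5,
                          n_tumor_types = 8) {
  rows <- list()
  if (!is.null(calls$merged_ses)) {
    called <- calls$merged_ses
    tr <- truth$planted_ses
    matched_call <- logical(nrow(called))
    matched_truth <- logical(nrow(tr))
    if (nrow(called) > 0L && nrow(tr) > 0L) {
      for (i in seq_len(nrow(called))) {
        cand <- which(tr$tumor_type == called$tumor_type[i] &
                      tr$chrom == called$chrom[i])
        for (j in cand) {
          ov <- min(called$end[i], tr$end[j]) -
            max(called$start[i], tr$start[j])
          if (ov >= overlap_fraction * (called$end[i] - called$start[i]) &&
              ov >= overlap_fraction * (tr$end[j] - tr$start[j])) {
            matched_call[i] <- TRUE
            matched_truth[j] <- TRUE
          }
        }
      }
    }
    rows[["se"]] <- data.frame(
      layer = "super_enhancer",
      precision = if (nrow(called) == 0L) NA_real_ else
        sum(matched_call) / nrow(called),
      recall = if (nrow(tr) == 0L) NA_real_ else
        sum(matched_truth) / nrow(tr),
      n_called = nrow(called), n_truth = nrow(tr),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(calls$gene_freq)) {
    gf <- calls$gene_freq
    truth_freq <- table(truth$planted_ses$gene)
    truth_cons <- names(truth_freq)[truth_freq > min(6, n_tumor_types - 1)]
    truth_spec <- names(truth_freq)[truth_freq == 1]
    for (cat in c("conservative", "specific")) {
      called_set <- gf$gene_symbol[gf$category == cat]
      truth_set <- if (cat == "conservative") truth_cons else truth_spec
      inter <- length(intersect(called_set, truth_set))
      rows[[paste0("gene_", cat)]] <- data.frame(
        layer = paste0("gene_", cat),
        precision = if (length(called_set) == 0L) NA_real_ else
          inter / length(called_set),
        recall = if (length(truth_set) == 0L) NA_real_ else
          inter / length(truth_set),
        n_called = length(called_set), n_truth = length(truth_set),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(calls$top_cliques)) {
    called_set <- sort(unique(unlist(calls$top_cliques)))
    truth_set <- truth$planted_clique
    inter <- length(intersect(called_set, truth_set))
    rows[["clique"]] <- data.frame(
      layer = "tf_clique",
      precision = if (length(called_set) == 0L) NA_real_ else
        inter / length(called_set),
      recall = if (length(truth_set) == 0L) NA_real_ else
        inter / length(truth_set),
      n_called = length(called_set), n_truth = length(truth_set),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
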