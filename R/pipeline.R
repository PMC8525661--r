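# End-to-end orchestration: YAML config, stage-wise execution, provenance.

.config_defaults <- function() {
  list(
    paths = list(
      sample_sheet = NULL, peaks_dir = NULL, fragments_dir = NULL,
      tss = NULL, genome = NULL, nfr = NULL, pwm = NULL,
      chrom_sizes = NULL, expression = NULL, output_dir = NULL
    ),
    parameters = list(
      p_threshold = 1e-9, min_tss_distance = 2500, bin_size = 100,
      corr_bin_size = 2000, stitch_distance = 12500, min_cell_lines = 2,
      gene_conservative_gt = 6, tf_conservative_gt = 4,
      motif_threshold = 0.8, min_clique_size = 2,
      enrichment_alpha = 0.05, n_background_nfrs = 200
    ),
    seed = 1
  )
}

.param_ranges <- list(
  p_threshold = c(0, 1), min_tss_distance = c(0, Inf),
  bin_size = c(1, Inf), corr_bin_size = c(1, Inf),
  stitch_distance = c(0, Inf), min_cell_lines = c(1, Inf),
  gene_conservative_gt = c(0, Inf), tf_conservative_gt = c(0, Inf),
  motif_threshold = c(0, 1), min_clique_size = c(1, Inf),
  enrichment_alpha = c(0, 1), n_background_nfrs = c(1, Inf)
)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent nested list), fills defaults,
#' rejects unknown keys (suggesting the closest known key), and range-checks
#' every numeric parameter.
#'
#' @param config Path to a YAML file, or a nested list with optional
#'   `paths`, `parameters` and `seed` entries. An empty file yields all
#'   defaults.
#' @return A validated `secrc_config` list with `paths`, `parameters`,
#'   `seed`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- .config_defaults()
  .reject_unknown(names(config), names(defaults), "config")
  out <- defaults
  for (sec in c("paths", "parameters")) {
    user <- config[[sec]]
    if (is.null(user)) next
    .reject_unknown(names(user), names(defaults[[sec]]), sec)
    for (k in names(user)) out[[sec]][[k]] <- user[[k]]
  }
  if (!is.null(config$seed)) out$seed <- config$seed
  for (k in names(out$parameters)) {
    v <- out$parameters[[k]]
    rng <- .param_ranges[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v <= rng[1L] || v > rng[2L]) {
      stop(sprintf("parameter '%s' = %s out of range (%g, %g]",
                   k, format(v), rng[1L], rng[2L]), call. = FALSE)
    }
  }
  if (!is.numeric(out$seed) || length(out$seed) != 1L) {
    stop("seed must be a single integer", call. = FALSE)
  }
  out$seed <- as.integer(out$seed)
  class(out) <- "secrc_config"
  out
}

.reject_unknown <- function(keys, known, where) {
  unknown <- setdiff(keys, known)
  if (length(unknown) == 0L) return(invisible())
  k <- unknown[1L]
  d <- utils::adist(k, known)
  hint <- if (min(d) <= 3L) sprintf(" - did you mean '%s'?",
                                    known[which.min(d)]) else ""
  stop(sprintf("unknown %s key '%s'%s", where, k, hint), call. = FALSE)
}

#' Point a configuration at a directory of pipeline inputs
#'
#' Convenience for directories laid out like [generate_synthetic()] output:
#' fills all input paths from their fixed file names.
#'
#' @param input_dir Directory holding `sample_sheet.tsv`, `peaks/`,
#'   `fragments/`, `tss.bed`, `genome.fa`, `nfr.bed`, `motifs.pfm`,
#'   `chrom.sizes` and optionally `expression.tsv`.
#' @param output_dir Where pipeline outputs go.
#' @param parameters,seed Optional overrides, as in [validate_config()].
#' @return A validated `secrc_config`.
#' @export
config_from_dir <- function(input_dir, output_dir,
                            parameters = list(), seed = 1) {
  expr_path <- file.path(input_dir, "expression.tsv")
  validate_config(list(
    paths = list(
      sample_sheet = file.path(input_dir, "sample_sheet.tsv"),
      peaks_dir = file.path(input_dir, "peaks"),
      fragments_dir = file.path(input_dir, "fragments"),
      tss = file.path(input_dir, "tss.bed"),
      genome = file.path(input_dir, "genome.fa"),
      nfr = file.path(input_dir, "nfr.bed"),
      pwm = file.path(input_dir, "motifs.pfm"),
      chrom_sizes = file.path(input_dir, "chrom.sizes"),
      expression = if (file.exists(expr_path)) expr_path else NULL,
      output_dir = output_dir
    ),
    parameters = parameters,
    seed = seed
  ))
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[secrc] stage %-12s %6.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

.require_path <- function(path, what, stage) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("stage '%s' aborted: missing %s file '%s'",
                 stage, what, if (is.null(path)) "<unset>" else path),
         call. = FALSE)
  }
  path
}

.write_tsv <- function(df, path) {
  listcols <- vapply(df, is.list, logical(1))
  for (cn in names(df)[listcols]) {
    df[[cn]] <- vapply(df[[cn]], function(v) paste(v, collapse = ","),
                       character(1))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  nrow(df)
}

#' Run the full SE-CRC pipeline
#'
#' Executes all stages in order on the inputs named by the configuration:
#' per-sample enhancer definition and signal quantification, ROSE-style
#' stitching and SE/TE classification, the genome-binned sample correlation
#' matrix, cross-cell-line SE merging per tumor type, SE-to-gene assignment
#' and gene frequency classification, NFR motif enrichment, TF frequency
#' classification, CRC graph and clique analysis, and (if an expression
#' matrix is configured) per-tumor-type expression summaries. Each output
#' table is written under `paths$output_dir` with a fixed name, and a
#' `manifest.json` records parameters, input checksums and output row
#' counts. Given identical inputs and configuration the run is
#' deterministic: the only randomness (background interval sampling for
#' enrichment) is seeded from `config$seed`.
#'
#' @param config A `secrc_config` from [validate_config()] or
#'   [config_from_dir()], or a path to a YAML config.
#' @return Invisibly, a list of the in-memory stage results plus `manifest`
#'   and `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "secrc_config")) config <- validate_config(config)
  p <- config$paths
  par <- config$parameters
  if (is.null(p$output_dir)) stop("paths$output_dir is required",
                                  call. = FALSE)
  dir.create(p$output_dir, showWarnings = FALSE, recursive = TRUE)

  # --- inputs ------------------------------------------------------------
  inputs <- .stage("inputs", {
    sheet_path <- .require_path(p$sample_sheet, "sample sheet", "inputs")
    sheet <- read.table(sheet_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "tumor_type") %in% names(sheet)))
    tss <- read_tss(.require_path(p$tss, "TSS", "enhancers"),
                    format = "bed6")
    sizes <- read_chrom_sizes(.require_path(p$chrom_sizes, "chrom.sizes",
                                            "correlate"))
    pwms <- read_pwms(.require_path(p$pwm, "PFM", "crc"))
    list(sheet = sheet, tss = tss, sizes = sizes, pwms = pwms)
  })
  sheet <- inputs$sheet
  tumor_of <- setNames(sheet$tumor_type, sheet$sample_id)

  # --- per-sample enhancers, signal, SE calling --------------------------
  per_sample <- .stage("rose", {
    lapply(seq_len(nrow(sheet)), function(i) {
      sid <- sheet$sample_id[i]
      pk_path <- .require_path(file.path(p$peaks_dir,
                                         paste0(sid, ".narrowPeak")),
                               "peak", "enhancers")
      fr_path <- .require_path(file.path(p$fragments_dir,
                                         paste0(sid, ".bed")),
                               "fragment", "signal")
      peaks <- filter_significant(read_peaks(pk_path, "narrowPeak"),
                                  par$p_threshold)
      enh <- define_enhancers(peaks, inputs$tss, par$min_tss_distance)
      track <- read_fragments(fr_path, sid, tumor_of[[sid]])
      enh <- quantify_enhancer_signal(enh, track, par$bin_size)
      st <- stitch(enh, par$stitch_distance)
      rc <- rank_and_cutoff(st)
      list(sample_id = sid, enhancers = enh, track = track,
           stitched = rc$stitched, cutoff = rc$cutoff,
           hockey = hockey_plot_data(rc))
    })
  })
  names(per_sample) <- sheet$sample_id

  out_counts <- list()
  enh_all <- do.call(rbind, lapply(per_sample, function(x)
    x$enhancers[, c("chrom", "start", "end", "name", "signal",
                    "sample_id")]))
  out_counts$enhancers.bed <-
    .write_tsv(enh_all, file.path(p$output_dir, "enhancers.bed"))
  ses_all <- do.call(rbind, lapply(per_sample, function(x) {
    st <- x$stitched
    data.frame(chrom = st$chrom, start = st$start, end = st$end,
               sample_id = x$sample_id, signal = st$signal,
               n_constituents = st$n_constituents, rank = st$rank,
               is_super = st$is_super, stringsAsFactors = FALSE)
  }))
  out_counts$ses.bed <- .write_tsv(ses_all,
                                   file.path(p$output_dir, "ses.bed"))
  hockey_all <- do.call(rbind, lapply(per_sample, function(x)
    cbind(sample_id = x$sample_id, x$hockey)))
  out_counts$hockey.tsv <- .write_tsv(hockey_all,
                                      file.path(p$output_dir, "hockey.tsv"))

  # --- genome-binned correlation ----------------------------------------
  corr <- .stage("correlate", {
    bm <- genome_bin_matrix(lapply(per_sample, `[[`, "track"),
                            inputs$sizes, par$corr_bin_size)
    sample_correlation(bm)
  })
  out_counts$correlation.tsv <- .write_tsv(
    data.frame(sample_id = rownames(corr), corr, check.names = FALSE),
    file.path(p$output_dir, "correlation.tsv"))

  # --- merge SEs per tumor type ------------------------------------------
  merged <- .stage("merge", {
    per_sample_ses <- lapply(per_sample, function(x) {
      st <- x$stitched
      st[st$is_super, c("chrom", "start", "end"), drop = FALSE]
    })
    merge_ses(per_sample_ses, tumor_of, par$min_cell_lines)
  })

  # --- gene assignment and frequency classification ----------------------
  gene_res <- .stage("genes", {
    assigned <- assign_genes(merged, inputs$tss)
    gf <- gene_frequency_table(assigned, par$gene_conservative_gt)
    list(assigned = assigned, gene_freq = gf)
  })
  merged <- gene_res$assigned
  out_counts$merged_ses.bed <- .write_tsv(
    merged, file.path(p$output_dir, "merged_ses.bed"))
  out_counts$gene_freq.tsv <- .write_tsv(
    gene_res$gene_freq, file.path(p$output_dir, "gene_freq.tsv"))

  # --- NFR motif enrichment and CRC per tumor type -----------------------
  crc_res <- .stage("crc", {
    genome <- .load_genome(.require_path(p$genome, "genome FASTA", "crc"))
    nfr_bed <- read_peaks(.require_path(p$nfr, "NFR BED", "crc"), "bed")
    nfr_iv <- nfr_bed[, c("chrom", "start", "end"), drop = FALSE]
    pwms <- inputs$pwms
    pwm_by_tf <- setNames(pwms, vapply(pwms, `[[`, character(1),
                                       "tf_name"))
    set.seed(config$seed)
    enr_rows <- list()
    edge_rows <- list()
    clique_rows <- list()
    enriched_by_type <- list()
    top_cliques <- list()
    for (tt in sort(unique(merged$tumor_type))) {
      mtt <- merged[merged$tumor_type == tt, , drop = FALSE]
      if (nrow(mtt) == 0L) next
      se_id <- sprintf("%s:%d-%d", mtt$chrom, mtt$start, mtt$end)
      consts <- data.frame(chrom = mtt$chrom, start = mtt$start,
                           end = mtt$end, name = se_id,
                           stringsAsFactors = FALSE)
      nfrs <- find_nfrs(consts, genome, mode = "provided", nfr = nfr_iv)
      # seeded random genomic background of matching widths
      w <- if (nrow(nfrs) > 0L) nfrs$end - nfrs$start else 120L
      bg_w <- sample(w, par$n_background_nfrs, replace = TRUE)
      chr1 <- names(genome)[1L]
      glen <- length(genome[[chr1]])
      bg_start <- floor(runif(par$n_background_nfrs, 0, glen - max(bg_w)))
      bg_seqs <- vapply(seq_len(par$n_background_nfrs), function(i)
        .genome_seq(genome, chr1, bg_start[i], bg_start[i] + bg_w[i]),
        character(1))
      enriched <- character(0)
      if (nrow(nfrs) > 0L) {
        for (pwm in pwms) {
          et <- enrichment_test(nfrs, bg_seqs, pwm, par$motif_threshold)
          et <- cbind(tumor_type = tt, et)
          enr_rows[[length(enr_rows) + 1L]] <- et
          if (et$p_value < par$enrichment_alpha) {
            enriched <- c(enriched, pwm$tf_name)
          }
        }
      }
      enriched_by_type[[tt]] <- enriched
      # CRC on TFs whose gene carries an SE in this type
      tf_rows <- which(mtt$gene_symbol %in% names(pwm_by_tf))
      if (length(tf_rows) > 0L) {
        tf_to_se <- setNames(se_id[tf_rows], mtt$gene_symbol[tf_rows])
        tf_to_se <- tf_to_se[!duplicated(names(tf_to_se))]
        nfrs_by_se <- split(nfrs$sequence, nfrs$parent)
        g <- build_crc(tf_to_se, nfrs_by_se, pwm_by_tf,
                       par$motif_threshold)
        if (nrow(g$edges) > 0L) {
          edge_rows[[length(edge_rows) + 1L]] <-
            cbind(tumor_type = tt, g$edges,
                  autoregulated = g$edges$from %in% g$autoregulated &
                    g$edges$from == g$edges$to)
        }
        cl <- enumerate_cliques(g, par$min_clique_size)
        if (nrow(cl) > 0L) {
          clique_rows[[length(clique_rows) + 1L]] <- data.frame(
            tumor_type = tt,
            members = vapply(cl$members, paste, character(1),
                             collapse = ","),
            size = cl$size, clique_score = cl$clique_score,
            stringsAsFactors = FALSE
          )
          top_cliques[[tt]] <- cl$members[[1L]]
        }
      }
    }
    list(
      enrichment = if (length(enr_rows)) do.call(rbind, enr_rows) else
        data.frame(tumor_type = character(0), pwm_id = character(0),
                   tf_name = character(0), n_target_hits = integer(0),
                   n_target = integer(0), n_background_hits = integer(0),
                   n_background = integer(0), p_value = numeric(0)),
      edges = if (length(edge_rows)) do.call(rbind, edge_rows) else
        data.frame(tumor_type = character(0), from = character(0),
                   to = character(0), autoregulated = logical(0)),
      cliques = if (length(clique_rows)) do.call(rbind, clique_rows) else
        data.frame(tumor_type = character(0), members = character(0),
                   size = integer(0), clique_score = numeric(0)),
      enriched_by_type = enriched_by_type,
      top_cliques = top_cliques,
      tf_freq = tf_frequency_table(enriched_by_type,
                                   par$tf_conservative_gt)
    )
  })
  out_counts$enrichment.tsv <- .write_tsv(
    crc_res$enrichment, file.path(p$output_dir, "enrichment.tsv"))
  out_counts$crc_edges.tsv <- .write_tsv(
    crc_res$edges, file.path(p$output_dir, "crc_edges.tsv"))
  out_counts$cliques.tsv <- .write_tsv(
    crc_res$cliques, file.path(p$output_dir, "cliques.tsv"))
  out_counts$tf_freq.tsv <- .write_tsv(
    crc_res$tf_freq, file.path(p$output_dir, "tf_freq.tsv"))

  # --- optional expression validation ------------------------------------
  expr_summary <- NULL
  if (!is.null(p$expression)) {
    expr_summary <- .stage("expression", {
      em <- read_expression(.require_path(p$expression, "expression",
                                          "expression"))
      expression_summary(em, tumor_of, gene_res$gene_freq$gene_symbol)
    })
    out_counts$expression_summary.tsv <- .write_tsv(
      data.frame(gene_symbol = rownames(expr_summary), expr_summary,
                 check.names = FALSE),
      file.path(p$output_dir, "expression_summary.tsv"))
  }

  # --- provenance manifest -----------------------------------------------
  input_files <- c(p$sample_sheet, p$tss, p$chrom_sizes, p$pwm, p$genome,
                   p$nfr, p$expression,
                   file.path(p$peaks_dir,
                             paste0(sheet$sample_id, ".narrowPeak")),
                   file.path(p$fragments_dir,
                             paste0(sheet$sample_id, ".bed")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("secrc")),
    seed = config$seed,
    parameters = par,
    n_samples = nrow(sheet),
    input_md5 = as.list(setNames(unname(tools::md5sum(input_files)),
                                 basename(input_files))),
    output_rows = out_counts
  )
  jsonlite::write_json(manifest, file.path(p$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    per_sample = per_sample, correlation = corr, merged_ses = merged,
    gene_freq = gene_res$gene_freq, enrichment = crc_res$enrichment,
    tf_freq = crc_res$tf_freq, crc_edges = crc_res$edges,
    cliques = crc_res$cliques, top_cliques = crc_res$top_cliques,
    expression_summary = expr_summary, manifest = manifest,
    output_dir = p$output_dir
  ))
}
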