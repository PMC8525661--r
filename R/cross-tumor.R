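#' Merge super-enhancer calls across cell lines of each tumor type
#'
#' Within each tumor type, SE intervals from different cell lines that share
#' at least one base are unioned transitively (bedtools-merge semantics on
#' overlapping intervals). Each merged SE records the contributing cell
#' lines; entities seen in fewer than `min_cell_lines` lines are dropped.
#'
#' @param per_sample_ses Named list, `sample_id` -> SE interval table
#'   (`chrom`, `start`, `end`).
#' @param tumor_of Named character vector mapping `sample_id` ->
#'   tumor type; every sample in `per_sample_ses` must be present.
#' @param min_cell_lines Minimum number of distinct cell lines supporting a
#'   merged SE (default 2).
#' @return `data.frame`: `tumor_type`, `chrom`, `start`, `end`,
#'   `cell_line_count`, and a `cell_lines` list-column.
#' @export
merge_ses <- function(per_sample_ses, tumor_of, min_cell_lines = 2) {
  samples <- names(per_sample_ses)
  unknown <- setdiff(samples, names(tumor_of))
  if (length(unknown) > 0L) {
    stop(sprintf("sample(s) with unknown tumor type: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(samples, function(sid) {
    df <- per_sample_ses[[sid]]
    .check_intervals(df, sprintf("SEs of %s", sid))
    if (nrow(df) == 0L) return(NULL)
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               sample_id = sid, tumor_type = unname(tumor_of[sid]),
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(tumor_type = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      cell_line_count = integer(0))
  empty$cell_lines <- list()
  if (is.null(pooled) || nrow(pooled) == 0L) return(empty)
  res <- lapply(split(pooled, pooled$tumor_type), function(tt) {
    tt <- .sort_intervals(tt)
    grp <- .merge_groups(tt$chrom, tt$start, tt$end, max_gap = -1L)
    pieces <- split(seq_len(nrow(tt)), grp)
    df <- data.frame(
      tumor_type = tt$tumor_type[1L],
      chrom = vapply(pieces, function(ix) tt$chrom[ix[1L]], character(1)),
      start = vapply(pieces, function(ix) min(tt$start[ix]), integer(1)),
      end = vapply(pieces, function(ix) max(tt$end[ix]), integer(1)),
      cell_line_count = vapply(pieces, function(ix)
        length(unique(tt$sample_id[ix])), integer(1)),
      stringsAsFactors = FALSE
    )
    df$cell_lines <- lapply(pieces, function(ix)
      sort(unique(tt$sample_id[ix])))
    df[df$cell_line_count >= min_cell_lines, , drop = FALSE]
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(out$tumor_type, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign merged super-enhancers to their nearest gene
#'
#' Each SE is assigned to the gene whose TSS is nearest to the SE center
#' (unbounded distance; ties broken by lexicographically smaller gene
#' symbol). SEs on chromosomes without any TSS get `NA`.
#'
#' @param merged_ses Output of [merge_ses()] (any interval table works).
#' @param tss TSS table from [read_tss()]; must be non-empty.
#' @return `merged_ses` with added `gene_symbol` and `tss_distance` columns.
#' @export
assign_genes <- function(merged_ses, tss) {
  if (nrow(tss) == 0L) stop("TSS table is empty", call. = FALSE)
  .check_intervals(merged_ses, "merged SEs")
  n <- nrow(merged_ses)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  if (n > 0L) {
    center <- (merged_ses$start + merged_ses$end) %/% 2L
    for (chr in unique(merged_ses$chrom)) {
      idx <- which(merged_ses$chrom == chr)
      cand <- tss[tss$chrom == chr, , drop = FALSE]
      if (nrow(cand) == 0L) next
      for (i in idx) {
        d <- abs(cand$tss - center[i])
        best <- which(d == min(d))
        if (length(best) > 1L) {
          best <- best[order(cand$gene_symbol[best])][1L]
        }
        gene[i] <- cand$gene_symbol[best]
        dist[i] <- d[best]
      }
    }
  }
  merged_ses$gene_symbol <- gene
  merged_ses$tss_distance <- dist
  merged_ses
}

#' Cross-tumor frequency and classification of SE-regulated genes
#'
#' For every gene with at least one merged SE, counts the number of distinct
#' tumor types in which it is SE-regulated and classifies it as
#' `conservative` (frequency strictly greater than `conservative_gt`, by
#' default > 6 of 8), `specific` (frequency exactly 1) or `intermediate`.
#'
#' @param assignments `data.frame` with `tumor_type` and `gene_symbol`
#'   columns ([assign_genes()] output pooled over tumor types).
#' @param conservative_gt Conservative threshold; frequency must exceed this
#'   value (default 6).
#' @return `data.frame`: `gene_symbol`, `frequency`, `category`, plus a
#'   `tumor_types` list-column; sorted by decreasing frequency then symbol.
#' @export
gene_frequency_table <- function(assignments, conservative_gt = 6) {
  a <- assignments[!is.na(assignments$gene_symbol), , drop = FALSE]
  if (nrow(a) == 0L) {
    out <- data.frame(gene_symbol = character(0), frequency = integer(0),
                      category = character(0))
    out$tumor_types <- list()
    return(out)
  }
  types <- lapply(split(a$tumor_type, a$gene_symbol),
                  function(v) sort(unique(v)))
  out <- data.frame(
    gene_symbol = names(types),
    frequency = lengths(types),
    stringsAsFactors = FALSE
  )
  out$category <- .freq_category(out$frequency, conservative_gt)
  out$tumor_types <- unname(types)
  out <- out[order(-out$frequency, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.freq_category <- function(freq, conservative_gt) {
  ifelse(freq > conservative_gt, "conservative",
         ifelse(freq == 1L, "specific", "intermediate"))
}

#' Cross-tumor frequency and classification of SE-bound TFs
#'
#' Counts, for each TF, the number of tumor types in which it is enriched
#' among SE nucleosome-free regions and classifies it as `conservative`
#' (frequency > `conservative_gt`, default > 4), `specific` (exactly 1) or
#' `intermediate`.
#'
#' @param enriched_tfs Named list: tumor type -> character vector of
#'   enriched TF names.
#' @param conservative_gt Conservative threshold (default 4).
#' @return `data.frame`: `tf_name`, `frequency`, `category`, with a
#'   `tumor_types` list-column.
#' @export
tf_frequency_table <- function(enriched_tfs, conservative_gt = 4) {
  pairs <- do.call(rbind, lapply(names(enriched_tfs), function(tt) {
    tfs <- unique(enriched_tfs[[tt]])
    if (length(tfs) == 0L) return(NULL)
    data.frame(tumor_type = tt, tf_name = tfs, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    out <- data.frame(tf_name = character(0), frequency = integer(0),
                      category = character(0))
    out$tumor_types <- list()
    return(out)
  }
  types <- lapply(split(pairs$tumor_type, pairs$tf_name),
                  function(v) sort(unique(v)))
  out <- data.frame(
    tf_name = names(types),
    frequency = lengths(types),
    stringsAsFactors = FALSE
  )
  out$category <- .freq_category(out$frequency, conservative_gt)
  out$tumor_types <- unname(types)
  out <- out[order(-out$frequency, out$tf_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genes x samples expression matrix (TSV)
#'
#' First column gene symbols, remaining columns one sample each
#' (FPKM-like, non-negative).
#'
#' @param path TSV file with a header row.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Per-tumor-type mean expression of selected genes
#'
#' Arithmetic mean of FPKM-like expression over the samples of each tumor
#' type. Genes absent from the matrix are reported in the `missing`
#' attribute, not imputed as zero.
#'
#' @param expression Genes x samples numeric matrix (non-negative), e.g.
#'   from [read_expression()].
#' @param sample_to_tumor Named character vector mapping every column of
#'   `expression` to a tumor type.
#' @param genes Genes to summarize (default: all rows).
#' @return Genes x tumor-types matrix of means, with attribute `missing`
#'   listing requested genes absent from the matrix.
#' @export
expression_summary <- function(expression, sample_to_tumor,
                               genes = rownames(expression)) {
  if (any(expression < 0)) stop("expression must be non-negative",
                                call. = FALSE)
  unmapped <- setdiff(colnames(expression), names(sample_to_tumor))
  if (length(unmapped) > 0L) {
    stop(sprintf("sample(s) without tumor type: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(genes, rownames(expression))
  present <- intersect(genes, rownames(expression))
  types <- sort(unique(unname(sample_to_tumor[colnames(expression)])))
  out <- matrix(NA_real_, nrow = length(present), ncol = length(types),
                dimnames = list(present, types))
  for (tt in types) {
    cols <- colnames(expression)[sample_to_tumor[colnames(expression)] == tt]
    out[, tt] <- rowMeans(expression[present, cols, drop = FALSE])
  }
  if (length(missing) > 0L) {
    message(sprintf("expression_summary: %d gene(s) missing from matrix",
                    length(missing)))
  }
  attr(out, "missing") <- missing
  out
}
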