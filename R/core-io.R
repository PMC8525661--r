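#' Read peak calls from narrowPeak or BED files
#'
#' Parses ENCODE narrowPeak (10 columns) or plain BED (>= 3 columns) peak
#' files into a peak table. Coordinates are kept 0-based half-open as in the
#' file. narrowPeak column 8 (-log10 p-value) is mapped to `neg_log10_p` and
#' column 10 to `summit_offset` (-1 becomes `NA`). BED files carry no
#' p-value; their peaks get `neg_log10_p = Inf`, i.e. they are treated as
#' already filtered for significance.
#'
#' @param path Path to the peak file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param format `"narrowPeak"` or `"bed"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `neg_log10_p`, `summit_offset`, sorted by (chrom, start).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t600\tpk1\t100\t.\t5.0\t12.0\t10.0\t250", tf)
#' read_peaks(tf, format = "narrowPeak")
read_peaks <- function(path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  lines <- .read_data_lines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      neg_log10_p = numeric(0), summit_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (format == "narrowPeak") 10L else 3L
  lnum <- attr(lines, "line_numbers")
  ncols <- lengths(fields)
  short <- which(ncols < min_cols)
  if (length(short) > 0L) {
    stop(sprintf("%s line %d: expected >= %d tab-separated columns, got %d",
                 basename(path), lnum[short[1L]], min_cols,
                 ncols[short[1L]]), call. = FALSE)
  }
  col <- function(k) vapply(fields, function(f)
    if (length(f) >= k) f[k] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: non-numeric coordinates", basename(path),
                 lnum[bad[1L]]), call. = FALSE)
  }
  bad <- which(start < 0L | end <= start)
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: invalid interval [%d,%d) (need 0 <= start < end)",
                 basename(path), lnum[bad[1L]], start[bad[1L]],
                 end[bad[1L]]), call. = FALSE)
  }
  if (format == "narrowPeak") {
    nlp <- suppressWarnings(as.numeric(col(8L)))
    bad <- which(is.na(nlp) | nlp < 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s line %d: column 8 (-log10 p) must be a non-negative number",
                   basename(path), lnum[bad[1L]]), call. = FALSE)
    }
    summit <- suppressWarnings(as.integer(col(10L)))
    summit[!is.na(summit) & summit < 0L] <- NA_integer_
    name <- col(4L)
  } else {
    nlp <- rep(Inf, n)
    summit <- rep(NA_integer_, n)
    name <- col(4L)
    name[is.na(name)] <- sprintf("peak_%d", which(is.na(name)))
  }
  df <- data.frame(
    chrom = col(1L), start = start, end = end, name = name,
    neg_log10_p = nlp, summit_offset = summit, stringsAsFactors = FALSE
  )
  df <- .sort_intervals(df)
  rownames(df) <- NULL
  df
}

# Returns non-comment lines with original line numbers attached.
.read_data_lines <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  attr(lines, "line_numbers") <- which(keep)
  lines
}

#' Filter peaks by MACS2 significance
#'
#' Retains peaks with p-value strictly below `p_threshold`, i.e.
#' `neg_log10_p > -log10(p_threshold)`. Peaks read from plain BED carry the
#' sentinel `neg_log10_p = Inf` and always pass. Input order is preserved;
#' the operation is idempotent.
#'
#' @param peaks Peak table from [read_peaks()].
#' @param p_threshold Significance threshold on the p-value scale,
#'   default `1e-9`.
#' @return The retained rows of `peaks`.
#' @export
filter_significant <- function(peaks, p_threshold = 1e-9) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must be a single number in (0, 1]", call. = FALSE)
  }
  keep <- peaks$neg_log10_p > -log10(p_threshold)
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read transcription start sites from BED6 or GTF
#'
#' For BED6, the TSS of a `+` feature is its `start` and of a `-` feature
#' its last base, `end - 1` (0-based). GTF input uses only `gene` and
#' `transcript` features; its 1-based inclusive coordinates are converted to
#' the package's 0-based convention on read.
#'
#' @param path Path to the annotation file.
#' @param format `"bed6"` or `"gtf"`.
#' @return A `data.frame` with columns `gene_id`, `gene_symbol`, `chrom`,
#'   `tss`, `strand`.
#' @export
read_tss <- function(path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  lines <- .read_data_lines(path)
  n <- length(lines)
  empty <- data.frame(gene_id = character(0), gene_symbol = character(0),
                      chrom = character(0), tss = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lnum <- attr(lines, "line_numbers")
  recs <- list()
  for (i in seq_len(n)) {
    f <- fields[[i]]
    ln <- lnum[i]
    if (format == "bed6") {
      if (length(f) < 6L) {
        stop(sprintf("%s line %d: BED6 needs 6 columns", basename(path), ln),
             call. = FALSE)
      }
      strand <- f[6L]
      start <- as.integer(f[2L]); end <- as.integer(f[3L])
      if (!(strand %in% c("+", "-"))) {
        stop(sprintf("%s line %d: strand must be '+' or '-', got '%s'",
                     basename(path), ln, strand), call. = FALSE)
      }
      tss <- if (strand == "+") start else end - 1L
      recs[[length(recs) + 1L]] <-
        list(f[4L], f[4L], f[1L], tss, strand)
    } else {
      if (length(f) < 9L) {
        stop(sprintf("%s line %d: GTF needs 9 columns", basename(path), ln),
             call. = FALSE)
      }
      if (!(f[3L] %in% c("gene", "transcript"))) next
      strand <- f[7L]
      if (!(strand %in% c("+", "-"))) {
        stop(sprintf("%s line %d: strand must be '+' or '-', got '%s'",
                     basename(path), ln, strand), call. = FALSE)
      }
      start1 <- as.integer(f[4L]); end1 <- as.integer(f[5L])
      # 1-based inclusive -> 0-based: first base = start1 - 1, last = end1 - 1
      tss <- if (strand == "+") start1 - 1L else end1 - 1L
      attrs <- f[9L]
      gid <- .gtf_attr(attrs, "gene_id")
      gname <- .gtf_attr(attrs, "gene_name")
      if (is.na(gname)) gname <- gid
      recs[[length(recs) + 1L]] <- list(gid, gname, f[1L], tss, strand)
    }
  }
  if (length(recs) == 0L) return(empty)
  data.frame(
    gene_id = vapply(recs, `[[`, character(1), 1L),
    gene_symbol = vapply(recs, `[[`, character(1), 2L),
    chrom = vapply(recs, `[[`, character(1), 3L),
    tss = vapply(recs, `[[`, integer(1), 4L),
    strand = vapply(recs, `[[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
}

.gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '[ =]+"?([^";]+)"?'), attrs))[[1L]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Read a JASPAR-style PFM motif library
#'
#' Each motif is a header line `>ID NAME` followed by four rows of counts or
#' probabilities in A, C, G, T order. Rows may be bare numbers or the
#' bracketed JASPAR dialect (`A [ 4 19 0 ]`). Counts are converted to
#' per-position probabilities with an additive pseudocount:
#' `(c + pseudocount) / (sum + 4 * pseudocount)`. The background defaults to
#' uniform 0.25 per base.
#'
#' @param path Path to the PFM text file.
#' @param pseudocount Additive pseudocount per cell, default 1. Use 0 only
#'   for exact-probability matrices in controlled settings (zero cells then
#'   yield -Inf log-odds).
#' @return A list of `secrc_pwm` objects: `motif_id`, `tf_name`,
#'   `matrix` (L x 4, rows sum to 1, columns A/C/G/T), `background`.
#' @export
read_pwms <- function(path, pseudocount = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' motif headers found", call. = FALSE)
  pwms <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1L]]
    motif_id <- toks[1L]
    tf_name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    body <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) < 4L) {
      stop(sprintf("motif %s: expected 4 base rows, got %d",
                   motif_id, length(body)), call. = FALSE)
    }
    body <- body[1:4]
    rows <- lapply(body, function(b) {
      b <- sub("^\\s*[ACGTacgt]\\s*", "", b)
      b <- gsub("[][]", " ", b)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(b), "\\s+")[[1L]]))
      if (anyNA(vals)) {
        stop(sprintf("motif %s: non-numeric matrix row", motif_id),
             call. = FALSE)
      }
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop(sprintf("motif %s: unequal row lengths (%s)", motif_id,
                   paste(lens, collapse = ",")), call. = FALSE)
    }
    counts <- do.call(cbind, rows)  # L x 4, columns A,C,G,T
    if (any(counts < 0)) {
      stop(sprintf("motif %s: negative matrix entries", motif_id),
           call. = FALSE)
    }
    counts <- counts + pseudocount
    mat <- counts / rowSums(counts)
    colnames(mat) <- c("A", "C", "G", "T")
    pwms[[k]] <- structure(
      list(motif_id = motif_id, tf_name = tf_name, matrix = mat,
           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
      class = "secrc_pwm"
    )
  }
  pwms
}

#' @export
print.secrc_pwm <- function(x, ...) {
  cat(sprintf("<secrc_pwm> %s (%s), length %d\nconsensus: %s\n",
              x$motif_id, x$tf_name, nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The maximum-probability base at each position.
#'
#' @param pwm A `secrc_pwm` object.
#' @return A character string over A/C/G/T.
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm$matrix)[max.col(pwm$matrix, ties.method = "first")],
        collapse = "")
}

#' Write an interval table as BED
#'
#' Writes `chrom`, `start`, `end` first, then any remaining columns, as a
#' tab-separated file with a single `#`-prefixed header line naming the
#' columns. Files written this way round-trip through
#' `read_peaks(format = "bed")` on the interval columns.
#'
#' @param intervals A `data.frame` with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  .check_intervals(intervals, "write_bed input")
  first <- c("chrom", "start", "end")
  rest <- setdiff(names(intervals), first)
  df <- intervals[, c(first, rest), drop = FALSE]
  listcols <- vapply(df, is.list, logical(1))
  for (cn in names(df)[listcols]) {
    df[[cn]] <- vapply(df[[cn]], function(v) paste(v, collapse = ","),
                       character(1))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L) {
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read a UCSC chrom.sizes file
#'
#' @param path Two-column text file: chromosome name, length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  if (any(df$size <= 0)) stop("chromosome sizes must be positive", call. = FALSE)
  setNames(as.integer(df$size), df$chrom)
}
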