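#' Construct a sample fragment track
#'
#' A track holds one sample's aligned fragments (0-based half-open
#' intervals) together with the sequencing depth used for per-million
#' normalization. Fragments are sorted by (chrom, start) on construction.
#'
#' @param sample_id Sample identifier.
#' @param tumor_type Tumor-type label of the sample.
#' @param fragments `data.frame` with `chrom`, `start`, `end` and optionally
#'   `weight` (defaults to 1 per fragment; bedGraph-derived tracks use the
#'   interval value as weight).
#' @return A `sample_track` object.
#' @export
sample_track <- function(sample_id, tumor_type, fragments) {
  .check_intervals(fragments, "fragments")
  if (!"weight" %in% names(fragments)) {
    fragments$weight <- rep(1, nrow(fragments))
  }
  fragments <- .sort_intervals(fragments)
  rownames(fragments) <- NULL
  total <- sum(fragments$weight)
  structure(
    list(sample_id = sample_id, tumor_type = tumor_type,
         fragments = fragments, total_fragments = total),
    class = "sample_track"
  )
}

#' @export
print.sample_track <- function(x, ...) {
  cat(sprintf("<sample_track> %s (%s): %d fragments, depth %.0f\n",
              x$sample_id, x$tumor_type, nrow(x$fragments),
              x$total_fragments))
  invisible(x)
}

#' Read a fragment BED file into a sample track
#'
#' @param path BED3+ file of aligned fragments.
#' @param sample_id,tumor_type Labels for the track.
#' @return A `sample_track`.
#' @export
read_fragments <- function(path, sample_id, tumor_type = NA_character_) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = c("character", "integer", "integer",
                                  rep("NULL", .n_extra_cols(path))),
                   col.names = c("chrom", "start", "end",
                                 if (.n_extra_cols(path) > 0L)
                                   paste0("x", seq_len(.n_extra_cols(path)))))
  sample_track(sample_id, tumor_type, df)
}

.n_extra_cols <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!grepl("^(#|track\\b|browser\\b)", first) & nzchar(first)]
  if (length(first) == 0L) return(0L)
  max(0L, max(lengths(strsplit(first, "\t", fixed = TRUE))) - 3L)
}

#' Read a bedGraph coverage file as a weighted pseudo-fragment track
#'
#' Each bedGraph interval becomes one pseudo-fragment weighted by its
#' coverage value, so downstream per-million normalization uses the summed
#' coverage as depth.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param sample_id,tumor_type Labels for the track.
#' @return A `sample_track` with weighted fragments.
#' @export
read_bedgraph_track <- function(path, sample_id, tumor_type = NA_character_) {
  lines <- .read_data_lines(path)
  if (length(lines) == 0L) {
    stop(sprintf("bedGraph %s is empty", path), call. = FALSE)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 4L)
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: bedGraph needs 4 columns", basename(path),
                 attr(lines, "line_numbers")[bad[1L]]), call. = FALSE)
  }
  df <- data.frame(
    chrom = vapply(f, `[[`, character(1), 1L),
    start = as.integer(vapply(f, `[[`, character(1), 2L)),
    end = as.integer(vapply(f, `[[`, character(1), 3L)),
    weight = as.numeric(vapply(f, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
  df <- df[df$weight > 0, , drop = FALSE]
  sample_track(sample_id, tumor_type, df)
}

#' Define enhancer candidates from significant peaks
#'
#' Peaks whose midpoint lies strictly more than `min_tss_distance` from the
#' nearest TSS are kept as enhancers; each is extended to a fixed window of
#' `extend` bases either side of the peak midpoint (start clamped at 0).
#' Peaks on chromosomes without any annotated TSS are treated as infinitely
#' distal and kept.
#'
#' @param peaks Significant peak table ([read_peaks()] +
#'   [filter_significant()]).
#' @param tss TSS table from [read_tss()]; must be non-empty.
#' @param min_tss_distance Minimum midpoint-to-TSS distance in bp
#'   (default 2500); strictly-greater rule.
#' @param extend Half-width of the enhancer window (default 5000, giving
#'   10 kb windows).
#' @return `data.frame` with `chrom`, `start`, `end` (the extended window),
#'   `name`, `peak_start`, `peak_end`, `peak_mid`, `tss_distance`.
#' @export
define_enhancers <- function(peaks, tss, min_tss_distance = 2500,
                             extend = 5000) {
  if (nrow(tss) == 0L) {
    stop("TSS table is empty: enhancer distance is undefined", call. = FALSE)
  }
  .check_intervals(peaks, "peaks")
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      peak_start = integer(0), peak_end = integer(0),
                      peak_mid = integer(0), tss_distance = numeric(0)))
  }
  mid <- (peaks$start + peaks$end) %/% 2L
  dist <- rep(Inf, nrow(peaks))
  tss_by_chrom <- split(tss$tss, tss$chrom)
  for (chr in unique(peaks$chrom)) {
    pos <- tss_by_chrom[[chr]]
    if (is.null(pos)) next
    idx <- which(peaks$chrom == chr)
    pos <- sort(pos)
    # nearest TSS via binary insertion points
    ins <- findInterval(mid[idx], pos)
    lo <- ifelse(ins >= 1L, pos[pmax(ins, 1L)], NA_integer_)
    hi <- ifelse(ins < length(pos), pos[pmin(ins + 1L, length(pos))],
                 NA_integer_)
    d <- pmin(abs(mid[idx] - lo), abs(hi - mid[idx]), na.rm = TRUE)
    dist[idx] <- d
  }
  keep <- dist > min_tss_distance
  out <- data.frame(
    chrom = peaks$chrom[keep],
    start = pmax(0L, mid[keep] - as.integer(extend)),
    end = mid[keep] + as.integer(extend),
    name = peaks$name[keep],
    peak_start = peaks$start[keep],
    peak_end = peaks$end[keep],
    peak_mid = mid[keep],
    tss_distance = dist[keep],
    stringsAsFactors = FALSE
  )
  out <- .sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Quantify H3K27ac signal of enhancers in fixed-size bins
#'
#' Each enhancer window is segmented into `bin_size` bp bins (last bin
#' truncated); a fragment counts once in every bin it shares at least one
#' base with. The enhancer signal is the mean per-bin count, normalized to
#' fragments per million by `1e6 / total_fragments`.
#'
#' @param enhancers Interval table from [define_enhancers()] (any
#'   chrom/start/end table works).
#' @param track A [sample_track()].
#' @param bin_size Bin width in bp, default 100.
#' @return `enhancers` with added `signal` and `sample_id` columns.
#' @export
quantify_enhancer_signal <- function(enhancers, track, bin_size = 100) {
  stopifnot(inherits(track, "sample_track"))
  if (track$total_fragments <= 0) {
    stop(sprintf("track %s has zero total fragments", track$sample_id),
         call. = FALSE)
  }
  .check_intervals(enhancers, "enhancers")
  n <- nrow(enhancers)
  enhancers$signal <- numeric(n)
  enhancers$sample_id <- track$sample_id
  if (n == 0L) return(enhancers)
  # materialize bins for all enhancers at once
  widths <- enhancers$end - enhancers$start
  nbins <- as.integer(ceiling(widths / bin_size))
  enh_idx <- rep.int(seq_len(n), nbins)
  off <- unlist(lapply(nbins, function(k) seq_len(k) - 1L), use.names = FALSE)
  bstart <- enhancers$start[enh_idx] + off * as.integer(bin_size)
  bend <- pmin(bstart + as.integer(bin_size), enhancers$end[enh_idx])
  bins <- data.frame(chrom = enhancers$chrom[enh_idx],
                     start = bstart, end = bend, stringsAsFactors = FALSE)
  counts <- .count_overlaps_by_chrom(bins, track$fragments,
                                     ref_weight = track$fragments$weight)
  persum <- rowsum(counts, group = enh_idx)
  enhancers$signal <- as.numeric(persum[, 1L] / nbins) *
    1e6 / track$total_fragments
  enhancers
}

#' Genome-wide binned, depth-normalized signal matrix
#'
#' Divides every chromosome into `bin_size` bp bins and counts, per sample,
#' the fragments overlapping each bin (a fragment spanning k bins counts
#' once in each), normalized to fragments per million.
#'
#' @param tracks List of [sample_track()] objects.
#' @param chrom_sizes Named vector of chromosome lengths
#'   ([read_chrom_sizes()]).
#' @param bin_size Bin width in bp, default 2000.
#' @return A `bin_matrix` object: `values` (samples x bins), `bins`
#'   (bin coordinate table), `bin_size`, `chrom_sizes`, and per-sample
#'   `tumor_type` labels.
#' @export
genome_bin_matrix <- function(tracks, chrom_sizes, bin_size = 2000) {
  stopifnot(length(tracks) > 0L, all(vapply(tracks, inherits,
                                            logical(1), "sample_track")))
  for (tr in tracks) {
    fr <- tr$fragments
    unknown <- setdiff(unique(fr$chrom), names(chrom_sizes))
    if (length(unknown) > 0L) {
      stop(sprintf("track %s: chromosome(s) %s absent from chrom_sizes",
                   tr$sample_id, paste(unknown, collapse = ",")),
           call. = FALSE)
    }
    over <- fr$end > chrom_sizes[fr$chrom]
    if (any(over)) {
      stop(sprintf("track %s: fragment beyond chromosome end (%s)",
                   tr$sample_id, fr$chrom[which(over)[1L]]), call. = FALSE)
    }
  }
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(chr) {
    k <- as.integer(ceiling(chrom_sizes[[chr]] / bin_size))
    s <- (seq_len(k) - 1L) * as.integer(bin_size)
    data.frame(chrom = chr, start = s,
               end = pmin(s + as.integer(bin_size),
                          as.integer(chrom_sizes[[chr]])),
               stringsAsFactors = FALSE)
  }))
  vals <- matrix(0, nrow = length(tracks), ncol = nrow(bins),
                 dimnames = list(vapply(tracks, `[[`, character(1),
                                        "sample_id"), NULL))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (tr$total_fragments <= 0) {
      stop(sprintf("track %s has zero total fragments", tr$sample_id),
           call. = FALSE)
    }
    counts <- .count_overlaps_by_chrom(bins, tr$fragments,
                                       ref_weight = tr$fragments$weight)
    vals[i, ] <- counts * 1e6 / tr$total_fragments
  }
  structure(
    list(values = vals, bins = bins, bin_size = as.integer(bin_size),
         chrom_sizes = chrom_sizes,
         tumor_type = vapply(tracks, `[[`, character(1), "tumor_type")),
    class = "bin_matrix"
  )
}

#' Pearson correlation between samples of a binned signal matrix
#'
#' @param bin_matrix A `bin_matrix` from [genome_bin_matrix()].
#' @param log1p Apply `log(1 + x)` before correlating (off by default; the
#'   default matches correlation on raw depth-normalized bins).
#' @return Symmetric samples x samples Pearson correlation matrix with unit
#'   diagonal.
#' @export
sample_correlation <- function(bin_matrix, log1p = FALSE) {
  stopifnot(inherits(bin_matrix, "bin_matrix"))
  v <- bin_matrix$values
  if (nrow(v) < 2L) stop("need >= 2 samples for correlation", call. = FALSE)
  if (log1p) v <- log1p(v)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance sample(s): %s",
                 paste(rownames(v)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  cc <- cor(t(v))
  diag(cc) <- 1
  cc
}
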