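# Internal interval helpers. Coordinates are 0-based, half-open everywhere:
# an interval [start, end) covers bases start .. end-1 and end > start.

.check_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L)) {
    stop(sprintf("%s: negative start coordinate", what), call. = FALSE)
  }
  bad <- which(df$end <= df$start)
  if (length(bad) > 0L) {
    stop(sprintf("%s: end <= start at row %d (%s:%d-%d)", what, bad[1L],
                 df$chrom[bad[1L]], df$start[bad[1L]], df$end[bad[1L]]),
         call. = FALSE)
  }
  invisible(df)
}

.sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# Assigns merge-group ids to intervals sorted by (chrom, start).
# Two consecutive intervals join the same group when
#   next.start - running.end <= max_gap.
# max_gap = 0 merges touching intervals, negative max_gap requires overlap
# (max_gap = -1 means ">= 1 shared base"), positive values stitch across gaps.
# The relation is applied transitively via a running maximum end.
.merge_groups <- function(chrom, start, end, max_gap = 0L) {
  n <- length(start)
  if (n == 0L) return(integer(0))
  grp <- integer(n)
  grp[1L] <- 1L
  g <- 1L
  cur_end <- end[1L]
  if (n > 1L) {
    for (i in 2:n) {
      if (chrom[i] == chrom[i - 1L] && start[i] - cur_end <= max_gap) {
        cur_end <- max(cur_end, end[i])
      } else {
        g <- g + 1L
        cur_end <- end[i]
      }
      grp[i] <- g
    }
  }
  grp
}

# IRanges view of a 0-based half-open table (1-based closed internally).
.as_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Count, per query interval, the reference intervals sharing >= 1 base.
# Both inputs are 0-based half-open data frames with chrom/start/end.
# Optional weights on the reference rows give a weighted sum instead.
.count_overlaps_by_chrom <- function(query, ref, ref_weight = NULL) {
  out <- numeric(nrow(query))
  if (nrow(query) == 0L || nrow(ref) == 0L) return(out)
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    ri <- which(ref$chrom == chr)
    if (length(ri) == 0L) next
    qr <- .as_iranges(query$start[qi], query$end[qi])
    rr <- .as_iranges(ref$start[ri], ref$end[ri])
    if (is.null(ref_weight)) {
      out[qi] <- IRanges::countOverlaps(qr, rr)
    } else {
      hits <- IRanges::findOverlaps(qr, rr)
      w <- ref_weight[ri][S4Vectors::subjectHits(hits)]
      acc <- rowsum(w, group = S4Vectors::queryHits(hits))
      out[qi[as.integer(rownames(acc))]] <- acc[, 1L]
    }
  }
  out
}
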