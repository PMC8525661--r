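#' Stitch enhancers within a fixed genomic distance
#'
#' Enhancers from one sample are merged transitively whenever the gap
#' between consecutive intervals (`next start - previous end`) is at most
#' `stitch_distance`; "within 12.5 kb" is inclusive, and overlapping or
#' touching intervals (gap <= 0) always merge. Isolated enhancers become
#' single-constituent stitched entities. The stitched signal is the sum of
#' constituent signals (ROSE's cumulative-signal convention).
#'
#' @param enhancers Signal-quantified enhancer table
#'   ([quantify_enhancer_signal()]); must contain a `signal` column.
#' @param stitch_distance Maximum gap in bp, default 12500.
#' @return `data.frame` of stitched enhancers, sorted and non-overlapping:
#'   `chrom`, `start`, `end`, `signal`, `n_constituents`, plus a
#'   `constituents` list-column holding each entity's constituent rows.
#' @export
stitch <- function(enhancers, stitch_distance = 12500) {
  .check_intervals(enhancers, "enhancers")
  if (!"signal" %in% names(enhancers)) {
    stop("enhancers must carry a 'signal' column (run quantify_enhancer_signal)",
         call. = FALSE)
  }
  if (nrow(enhancers) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), signal = numeric(0),
                      n_constituents = integer(0)))
  }
  enh <- .sort_intervals(enhancers)
  grp <- .merge_groups(enh$chrom, enh$start, enh$end,
                       max_gap = as.integer(stitch_distance))
  pieces <- split(seq_len(nrow(enh)), grp)
  out <- data.frame(
    chrom = vapply(pieces, function(ix) enh$chrom[ix[1L]], character(1)),
    start = vapply(pieces, function(ix) min(enh$start[ix]), integer(1)),
    end = vapply(pieces, function(ix) max(enh$end[ix]), integer(1)),
    signal = vapply(pieces, function(ix) sum(enh$signal[ix]), numeric(1)),
    n_constituents = vapply(pieces, length, integer(1)),
    stringsAsFactors = FALSE
  )
  out$constituents <- lapply(pieces, function(ix) {
    rownames(enh) <- NULL
    enh[ix, , drop = FALSE]
  })
  out <- .sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Classify super-enhancers with the slope-1 tangent cutoff
#'
#' Entities are sorted by signal (ascending), ranks and signals are both
#' scaled to `[0, 1]`, and the cutoff is the point where the slope of the
#' scaled rank curve reaches 1 - found as the point maximizing
#' `scaled_rank - scaled_signal`, the geometric identity for a convex
#' increasing curve. Entities with signal strictly greater than the cutoff
#' entity's signal are super-enhancers; ties at the cutoff signal stay
#' typical.
#'
#' @param stitched Stitched-enhancer table from [stitch()], >= 2 rows with
#'   non-constant signals.
#' @return A list with `stitched` (input plus `rank`, 1 = lowest signal, and
#'   `is_super`) and `cutoff` (`cutoff_signal`, `cutoff_rank`, `n_super`,
#'   `n_typical`).
#' @export
rank_and_cutoff <- function(stitched) {
  n <- nrow(stitched)
  if (n < 2L) stop("need >= 2 stitched enhancers to rank", call. = FALSE)
  s <- stitched$signal
  if (diff(range(s)) == 0) stop("degenerate rank curve: all signals equal",
                                call. = FALSE)
  ord <- order(s, stitched$chrom, stitched$start)
  ss <- s[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (ss - ss[1L]) / (ss[n] - ss[1L])
  i_cut <- which.max(x - y)
  cutoff_signal <- ss[i_cut]
  # rank of the last entity at/below the cutoff signal; with distinct
  # signals this is i_cut itself
  cutoff_rank <- sum(ss <= cutoff_signal)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  is_super <- s > cutoff_signal
  stitched$rank <- rank
  stitched$is_super <- is_super
  list(
    stitched = stitched,
    cutoff = list(cutoff_signal = cutoff_signal,
                  cutoff_rank = cutoff_rank,
                  cutoff_scaled_rank = x[i_cut],
                  n_super = sum(is_super),
                  n_typical = n - sum(is_super))
  )
}

#' Hockey-stick plot data for ranked stitched enhancers
#'
#' @param ranked Output of [rank_and_cutoff()] (or its `stitched` element
#'   carrying `rank` and `is_super`).
#' @return Plot-ready `data.frame` sorted by ascending rank: `rank`,
#'   `signal`, `scaled_rank`, `scaled_signal`, `is_super`.
#' @export
hockey_plot_data <- function(ranked) {
  st <- if (is.list(ranked) && !is.data.frame(ranked) &&
            !is.null(ranked$stitched)) ranked$stitched else ranked
  if (!all(c("rank", "is_super", "signal") %in% names(st))) {
    stop("input is unranked: run rank_and_cutoff first", call. = FALSE)
  }
  st <- st[order(st$rank), , drop = FALSE]
  n <- nrow(st)
  s <- st$signal
  data.frame(
    rank = st$rank,
    signal = s,
    scaled_rank = (st$rank - 1) / (n - 1),
    scaled_signal = (s - min(s)) / (max(s) - min(s)),
    is_super = st$is_super,
    row.names = NULL
  )
}
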