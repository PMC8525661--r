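# Motif scanning in nucleosome-free regions and core regulatory circuitry.

.load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome) && !is.null(names(genome))) {
    gs <- Biostrings::DNAStringSet(genome)
  } else {
    stop("genome must be a FASTA path, a named character vector, or a DNAStringSet",
         call. = FALSE)
  }
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

.genome_seq <- function(gs, chrom, start, end) {
  if (!(chrom %in% names(gs))) {
    stop(sprintf("genome is missing chromosome '%s'", chrom), call. = FALSE)
  }
  as.character(Biostrings::subseq(gs[[chrom]], start = start + 1L, end = end))
}

.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# log2 odds weights of a PWM against its background; L x 4
.pwm_weights <- function(pwm) {
  log2(sweep(pwm$matrix, 2L, pwm$background, "/"))
}

.pwm_max_score <- function(pwm) {
  sum(apply(.pwm_weights(pwm), 1L, max))
}

#' Locate nucleosome-free regions on SE constituents
#'
#' In `provided` mode, user-supplied NFR intervals are intersected with the
#' constituent intervals (keeping intersections of >= 1 bp). In `valley`
#' mode, NFRs are detected from the fragment track as coverage valleys:
#' within each constituent, maximal runs of at least `min_width` bp where
#' coverage drops below `valley_frac` times the constituent's peak
#' coverage, flanked on both sides by coverage reaching at least
#' `flank_frac` times the peak. Sequences are extracted from the genome.
#'
#' @param constituents Interval table of SE constituent peaks
#'   (`chrom`, `start`, `end`, optional `name`).
#' @param genome FASTA path, named character vector, or `DNAStringSet`.
#' @param mode `"provided"` or `"valley"`.
#' @param nfr NFR interval table (required for `provided`).
#' @param track [sample_track()] supplying coverage (required for `valley`).
#' @param min_width Minimum valley width in bp (default 50).
#' @param valley_frac Valley depth threshold as a fraction of peak coverage
#'   (default 0.25).
#' @param flank_frac Flank height threshold as a fraction of peak coverage
#'   (default 0.5).
#' @return `data.frame`: `chrom`, `start`, `end`, `parent` (constituent
#'   name or index), `sequence`.
#' @export
find_nfrs <- function(constituents, genome, mode = c("provided", "valley"),
                      nfr = NULL, track = NULL, min_width = 50,
                      valley_frac = 0.25, flank_frac = 0.5) {
  mode <- match.arg(mode)
  .check_intervals(constituents, "constituents")
  gs <- .load_genome(genome)
  parent_name <- if ("name" %in% names(constituents)) constituents$name
                 else as.character(seq_len(nrow(constituents)))
  recs <- list()
  if (mode == "provided") {
    if (is.null(nfr)) stop("mode='provided' requires an nfr table",
                           call. = FALSE)
    .check_intervals(nfr, "nfr")
    for (chr in unique(constituents$chrom)) {
      ci <- which(constituents$chrom == chr)
      ni <- which(nfr$chrom == chr)
      if (length(ni) == 0L) next
      hits <- IRanges::findOverlaps(
        .as_iranges(nfr$start[ni], nfr$end[ni]),
        .as_iranges(constituents$start[ci], constituents$end[ci])
      )
      for (h in seq_along(hits)) {
        i <- ni[S4Vectors::queryHits(hits)[h]]
        j <- ci[S4Vectors::subjectHits(hits)[h]]
        s <- max(nfr$start[i], constituents$start[j])
        e <- min(nfr$end[i], constituents$end[j])
        recs[[length(recs) + 1L]] <- list(chr, s, e, parent_name[j])
      }
    }
  } else {
    if (is.null(track)) stop("mode='valley' requires a fragment track",
                             call. = FALSE)
    for (j in seq_len(nrow(constituents))) {
      chr <- constituents$chrom[j]
      s0 <- constituents$start[j]
      e0 <- constituents$end[j]
      fr <- track$fragments
      fr <- fr[fr$chrom == chr, , drop = FALSE]
      width <- e0 - s0
      cov <- numeric(width)
      if (nrow(fr) > 0L) {
        rng <- .as_iranges(pmax(fr$start, s0), pmin(fr$end, e0))
        rng <- rng[IRanges::width(rng) > 0L]
        if (length(rng) > 0L) {
          covr <- IRanges::coverage(IRanges::shift(rng, -s0),
                                    width = width)
          cov <- as.numeric(covr)
        }
      }
      peak <- max(cov)
      if (peak <= 0) next
      below <- cov < valley_frac * peak
      r <- rle(below)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (!r$values[k] || r$lengths[k] < min_width) next
        left <- cov[seq_len(starts[k] - 1L)]
        right <- if (ends[k] < width) cov[(ends[k] + 1L):width] else numeric(0)
        if (length(left) == 0L || length(right) == 0L) next
        if (max(left) >= flank_frac * peak && max(right) >= flank_frac * peak) {
          recs[[length(recs) + 1L]] <-
            list(chr, s0 + starts[k] - 1L, s0 + ends[k], parent_name[j])
        }
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), parent = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    chrom = vapply(recs, `[[`, character(1), 1L),
    start = as.integer(vapply(recs, `[[`, numeric(1), 2L)),
    end = as.integer(vapply(recs, `[[`, numeric(1), 3L)),
    parent = vapply(recs, `[[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
  out$sequence <- vapply(seq_len(nrow(out)), function(i)
    .genome_seq(gs, out$chrom[i], out$start[i], out$end[i]), character(1))
  out <- .sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Scan a sequence for PWM matches on both strands
#'
#' Scores every offset on both strands with additive log2 odds,
#' `sum_j log2(p_j(base) / bg(base))`, and reports hits scoring at least
#' `threshold_fraction` times the maximum attainable score of the PWM.
#' Windows containing `N` never match. Offsets are 0-based positions of the
#' leftmost matched base on the forward sequence. A PWM longer than the
#' sequence yields no hits. For the degenerate uniform PWM against a uniform
#' background every window scores 0 = the maximum, so every offset is a hit.
#'
#' @param pwm A `secrc_pwm`.
#' @param sequence Character string over A/C/G/T/N (case-insensitive).
#' @param threshold_fraction Fraction of the maximum attainable score in
#'   (0, 1], default 0.8.
#' @return `data.frame`: `pwm_id`, `offset`, `strand`, `log_odds`, sorted
#'   by offset.
#' @export
scan_motif <- function(pwm, sequence, threshold_fraction = 0.8) {
  stopifnot(inherits(pwm, "secrc_pwm"), is.character(sequence),
            length(sequence) == 1L)
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1) {
    stop("threshold_fraction must be in (0, 1]", call. = FALSE)
  }
  W <- .pwm_weights(pwm)
  L <- nrow(W)
  thr <- threshold_fraction * .pwm_max_score(pwm)
  seq_fw <- toupper(sequence)
  n <- nchar(seq_fw)
  empty <- data.frame(pwm_id = character(0), offset = integer(0),
                      strand = character(0), log_odds = numeric(0))
  if (n < L) return(empty)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fw else .revcomp(seq_fw)
    sc <- .scan_scores(W, s)
    hit <- which(!is.na(sc) & sc >= thr)
    if (length(hit) > 0L) {
      off <- hit - 1L
      if (strand == "-") off <- n - (off + L)
      res[[strand]] <- data.frame(pwm_id = pwm$motif_id, offset = off,
                                  strand = strand, log_odds = sc[hit],
                                  stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# scores at every offset of one sequence; NA where a window contains N
.scan_scores <- function(W, s) {
  L <- nrow(W)
  idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  n <- length(idx)
  noff <- n - L + 1L
  sc <- numeric(noff)
  for (j in seq_len(L)) {
    sc <- sc + W[j, ][idx[j:(j + noff - 1L)]]
  }
  sc
}

# reverse-complement of a weight matrix: scanning a sequence with it is
# equivalent to scanning the reverse complement of the sequence with W
.rc_weights <- function(W) {
  W[rev(seq_len(nrow(W))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

# vectorized "sequence has >= 1 hit on either strand" over many sequences
.seqs_have_hit <- function(pwm, seqs, threshold_fraction = 0.8) {
  W <- .pwm_weights(pwm)
  Wrc <- .rc_weights(W)
  L <- nrow(W)
  thr <- threshold_fraction * .pwm_max_score(pwm)
  out <- logical(length(seqs))
  if (length(seqs) == 0L) return(out)
  fw <- toupper(seqs)
  by_len <- split(seq_along(fw), nchar(fw))
  for (grp in by_len) {
    len <- nchar(fw[grp[1L]])
    if (len < L) next
    idx <- matrix(match(unlist(strsplit(fw[grp], "", fixed = TRUE)),
                        c("A", "C", "G", "T")),
                  nrow = length(grp), byrow = TRUE)
    noff <- len - L + 1L
    m <- length(grp)
    s_fw <- matrix(0, m, noff)
    s_rc <- matrix(0, m, noff)
    for (j in seq_len(L)) {
      win <- idx[, j:(j + noff - 1L), drop = FALSE]
      s_fw <- s_fw + matrix(W[j, ][win], m, noff)
      s_rc <- s_rc + matrix(Wrc[j, ][win], m, noff)
    }
    hit <- rowSums((!is.na(s_fw) & s_fw >= thr) |
                   (!is.na(s_rc) & s_rc >= thr)) > 0L
    out[grp[hit]] <- TRUE
  }
  out
}

#' Hypergeometric motif enrichment of target vs background sequences
#'
#' A sequence "has" the motif if it contains at least one hit at the given
#' threshold. The p-value is the hypergeometric upper tail
#' `P(X >= n_target_hits)` for drawing `n_target` sequences from the pooled
#' population with `n_target_hits + n_background_hits` motif-carrying
#' sequences.
#'
#' @param target_nfrs,background_nfrs NFR tables ([find_nfrs()]) with a
#'   `sequence` column, or plain character vectors of sequences. Both must
#'   be non-empty.
#' @param pwm A `secrc_pwm`.
#' @param threshold_fraction Hit threshold, see [scan_motif()].
#' @return One-row `data.frame`: `pwm_id`, `tf_name`, `n_target_hits`,
#'   `n_target`, `n_background_hits`, `n_background`, `p_value`.
#' @export
enrichment_test <- function(target_nfrs, background_nfrs, pwm,
                            threshold_fraction = 0.8) {
  tseq <- .as_sequences(target_nfrs)
  bseq <- .as_sequences(background_nfrs)
  if (length(tseq) == 0L) stop("empty target set", call. = FALSE)
  if (length(bseq) == 0L) stop("empty background set", call. = FALSE)
  th <- sum(.seqs_have_hit(pwm, tseq, threshold_fraction))
  bh <- sum(.seqs_have_hit(pwm, bseq, threshold_fraction))
  nt <- length(tseq)
  nb <- length(bseq)
  m <- th + bh
  p <- stats::phyper(th - 1L, m, nt + nb - m, nt, lower.tail = FALSE)
  data.frame(pwm_id = pwm$motif_id, tf_name = pwm$tf_name,
             n_target_hits = th, n_target = nt,
             n_background_hits = bh, n_background = nb,
             p_value = p, stringsAsFactors = FALSE)
}

.as_sequences <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && "sequence" %in% names(x)) return(x$sequence)
  stop("expected a character vector or a table with a 'sequence' column",
       call. = FALSE)
}

#' Build the SE-TF core regulatory circuitry graph
#'
#' A directed edge u -> v is drawn when TF u's motif has at least one hit in
#' any NFR sequence of TF v's super-enhancer. TFs whose own SE NFRs contain
#' their motif (u -> u) are autoregulated; clique analysis is restricted to
#' them. TFs without a PWM are excluded with a warning.
#'
#' @param tf_to_se Named character vector: TF name -> SE identifier.
#' @param nfrs_by_se Named list: SE identifier -> character vector of NFR
#'   sequences (or NFR table with a `sequence` column).
#' @param pwms_by_tf Named list: TF name -> `secrc_pwm`.
#' @param threshold_fraction Hit threshold, see [scan_motif()].
#' @return A `crc_graph`: `nodes`, `edges` (`data.frame` of `from`, `to`),
#'   `autoregulated`.
#' @export
build_crc <- function(tf_to_se, nfrs_by_se, pwms_by_tf,
                      threshold_fraction = 0.8) {
  tfs <- names(tf_to_se)
  no_pwm <- tfs[!tfs %in% names(pwms_by_tf)]
  if (length(no_pwm) > 0L) {
    warning(sprintf("TF(s) without a PWM excluded: %s",
                    paste(no_pwm, collapse = ", ")), call. = FALSE)
    tfs <- setdiff(tfs, no_pwm)
  }
  se_ids <- unique(unname(tf_to_se[tfs]))
  edges <- list()
  for (u in tfs) {
    pwm <- pwms_by_tf[[u]]
    hit_in_se <- vapply(se_ids, function(se) {
      seqs <- .as_sequences(if (is.null(nfrs_by_se[[se]])) character(0)
                            else nfrs_by_se[[se]])
      any(.seqs_have_hit(pwm, seqs, threshold_fraction))
    }, logical(1))
    for (v in tfs) {
      if (hit_in_se[[tf_to_se[[v]]]]) {
        edges[[length(edges) + 1L]] <- c(u, v)
      }
    }
  }
  edges_df <- if (length(edges) > 0L) {
    data.frame(from = vapply(edges, `[`, character(1), 1L),
               to = vapply(edges, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0))
  }
  auto <- sort(edges_df$from[edges_df$from == edges_df$to])
  structure(list(nodes = sort(tfs), edges = edges_df,
                 autoregulated = auto),
            class = "crc_graph")
}

#' @export
print.crc_graph <- function(x, ...) {
  cat(sprintf("<crc_graph> %d TFs, %d edges, %d autoregulated\n",
              length(x$nodes), nrow(x$edges), length(x$autoregulated)))
  invisible(x)
}

#' Enumerate fully interconnected cliques of autoregulated TFs
#'
#' Restricted to autoregulated nodes, finds all maximal sets of size
#' `min_size` or more in which every ordered pair of members is an edge
#' (mutual regulation). Each TF's score is the fraction of enumerated
#' cliques containing it; a clique's score is the mean of its members'
#' scores. Cliques are sorted by decreasing score, ties broken by the
#' lexicographic member list.
#'
#' @param graph A `crc_graph` from [build_crc()].
#' @param min_size Minimum clique size, default 2.
#' @return `data.frame` with `members` (list-column), `size`,
#'   `clique_score`; attribute `tf_scores` holds the named score vector.
#' @export
enumerate_cliques <- function(graph, min_size = 2) {
  stopifnot(inherits(graph, "crc_graph"))
  empty <- data.frame(size = integer(0), clique_score = numeric(0))
  empty$members <- list()
  empty <- empty[, c("members", "size", "clique_score")]
  attr(empty, "tf_scores") <- setNames(numeric(0), character(0))
  auto <- graph$autoregulated
  if (length(auto) < min_size) return(empty)
  e <- graph$edges
  e <- e[e$from != e$to & e$from %in% auto & e$to %in% auto, , drop = FALSE]
  key <- paste(e$from, e$to, sep = "\r")
  rkey <- paste(e$to, e$from, sep = "\r")
  mutual <- e[key %in% rkey & e$from < e$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(mutual, directed = FALSE,
                                     vertices = auto)
  cl <- igraph::max_cliques(g, min = min_size)
  if (length(cl) == 0L) return(empty)
  members <- lapply(cl, function(v) sort(names(v)))
  all_tf <- sort(unique(unlist(members)))
  tf_scores <- vapply(all_tf, function(tf)
    mean(vapply(members, function(m) tf %in% m, logical(1))), numeric(1))
  cs <- vapply(members, function(m) mean(tf_scores[m]), numeric(1))
  keyv <- vapply(members, paste, character(1), collapse = ",")
  ord <- order(-cs, keyv)
  out <- data.frame(size = lengths(members)[ord], clique_score = cs[ord])
  out$members <- members[ord]
  out <- out[, c("members", "size", "clique_score")]
  rownames(out) <- NULL
  attr(out, "tf_scores") <- tf_scores
  out
}
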