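# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms (O(n^2) union-find, exhaustive
# subset enumeration, per-position rescanning) so they share no code with
# the package internals they verify.

# O(n^2) union-find merge of intervals: i and j belong together when
# gap(i, j) <= max_gap on the same chromosome (gap < 0 means overlap).
oracle_merge <- function(df, max_gap) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  for (i in seq_len(n)) {
    # pairwise gap of i against every other interval, computed vectorized
    gap <- pmax(df$start[i], df$start) - pmin(df$end[i], df$end)
    nbrs <- which(gap <= max_gap & df$chrom == df$chrom[i])
    for (j in nbrs) {
      if (j == i) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  out <- do.call(rbind, lapply(groups, function(ix) {
    data.frame(chrom = df$chrom[ix[1]], start = min(df$start[ix]),
               end = max(df$end[ix]), n = length(ix),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, n_chrom = 2, max_pos = 5e5,
                             max_width = 2e4) {
  start <- as.integer(floor(runif(n, 0, max_pos)))
  data.frame(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + as.integer(ceiling(runif(n, 1, max_width))),
    stringsAsFactors = FALSE
  )
}

# exhaustive enumeration of maximal fully interconnected subsets of
# autoregulated nodes (all ordered pairs present), size >= min_size
oracle_cliques <- function(nodes, edges, min_size = 2) {
  auto <- sort(nodes[vapply(nodes, function(u)
    any(edges$from == u & edges$to == u), logical(1))])
  k <- length(auto)
  if (k == 0) return(list())
  has_edge <- function(u, v) any(edges$from == u & edges$to == v)
  complete <- list()
  for (mask in seq_len(2^k) - 1L) {
    s <- auto[bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L) == 1L]
    if (length(s) < min_size) next
    ok <- TRUE
    for (u in s) for (v in s) {
      if (u != v && !has_edge(u, v)) { ok <- FALSE; break }
    }
    if (ok) complete[[length(complete) + 1L]] <- sort(s)
  }
  maximal <- Filter(function(s) {
    !any(vapply(complete, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, complete)
  unique(maximal)
}

random_digraph <- function(n, p_edge = 0.4, p_self = 0.6) {
  nodes <- LETTERS[seq_len(n)]
  from <- character(0); to <- character(0)
  for (u in nodes) for (v in nodes) {
    pr <- if (u == v) p_self else p_edge
    if (runif(1) < pr) { from <- c(from, u); to <- c(to, v) }
  }
  list(nodes = nodes,
       edges = data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

as_crc_graph <- function(g) {
  auto <- sort(unique(g$edges$from[g$edges$from == g$edges$to]))
  structure(list(nodes = sort(g$nodes), edges = g$edges,
                 autoregulated = auto), class = "crc_graph")
}

# naive per-position motif scan: explicit loop, string reverse via rev()
oracle_scan <- function(pwm, sequence, threshold_fraction = 0.8) {
  W <- log2(sweep(pwm$matrix, 2, pwm$background, "/"))
  L <- nrow(W)
  maxsc <- sum(apply(W, 1, max))
  thr <- threshold_fraction * maxsc
  score_at <- function(chars, o) {
    sc <- 0
    for (j in seq_len(L)) {
      b <- chars[o + j - 1L]
      if (!(b %in% c("A", "C", "G", "T"))) return(NA_real_)
      sc <- sc + W[j, b]
    }
    sc
  }
  hits <- list()
  fw <- strsplit(toupper(sequence), "")[[1]]
  n <- length(fw)
  if (n >= L) {
    rc <- rev(chartr("ACGTN", "TGCAN", fw))
    for (o in seq_len(n - L + 1L)) {
      s <- score_at(fw, o)
      if (!is.na(s) && s >= thr) {
        hits[[length(hits) + 1L]] <- data.frame(
          offset = o - 1L, strand = "+", log_odds = s)
      }
      s <- score_at(rc, o)
      if (!is.na(s) && s >= thr) {
        hits[[length(hits) + 1L]] <- data.frame(
          offset = n - (o - 1L) - L, strand = "-", log_odds = s)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(offset = integer(0), strand = character(0),
                      log_odds = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
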