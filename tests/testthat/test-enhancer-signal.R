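test_that("TSS-distance filter is strict and windows are midpoint-anchored", {
  tss <- make_tss(c(12400L, 900000L))
  pk <- data.frame(chrom = "chr1", start = 9500L, end = 10500L,
                   name = "p1", neg_log10_p = Inf,
                   summit_offset = NA_integer_)
  # midpoint 10000, nearest TSS 12400 -> distance 2400 <= 2500: excluded
  expect_equal(nrow(define_enhancers(pk, tss)), 0L)
  # distance 2501 > 2500: retained with the +-5 kb window
  enh <- define_enhancers(pk, make_tss(12501L))
  expect_equal(enh[, c("start", "end")],
               data.frame(start = 5000L, end = 15000L))
  # window clamped at chromosome start
  pk2 <- data.frame(chrom = "chr1", start = 2500L, end = 3500L,
                    name = "p2", neg_log10_p = Inf,
                    summit_offset = NA_integer_)
  enh <- define_enhancers(pk2, make_tss(900000L))
  expect_equal(enh[, c("start", "end")],
               data.frame(start = 0L, end = 8000L))
  expect_error(define_enhancers(pk, make_tss(integer(0))), "empty")
})

test_that("enhancer count is non-increasing in the TSS distance cutoff", {
  set.seed(7)
  pk <- random_intervals(80, n_chrom = 1, max_pos = 1e6, max_width = 1500)
  pk$name <- sprintf("p%d", seq_len(nrow(pk)))
  pk$neg_log10_p <- Inf
  pk$summit_offset <- NA_integer_
  tss <- make_tss(sort(as.integer(floor(runif(30, 0, 1e6)))))
  counts <- vapply(c(0, 1000, 2500, 5000, 20000), function(d)
    nrow(define_enhancers(pk, tss, min_tss_distance = d)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-bin signal matches the hand-counted overlap oracle", {
  enh <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  # one fragment overlapping bins 0-4 only
  tr <- make_track(0L, 500L)
  q <- quantify_enhancer_signal(enh, tr, bin_size = 100)
  expect_equal(q$signal, mean(c(rep(1, 5), rep(0, 5))) * 1e6 / 1)
  # no overlap -> 0
  q <- quantify_enhancer_signal(enh, make_track(5000L, 5200L), 100)
  expect_equal(q$signal, 0)
  # a fragment straddling a bin boundary counts in both bins
  q <- quantify_enhancer_signal(enh, make_track(95L, 105L), 100)
  expect_equal(q$signal, 2 / 10 * 1e6)
  # truncated last bin still counts
  enh2 <- data.frame(chrom = "chr1", start = 0L, end = 250L)
  q <- quantify_enhancer_signal(enh2, make_track(200L, 240L), 100)
  expect_equal(q$signal, (1 / 3) * 1e6)
  # zero-depth track errors
  empty <- sample_track("s0", "T01",
                        data.frame(chrom = character(0),
                                   start = integer(0), end = integer(0)))
  expect_error(quantify_enhancer_signal(enh, empty, 100), "zero total")
})

test_that("signal is invariant under uniform fragment duplication", {
  set.seed(3)
  enh <- data.frame(chrom = "chr1", start = c(0L, 20000L),
                    end = c(10000L, 30000L))
  fr <- random_intervals(500, n_chrom = 1, max_pos = 30000, max_width = 300)
  t1 <- sample_track("a", "T01", fr)
  t2 <- sample_track("a2", "T01", rbind(fr, fr))
  q1 <- quantify_enhancer_signal(enh, t1, 100)
  q2 <- quantify_enhancer_signal(enh, t2, 100)
  expect_equal(q1$signal, q2$signal)
})

test_that("genome bin matrix counts a fragment once per overlapped bin", {
  cs <- c(chr1 = 10000L)
  t1 <- make_track(100L, 300L)
  bm <- genome_bin_matrix(list(t1), cs, bin_size = 2000)
  expect_equal(ncol(bm$values), 5L)
  expect_equal(unname(bm$values[1, ]), c(1e6, 0, 0, 0, 0))
  # fragment spanning the bin-0/bin-1 boundary increments both
  t2 <- make_track(1900L, 2100L, sample_id = "s2")
  bm <- genome_bin_matrix(list(t2), cs, 2000)
  expect_equal(unname(bm$values[1, 1:2]), c(1e6, 1e6))
  # identical samples give identical rows
  t3 <- make_track(c(100L, 4100L), c(300L, 4300L), sample_id = "s3")
  t4 <- make_track(c(100L, 4100L), c(300L, 4300L), sample_id = "s4")
  bm <- genome_bin_matrix(list(t3, t4), cs, 2000)
  expect_equal(unname(bm$values[1, ]), unname(bm$values[2, ]))
  # fragments beyond the chromosome end are rejected
  expect_error(genome_bin_matrix(list(make_track(9900L, 10100L)), cs, 2000),
               "beyond chromosome end")
  expect_error(genome_bin_matrix(
    list(make_track(0L, 10L, chrom = "chrX")), cs, 2000), "chrX")
})

test_that("sample correlation has the expected structure and edge cases", {
  cs <- c(chr1 = 20000L)
  set.seed(9)
  fr <- random_intervals(300, n_chrom = 1, max_pos = 19000, max_width = 500)
  t1 <- sample_track("s1", "T01", fr)
  t2 <- sample_track("s2", "T01", fr)          # duplicate -> r = 1
  bm <- genome_bin_matrix(list(t1, t2), cs, 2000)
  cc <- sample_correlation(bm)
  expect_equal(cc["s1", "s2"], 1.0)
  expect_equal(diag(cc), c(s1 = 1, s2 = 1))
  expect_true(isSymmetric(cc))

  # anti-correlated rows built directly on the bin matrix
  bm$values <- rbind(s1 = 1:10, s2 = -(1:10) + 20)
  expect_equal(sample_correlation(bm)["s1", "s2"], -1.0)

  # independent samples over many bins: |r| small (seeded Monte Carlo)
  set.seed(10)
  bm$values <- rbind(a = runif(10000), b = runif(10000))
  expect_lt(abs(sample_correlation(bm)["a", "b"]), 0.05)

  bm$values <- rbind(s1 = rep(2, 10), s2 = 1:10)
  expect_error(sample_correlation(bm), "zero-variance sample.*s1")
})

test_that("bedGraph tracks reproduce fragment-track signal", {
  enh <- data.frame(chrom = "chr1", start = 0L, end = 400L)
  # two fragments covering [0,200); as bedGraph: value 2 over [0,200)
  t_frag <- make_track(c(0L, 0L), c(200L, 200L))
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t200\t2", bg)
  t_bg <- read_bedgraph_track(bg, "s1", "T01")
  expect_equal(t_bg$total_fragments, 2)
  q1 <- quantify_enhancer_signal(enh, t_frag, 100)
  q2 <- quantify_enhancer_signal(enh, t_bg, 100)
  expect_equal(q1$signal, q2$signal)
})
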