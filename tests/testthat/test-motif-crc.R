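test_that("provided NFRs are intersected with constituents and sequenced", {
  genome <- c(chr1 = paste(rep("ACGT", 100), collapse = ""))
  const <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                      name = "se1")
  nfr <- data.frame(chrom = "chr1", start = c(120L, 350L),
                    end = c(180L, 390L))
  got <- find_nfrs(const, genome, mode = "provided", nfr = nfr)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$start, got$end), c(120L, 180L))
  expect_equal(got$parent, "se1")
  expect_equal(got$sequence, substr(genome[["chr1"]], 121, 180))
  # partial overlap is clipped to the constituent
  nfr2 <- data.frame(chrom = "chr1", start = 180L, end = 260L)
  got <- find_nfrs(const, genome, "provided", nfr = nfr2)
  expect_equal(c(got$start, got$end), c(180L, 200L))
  expect_error(find_nfrs(data.frame(chrom = "chrZ", start = 1L, end = 10L),
                         genome, "provided",
                         nfr = data.frame(chrom = "chrZ", start = 1L,
                                          end = 5L)),
               "missing chromosome")
})

test_that("valley mode finds coverage dips between flanking peaks", {
  genome <- c(chr1 = paste(rep("A", 2000), collapse = ""))
  const <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  # twin rectangles of height 10 with a 100 bp low gap between them
  high1 <- do.call(rbind, replicate(10, data.frame(
    chrom = "chr1", start = 0L, end = 400L), simplify = FALSE))
  high2 <- do.call(rbind, replicate(10, data.frame(
    chrom = "chr1", start = 500L, end = 1000L), simplify = FALSE))
  low <- data.frame(chrom = "chr1", start = 400L, end = 500L)
  tr <- sample_track("s", "T", rbind(high1, high2, low))
  got <- find_nfrs(const, genome, mode = "valley", track = tr)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$start, got$end), c(400L, 500L))
  # flat coverage has no valley
  flat <- sample_track("s", "T", data.frame(chrom = "chr1", start = 0L,
                                            end = 1000L))
  expect_equal(nrow(find_nfrs(const, genome, "valley", track = flat)), 0L)
  # a wide-enough dip without a right flank is not an NFR
  edge <- sample_track("s", "T", rbind(high1))
  expect_equal(nrow(find_nfrs(const, genome, "valley", track = edge)), 0L)
})

test_that("motif scanning matches exact-match expectations and the N rule", {
  pwm <- make_exact_pwm("ACGT")
  hits <- scan_motif(pwm, "TTACGTTT", 0.8)
  # ACGT is its own reverse complement: one hit per strand at offset 2
  expect_equal(hits$offset, c(2L, 2L))
  expect_setequal(hits$strand, c("-", "+"))
  expect_equal(hits$log_odds, c(8, 8))

  expect_equal(nrow(scan_motif(pwm, "NNNN", 0.5)), 0L)
  expect_equal(nrow(scan_motif(pwm, "ACG", 0.8)), 0L)  # PWM longer than seq

  # degenerate uniform PWM: every window scores the maximum (0)
  uni <- make_exact_pwm("AA")
  uni$matrix[] <- 0.25
  hits <- scan_motif(uni, "ACGTAC", 1.0)
  expect_equal(sort(unique(hits$offset)), 0:4)
  expect_equal(nrow(hits), 10L)  # 5 offsets x 2 strands
})

test_that("scanning agrees with the naive per-position oracle", {
  set.seed(71)
  for (rep in 1:25) {
    pwm <- make_pwm(paste(sample(c("A", "C", "G", "T"), sample(4:8, 1),
                                 replace = TRUE), collapse = ""))
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    thr <- sample(c(0.6, 0.8, 1.0), 1)
    got <- scan_motif(pwm, s, thr)
    orc <- oracle_scan(pwm, s, thr)
    expect_equal(got[, c("offset", "strand")],
                 orc[, c("offset", "strand")])
    expect_equal(got$log_odds, orc$log_odds)
    # reverse complement: strand-swapped, position-mirrored hits
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    got_rc <- scan_motif(pwm, rc, thr)
    n <- nchar(s)
    L <- nrow(pwm$matrix)
    mirrored <- data.frame(
      offset = n - got$offset - L,
      strand = as.character(ifelse(got$strand == "+", "-", "+")),
      stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_equal(got_rc[, c("offset", "strand")], mirrored)
  }
})

test_that("enrichment p-values match exact hypergeometric computations", {
  pwm <- make_pwm("CCGGCCGG")
  with_motif <- paste0("AAAA", "CCGGCCGG", "AAAA")
  no_motif <- paste(rep("A", 16), collapse = "")
  # 10 targets all hit, 100 background none: p = 1 / choose(110, 10)
  et <- enrichment_test(rep(with_motif, 10), rep(no_motif, 100), pwm)
  expect_equal(et$n_target_hits, 10L)
  expect_equal(et$n_background_hits, 0L)
  expect_equal(et$p_value, 1 / choose(110, 10))
  # identical target and background: no enrichment signal
  et <- enrichment_test(rep(with_motif, 20), rep(with_motif, 20), pwm)
  expect_gte(et$p_value, 0.5)
  # zero target hits: upper tail at 0 is 1
  et <- enrichment_test(rep(no_motif, 10), rep(with_motif, 10), pwm)
  expect_equal(et$p_value, 1.0)
  expect_error(enrichment_test(character(0), no_motif, pwm), "target")
  expect_error(enrichment_test(no_motif, character(0), pwm), "background")
})

test_that("CRC graphs encode motif-in-SE-NFR regulation", {
  pwms <- list(TFA = make_pwm("ACCGGAAGTG", tf = "TFA"),
               TFB = make_pwm("CATGCCTAAG", tf = "TFB"),
               TFC = make_pwm("GTACGTCAGC", tf = "TFC"))
  allmot <- paste0("TTTTT", "ACCGGAAGTG", "TTTTT", "CATGCCTAAG",
                   "TTTTT", "GTACGTCAGC", "TTTTT")
  tf_to_se <- c(TFA = "se_a", TFB = "se_b", TFC = "se_c")
  # all three motifs in all three SEs: complete autoregulated triad
  nfrs <- list(se_a = allmot, se_b = allmot, se_c = allmot)
  g <- build_crc(tf_to_se, nfrs, pwms)
  expect_equal(g$autoregulated, c("TFA", "TFB", "TFC"))
  expect_equal(nrow(g$edges), 9L)
  cl <- enumerate_cliques(g)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$members[[1]], c("TFA", "TFB", "TFC"))
  expect_equal(cl$clique_score, 1.0)
  expect_equal(attr(cl, "tf_scores"),
               c(TFA = 1, TFB = 1, TFC = 1))

  # TFA's motif nowhere: no outgoing edges, not autoregulated
  no_a <- paste0("TTTTT", "CATGCCTAAG", "TTTTT", "GTACGTCAGC", "TTTTT")
  nfrs2 <- list(se_a = no_a, se_b = no_a, se_c = no_a)
  g2 <- build_crc(tf_to_se, nfrs2, pwms)
  expect_false("TFA" %in% g2$edges$from)
  expect_false("TFA" %in% g2$autoregulated)

  # TFA binds others' SEs but not its own: excluded from clique search
  nfrs3 <- list(se_a = no_a, se_b = allmot, se_c = allmot)
  g3 <- build_crc(tf_to_se, nfrs3, pwms)
  expect_true(any(g3$edges$from == "TFA" & g3$edges$to != "TFA"))
  expect_false("TFA" %in% g3$autoregulated)
  cl3 <- enumerate_cliques(g3)
  expect_false(any(vapply(cl3$members, function(m) "TFA" %in% m,
                          logical(1))))

  # TFs without a PWM are dropped with a warning
  expect_warning(
    g4 <- build_crc(c(tf_to_se, TFZ = "se_z"), nfrs, pwms),
    "TFZ")
  expect_false("TFZ" %in% g4$nodes)
})

test_that("clique enumeration equals the exhaustive-subset oracle", {
  g <- as_crc_graph(list(
    nodes = c("A", "B"),
    edges = data.frame(from = character(0), to = character(0))))
  expect_equal(nrow(enumerate_cliques(g)), 0L)

  set.seed(81)
  for (rep in 1:20) {
    rg <- random_digraph(sample(2:10, 1))
    got <- enumerate_cliques(as_crc_graph(rg), min_size = 2)
    orc <- oracle_cliques(rg$nodes, rg$edges, min_size = 2)
    got_sets <- lapply(got$members, sort)
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(orc, paste, "", collapse = ","))
  }
})

test_that("lowering the motif threshold never removes CRC edges", {
  set.seed(91)
  pwms <- list(TFA = make_pwm("ACCGGAAGTG", tf = "TFA"),
               TFB = make_pwm("CATGCCTAAG", tf = "TFB"))
  tf_to_se <- c(TFA = "se_a", TFB = "se_b")
  for (rep in 1:10) {
    nfrs <- list(se_a = rand_seqs(3, 40), se_b = rand_seqs(3, 40))
    key <- function(g) paste(g$edges$from, g$edges$to)
    e_hi <- key(build_crc(tf_to_se, nfrs, pwms, threshold_fraction = 0.8))
    e_lo <- key(build_crc(tf_to_se, nfrs, pwms, threshold_fraction = 0.5))
    expect_true(all(e_hi %in% e_lo))
  }
})
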