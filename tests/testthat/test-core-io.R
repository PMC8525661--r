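test_that("narrowPeak parsing maps columns and sorts by position", {
  tf <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c(
    "chr2\t100\t600\tpk3\t900\t.\t4.1\t120.0\t80.0\t250",
    "chr1\t5000\t5400\tpk2\t800\t.\t3.0\t5.0\t2.0\t-1",
    "chr1\t100\t900\tpk1\t700\t.\t6.2\t12.0\t9.0\t400"
  ), tf)
  pk <- read_peaks(tf, format = "narrowPeak")
  expect_equal(pk$name, c("pk1", "pk2", "pk3"))
  expect_equal(pk$neg_log10_p, c(12.0, 5.0, 120.0))
  expect_equal(pk$summit_offset, c(400L, NA_integer_, 250L))
  expect_equal(pk$start, c(100L, 5000L, 100L))
})

test_that("empty and header-only peak files give empty tables", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), tf)
  expect_equal(nrow(read_peaks(tf, "bed")), 0L)
  writeLines(c("# comment", "track name=x"), tf)
  expect_equal(nrow(read_peaks(tf, "bed")), 0L)
})

test_that("malformed peak lines fail with the offending line number", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t100\t100"), tf)
  expect_error(read_peaks(tf, "bed"), "line 2.*invalid interval")
  writeLines(c("chr1\t100\t200\tx", "chr1\tabc\t300"), tf)
  expect_error(read_peaks(tf, "bed"), "line 2.*non-numeric")
  writeLines("chr1\t100", tf)
  expect_error(read_peaks(tf, "bed"), "line 1.*columns")
})

test_that("BED peaks carry the pre-filtered significance sentinel", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30\t40\tnamed"), tf)
  pk <- read_peaks(tf, "bed")
  expect_true(all(is.infinite(pk$neg_log10_p)))
  expect_equal(pk$name, c("peak_1", "named"))
})

test_that("significance filter uses strict p < threshold and is idempotent", {
  pk <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                   end = c(50L, 150L, 250L), name = c("a", "b", "c"),
                   neg_log10_p = c(8.9, 9.1, Inf),
                   summit_offset = NA_integer_)
  kept <- filter_significant(pk, 1e-9)
  expect_equal(kept$name, c("b", "c"))
  expect_equal(filter_significant(kept, 1e-9), kept)
  expect_equal(nrow(filter_significant(pk, 1.0)), 3L)
  expect_equal(nrow(filter_significant(pk[0, ], 1e-9)), 0L)
  expect_error(filter_significant(pk, 0), "p_threshold")
})

test_that("TSS coordinates follow strand and format conventions", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t2000\tGENE1\t0\t-",
               "chr1\t3000\t4000\tGENE2\t0\t+"), tf)
  ts <- read_tss(tf, "bed6")
  expect_equal(ts$tss, c(1999L, 3000L))

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t501\t800\t.\t+\t.\tgene_id "G1"; gene_name "GENE1";',
    'chr1\tsrc\texon\t501\t600\t.\t+\t.\tgene_id "G1";',
    'chr1\tsrc\tgene\t901\t1200\t.\t-\t.\tgene_id "G2";'
  ), gtf)
  ts <- read_tss(gtf, "gtf")
  expect_equal(nrow(ts), 2L)  # exon feature skipped
  expect_equal(ts$tss, c(500L, 1199L))
  expect_equal(ts$gene_symbol, c("GENE1", "G2"))

  writeLines("chr1\t1000\t2000\tGENE1\t0\t.", tf)
  expect_error(read_tss(tf, "bed6"), "strand")
})

test_that("PFM parsing normalizes with the pseudocount", {
  tf <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 TF1", "A [ 8 2 ]", "C [ 0 2 ]", "G [ 0 2 ]",
               "T [ 0 2 ]"), tf)
  pw <- read_pwms(tf)[[1]]
  expect_equal(pw$tf_name, "TF1")
  expect_equal(unname(pw$matrix[1, ]), c(9, 1, 1, 1) / 12)
  expect_equal(unname(pw$matrix[2, ]), rep(0.25, 4))
  expect_equal(sum(pw$background), 1)
  expect_true(all(abs(rowSums(pw$matrix) - 1) < 1e-9))

  writeLines(c(">M2", "8 0", "0 8", "8 0", "0 8"), tf)  # bare-number dialect
  pw <- read_pwms(tf, pseudocount = 0)[[1]]
  expect_equal(unname(pw$matrix[1, ]), c(1, 0, 1, 0) / 2)

  writeLines(c(">M3", "A [ 1 1 ]", "C [ 1 ]", "G [ 1 1 ]", "T [ 1 1 ]"), tf)
  expect_error(read_pwms(tf), "unequal row lengths")
  writeLines(c(">M4", "A [ 1 1 ]", "C [ 1 1 ]", "G [ 1 1 ]"), tf)
  expect_error(read_pwms(tf), "4 base rows")
})

test_that("BED writing round-trips interval tables", {
  set.seed(42)
  iv <- random_intervals(100)
  iv <- iv[order(iv$chrom, iv$start, iv$end), ]
  rownames(iv) <- NULL
  iv$name <- sprintf("iv%03d", seq_len(nrow(iv)))
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, tf)
  back <- read_peaks(tf, "bed")
  expect_equal(back[, c("chrom", "start", "end", "name")],
               iv[, c("chrom", "start", "end", "name")])

  write_bed(iv[0, ], tf)
  expect_equal(nrow(read_peaks(tf, "bed")), 0L)
  expect_match(readLines(tf)[1], "^#chrom\tstart\tend")
})

test_that("GTF -> internal -> BED conversion preserves interval length", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  lens <- c(300L, 1L, 25000L)
  writeLines(sprintf(
    'chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tgene_id "G%d";',
    c(501L, 99L, 12345L), c(501L, 99L, 12345L) + lens - 1L, 1:3), gtf)
  ts <- read_tss(gtf, "gtf")
  # '+' TSS is the 0-based first base: 1-based start - 1
  expect_equal(ts$tss, c(500L, 98L, 12344L))
  bed <- data.frame(chrom = ts$chrom, start = ts$tss,
                    end = ts$tss + lens, name = ts$gene_id)
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, tf)
  back <- read_peaks(tf, "bed")  # sorted by (chrom, start) on read
  expect_equal(setNames(back$end - back$start, back$name),
               setNames(lens, ts$gene_id)[back$name])
})

test_that("chrom.sizes reads names and lengths", {
  tf <- withr::local_tempfile(fileext = ".sizes")
  writeLines(c("chr1\t1000000", "chr2\t500000"), tf)
  cs <- read_chrom_sizes(tf)
  expect_equal(cs, c(chr1 = 1000000L, chr2 = 500000L))
  writeLines("chr1\t0", tf)
  expect_error(read_chrom_sizes(tf), "positive")
})
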