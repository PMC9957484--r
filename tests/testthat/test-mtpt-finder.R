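test_that("a planted chloroplast segment is found exactly", {
  set.seed(501)
  cp_seq <- rdna(15000, 0.37)
  mt_seq <- rdna(20000, 0.45)
  seg <- substr(cp_seq, 6000, 6499)
  mt_seq <- splice_at(mt_seq, 9000, seg)
  mt <- genome_set(c(mt1 = mt_seq)); cp <- genome_set(c(cp1 = cp_seq))
  hits <- find_mtpts(mt, cp)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mt_start, 9000L)
  expect_equal(hits$mt_end, 9499L)
  expect_equal(hits$cp_start, 6000L)
  expect_equal(hits$cp_end, 6499L)
  expect_equal(hits$length, 500L)
  expect_equal(hits$identity, 100)
  expect_lte(hits$evalue, 1e-5)
})

test_that("unrelated random genomes yield no hits at the default threshold", {
  set.seed(502)
  mt <- genome_set(c(mt1 = rdna(20000)))
  cp <- genome_set(c(cp1 = rdna(15000)))
  expect_equal(nrow(find_mtpts(mt, cp)), 0)
  expect_error(find_mtpts(genome_set(), cp), "non-empty")
})

test_that("one cp segment at two mt loci gives two hits sharing cp coordinates", {
  set.seed(503)
  cp_seq <- rdna(15000, 0.37)
  mt_seq <- rdna(25000, 0.45)
  seg <- substr(cp_seq, 2000, 2399)
  mt_seq <- splice_at(mt_seq, 5000, seg)
  mt_seq <- splice_at(mt_seq, 18000, seg)
  hits <- find_mtpts(genome_set(c(mt1 = mt_seq)),
                     genome_set(c(cp1 = cp_seq)))
  expect_equal(nrow(hits), 2)
  # chance 1 bp extensions into matching background are legitimate
  expect_true(all(abs(hits$mt_start - c(5000L, 18000L)) <= 2))
  expect_true(all(abs(hits$cp_start - 2000L) <= 2))
  expect_true(all(abs(hits$cp_end - 2399L) <= 2))
})

test_that("reverse-strand transfers are detected", {
  set.seed(504)
  cp_seq <- rdna(12000, 0.37)
  mt_seq <- rdna(18000, 0.45)
  seg <- substr(cp_seq, 4000, 4299)
  mt_seq <- splice_at(mt_seq, 7000, rc_chr(seg))
  hits <- find_mtpts(genome_set(c(mt1 = mt_seq)),
                     genome_set(c(cp1 = cp_seq)))
  expect_equal(nrow(hits), 1)
  expect_identical(hits$strand, "-")
  expect_lte(abs(hits$cp_start - 4000L), 2)
  expect_lte(abs(hits$mt_start - 7000L), 2)
})

test_that("tightening the e-value threshold never adds hits", {
  set.seed(505)
  cp_seq <- rdna(15000, 0.37)
  mt_seq <- rdna(20000, 0.45)
  for (at in c(3000, 8000, 14000)) {
    len <- sample(40:120, 1)
    cs <- sample(10000, 1)
    mt_seq <- splice_at(mt_seq, at, sub_mutate(substr(cp_seq, cs, cs + len - 1),
                                               round(len * 0.05)))
  }
  mt <- genome_set(c(mt1 = mt_seq)); cp <- genome_set(c(cp1 = cp_seq))
  thresholds <- c(1e-2, 1e-5, 1e-10, 1e-20)
  counts <- vapply(thresholds, function(t) nrow(find_mtpts(mt, cp, t)), 0L)
  expect_true(all(diff(counts) <= 0))
  keys <- lapply(thresholds, function(t) {
    h <- find_mtpts(mt, cp, t)
    paste(h$mt_start, h$mt_end)
  })
  for (i in seq_len(length(keys) - 1))
    expect_true(all(keys[[i + 1]] %in% keys[[i]]))
})

test_that("overlapping and abutting hits merge on the mt axis", {
  base <- data.frame(
    mt_chrom = "mt1", mt_start = c(100L, 301L, 800L),
    mt_end = c(300L, 450L, 900L), cp_chrom = "cp1",
    cp_start = c(1L, 1L, 1L), cp_end = c(10L, 10L, 10L),
    strand = "+", length = c(201L, 150L, 101L),
    identity = c(99, 95, 100), score = c(300L, 200L, 180L),
    evalue = c(1e-30, 1e-20, 1e-10), stringsAsFactors = FALSE)
  merged <- merge_mtpt_hits(base)
  # rows 1 and 2 abut (300 -> 301): count drops by one, total bp unchanged
  expect_equal(nrow(merged), 2)
  expect_equal(sum(merged$mt_end - merged$mt_start + 1),
               sum(c(300 - 100 + 1 + 450 - 301 + 1, 900 - 800 + 1)))
  expect_equal(merged$mt_start[1], 100L)
  expect_equal(merged$mt_end[1], 450L)
  expect_equal(merged$evalue[1], 1e-30)  # best component metadata kept
})

test_that("summaries report count, summed length and percentage", {
  empty <- find_mtpts(genome_set(c(m = rdna(5000))),
                      genome_set(c(c = rdna(5000))))
  s0 <- summarize_mtpts(empty, 436464)
  expect_equal(s0$count, 0L)
  expect_equal(s0$total_bp, 0L)
  expect_equal(s0$percent, 0)
  # planted blocks totalling 3237 bp on a 436,464 bp genome occupy 0.74%
  hits <- data.frame(mt_chrom = "mt1",
                     mt_start = c(1000L, 10000L, 30000L),
                     mt_end = c(1000L + 879L - 1L, 10000L + 1479L - 1L,
                                30000L + 879L - 1L))
  expect_equal(sum(hits$mt_end - hits$mt_start + 1), 3237)
  s <- summarize_mtpts(hits, 436464)
  expect_equal(s$total_bp, 3237L)
  expect_equal(s$percent, 0.74)
  expect_equal(s$percent, round(100 * 3237 / 436464, 2))
})

test_that("hits can be labelled with overlapping features", {
  hits <- data.frame(mt_chrom = "mt1", mt_start = c(100L, 5000L),
                     mt_end = c(400L, 5300L), stringsAsFactors = FALSE)
  feats <- data.frame(chrom = "mt1", start = c(50L, 350L, 9000L),
                      end = c(120L, 600L, 9500L),
                      name = c("trnD-GUC", "psbA", "ndhC"),
                      stringsAsFactors = FALSE)
  ann <- annotate_mtpts(hits, feats)
  expect_identical(ann$features, c("trnD-GUC,psbA", ""))
  # TSV path input
  tsv <- tempfile(fileext = ".tsv")
  write.table(feats, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(annotate_mtpts(hits, tsv)$features, c("trnD-GUC,psbA", ""))
  expect_error(annotate_mtpts(hits, data.frame(x = 1)), "columns")
})

test_that("planted transfers at 90-100% identity are recovered precisely", {
  set.seed(506)
  for (rep in 1:10) {
    cp_seq <- rdna(15000, 0.37)
    mt_seq <- rdna(20000, 0.45)
    n_seg <- sample(1:4, 1)
    truth <- list()
    at <- 2000
    for (i in seq_len(n_seg)) {
      len <- sample(50:900, 1)
      ident <- runif(1, 90, 100)
      cs <- 2000 + (i - 1) * 3200
      seg <- sub_mutate(substr(cp_seq, cs, cs + len - 1),
                        round((1 - ident / 100) * len))
      mt_seq <- splice_at(mt_seq, at, seg)
      truth[[i]] <- c(at, at + len - 1)
      at <- at + len + 2500
    }
    hits <- find_mtpts(genome_set(c(mt1 = mt_seq)),
                       genome_set(c(cp1 = cp_seq)))
    for (tr in truth) {
      match <- which(abs(hits$mt_start - tr[1]) <= 10 &
                       abs(hits$mt_end - tr[2]) <= 10)
      expect_length(match, 1)
    }
  }
})
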