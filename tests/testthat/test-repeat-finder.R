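test_that("classify_size bins repeats by the survey size classes", {
  expect_identical(classify_size(7887), "large")
  expect_identical(classify_size(1235), "large")
  expect_identical(classify_size(89), "short")
  expect_identical(classify_size(331), "medium")
  # boundary ties: 100 and 1000 are medium
  expect_identical(classify_size(c(99, 100, 1000, 1001)),
                   c("short", "medium", "medium", "large"))
  expect_error(classify_size(0), ">= 1")
})

test_that("a planted exact direct repeat is found exactly (with oracle)", {
  set.seed(101)
  fx <- plant_pair_genome(50000, 500, s1 = 12000, s2 = 31000)
  pairs <- find_repeat_pairs(fx$genome, min_length = 100)
  expect_length(pairs, 1)
  p <- pairs[[1]]
  expect_identical(p$id, "R1")
  expect_equal(p$length, 500L)
  expect_equal(p$identity, 100)
  expect_identical(p$orientation, "direct")
  expect_equal(c(p$copy1$location$start, p$copy1$location$end), c(12000L, 12499L))
  expect_equal(c(p$copy2$location$start, p$copy2$location$end), c(31000L, 31499L))
  # brute-force all-substring-pairs oracle agrees
  expect_identical(repeat_pair_keys(pairs),
                   oracle_exact_repeats(list(chrA = fx$seq), 100))
})

test_that("a repeat-free random genome yields no pairs (oracle-confirmed)", {
  set.seed(102)
  s <- rdna(20000)
  pairs <- find_repeat_pairs(genome_set(c(chrA = s)), min_length = 100)
  expect_length(pairs, 0)
  expect_length(oracle_exact_repeats(list(chrA = s), 100), 0)
  expect_length(find_repeat_pairs(genome_set(), min_length = 100), 0)
  expect_error(find_repeat_pairs(genome_set(c(a = "ACGT")), min_length = 10),
               "min_length")
})

test_that("inverted and inter-chromosomal plantings are recovered", {
  set.seed(103)
  fx <- plant_pair_genome(40000, 300, s1 = 5000, s2 = 22000, inverted = TRUE)
  pairs <- find_repeat_pairs(fx$genome, min_length = 100)
  expect_length(pairs, 1)
  expect_identical(pairs[[1]]$orientation, "inverted")
  expect_identical(pairs[[1]]$copy2$location$strand, "-")
  expect_equal(pairs[[1]]$copy2$location$start, 22000L)
  # copy1 sequence equals revcomp of copy2 sequence for an exact inverted pair
  expect_identical(pairs[[1]]$copy1$seq,
                   reverse_complement(pairs[[1]]$copy2$seq))

  sA <- rdna(25000); sB <- rdna(12000)
  seg <- substr(sA, 8000, 8799)
  sB <- splice_at(sB, 4000, seg)
  g <- genome_set(c(chr1 = sA, chr2 = sB))
  pairs2 <- find_repeat_pairs(g, min_length = 100)
  expect_length(pairs2, 1)
  expect_identical(pairs2[[1]]$copy1$location$chrom, "chr1")
  expect_identical(pairs2[[1]]$copy2$location$chrom, "chr2")
  # chance 1 bp extensions into matching flank characters are legitimate
  expect_lte(abs(pairs2[[1]]$length - 800L), 5)
})

test_that("diverged planted pairs are recovered with tight boundaries", {
  set.seed(104)
  # identity 97: 24 substitutions over 800 bp
  fx <- plant_pair_genome(30000, 800, s1 = 4000, s2 = 18000, nmut = 24)
  pairs <- find_repeat_pairs(fx$genome)
  expect_length(pairs, 1)
  p <- pairs[[1]]
  expect_lt(abs(p$identity - 97), 1)
  expect_lte(abs(p$copy1$location$start - 4000), 5)
  expect_lte(abs(p$copy2$location$end - 18799), 5)
})

test_that("planting recovery holds across random genomes and parameter ranges", {
  set.seed(105)
  for (rep in 1:15) {
    n_pairs <- sample(1:3, 1)
    sA <- rdna(30000); sB <- rdna(14000)
    planted <- list()
    at1 <- 2000
    for (i in seq_len(n_pairs)) {
      len <- sample(89:3000, 1)
      ident <- runif(1, 95, 100)
      nmut <- round((1 - ident / 100) * len)
      inter <- runif(1) < 0.4
      inverted <- runif(1) < 0.5
      src <- substr(sA, at1, at1 + len - 1)
      copy <- sub_mutate(src, nmut)
      if (inverted) copy <- rc_chr(copy)
      if (inter) {
        at2 <- 2000 + (i - 1) * 4500
        sB <- splice_at(sB, at2, copy)
        host2 <- "chr2"
      } else {
        at2 <- 16000 + (i - 1) * 4500
        sA <- splice_at(sA, at2, copy)
        host2 <- "chr1"
      }
      planted[[i]] <- list(s1 = at1, e1 = at1 + len - 1, host2 = host2,
                           s2 = at2, e2 = at2 + len - 1, len = len)
      at1 <- at1 + len + 1500
    }
    g <- genome_set(c(chr1 = sA, chr2 = sB))
    pairs <- find_repeat_pairs(g, min_length = 50, min_identity = 90)
    for (pl in planted) {
      hit <- Filter(function(p)
        p$copy1$location$chrom == "chr1" &&
          abs(p$copy1$location$start - pl$s1) <= 5 &&
          p$copy2$location$chrom == pl$host2 &&
          abs(p$copy2$location$start - pl$s2) <= 5, pairs)
      expect_length(hit, 1)
      expect_lte(abs(hit[[1]]$length - pl$len), 10)
    }
  }
})

test_that("one long planting (8 kb) is recovered", {
  set.seed(106)
  fx <- plant_pair_genome(30000, 8000, s1 = 2000, s2 = 15000, nmut = 80)
  pairs <- find_repeat_pairs(fx$genome)
  expect_length(pairs, 1)
  expect_lte(abs(pairs[[1]]$length - 8000), 10)
  expect_identical(pairs[[1]]$size_class, "large")
})

test_that("results are invariant under chromosome input order", {
  set.seed(107)
  sA <- rdna(20000); sB <- rdna(9000)
  seg <- substr(sA, 3000, 3599)
  sB <- splice_at(sB, 2000, rc_chr(seg))
  g1 <- genome_set(c(chr1 = sA, chr2 = sB))
  g2 <- genome_set(c(chr2 = sB, chr1 = sA))
  expect_identical(repeat_pair_keys(find_repeat_pairs(g1, min_length = 100)),
                   repeat_pair_keys(find_repeat_pairs(g2, min_length = 100)))
})

test_that("ids follow descending length and the report table mirrors it", {
  set.seed(108)
  s <- rdna(40000)
  s <- splice_at(s, 20000, substr(s, 2000, 2999))   # 1000 bp pair
  s <- splice_at(s, 30000, substr(s, 8000, 8299))   # 300 bp pair
  pairs <- find_repeat_pairs(genome_set(c(chrA = s)), min_length = 100)
  expect_length(pairs, 2)
  expect_identical(vapply(pairs, `[[`, "", "id"), c("R1", "R2"))
  expect_true(pairs[[1]]$length >= pairs[[2]]$length)
  tab <- repeat_pairs_table(pairs)
  expect_identical(tab$id, c("R1", "R2"))
  expect_true(all(grepl("; ", tab$position, fixed = TRUE)))
})
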