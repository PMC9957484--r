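test_that("generated genomes hit the configured GC and are deterministic", {
  cfg <- sim_config(seed = 7)
  gen <- generate_genome(cfg)
  expect_identical(names(gen$genome$chromosomes), c("chr1", "chr2"))
  expect_equal(total_length(gen$genome), 43000L)
  expect_lt(abs(gc_content(gen$genome) - 0.452), 0.01)
  gen2 <- generate_genome(cfg)
  expect_identical(gen2$genome$chromosomes$chr1$seq,
                   gen$genome$chromosomes$chr1$seq)
  expect_identical(gen2$cp$chromosomes$cp1$seq, gen$cp$chromosomes$cp1$seq)
  # a different seed gives a different genome
  gen3 <- generate_genome(sim_config(seed = 8))
  expect_false(identical(gen3$genome$chromosomes$chr1$seq,
                         gen$genome$chromosomes$chr1$seq))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(generate_genome(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("planted features match their specs and the truth record", {
  cfg <- sim_config(seed = 11, repeat_specs = list(
    list(length = 800L, identity = 97, orientation = "inverted",
         placement = "intra"),
    list(length = 300L, identity = 100, orientation = "direct",
         placement = "inter")),
    alt_fractions = c(0.5, 0.1))
  gen <- generate_genome(cfg)
  tr <- gen$truth$repeats
  expect_named(tr, c("P1", "P2"))
  expect_identical(tr$P1$orientation, "inverted")
  expect_equal(tr$P1$identity, 97, tolerance = 0.001)
  # the finder recovers both planted pairs with identity within 1 point
  pairs <- find_repeat_pairs(gen$genome)
  expect_length(pairs, 2)
  found_ident <- sort(vapply(pairs, `[[`, 0, "identity"))
  expect_lt(abs(found_ident[1] - 97), 1)
  expect_equal(found_ident[2], 100)
  # planted MTPTs are recoverable and recorded
  expect_equal(nrow(gen$truth$mtpts), 5)
  hits <- find_mtpts(gen$genome, gen$cp)
  for (i in seq_len(nrow(gen$truth$mtpts)))
    expect_true(any(abs(hits$mt_start - gen$truth$mtpts$mt_start[i]) <= 10))
  expect_error(
    generate_genome(sim_config(chromosome_lengths = c(chr1 = 8000L),
                               repeat_specs = list(list(
                                 length = 7000L, identity = 100,
                                 orientation = "direct",
                                 placement = "intra")),
                               alt_fractions = 0.5)),
    "does not fit")
})

test_that("molecule pools mix major and recombined forms as labelled", {
  cfg <- sim_config(seed = 7)
  gen <- generate_genome(cfg)
  pool0 <- simulate_molecule_pool(gen$genome, gen$truth$repeats$P1, 0)
  sim0 <- simulate_reads(pool0, read_params(count = 50, mean_length = 1500,
                                            sdlog = 0.2), seed = 1)
  expect_true(all(sim0$truth$label == "major"))
  pool1 <- simulate_molecule_pool(gen$genome, gen$truth$repeats$P1, 1)
  sim1 <- simulate_reads(pool1, read_params(count = 50, mean_length = 1500,
                                            sdlog = 0.2), seed = 1)
  expect_true(all(sim1$truth$label == "alt"))
  expect_error(simulate_molecule_pool(gen$genome, gen$truth$repeats$P1, 1.2),
               "alt_fraction")
  # the intra-chromosomal direct pair yields two fission circles in the pool
  expect_setequal(unique(pool1$label), c("major", "alt"))
  expect_equal(sum(pool1$label == "alt"), 2L)
})

test_that("simulated reads obey the length and error model", {
  cfg <- sim_config(seed = 7)
  gen <- generate_genome(cfg)
  pool <- simulate_molecule_pool(gen$genome, gen$truth$repeats$P1, 0.3)
  # error rate 0: every read is an exact substring of a pool molecule
  sim0 <- simulate_reads(pool, read_params(count = 100, mean_length = 1500,
                                           sdlog = 0.3, error_rate = 0),
                         seed = 3)
  doubled <- lapply(pool$molecules, function(m) strrep(m$seq, 2))
  for (i in seq_along(sim0$reads)) {
    rd <- sim0$reads[[i]]
    src <- doubled[[sim0$truth$molecule[i]]]
    expect_true(grepl(rd, src, fixed = TRUE) ||
                  grepl(rc_chr(rd), src, fixed = TRUE))
  }
  # 10,000 reads at mean 8,000 bp: empirical mean within 2% (a pool of the
  # 30 kb chromosome alone, so truncation at molecule length is negligible)
  pool_big <- simulate_molecule_pool(gen$genome, gen$truth$repeats$P1, 0)
  simL <- simulate_reads(pool_big, read_params(count = 10000,
                                               mean_length = 8000,
                                               error_rate = 0), seed = 4)
  expect_lt(abs(mean(nchar(simL$reads)) - 8000) / 8000, 0.02)
  # determinism and truth completeness
  simA <- simulate_reads(pool, read_params(count = 80), seed = 12)
  simB <- simulate_reads(pool, read_params(count = 80), seed = 12)
  expect_identical(simA$reads, simB$reads)
  expect_identical(simA$truth, simB$truth)
  expect_equal(anyDuplicated(simA$truth$read_id), 0L)
  expect_setequal(names(simA$reads), simA$truth$read_id)
  # errors at 5% change roughly that fraction of bases
  simE <- simulate_reads(pool, read_params(count = 200, mean_length = 2000,
                                           sdlog = 0.2), seed = 13)
  lens <- nchar(simE$reads)
  expect_lt(abs(mean(lens) - 2000) / 2000, 0.05)
})

test_that("simulate_bundle writes a complete, re-readable bundle", {
  outdir <- file.path(tempdir(), "bundle-test")
  cfg <- sim_config(seed = 21,
                    read_params = read_params(count = 30, mean_length = 1500,
                                              sdlog = 0.2))
  bundle <- simulate_bundle(cfg, outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("genome.fasta", "chloroplast.fasta", "reads.fastq", "read_truth.tsv",
      "truth.json", "pool_P1.fasta", "pool_P2.fasta")))))
  g <- read_fasta(file.path(outdir, "genome.fasta"))
  expect_identical(g$chromosomes$chr1$seq, bundle$genome$chromosomes$chr1$seq)
  reads <- read_reads(file.path(outdir, "reads.fastq"))
  expect_length(reads, 60)  # 30 per repeat pair
  expect_identical(unname(reads), unname(bundle$reads))
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"))
  expect_named(truth$repeats, c("P1", "P2"))
  unlink(outdir, recursive = TRUE)
})
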