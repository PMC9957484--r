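# Seeded synthetic-data generation: multipartite circular genomes with
# planted repeat pairs and plastid-derived segments, conformer molecule pools
# at stated mixture fractions, and error-bearing nanopore-like long reads
# with complete truth records.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Random DNA string at a target GC content
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/2`. Uses the current RNG
#' state (wrap in `set.seed()` or pass through [generate_genome()] for
#' reproducibility).
#'
#' @param n Length in bp.
#' @param gc Target GC fraction.
#' @return A DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Read-simulation parameters
#'
#' Defaults emulate a plausible nanopore run: log-normal read lengths (mean
#' 8 kb, shape factor 1.6) and a 5% per-base error rate split 40/30/30 between
#' substitutions, insertions and deletions. Quality scores are a constant
#' placeholder.
#'
#' @param count Number of reads.
#' @param mean_length Mean read length in bp (log-normal `meanlog` is derived
#'   so the distribution mean equals this).
#' @param sdlog Log-scale standard deviation of the length distribution.
#' @param error_rate Total per-base error rate.
#' @param error_mix Length-3 vector of substitution/insertion/deletion shares
#'   (normalized to sum to 1).
#' @param min_length Reads shorter than this are redrawn at the floor.
#' @param spanning If `TRUE`, reads are drawn conditioned to span a planted
#'   repeat copy plus `span_anchor` bp on each side (importance sampling of
#'   the informative reads; the conformation mixture is untouched).
#' @param span_anchor Flank coverage required of spanning reads, bp.
#' @return A `ReadParams` list.
#' @export
read_params <- function(count = 2000L, mean_length = 8000, sdlog = log(1.6),
                        error_rate = 0.05,
                        error_mix = c(sub = 0.4, ins = 0.3, del = 0.3),
                        min_length = 500L, spanning = FALSE,
                        span_anchor = 200L) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  error_mix <- error_mix / sum(error_mix)
  structure(list(count = as.integer(count), mean_length = mean_length,
                 sdlog = sdlog, error_rate = error_rate,
                 error_mix = error_mix, min_length = as.integer(min_length),
                 spanning = isTRUE(spanning),
                 span_anchor = as.integer(span_anchor)),
            class = "ReadParams")
}

#' Simulation configuration
#'
#' The desk-scale defaults mirror the shape of a two-chromosome plant
#' mitochondrial genome at one tenth scale (30 kb + 13 kb circles, GC 0.452)
#' with two planted direct repeats standing in for the large intra- and
#' inter-chromosomal recombination-active repeats, alternative-conformation
#' fractions at the observed extremes, and a handful of chloroplast-derived
#' segments spanning the reported MTPT length range.
#'
#' @param seed Integer master seed; identical config + seed gives
#'   byte-identical outputs.
#' @param chromosome_lengths Named integer vector of circular chromosome
#'   lengths.
#' @param gc GC fraction of the random background.
#' @param repeat_specs List of repeat plans: each a list with `length`,
#'   `identity` (percent), `orientation` (`"direct"`/`"inverted"`) and
#'   `placement` (`"intra"`/`"inter"`).
#' @param alt_fractions Numeric vector (one per repeat spec) of
#'   alternative-conformation fractions in `[0, 1]`.
#' @param cp_length Chloroplast genome length.
#' @param mtpt_specs List of plastid-transfer plans: each a list with `length`
#'   and `identity`.
#' @param read_params A [read_params()] object.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       chromosome_lengths = c(chr1 = 30000L, chr2 = 13000L),
                       gc = 0.452,
                       repeat_specs = list(
                         list(length = 800L, identity = 100,
                              orientation = "direct", placement = "intra"),
                         list(length = 124L, identity = 100,
                              orientation = "direct", placement = "inter")),
                       alt_fractions = c(0.5467, 0.0111),
                       cp_length = 15000L,
                       mtpt_specs = list(
                         list(length = 880L, identity = 100),
                         list(length = 320L, identity = 98),
                         list(length = 150L, identity = 97),
                         list(length = 90L, identity = 95),
                         list(length = 60L, identity = 100)),
                       read_params = mitorecomb::read_params()) {
  if (any(gc < 0 | gc > 1)) stop("gc must be in [0, 1]")
  if (any(alt_fractions < 0 | alt_fractions > 1))
    stop("alt_fractions must be in [0, 1]")
  for (rs in repeat_specs) {
    if (rs$length < 1) stop("repeat lengths must be positive")
    if (rs$identity <= 0 || rs$identity > 100)
      stop("identity must be in (0, 100]")
  }
  if (length(alt_fractions) != length(repeat_specs))
    stop("need one alt_fraction per repeat spec")
  structure(list(seed = as.integer(seed),
                 chromosome_lengths = chromosome_lengths, gc = gc,
                 repeat_specs = repeat_specs, alt_fractions = alt_fractions,
                 cp_length = as.integer(cp_length), mtpt_specs = mtpt_specs,
                 read_params = read_params),
            class = "SimulationConfig")
}

# Mutate `seq` down to `identity` percent by substitutions at distinct
# random positions (planting uses substitutions only, so planted identity is
# exact and ungapped detection recovers the full span).
mutate_to_identity <- function(seq, identity) {
  len <- nchar(seq)
  nmut <- round((1 - identity / 100) * len)
  if (nmut == 0) return(seq)
  pos <- sample.int(len, nmut)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# pick `n` window starts of width `w` on a chromosome of length `L`, keeping
# `gap` bp clear of every interval in `occupied` (list of c(start, end)) and
# away from the origin (windows must not wrap)
pick_windows <- function(n, w, L, occupied, gap = 2500L, tries = 2000L) {
  starts <- integer(0)
  occ <- occupied
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(tries)) {
      s <- sample.int(L - w - 1L, 1L) + 1L
      e <- s + w - 1L
      clash <- FALSE
      for (iv in occ)
        if (overlap_bp(s - gap, e + gap, iv[1], iv[2]) > 0L) {
          clash <- TRUE; break
        }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place a ", w, " bp window on a ", L,
                  " bp chromosome (too crowded)")
    starts <- c(starts, s)
    occ <- c(occ, list(c(s, e)))
  }
  starts
}

#' Generate a synthetic genome with planted repeats and plastid transfers
#'
#' Builds random circular chromosomes at the requested GC, plants each repeat
#' by copying a source window to a second locus (mutated to the requested
#' identity by substitutions; reverse-complemented when inverted), generates a
#' chloroplast genome and copies segments of it into the mitochondrial genome
#' as planted MTPTs. All planted coordinates are recorded in the truth record.
#' Placement keeps planted features at least ~2.5 kb apart (so 1 kb flanks
#' remain unique) and clear of the origin.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`GenomeSet`), `cp` (`GenomeSet`), and `truth`
#'   (list with `repeats`, a list of `RepeatPair` objects named `P1, P2, ...`,
#'   `alt_fractions` named accordingly, and `mtpts`, a data frame of planted
#'   segment coordinates).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  lens <- config$chromosome_lengths
  for (rs in config$repeat_specs)
    if (rs$length > min(lens) - 6000L)
      stop("repeat of ", rs$length,
           " bp does not fit its host chromosome with flanks")
  with_seed(config$seed, {
    ids <- names(lens)
    if (is.null(ids)) ids <- paste0("chr", seq_along(lens))
    seqs <- setNames(
      vapply(lens, function(L) random_dna(L, config$gc), ""), ids)
    occupied <- setNames(rep(list(list()), length(ids)), ids)

    plant <- function(chrom_id, start, segment) {
      w <- nchar(segment)
      s <- seqs[[chrom_id]]
      seqs[[chrom_id]] <<- paste0(substr(s, 1L, start - 1L), segment,
                                  substr(s, start + w, nchar(s)))
      occupied[[chrom_id]] <<- c(occupied[[chrom_id]],
                                 list(c(start, start + w - 1L)))
    }

    truth_pairs <- list()
    for (i in seq_along(config$repeat_specs)) {
      rs <- config$repeat_specs[[i]]
      w <- as.integer(rs$length)
      inter <- identical(rs$placement, "inter") && length(ids) >= 2L
      host1 <- ids[1]
      host2 <- if (inter) ids[2] else ids[1]
      s1 <- pick_windows(1L, w, lens[[host1]], occupied[[host1]])
      src <- substr(seqs[[host1]], s1, s1 + w - 1L)
      occupied[[host1]] <- c(occupied[[host1]], list(c(s1, s1 + w - 1L)))
      s2 <- pick_windows(1L, w, lens[[host2]], occupied[[host2]])
      copy <- mutate_to_identity(src, rs$identity)
      planted <- if (identical(rs$orientation, "inverted"))
        reverse_complement(copy) else copy
      plant(host2, s2, planted)

      iv1 <- interval(host1, s1, s1 + w - 1L, "+")
      iv2 <- interval(host2, s2, s2 + w - 1L,
                      if (identical(rs$orientation, "inverted")) "-" else "+")
      # canonical copy order: smaller (chrom, start) first, copy1 on "+"
      if (sprintf("%s:%012d", iv2$chrom, iv2$start) <
          sprintf("%s:%012d", iv1$chrom, iv1$start)) {
        tmp <- iv1; iv1 <- iv2; iv2 <- tmp
      }
      if (iv1$strand == "-") {
        iv1$strand <- "+"
        iv2$strand <- if (iv2$strand == "+") "-" else "+"
      }
      nmut <- round((1 - rs$identity / 100) * w)
      truth_pairs[[paste0("P", i)]] <- new_repeat_pair(
        paste0("P", i),
        new_repeat_copy(iv1, substr(seqs[[iv1$chrom]], iv1$start, iv1$end)),
        new_repeat_copy(iv2, substr(seqs[[iv2$chrom]], iv2$start, iv2$end)),
        100 * (w - nmut) / w, rs$orientation)
    }

    cp_seq <- random_dna(config$cp_length, 0.37)  # plastids are AT-rich
    cp_occ <- list()
    mtpt_rows <- list()
    for (j in seq_along(config$mtpt_specs)) {
      ms <- config$mtpt_specs[[j]]
      w <- as.integer(ms$length)
      cs <- pick_windows(1L, w, config$cp_length, cp_occ, gap = 200L)
      cp_occ <- c(cp_occ, list(c(cs, cs + w - 1L)))
      host <- ids[1L + (j - 1L) %% length(ids)]
      ts <- pick_windows(1L, w, lens[[host]], occupied[[host]], gap = 500L)
      seg <- mutate_to_identity(substr(cp_seq, cs, cs + w - 1L), ms$identity)
      plant(host, ts, seg)
      mtpt_rows[[j]] <- data.frame(
        mt_chrom = host, mt_start = ts, mt_end = ts + w - 1L,
        cp_start = cs, cp_end = cs + w - 1L, length = w,
        identity = ms$identity, stringsAsFactors = FALSE)
    }

    # refresh truth copy sequences from the final chromosomes (MTPT planting
    # never touches repeat windows, but keep this authoritative)
    for (pid in names(truth_pairs)) {
      p <- truth_pairs[[pid]]
      p$copy1$seq <- substr(seqs[[p$copy1$location$chrom]],
                            p$copy1$location$start, p$copy1$location$end)
      p$copy2$seq <- substr(seqs[[p$copy2$location$chrom]],
                            p$copy2$location$start, p$copy2$location$end)
      truth_pairs[[pid]] <- p
    }

    alt <- setNames(config$alt_fractions, names(truth_pairs))
    list(genome = genome_set(seqs),
         cp = genome_set(setNames(cp_seq, "cp1")),
         truth = list(repeats = truth_pairs, alt_fractions = alt,
                      mtpts = if (length(mtpt_rows))
                        do.call(rbind, mtpt_rows)
                      else NULL))
  })
}

#' Build the conformer molecule pool for a repeat pair
#'
#' The pool mixes the major-conformation molecules (the host chromosome(s) of
#' the pair) with the recombined molecules predicted by [predict_products()],
#' emulating the biological mixture that read counts sample: each simulated
#' read is later drawn from a molecule chosen with probability `alt_fraction`
#' from the recombined form.
#'
#' @param genome A `GenomeSet` carrying the pair.
#' @param pair A `RepeatPair`.
#' @param alt_fraction Fraction of molecules in the recombined conformation,
#'   in `[0, 1]`.
#' @return A `MoleculePool`: list with `molecules` (named list of
#'   `CircularSequence`), `label` (named `"major"`/`"alt"` vector), `focus`
#'   (named list of repeat-copy span matrices) and `alt_fraction`.
#' @export
simulate_molecule_pool <- function(genome, pair, alt_fraction) {
  stopifnot(inherits(genome, "GenomeSet"), inherits(pair, "RepeatPair"))
  if (alt_fraction < 0 || alt_fraction > 1)
    stop("alt_fraction must be in [0, 1]")
  hosts <- unique(c(pair$copy1$location$chrom, pair$copy2$location$chrom))
  majors <- genome$chromosomes[hosts]
  major_focus <- lapply(hosts, function(h) {
    spans <- list()
    for (cp in list(pair$copy1, pair$copy2))
      if (cp$location$chrom == h)
        spans[[length(spans) + 1L]] <- c(cp$location$start, cp$location$end)
    do.call(rbind, spans)
  })
  names(major_focus) <- hosts

  prods <- predict_products(molecule_set(majors), pair)
  alt_focus <- attr(prods, "focus")

  molecules <- c(majors, prods$molecules)
  label <- setNames(c(rep("major", length(majors)),
                      rep("alt", length(prods$molecules))),
                    names(molecules))
  structure(list(molecules = molecules, label = label,
                 focus = c(major_focus, alt_focus),
                 alt_fraction = alt_fraction,
                 provenance = prods$provenance),
            class = "MoleculePool")
}

#' Simulate long reads from a molecule pool
#'
#' Reads are drawn from random positions and strands of pool molecules
#' (wrapping circular molecules), with the source conformation chosen per
#' read with probability `alt_fraction` for the recombined form and molecules
#' within a conformation weighted by length. Lengths follow the configured
#' log-normal (clipped to `[min_length, molecule length]`); errors are applied
#' at the configured rates. With `spanning = TRUE` read positions are
#' conditioned to cover a repeat copy plus `span_anchor` bp on each side
#' (and lengths floored accordingly) — importance sampling of the informative
#' reads that leaves the conformation mixture untouched.
#'
#' @param pool A `MoleculePool` from [simulate_molecule_pool()].
#' @param params A [read_params()] object.
#' @param seed Integer seed (independent of the genome seed, so changing the
#'   read count never perturbs the genome).
#' @return List with `reads` (named character vector) and `truth` (data frame
#'   mapping read id to source molecule, start, strand and conformation
#'   label).
#' @export
simulate_reads <- function(pool, params = read_params(), seed = 1L) {
  stopifnot(inherits(pool, "MoleculePool"), inherits(params, "ReadParams"))
  n <- params$count
  mols <- pool$molecules
  mol_len <- vapply(mols, `[[`, 0L, "length")
  labels <- pool$label
  meanlog <- log(params$mean_length) - params$sdlog^2 / 2

  with_seed(seed, {
    is_alt <- runif(n) < pool$alt_fraction
    # in spanning mode each repeat copy is an equal sampling opportunity (the
    # per-molecule chance that a uniform read spans a copy does not grow with
    # molecule length), so weight molecules by copy count, not length
    pick_mol <- function(alt) {
      cand <- names(labels)[labels == (if (alt) "alt" else "major")]
      if (length(cand) == 1L) return(rep(cand, sum(if (alt) is_alt else !is_alt)))
      w <- if (params$spanning)
        vapply(pool$focus[cand], nrow, 0L) else mol_len[cand]
      sample(cand, sum(if (alt) is_alt else !is_alt), replace = TRUE,
             prob = w)
    }
    mol_id <- character(n)
    mol_id[is_alt] <- pick_mol(TRUE)
    mol_id[!is_alt] <- pick_mol(FALSE)

    len <- as.integer(round(rlnorm(n, meanlog, params$sdlog)))
    len <- pmax(len, params$min_length)

    start <- integer(n)
    if (params$spanning) {
      a <- params$span_anchor
      for (i in seq_len(n)) {
        foc <- pool$focus[[mol_id[i]]]
        row <- foc[sample.int(nrow(foc), 1L), ]
        wlen <- (row[2] - row[1] + 1L) + 2L * a
        L <- mol_len[[mol_id[i]]]
        if (wlen > L) stop("spanning window exceeds molecule length")
        len[i] <- max(len[i], wlen + 20L)
        len[i] <- min(len[i], L)
        ws <- row[1] - a
        start[i] <- ws - sample.int(len[i] - wlen + 1L, 1L) + 1L
        start[i] <- ((start[i] - 1L) %% L) + 1L
      }
    } else {
      len <- pmin(len, mol_len[mol_id])
      start <- vapply(mol_len[mol_id], function(L) sample.int(L, 1L), 0L)
    }

    strand <- sample(c("+", "-"), n, replace = TRUE)
    doubled <- lapply(mols, function(m) strrep(m$seq, 2L))
    raw <- character(n)
    for (m in unique(mol_id)) {
      idx <- which(mol_id == m)
      raw[idx] <- substring(doubled[[m]], start[idx], start[idx] + len[idx] - 1L)
    }
    flip <- strand == "-"
    if (any(flip)) raw[flip] <- reverse_complement(raw[flip])
    mix <- params$error_mix * params$error_rate
    reads <- as.character(cpp_mutate_reads(raw, mix[1], mix[2], mix[3]))
    ids <- sprintf("read%06d", seq_len(n))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, molecule = mol_id, start = start,
                            strand = strand,
                            label = ifelse(is_alt, "alt", "major"),
                            stringsAsFactors = FALSE))
  })
}

#' Run the full simulation and write its outputs to a directory
#'
#' Emits the mitochondrial genome FASTA, chloroplast FASTA, per-pair molecule
#' pool FASTA, reads FASTQ and truth JSON/TSV.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of the generated objects.
#' @export
simulate_bundle <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(config)
  write_fasta(gen$genome, file.path(outdir, "genome.fasta"))
  write_fasta(gen$cp, file.path(outdir, "chloroplast.fasta"))

  all_reads <- character(0)
  truth_tabs <- list()
  for (i in seq_along(gen$truth$repeats)) {
    pid <- names(gen$truth$repeats)[i]
    pool <- simulate_molecule_pool(gen$genome, gen$truth$repeats[[pid]],
                                   gen$truth$alt_fractions[[pid]])
    write_fasta(genome_set(setNames(
      vapply(pool$molecules, `[[`, "", "seq"),
      paste0(pid, "_", names(pool$molecules)))),
      file.path(outdir, paste0("pool_", pid, ".fasta")))
    sim <- simulate_reads(pool, config$read_params,
                          seed = config$seed + 1000L + i)
    names(sim$reads) <- paste0(pid, "_", names(sim$reads))
    sim$truth$read_id <- paste0(pid, "_", sim$truth$read_id)
    sim$truth$pair_id <- pid
    all_reads <- c(all_reads, sim$reads)
    truth_tabs[[pid]] <- sim$truth
  }
  write_fastq(all_reads, file.path(outdir, "reads.fastq"))
  truth <- do.call(rbind, truth_tabs)
  rownames(truth) <- NULL
  write.table(truth, file.path(outdir, "read_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         repeats = lapply(gen$truth$repeats, function(p) list(
           id = p$id, length = p$length, identity = p$identity,
           orientation = p$orientation,
           position = paste(format_position(p$copy1$location),
                            format_position(p$copy2$location), sep = "; "))),
         alt_fractions = as.list(gen$truth$alt_fractions),
         mtpts = gen$truth$mtpts),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(list(genome = gen$genome, cp = gen$cp, truth = gen$truth,
                 reads = all_reads, read_truth = truth))
}
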