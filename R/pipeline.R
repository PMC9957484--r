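# One-command orchestration: genome -> repeat pairs -> conformation
# references -> read classification -> frequencies -> isomer predictions ->
# MTPT report, with a machine-readable result bundle.

pipeline_defaults <- function() {
  list(min_length = 50L, min_identity = 90, flank_len = 1000L,
       min_anchor = 100L, max_error_rate = 0.15, min_identity_margin = 0.02,
       evalue_threshold = 1e-5, mtpt_min_length = 30L, topology = NULL)
}

#' Run the full recombination-analysis pipeline
#'
#' Stages: read inputs, detect repeat pairs, build conformation references
#' per pair, classify reads and compute major/alternative conformation
#' frequencies, predict the recombination products of each pair
#' (length-stub mode), and (when a chloroplast genome is supplied) detect and
#' summarize MTPTs. The report is a pure function of the inputs and
#' parameters: rerunning on identical inputs reproduces it byte-identically.
#'
#' @param genome_fasta Path to the genome FASTA, or a `GenomeSet`.
#' @param reads Path to a reads FASTA/FASTQ, or a named character vector.
#' @param cp_fasta Optional chloroplast FASTA path or `GenomeSet`; when
#'   omitted the MTPT section is absent.
#' @param params Named list overriding any of: `min_length`, `min_identity`,
#'   `flank_len`, `min_anchor`, `max_error_rate`, `min_identity_margin`,
#'   `evalue_threshold`, `mtpt_min_length`, `topology`.
#' @param quiet Suppress per-stage log lines.
#' @return A `RunReport` list with elements `version`, `params`,
#'   `input_checksums`, `repeats` (per-pair table with counts and
#'   frequencies), `isomers` (per-pair product predictions) and `mtpt`
#'   (summary + hits, or `NULL`).
#' @export
run_all <- function(genome_fasta, reads, cp_fasta = NULL, params = list(),
                    quiet = FALSE) {
  params <- modifyList(pipeline_defaults(), params)
  say <- function(...) if (!quiet) message(sprintf(...))
  checksums <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- stage("load-genome", {
    if (inherits(genome_fasta, "GenomeSet")) genome_fasta
    else {
      checksums$genome <- unname(tools::md5sum(genome_fasta))
      read_fasta(genome_fasta, topology = params$topology)
    }
  })
  read_seqs <- stage("load-reads", {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
      checksums$reads <- unname(tools::md5sum(reads))
      read_reads(reads)
    } else reads
  })
  say("loaded genome: %d chromosome(s), %d bp; %d reads",
      length(genome$chromosomes), total_length(genome), length(read_seqs))

  pairs <- stage("find-repeats",
                 find_repeat_pairs(genome, params$min_length,
                                   params$min_identity))
  say("find-repeats: %d pair(s) at min_length=%d min_identity=%s",
      length(pairs), params$min_length, format(params$min_identity))

  cparams <- classification_params(params$min_anchor, params$max_error_rate,
                                   params$min_identity_margin)
  rep_rows <- list()
  isomers <- list()
  for (p in pairs) {
    confs <- stage(paste0("conformations-", p$id),
                   build_conformation_refs(genome, p, params$flank_len))
    counts <- stage(paste0("classify-", p$id),
                    count_support(read_seqs, confs, cparams))
    n_inf <- counts$m1 + counts$m2 + counts$a1 + counts$a2
    freq <- if (n_inf > 0L) compute_frequencies(counts) else NULL
    rep_rows[[p$id]] <- data.frame(
      id = p$id, length = p$length,
      identity = round_half_up(p$identity, 3),
      orientation = p$orientation, size_class = p$size_class,
      position = paste(format_position(p$copy1$location),
                       format_position(p$copy2$location), sep = "; "),
      major1 = counts$m1, major2 = counts$m2,
      alternative1 = counts$a1, alternative2 = counts$a2,
      ambiguous = counts$ambiguous, unclassified = counts$unclassified,
      major_fraction = if (is.null(freq)) NA_real_ else freq$major_fraction,
      alternative_fraction = if (is.null(freq)) NA_real_
                             else freq$alternative_fraction,
      stringsAsFactors = FALSE)
    say("classify %s: m1=%d m2=%d a1=%d a2=%d", p$id, counts$m1, counts$m2,
        counts$a1, counts$a2)

    lens <- setNames(vapply(genome$chromosomes, `[[`, 0L, "length"),
                     names(genome$chromosomes))
    iso <- tryCatch({
      prods <- predict_products(molecule_set(lens), p)
      list(pair_id = p$id, provenance = prods$provenance,
           product_lengths = as.list(molecule_lengths(prods)))
    }, error = function(e) list(pair_id = p$id,
                                error = conditionMessage(e)))
    isomers[[p$id]] <- iso
  }
  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else NULL
  if (!is.null(repeats)) rownames(repeats) <- NULL

  mtpt <- NULL
  if (!is.null(cp_fasta)) {
    cp <- stage("load-cp", {
      if (inherits(cp_fasta, "GenomeSet")) cp_fasta
      else {
        checksums$cp <- unname(tools::md5sum(cp_fasta))
        read_fasta(cp_fasta)
      }
    })
    hits <- stage("find-mtpt",
                  find_mtpts(genome, cp, params$evalue_threshold,
                             params$mtpt_min_length))
    mtpt <- list(summary = summarize_mtpts(hits, total_length(genome)),
                 hits = hits)
    say("find-mtpt: %d hit(s), %d bp (%.2f%%)", mtpt$summary$count,
        mtpt$summary$total_bp, mtpt$summary$percent)
  }

  genome_summary <- list(
    chromosomes = lapply(genome$chromosomes, function(ch)
      list(id = ch$id, topology = ch$topology, length = ch$length)),
    total_length = total_length(genome),
    gc_content = signif(gc_content(genome), 4))

  structure(list(
    version = as.character(utils::packageVersion("mitorecomb")),
    params = params[!vapply(params, is.null, TRUE)],
    input_checksums = checksums,
    genome = genome_summary,
    repeats = repeats, isomers = isomers, mtpt = mtpt),
    class = "RunReport")
}

#' Write a run report as TSV tables plus one JSON bundle
#'
#' @param report A `RunReport` from [run_all()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the path of the JSON bundle.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "RunReport"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$repeats))
    write.table(report$repeats, file.path(outdir, "repeats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$mtpt))
    write_mtpt_hits(report$mtpt$hits,
                    tsv_path = file.path(outdir, "mtpt.tsv"),
                    bed_path = file.path(outdir, "mtpt.bed"))
  path <- file.path(outdir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("<RunReport> mitorecomb %s\n", x$version))
  if (!is.null(x$repeats)) {
    cat(sprintf("  %d repeat pair(s):\n", nrow(x$repeats)))
    print(x$repeats[, c("id", "length", "identity", "orientation",
                        "major1", "major2", "alternative1", "alternative2",
                        "major_fraction", "alternative_fraction")])
  } else cat("  no repeat pairs detected\n")
  if (!is.null(x$mtpt))
    cat(sprintf("  MTPT: %d block(s), %d bp, %.2f%% of the genome\n",
                x$mtpt$summary$count, x$mtpt$summary$total_bp,
                x$mtpt$summary$percent))
  invisible(x)
}
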