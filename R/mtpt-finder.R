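# Mitochondrial plastid transfer (MTPT) detection: local similarity search
# between a chloroplast and a mitochondrial genome (seed-and-extend on both
# strands) with a Karlin-Altschul-style e-value filter, hit merging on the
# mitochondrial axis, and summary statistics.

# Ungapped Karlin-Altschul lambda for a +2/-3 nucleotide scoring scheme under
# uniform base composition: the unique positive root of
# sum_ij p_i p_j exp(lambda * s_ij) = 1. K is fixed at the customary 0.71
# approximation for nucleotide searches; only the e-value *threshold*
# behaviour matters here, not engine parity.
mtpt_env <- new.env(parent = emptyenv())

karlin_lambda <- function(match = 2, mismatch = -3) {
  key <- paste(match, mismatch)
  if (!is.null(mtpt_env[[key]])) return(mtpt_env[[key]])
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lam <- uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  mtpt_env[[key]] <- lam
  lam
}

mtpt_evalue <- function(score, m, n, match = 2, mismatch = -3, K = 0.71) {
  K * m * n * exp(-karlin_lambda(match, mismatch) * score)
}

#' Find mitochondrial plastid transfers
#'
#' Local similarity search of the chloroplast genome against the
#' mitochondrial genome (exact k-mer seeds, ungapped X-drop extension, both
#' strands). Hits are scored with match +2 / mismatch -3 and filtered at a
#' Karlin-Altschul e-value threshold (default `1e-5`); hits overlapping or
#' abutting on the mitochondrial axis are merged; output is sorted by
#' mitochondrial coordinate.
#'
#' @param mt,cp `GenomeSet` objects (mitochondrial and chloroplast genomes).
#' @param evalue_threshold Maximum e-value for a reported hit.
#' @param min_length Minimum hit length in bp.
#' @param k Seed k-mer size (shorter than for repeat finding: transferred
#'   segments can be short and diverged).
#' @return A `data.frame` (class `MtptHits`) with columns `mt_chrom`,
#'   `mt_start`, `mt_end`, `cp_chrom`, `cp_start`, `cp_end`, `strand`,
#'   `length`, `identity`, `score`, `evalue`.
#' @export
find_mtpts <- function(mt, cp, evalue_threshold = 1e-5, min_length = 30L,
                       k = 11L) {
  stopifnot(inherits(mt, "GenomeSet"), inherits(cp, "GenomeSet"))
  if (length(mt$chromosomes) == 0L || length(cp$chromosomes) == 0L)
    stop("both genomes must be non-empty")
  m <- total_length(mt); n <- total_length(cp)
  rows <- list()
  for (mi in names(mt$chromosomes)) {
    sm <- mt$chromosomes[[mi]]$seq
    for (ci in names(cp$chromosomes)) {
      sc <- cp$chromosomes[[ci]]$seq
      lc <- nchar(sc)
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") sc else reverse_complement(sc)
        hits <- seed_extend_hits(sm, subject, k, min_length, 0.6,
                                 self = FALSE, match = 2L, mismatch = -3L,
                                 xdrop = 40L, max_gap = 50L)
        for (h in hits) {
          score <- 2L * (h$length - h$mismatches) - 3L * h$mismatches
          ev <- mtpt_evalue(score, m, n)
          if (ev > evalue_threshold) next
          if (strand == "+") { cs <- h$start2; ce <- h$end2 }
          else { cs <- lc - h$end2 + 1L; ce <- lc - h$start2 + 1L }
          rows[[length(rows) + 1L]] <- data.frame(
            mt_chrom = mi, mt_start = h$start1, mt_end = h$end1,
            cp_chrom = ci, cp_start = cs, cp_end = ce, strand = strand,
            length = h$length,
            identity = 100 * (h$length - h$mismatches) / h$length,
            score = score, evalue = ev, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(mt_chrom = character(0), mt_start = integer(0),
                      mt_end = integer(0), cp_chrom = character(0),
                      cp_start = integer(0), cp_end = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0), score = integer(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("MtptHits", "data.frame")
    return(out)
  }
  hits <- do.call(rbind, rows)
  hits <- hits[!duplicated(hits[c("mt_chrom", "mt_start", "mt_end",
                                  "cp_chrom", "cp_start", "cp_end",
                                  "strand")]), , drop = FALSE]
  out <- merge_mtpt_hits(hits)
  out <- out[order(out$mt_chrom, out$mt_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MtptHits", "data.frame")
  out
}

#' Merge MTPT hits that overlap or abut on the mitochondrial axis
#'
#' Hits whose mitochondrial intervals overlap by at least 1 bp or abut are
#' merged into one block (transferred segments are reported as disjoint
#' blocks). The merged row keeps the chloroplast interval, identity, score and
#' e-value of its best (lowest e-value) component; `length` is the width of
#' the merged mitochondrial interval.
#'
#' @param hits A `data.frame` of MTPT hits (as from [find_mtpts()]).
#' @return A merged `data.frame` with the same columns.
#' @export
merge_mtpt_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  out <- list()
  for (chrom in unique(hits$mt_chrom)) {
    h <- hits[hits$mt_chrom == chrom, , drop = FALSE]
    h <- h[order(h$mt_start, h$mt_end), , drop = FALSE]
    cur <- h[1, , drop = FALSE]
    best <- cur
    flush <- function(cur, best) {
      row <- best
      row$mt_start <- cur$mt_start; row$mt_end <- cur$mt_end
      row$length <- cur$mt_end - cur$mt_start + 1L
      row
    }
    if (nrow(h) > 1L) for (i in 2:nrow(h)) {
      if (h$mt_start[i] <= cur$mt_end + 1L) {  # overlap or abutting
        cur$mt_end <- max(cur$mt_end, h$mt_end[i])
        if (h$evalue[i] < best$evalue) best <- h[i, , drop = FALSE]
      } else {
        out[[length(out) + 1L]] <- flush(cur, best)
        cur <- h[i, , drop = FALSE]
        best <- cur
      }
    }
    out[[length(out) + 1L]] <- flush(cur, best)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize MTPT content of a mitochondrial genome
#'
#' @param hits Merged MTPT hits (non-overlapping on the mitochondrial axis).
#' @param mt_total_length Total mitochondrial genome length in bp.
#' @return List with `count`, `total_bp` (summed mitochondrial-axis length)
#'   and `percent` (of `mt_total_length`, rounded to 2 decimals).
#' @export
summarize_mtpts <- function(hits, mt_total_length) {
  if (nrow(hits) == 0L)
    return(list(count = 0L, total_bp = 0L, percent = 0))
  total <- sum(hits$mt_end - hits$mt_start + 1L)
  list(count = nrow(hits), total_bp = as.integer(total),
       percent = round_half_up(100 * total / mt_total_length, 2))
}

#' Label MTPT hits with overlapping genome features
#'
#' Optional intersection of MTPT blocks with a user-supplied feature table
#' (e.g. gene annotations), adding a comma-separated `features` column. Gene
#' identification itself is out of scope; this only reports overlaps.
#'
#' @param hits `MtptHits` data frame (mitochondrial-axis coordinates).
#' @param features A data frame with columns `chrom`, `start`, `end`, `name`
#'   (1-based inclusive), or a path to such a TSV (with header), or a path to
#'   a BED file (`.bed`, 0-based half-open; requires the rtracklayer
#'   package).
#' @return `hits` with an added `features` character column.
#' @export
annotate_mtpts <- function(hits, features) {
  if (is.character(features)) {
    if (grepl("\\.bed$", features, ignore.case = TRUE)) {
      if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("reading BED features requires the rtracklayer package")
      gr <- rtracklayer::import(features)
      features <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
        name = if (!is.null(gr$name)) gr$name
               else paste0("feature", seq_along(gr)),
        stringsAsFactors = FALSE)
    } else {
      features <- read.delim(features, stringsAsFactors = FALSE)
    }
  }
  if (!all(c("chrom", "start", "end", "name") %in% names(features)))
    stop("features need columns: chrom, start, end, name")
  hits$features <- vapply(seq_len(nrow(hits)), function(i) {
    f <- features$name[features$chrom == hits$mt_chrom[i] &
                         features$start <= hits$mt_end[i] &
                         features$end >= hits$mt_start[i]]
    paste(f, collapse = ",")
  }, "")
  hits
}

#' Write MTPT hits as TSV and BED
#'
#' The BED file is on the mitochondrial axis (0-based half-open starts, per
#' the BED convention).
#'
#' @param hits `MtptHits` data frame.
#' @param tsv_path,bed_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, `NULL`.
#' @export
write_mtpt_hits <- function(hits, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    write.table(hits, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = hits$mt_chrom, start = hits$mt_start - 1L,
                      end = hits$mt_end,
                      name = sprintf("MTPT%d", seq_len(nrow(hits))),
                      score = hits$score, strand = hits$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
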