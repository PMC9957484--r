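# Detection of direct and inverted repeat pairs within and between
# chromosomes: exact k-mer seeds, ungapped X-drop extension, deterministic
# filtering (mirror/self-hit removal, containment in a longer pair's
# footprint), size classification.

#' Classify a repeat by length
#'
#' Short `< 100` bp, medium `100-1000` bp (inclusive on both ends), large
#' `> 1000` bp.
#'
#' @param length Repeat length(s) in bp, `>= 1`.
#' @return Character vector: `"short"`, `"medium"` or `"large"`.
#' @examples
#' classify_size(c(89, 331, 1235, 7887))
#' @export
classify_size <- function(length) {
  if (any(length < 1)) stop("length must be >= 1")
  ifelse(length < 100, "short", ifelse(length <= 1000, "medium", "large"))
}

new_repeat_copy <- function(location, seq) {
  structure(list(location = location, seq = seq), class = "RepeatCopy")
}

new_repeat_pair <- function(id, copy1, copy2, identity, orientation) {
  len <- iv_len(copy1$location)
  structure(list(id = id, copy1 = copy1, copy2 = copy2, length = len,
                 identity = identity, orientation = orientation,
                 size_class = classify_size(len)),
            class = "RepeatPair")
}

#' @export
print.RepeatPair <- function(x, ...) {
  cat(sprintf("<RepeatPair> %s  %d bp  %.3f%%  %s (%s)\n  %s; %s\n",
              x$id, x$length, x$identity, x$orientation, x$size_class,
              format_position(x$copy1$location),
              format_position(x$copy2$location)))
  invisible(x)
}

# raw hits from one sequence-vs-sequence comparison; coordinates on the
# strings as passed (minus-strand mapping is done by the caller)
seed_extend_hits <- function(s1, s2, k, min_len, min_ident_frac, self,
                             match = 1L, mismatch = -2L, xdrop = 30L,
                             max_gap = 60L, max_occ = 100L) {
  m <- cpp_kmer_matches(s1, s2, k, self, max_occ)
  if (nrow(m) == 0L) return(list())
  diag <- m[, 2] - m[, 1]
  ord <- order(diag, m[, 1])
  m <- m[ord, , drop = FALSE]
  diag <- diag[ord]
  newgrp <- c(TRUE, diff(diag) != 0L | diff(m[, 1]) > max_gap)
  grp <- cumsum(newgrp)
  hits <- list()
  seen <- character(0)
  for (g in split(seq_len(nrow(m)), grp)) {
    i1 <- m[g[1], 1]; i2 <- m[g[1], 2]
    span <- m[g[length(g)], 1] + k - i1
    ext <- cpp_extend_seed(s1, s2, i1, i2, span, min_ident_frac,
                           match, mismatch, xdrop)
    if (!isTRUE(ext$ok) || ext$length < min_len) next
    key <- paste(ext$start1, ext$start2, ext$length)
    if (key %in% seen) next
    seen <- c(seen, key)
    hits[[length(hits) + 1L]] <- ext
  }
  hits
}

overlap_bp <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1) + 1L)

iv_overlap_frac <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  overlap_bp(a$start, a$end, b$start, b$end) / iv_len(a)
}

#' Find repeat pairs in a genome
#'
#' Detects pairs of repeated sequences (both orientations, intra- and
#' inter-chromosomal) by exact k-mer seeding followed by ungapped X-drop
#' extension. Deterministic filters replace manual curation: self-hits,
#' mirror duplicates and pairs whose both copies overlap a longer kept pair's
#' footprint by more than half are dropped. Pairs are sorted by descending
#' length and assigned ids `R1, R2, ...` in that order; within a pair, `copy1`
#' is the copy with the lexicographically smaller `(chrom, start)`.
#'
#' The default `min_length = 50` and `min_identity = 90` comfortably capture
#' the shortest / most diverged repeats that matter for organelle
#' recombination surveys (down to ~89 bp at ~96.6% identity).
#'
#' @param genome A `GenomeSet`.
#' @param min_length Minimum repeat length in bp (`>= 20`).
#' @param min_identity Minimum percent identity in `(0, 100]`.
#' @param k Seed k-mer size.
#' @return List of `RepeatPair` objects.
#' @export
find_repeat_pairs <- function(genome, min_length = 50L, min_identity = 90,
                              k = 15L) {
  stopifnot(inherits(genome, "GenomeSet"))
  if (min_length < 20L) stop("min_length must be >= 20")
  if (min_identity <= 0 || min_identity > 100)
    stop("min_identity must be in (0, 100]")
  chroms <- genome$chromosomes
  if (length(chroms) == 0L) return(list())
  frac <- min_identity / 100

  cands <- list()
  add_cand <- function(iv1, iv2, mismatches, len, orientation) {
    # canonical copy order: smaller (chrom, start) first, and copy1 always on
    # the plus strand (an inverted pair is the same object under flipping
    # both strands, so this makes results order-invariant)
    key1 <- sprintf("%s:%012d", iv1$chrom, iv1$start)
    key2 <- sprintf("%s:%012d", iv2$chrom, iv2$start)
    if (key2 < key1) { tmp <- iv1; iv1 <- iv2; iv2 <- tmp }
    if (iv1$strand == "-") {
      iv1$strand <- "+"
      iv2$strand <- if (iv2$strand == "+") "-" else "+"
    }
    # self-hit guard: heavily overlapping copies are one locus, not a pair
    if (iv_overlap_frac(iv1, iv2) > 0.5) return()
    cands[[length(cands) + 1L]] <<- list(
      iv1 = iv1, iv2 = iv2, mismatches = mismatches, len = len,
      orientation = orientation,
      key = paste(format_position(iv1), format_position(iv2), orientation))
  }

  ids <- names(chroms)
  for (ai in seq_along(ids)) {
    for (bi in ai:length(ids)) {
      sa <- chroms[[ai]]$seq; sb <- chroms[[bi]]$seq
      la <- nchar(sa); lb <- nchar(sb)
      # forward vs forward -> direct pairs
      for (h in seed_extend_hits(sa, sb, k, min_length, frac, ai == bi)) {
        add_cand(interval(ids[ai], h$start1, h$end1, "+"),
                 interval(ids[bi], h$start2, h$end2, "+"),
                 h$mismatches, h$length, "direct")
      }
      # forward vs reverse-complement -> inverted pairs
      for (h in seed_extend_hits(sa, reverse_complement(sb), k, min_length,
                                 frac, FALSE)) {
        # map hit on revcomp(sb) back to plus-strand coordinates of sb
        s2 <- lb - h$end2 + 1L; e2 <- lb - h$start2 + 1L
        add_cand(interval(ids[ai], h$start1, h$end1, "+"),
                 interval(ids[bi], s2, e2, "-"),
                 h$mismatches, h$length, "inverted")
      }
    }
  }
  if (length(cands) == 0L) return(list())

  # mirror/duplicate removal (inverted intra-chromosomal hits are seen twice)
  keys <- vapply(cands, `[[`, "", "key")
  cands <- cands[!duplicated(keys)]

  # identity filter (trimming already enforces it, but recheck), then sort by
  # descending length with a deterministic tiebreak
  lens <- vapply(cands, `[[`, 0L, "len")
  keys <- vapply(cands, `[[`, "", "key")
  cands <- cands[order(-lens, keys)]

  # containment filter: drop a pair when BOTH copies overlap a longer kept
  # pair's copies by > 50% of their own length
  kept <- list()
  for (cand in cands) {
    contained <- FALSE
    for (kp in kept) {
      o1 <- max(iv_overlap_frac(cand$iv1, kp$iv1),
                iv_overlap_frac(cand$iv1, kp$iv2))
      o2 <- max(iv_overlap_frac(cand$iv2, kp$iv1),
                iv_overlap_frac(cand$iv2, kp$iv2))
      if (o1 > 0.5 && o2 > 0.5) { contained <- TRUE; break }
    }
    if (!contained) kept[[length(kept) + 1L]] <- cand
  }

  out <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    cand <- kept[[i]]
    seq1 <- substr(chroms[[cand$iv1$chrom]]$seq, cand$iv1$start, cand$iv1$end)
    seq2 <- substr(chroms[[cand$iv2$chrom]]$seq, cand$iv2$start, cand$iv2$end)
    identity <- 100 * (cand$len - cand$mismatches) / cand$len
    out[[i]] <- new_repeat_pair(paste0("R", i),
                                new_repeat_copy(cand$iv1, seq1),
                                new_repeat_copy(cand$iv2, seq2),
                                identity, cand$orientation)
  }
  out
}

#' Tabulate repeat pairs in the printed-report layout
#'
#' One row per pair: id, length, identity, and the two copy positions joined
#' by `"; "` (minus-strand copies printed with reversed coordinates).
#'
#' @param pairs List of `RepeatPair` objects.
#' @return A `data.frame`.
#' @export
repeat_pairs_table <- function(pairs) {
  data.frame(
    id = vapply(pairs, `[[`, "", "id"),
    length = vapply(pairs, `[[`, 0L, "length"),
    identity = round_half_up(vapply(pairs, `[[`, 0, "identity"), 3),
    orientation = vapply(pairs, `[[`, "", "orientation"),
    size_class = vapply(pairs, `[[`, "", "size_class"),
    position = vapply(pairs, function(p)
      paste(format_position(p$copy1$location),
            format_position(p$copy2$location), sep = "; "), ""),
    stringsAsFactors = FALSE)
}
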