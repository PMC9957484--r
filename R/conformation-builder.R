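# Flank-swap construction of conformation references: for each repeat pair,
# the two observed (major) repeat+flank contexts and the two references
# obtained by exchanging the downstream flanks, which model the recombined
# (alternative) arrangement.

CONF_LABELS <- c("major1", "major2", "alt1", "alt2")

new_conf_ref <- function(pair_id, label, seq, repeat_span, flank_len, flags) {
  structure(list(pair_id = pair_id, label = label, seq = seq,
                 repeat_span = repeat_span, flank_len = flank_len,
                 flags = flags),
            class = "ConformationReference")
}

# flanks of one repeat copy, oriented so that "upstream/downstream" refer to
# the common repeat orientation (copy read 5'->3' as it aligns to copy1)
copy_flanks <- function(genome, iv, flank_len) {
  ch <- gs_seq(genome, iv$chrom)
  L <- ch$length
  trunc_up <- trunc_down <- FALSE
  if (ch$topology == "circular") {
    up <- slice_wrap(ch, iv$start - flank_len, flank_len)
    down <- slice_wrap(ch, iv$end + 1L, flank_len)
  } else {
    u0 <- max(1L, iv$start - flank_len)
    up <- if (iv$start == 1L) "" else substr(ch$seq, u0, iv$start - 1L)
    trunc_up <- nchar(up) < flank_len
    d1 <- min(L, iv$end + flank_len)
    down <- if (iv$end == L) "" else substr(ch$seq, iv$end + 1L, d1)
    trunc_down <- nchar(down) < flank_len
  }
  seq <- substr(ch$seq, iv$start, iv$end)
  if (iv$strand == "-") {
    # orient to the common repeat direction: reverse-complement the copy and
    # swap/transform its flanks accordingly
    tmp <- up
    up <- reverse_complement(down)
    down <- reverse_complement(tmp)
    seq <- reverse_complement(seq)
    tt <- trunc_up; trunc_up <- trunc_down; trunc_down <- tt
  }
  list(up = up, down = down, seq = seq,
       trunc_up = trunc_up, trunc_down = trunc_down)
}

#' Build the four conformation references for a repeat pair
#'
#' With `U1`/`D1` the upstream/downstream `flank_len` bp of copy 1 and
#' `U2`/`D2` those of copy 2 (copy 2 first reverse-complemented, flanks
#' transformed accordingly, when the pair is inverted), the references are
#'
#' * `major1 = U1 + R1 + D1` and `major2 = U2 + R2 + D2` — exact substrings of
#'   the source chromosomes (each major carries its own copy's sequence);
#' * `alt1 = U1 + R1 + D2` and `alt2 = U2 + R1 + D1` — the flank-swapped
#'   references modelling the recombined arrangement (both carry copy 1's
#'   repeat sequence, matching the consensus convention used by
#'   [predict_products()]).
#'
#' Flanks wrap the origin on circular chromosomes and are truncated (and
#' flagged) on linear ones. A flank that overlaps the partner copy's footprint
#' is flagged (`flank_overlap`): such references have reduced distinguishing
#' power but are not an error.
#'
#' @param genome A `GenomeSet` containing both host chromosomes.
#' @param pair A `RepeatPair`.
#' @param flank_len Flank length in bp (default 1000).
#' @return A `ConformationSet`: list with `pair_id`, `flank_len`,
#'   `repeat_len`, `flags` and `refs` (named list of the four
#'   `ConformationReference` objects).
#' @export
build_conformation_refs <- function(genome, pair, flank_len = 1000L) {
  stopifnot(inherits(genome, "GenomeSet"), inherits(pair, "RepeatPair"))
  flank_len <- as.integer(flank_len)
  if (flank_len < 1L) stop("flank_len must be >= 1")
  f1 <- copy_flanks(genome, pair$copy1$location, flank_len)
  f2 <- copy_flanks(genome, pair$copy2$location, flank_len)
  r1 <- f1$seq
  rlen <- nchar(r1)

  flags <- character(0)
  if (f1$trunc_up || f1$trunc_down || f2$trunc_up || f2$trunc_down)
    flags <- c(flags, "flank_truncated")
  # flank running into the partner copy's repeat footprint reduces the
  # sequence signal available to distinguish conformations
  flank_iv <- function(iv, ch) {
    list(interval(iv$chrom, max(1L, iv$start - flank_len),
                  max(1L, iv$start - 1L)),
         interval(iv$chrom, min(ch$length, iv$end + 1L),
                  min(ch$length, iv$end + flank_len)))
  }
  fi1 <- flank_iv(pair$copy1$location, gs_seq(genome, pair$copy1$location$chrom))
  fi2 <- flank_iv(pair$copy2$location, gs_seq(genome, pair$copy2$location$chrom))
  overl <- function(a, b) a$chrom == b$chrom &&
    overlap_bp(a$start, a$end, b$start, b$end) > 0L
  if (any(vapply(fi1, overl, TRUE, b = pair$copy2$location)) ||
      any(vapply(fi2, overl, TRUE, b = pair$copy1$location)))
    flags <- c(flags, "flank_overlap")

  mk <- function(label, up, rep_seq, down) {
    new_conf_ref(pair$id, label, paste0(up, rep_seq, down),
                 c(nchar(up) + 1L, nchar(up) + nchar(rep_seq)),
                 flank_len, flags)
  }
  refs <- list(
    major1 = mk("major1", f1$up, f1$seq, f1$down),
    major2 = mk("major2", f2$up, f2$seq, f2$down),
    alt1   = mk("alt1",   f1$up, r1,     f2$down),
    alt2   = mk("alt2",   f2$up, r1,     f1$down))
  structure(list(pair_id = pair$id, flank_len = flank_len, repeat_len = rlen,
                 flags = flags, refs = refs),
            class = "ConformationSet")
}

#' @export
print.ConformationSet <- function(x, ...) {
  cat(sprintf("<ConformationSet> pair %s, repeat %d bp, flanks %d bp%s\n",
              x$pair_id, x$repeat_len, x$flank_len,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Write conformation references as multi-FASTA plus a JSON sidecar
#'
#' Record ids are `"<pair_id>_<label>"`; the sidecar records each reference's
#' repeat span and flags.
#'
#' @param confs A `ConformationSet`.
#' @param fasta_path,json_path Output paths (`json_path = NULL` skips the
#'   sidecar).
#' @return Invisibly, `fasta_path`.
#' @export
write_conformation_refs <- function(confs, fasta_path, json_path = NULL) {
  stopifnot(inherits(confs, "ConformationSet"))
  seqs <- setNames(
    vapply(confs$refs, `[[`, "", "seq"),
    paste0(confs$pair_id, "_", vapply(confs$refs, `[[`, "", "label")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  if (!is.null(json_path)) {
    meta <- lapply(confs$refs, function(r)
      list(repeat_span = r$repeat_span, flank_len = r$flank_len,
           flags = r$flags))
    names(meta) <- names(seqs)
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(fasta_path)
}
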