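# Independent oracles and tiny fixture builders used across the suite.
# These deliberately avoid the package's own machinery wherever they serve as
# a cross-check on it.

# base-R reverse complement, independent of the package implementation
rc_chr <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

rdna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# overwrite `len` characters of `s` at `at` with `piece`
splice_at <- function(s, at, piece) {
  paste0(substr(s, 1, at - 1), piece, substr(s, at + nchar(piece), nchar(s)))
}

# mutate a string by `nmut` substitutions at distinct positions
sub_mutate <- function(s, nmut) {
  if (nmut == 0) return(s)
  chars <- strsplit(s, "")[[1]]
  for (p in sample(length(chars), nmut))
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# circular substring extraction by doubling (independent of circular_slice)
circ_sub <- function(s, start, len) substr(strrep(s, 2), start, start + len - 1)

## ---- brute-force maximal exact repeat oracle ------------------------------

# all maximal exact matches of length >= L between two strings, as a matrix
# (s1, e1, s2, e2); self = TRUE restricts to i < j
oracle_pairs_two <- function(sa, sb, L, self) {
  wa <- substring(sa, 1:(nchar(sa) - L + 1), L:nchar(sa))
  wb <- substring(sb, 1:(nchar(sb) - L + 1), L:nchar(sb))
  common <- intersect(wa, wb)
  if (length(common) == 0) return(NULL)
  fa <- factor(wa, levels = common)
  fb <- factor(wb, levels = common)
  ia_by <- split(which(!is.na(fa)), fa[!is.na(fa)])
  ib_by <- split(which(!is.na(fb)), fb[!is.na(fb)])
  res <- list()
  for (w in common) {
    for (i in ia_by[[w]]) for (j in ib_by[[w]]) {
      if (self && i >= j) next
      res[[length(res) + 1]] <- c(i, j)
    }
  }
  if (length(res) == 0) return(NULL)
  m <- do.call(rbind, res)
  d <- m[, 2] - m[, 1]
  o <- order(d, m[, 1])
  m <- m[o, , drop = FALSE]
  d <- d[o]
  runs <- cumsum(c(TRUE, diff(d) != 0 | diff(m[, 1]) != 1))
  out <- list()
  for (g in split(seq_len(nrow(m)), runs)) {
    i0 <- m[g[1], 1]; j0 <- m[g[1], 2]
    len <- m[g[length(g)], 1] - i0 + L
    out[[length(out) + 1]] <- c(i0, i0 + len - 1, j0, j0 + len - 1)
  }
  do.call(rbind, out)
}

# canonical key set of all maximal exact repeat pairs >= L in a named list of
# (circular) chromosome strings; keys match the package's position format
oracle_exact_repeats <- function(seqs, L) {
  keys <- character(0)
  pos_key <- function(chrom, s, e, strand) {
    if (strand == "+") sprintf("%s: %d-%d", chrom, s, e)
    else sprintf("%s: %d-%d", chrom, e, s)
  }
  add <- function(c1, s1, e1, st1, c2, s2, e2, st2, ori) {
    a <- list(chrom = c1, s = s1, e = e1, st = st1)
    b <- list(chrom = c2, s = s2, e = e2, st = st2)
    if (sprintf("%s:%012d", b$chrom, b$s) < sprintf("%s:%012d", a$chrom, a$s)) {
      tmp <- a; a <- b; b <- tmp
    }
    if (a$st == "-") {  # canonical: copy1 on the plus strand
      a$st <- "+"
      b$st <- if (b$st == "+") "-" else "+"
    }
    # self-overlap guard (mirrors the package rule)
    if (a$chrom == b$chrom &&
        min(a$e, b$e) - max(a$s, b$s) + 1 > 0.5 * (a$e - a$s + 1)) return()
    keys <<- c(keys, paste(pos_key(a$chrom, a$s, a$e, a$st),
                           pos_key(b$chrom, b$s, b$e, b$st), ori))
  }
  ids <- names(seqs)
  for (ai in seq_along(ids)) for (bi in ai:length(ids)) {
    sa <- seqs[[ai]]; sb <- seqs[[bi]]
    m <- oracle_pairs_two(sa, sb, L, ai == bi)
    if (!is.null(m)) for (r in seq_len(nrow(m)))
      add(ids[ai], m[r, 1], m[r, 2], "+", ids[bi], m[r, 3], m[r, 4], "+",
          "direct")
    mrc <- oracle_pairs_two(sa, rc_chr(sb), L, FALSE)
    lb <- nchar(sb)
    if (!is.null(mrc)) for (r in seq_len(nrow(mrc)))
      add(ids[ai], mrc[r, 1], mrc[r, 2], "+",
          ids[bi], lb - mrc[r, 4] + 1, lb - mrc[r, 3] + 1, "-", "inverted")
  }
  sort(unique(keys))
}

repeat_pair_keys <- function(pairs) {
  sort(vapply(pairs, function(p)
    paste(format_position(p$copy1$location),
          format_position(p$copy2$location), p$orientation), ""))
}

## ---- substring-containment classification oracle --------------------------

oracle_classify <- function(read, refs, anchor = 100) {
  wins <- vapply(refs$refs, function(r)
    substr(r$seq, r$repeat_span[1] - anchor, r$repeat_span[2] + anchor), "")
  rcr <- rc_chr(read)
  qual <- vapply(wins, function(w)
    grepl(w, read, fixed = TRUE) || grepl(w, rcr, fixed = TRUE), TRUE)
  if (!any(qual)) return("unclassified")
  if (sum(qual) == 1) return(names(wins)[qual])
  "ambiguous"
}

## ---- handy fixture: genome with one planted pair --------------------------

# returns list(genome, pair) with an exact or mutated copy planted; built by
# hand, not via generate_genome()
plant_pair_genome <- function(chrom_len, rep_len, s1, s2, inverted = FALSE,
                              nmut = 0, gc = 0.5, id = "chrA") {
  s <- rdna(chrom_len, gc)
  src <- substr(s, s1, s1 + rep_len - 1)
  copy <- sub_mutate(src, nmut)
  if (inverted) copy <- rc_chr(copy)
  s <- splice_at(s, s2, copy)
  g <- genome_set(setNames(s, id))
  iv1 <- interval(id, s1, s1 + rep_len - 1, "+")
  iv2 <- interval(id, s2, s2 + rep_len - 1, if (inverted) "-" else "+")
  pair <- mitorecomb:::new_repeat_pair(
    "T1",
    mitorecomb:::new_repeat_copy(iv1, substr(s, iv1$start, iv1$end)),
    mitorecomb:::new_repeat_copy(iv2, substr(s, iv2$start, iv2$end)),
    100 * (rep_len - nmut) / rep_len, if (inverted) "inverted" else "direct")
  list(genome = g, pair = pair, seq = s)
}
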