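# Core sequence/coordinate types and circular-genome arithmetic.
#
# External coordinates are 1-based inclusive throughout (matching the usual
# organelle-genomics reporting convention); a position string whose first
# number exceeds the second denotes a minus-strand copy spanning the reversed
# range.

VALID_DNA_RE <- "^[ACGTN]*$"

normalize_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq)) stop("`", what, "` must be a single string")
  s <- toupper(seq)
  if (!grepl(VALID_DNA_RE, s)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", s), "")[[1]])
    stop("`", what, "` contains non-DNA characters: ",
         paste(bad, collapse = ", "))
  }
  s
}

#' Create a circular (or linear) chromosome
#'
#' A named DNA sequence with explicit topology. Sequences are upper-cased and
#' restricted to the alphabet `A`, `C`, `G`, `T`, `N`; anything else is
#' rejected rather than silently remapped.
#'
#' @param id Chromosome name.
#' @param seq DNA string.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `CircularSequence` with fields `id`, `seq`,
#'   `topology` and derived `length`.
#' @examples
#' chr <- circular_sequence("chr1", "ACGTACGTAC")
#' chr$length
#' @export
circular_sequence <- function(id, seq, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (length(id) != 1L || !nzchar(id)) stop("`id` must be a non-empty string")
  seq <- normalize_dna(seq, "seq")
  if (nchar(seq) < 1L) stop("sequence must have length >= 1")
  structure(list(id = id, seq = seq, topology = topology,
                 length = nchar(seq)),
            class = "CircularSequence")
}

#' @export
print.CircularSequence <- function(x, ...) {
  cat(sprintf("<CircularSequence> %s  %s  %s bp\n", x$id, x$topology,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Create a genome set
#'
#' An ordered collection of chromosomes with unique ids. An empty set is
#' allowed (an empty FASTA yields one).
#'
#' @param chromosomes List of [circular_sequence()] objects, or a named
#'   character vector of sequences (all circular by default).
#' @param topology Optional named vector overriding topology per chromosome
#'   when `chromosomes` is a character vector.
#' @return A `GenomeSet` object.
#' @examples
#' g <- genome_set(c(chr1 = "ACGTACGT", chr2 = "GGCC"))
#' total_length(g)
#' @export
genome_set <- function(chromosomes = list(), topology = NULL) {
  if (is.character(chromosomes)) {
    ids <- names(chromosomes)
    if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named")
    chromosomes <- lapply(seq_along(chromosomes), function(i) {
      topo <- if (!is.null(topology) && ids[i] %in% names(topology))
        topology[[ids[i]]] else "circular"
      circular_sequence(ids[i], chromosomes[[i]], topo)
    })
  }
  if (!all(vapply(chromosomes, inherits, TRUE, "CircularSequence")))
    stop("`chromosomes` must be CircularSequence objects")
  ids <- vapply(chromosomes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("chromosome ids must be unique")
  names(chromosomes) <- ids
  structure(list(chromosomes = chromosomes), class = "GenomeSet")
}

#' @export
print.GenomeSet <- function(x, ...) {
  cat(sprintf("<GenomeSet> %d chromosome(s), %s bp total\n",
              length(x$chromosomes), format(total_length(x), big.mark = ",")))
  for (ch in x$chromosomes) print(ch)
  invisible(x)
}

#' Total genome length in bp
#' @param genome A `GenomeSet`.
#' @return Integer sum of chromosome lengths.
#' @export
total_length <- function(genome) {
  stopifnot(inherits(genome, "GenomeSet"))
  sum(vapply(genome$chromosomes, `[[`, 0L, "length"))
}

gs_seq <- function(genome, chrom) {
  ch <- genome$chromosomes[[chrom]]
  if (is.null(ch)) stop("chromosome not in genome: ", chrom)
  ch
}

#' Genomic interval (1-based, inclusive)
#'
#' @param chrom Chromosome id.
#' @param start,end 1-based inclusive coordinates with `start <= end`.
#' @param strand `"+"` or `"-"`. Minus-strand intervals represent
#'   reverse-complement copies; coordinates still refer to the plus strand.
#' @return An `Interval` object.
#' @export
interval <- function(chrom, start, end, strand = "+") {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start) stop("need 1 <= start <= end")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "Interval")
}

iv_len <- function(iv) iv$end - iv$start + 1L

#' Parse a printed position string
#'
#' A position like `"chr1: 48854-48524"` with the first coordinate larger than
#' the second denotes the minus-strand copy spanning the reversed range; this
#' is the only reading consistent with the printed lengths of such repeats
#' (48854 - 48524 + 1 = 331).
#'
#' @param x A string `"chrom: a-b"`.
#' @return An [interval()].
#' @examples
#' parse_position("chr1: 48854-48524")
#' @export
parse_position <- function(x) {
  m <- regmatches(x, regexec("^\\s*([^:]+?)\\s*:\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", x))[[1]]
  if (length(m) != 4L) stop("malformed position string: ", x)
  a <- as.integer(m[3]); b <- as.integer(m[4])
  if (a <= b) interval(m[2], a, b, "+") else interval(m[2], b, a, "-")
}

#' Format an interval as a printed position string
#'
#' Minus-strand copies are printed with reversed coordinates.
#' @param iv An [interval()].
#' @return A string `"chrom: a-b"`.
#' @export
format_position <- function(iv) {
  if (iv$strand == "+") sprintf("%s: %d-%d", iv$chrom, iv$start, iv$end)
  else sprintf("%s: %d-%d", iv$chrom, iv$end, iv$start)
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`; any other non-DNA character is an error. The operation is
#' an involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq DNA string (or character vector of them).
#' @return The reverse complement(s).
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (!all(grepl(VALID_DNA_RE, toupper(seq))))
    stop("non-DNA character in input to reverse_complement()")
  as.character(cpp_revcomp(toupper(seq)))
}

#' Extract a slice from a (possibly circular) chromosome
#'
#' Returns exactly `length` characters starting at `start` (1-based), wrapping
#' through the origin on circular chromosomes. Overrunning the end of a linear
#' chromosome is a coordinate error.
#'
#' @param chrom A [circular_sequence()].
#' @param start 1-based start, `1 <= start <= chrom$length`.
#' @param length Number of characters (`>= 0`); may exceed the chromosome
#'   length on circular molecules (multiple wraps).
#' @return A DNA string of exactly `length` characters.
#' @export
circular_slice <- function(chrom, start, length) {
  stopifnot(inherits(chrom, "CircularSequence"))
  start <- as.integer(start); length <- as.integer(length)
  L <- chrom$length
  if (start < 1L || start > L) stop("start out of range [1, ", L, "]")
  if (length < 0L) stop("length must be >= 0")
  if (length == 0L) return("")
  end <- start + length - 1L
  if (end <= L) return(substr(chrom$seq, start, end))
  if (chrom$topology != "circular")
    stop("slice overruns the end of linear chromosome ", chrom$id)
  reps <- ceiling(end / L)
  substr(strrep(chrom$seq, reps), start, end)
}

# Slice a circular chromosome by possibly out-of-range 1-based coordinates
# (negative/zero start wraps backwards through the origin).
slice_wrap <- function(chrom, start, length) {
  L <- chrom$length
  s <- ((start - 1L) %% L) + 1L
  circular_slice(chrom, s, length)
}

#' GC content of a genome, chromosome or DNA string
#'
#' Fraction of `G` + `C` among the unambiguous bases (`N` is ignored).
#' A sequence with no unambiguous bases is a degenerate input and raises an
#' error.
#'
#' @param x A `GenomeSet`, `CircularSequence` or DNA string.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(x) {
  if (inherits(x, "GenomeSet")) {
    if (length(x$chromosomes) == 0L) stop("empty genome has no GC content")
    s <- paste(vapply(x$chromosomes, `[[`, "", "seq"), collapse = "")
  } else if (inherits(x, "CircularSequence")) {
    s <- x$seq
  } else {
    s <- normalize_dna(x, "x")
  }
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    lengths(regmatches(s, gregexpr(b, s, fixed = TRUE)))
  }, 0L)
  tot <- sum(counts)
  if (tot == 0L) stop("sequence contains no unambiguous bases (all N)")
  unname((counts["G"] + counts["C"]) / tot)
}

## ---- FASTA / FASTQ I/O (Biostrings-backed) --------------------------------

#' Read a genome from FASTA
#'
#' FASTA cannot express topology, so circularity is declared via `topology`
#' (defaulting to circular, the usual case for assembled organelle
#' chromosomes). An empty file yields an empty `GenomeSet`.
#'
#' @param path FASTA file.
#' @param topology Optional named character vector, e.g.
#'   `c(chr1 = "circular", chr2 = "linear")`.
#' @return A `GenomeSet`.
#' @export
read_fasta <- function(path, topology = NULL) {
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) return(genome_set())
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_set(seqs, topology = topology)
}

#' Write a genome to FASTA
#'
#' @param genome A `GenomeSet`.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "GenomeSet"))
  seqs <- vapply(genome$chromosomes, `[[`, "", "seq")
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read long reads from FASTA or FASTQ
#'
#' The format is detected from the first non-empty character (`>` FASTA, `@`
#' FASTQ). Malformed records (including a quality line whose length does not
#' match its sequence) raise a parse error naming the file.
#'
#' @param path Reads file.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  first <- ""
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1L, 1L); break }
  }
  if (first == "") return(setNames(character(0), character(0)))
  if (first == ">") {
    set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                    error = function(e) stop("malformed FASTA reads '", path,
                                             "': ", conditionMessage(e)))
  } else if (first == "@") {
    set <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
      error = function(e) stop("malformed FASTQ reads '", path, "': ",
                               conditionMessage(e)))
    # Biostrings nul-pads short quality lines; materializing the strings
    # surfaces any record whose quality length disagrees with its sequence
    quals <- tryCatch(suppressWarnings(as.character(Biostrings::quality(set))),
                      error = function(e)
                        stop("malformed FASTQ reads '", path,
                             "': quality length mismatch"))
    if (any(nchar(quals) != Biostrings::width(set))) {
      bad <- which(nchar(quals) != Biostrings::width(set))[1]
      stop("malformed FASTQ reads '", path, "': quality length mismatch in ",
           "record ", bad)
    }
  } else {
    stop("unrecognized reads format in '", path, "' (expected FASTA or FASTQ)")
  }
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write reads to FASTQ with a constant placeholder quality
#'
#' @param reads Named character vector of sequences.
#' @param path Output file.
#' @param quality_char Single character used for every base quality.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  if (length(reads) > 0 && is.null(names(reads))) stop("reads must be named")
  quals <- vapply(nchar(reads), function(n) strrep(quality_char, n), "")
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(unname(as.character(reads))),
    Biostrings::PhredQuality(unname(quals)))
  names(set) <- names(reads)
  suppressWarnings(
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = Biostrings::quality(set)))
  invisible(path)
}

# round half-up at `digits` decimals (matches printed-table formatting;
# base round() is banker's rounding)
round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits
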