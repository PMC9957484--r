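# Products of a single homologous-recombination event at a repeat pair on
# circular molecules: direct pair on one circle -> fission into two circles;
# direct pair on two circles -> fusion into one; inverted pair on one circle
# -> inversion of the intervening segment; inverted pair on two circles ->
# fusion with one contribution reverse-complemented. Total length is always
# conserved.

#' Create a molecule set
#'
#' Molecules are either full [circular_sequence()] objects (sequence mode) or
#' named lengths (length-stub mode, for pure arithmetic on genome-scale
#' molecules).
#'
#' @param molecules Named list of `CircularSequence` objects, or a named
#'   numeric vector of molecule lengths (treated as circular stubs).
#' @param provenance Free-text description of how the set arose.
#' @return A `MoleculeSet` object; `$mode` is `"sequence"` or `"lengths"`.
#' @export
molecule_set <- function(molecules, provenance = "input") {
  if (is.numeric(molecules)) {
    if (is.null(names(molecules)) || any(!nzchar(names(molecules))))
      stop("length stubs must be named")
    if (any(molecules < 1)) stop("molecule lengths must be >= 1")
    return(structure(list(molecules = as.list(molecules), mode = "lengths",
                          provenance = provenance),
                     class = "MoleculeSet"))
  }
  if (!all(vapply(molecules, inherits, TRUE, "CircularSequence")))
    stop("molecules must be CircularSequence objects or named lengths")
  names(molecules) <- vapply(molecules, `[[`, "", "id")
  structure(list(molecules = molecules, mode = "sequence",
                 provenance = provenance),
            class = "MoleculeSet")
}

#' Total length of a molecule set
#' @param x A `MoleculeSet`.
#' @return Sum of molecule lengths in bp.
#' @export
molecule_lengths <- function(x) {
  stopifnot(inherits(x, "MoleculeSet"))
  if (x$mode == "lengths") vapply(x$molecules, as.numeric, 0)
  else vapply(x$molecules, `[[`, 0L, "length")
}

#' @export
print.MoleculeSet <- function(x, ...) {
  lens <- molecule_lengths(x)
  cat(sprintf("<MoleculeSet> (%s mode) %d molecule(s): %s\n  provenance: %s\n",
              x$mode, length(lens),
              paste(sprintf("%s=%s bp", names(lens),
                            format(lens, big.mark = ",", trim = TRUE)),
                    collapse = ", "),
              x$provenance))
  invisible(x)
}

rotate_circle <- function(seq, start) {
  if (start == 1L) return(seq)
  paste0(substr(seq, start, nchar(seq)), substr(seq, 1L, start - 1L))
}

replace_range <- function(seq, start, end, replacement) {
  paste0(substr(seq, 1L, start - 1L), replacement,
         substr(seq, end + 1L, nchar(seq)))
}

#' Predict the products of one recombination event at a repeat pair
#'
#' The crossover is modelled within the repeat such that every product
#' molecule carries one intact repeat copy; for non-identical copies the
#' products carry copy 1's sequence in the exchanged region (an explicit
#' consensus simplification, flagged in the provenance). The along-circle
#' distance `d` between copies is measured start-to-start in the `+` direction
#' of the host circle.
#'
#' Cases:
#' * direct pair, one circle of length `L`: fission into circles of `d` and
#'   `L - d` bp, each carrying one copy;
#' * direct pair, two circles: fusion into one circle of `L1 + L2` bp carrying
#'   both copies;
#' * inverted pair, one circle: one circle of unchanged length with the
#'   segment between the copies reverse-complemented (an involution);
#' * inverted pair, two circles: fusion into `L1 + L2` bp with one source
#'   molecule's contribution reverse-complemented.
#'
#' @param molecules A [molecule_set()] whose members host both repeat copies.
#' @param pair A `RepeatPair` (copy locations name molecules in the set).
#' @return A `MoleculeSet` of the product molecule(s). In sequence mode the
#'   attribute `"focus"` records the repeat-copy spans within each product.
#' @export
predict_products <- function(molecules, pair) {
  stopifnot(inherits(molecules, "MoleculeSet"), inherits(pair, "RepeatPair"))
  iv1 <- pair$copy1$location; iv2 <- pair$copy2$location
  for (cid in unique(c(iv1$chrom, iv2$chrom)))
    if (!cid %in% names(molecules$molecules))
      stop("repeat copy lies on a molecule absent from the set: ", cid)
  same <- iv1$chrom == iv2$chrom
  r <- pair$length
  note <- if (pair$identity < 100)
    "; non-identical copies: products carry copy1's sequence in the exchanged region"
  else ""

  if (molecules$mode == "lengths") {
    L1 <- as.numeric(molecules$molecules[[iv1$chrom]])
    if (same) {
      if (pair$orientation == "direct") {
        d <- (iv2$start - iv1$start) %% L1
        out <- setNames(c(d, L1 - d),
                        paste0(iv1$chrom, c("_fission_a", "_fission_b")))
        prov <- sprintf("fission of %s at %s (direct pair, d = %d)",
                        iv1$chrom, pair$id, as.integer(d))
      } else {
        out <- setNames(L1, paste0(iv1$chrom, "_inverted"))
        prov <- sprintf("inversion within %s at %s", iv1$chrom, pair$id)
      }
    } else {
      L2 <- as.numeric(molecules$molecules[[iv2$chrom]])
      out <- setNames(L1 + L2, paste0(iv1$chrom, "_", iv2$chrom, "_fused"))
      prov <- sprintf("fusion of %s and %s at %s (%s pair)",
                      iv1$chrom, iv2$chrom, pair$id, pair$orientation)
    }
    return(molecule_set(out, paste0(prov, note)))
  }

  ## sequence mode
  c1 <- molecules$molecules[[iv1$chrom]]
  if (c1$topology != "circular")
    stop("unsupported topology: host molecule ", c1$id, " is linear")
  r1seq <- substr(c1$seq, iv1$start, iv1$end)
  focus <- list()

  if (same) {
    L <- c1$length
    if (pair$orientation == "direct") {
      d <- (iv2$start - iv1$start) %% L
      if (d == 0) stop("degenerate direct pair: copies share a start")
      rot1 <- rotate_circle(c1$seq, iv1$start)
      rot2 <- rotate_circle(c1$seq, iv2$start)
      seq_a <- substr(rot1, 1L, d)
      seq_b <- replace_range(substr(rot2, 1L, L - d), 1L, r, r1seq)
      prods <- list(
        circular_sequence(paste0(c1$id, "_fission_a"), seq_a),
        circular_sequence(paste0(c1$id, "_fission_b"), seq_b))
      focus <- list(matrix(c(1L, r), 1L), matrix(c(1L, r), 1L))
      prov <- sprintf("fission of %s at %s (direct pair, d = %d)",
                      c1$id, pair$id, as.integer(d))
    } else {
      if (iv1$end >= iv2$start)
        stop("overlapping inverted copies are not supported in sequence mode")
      interior <- if (iv1$end + 1L > iv2$start - 1L) "" else
        substr(c1$seq, iv1$end + 1L, iv2$start - 1L)
      seq_inv <- paste0(substr(c1$seq, 1L, iv1$end),
                        if (nzchar(interior)) reverse_complement(interior) else "",
                        substr(c1$seq, iv2$start, c1$length))
      seq_inv <- replace_range(seq_inv, iv2$start, iv2$end,
                               reverse_complement(r1seq))
      prods <- list(circular_sequence(paste0(c1$id, "_inverted"), seq_inv))
      focus <- list(matrix(c(iv1$start, iv1$end, iv2$start, iv2$end),
                           2L, byrow = TRUE))
      prov <- sprintf("inversion within %s at %s", c1$id, pair$id)
    }
  } else {
    c2 <- molecules$molecules[[iv2$chrom]]
    if (c2$topology != "circular")
      stop("unsupported topology: host molecule ", c2$id, " is linear")
    part1 <- rotate_circle(c1$seq, iv1$start)
    if (pair$orientation == "direct") {
      part2 <- rotate_circle(c2$seq, iv2$start)
    } else {
      # orient the second circle so its copy reads in the common direction
      s2o <- c2$length - iv2$end + 1L
      part2 <- rotate_circle(reverse_complement(c2$seq), s2o)
    }
    part2 <- replace_range(part2, 1L, r, r1seq)
    fused <- circular_sequence(paste0(c1$id, "_", c2$id, "_fused"),
                               paste0(part1, part2))
    prods <- list(fused)
    focus <- list(matrix(c(1L, r, c1$length + 1L, c1$length + r),
                         2L, byrow = TRUE))
    prov <- sprintf("fusion of %s and %s at %s (%s pair)",
                    c1$id, c2$id, pair$id, pair$orientation)
  }
  out <- molecule_set(prods, paste0(prov, note))
  names(focus) <- names(out$molecules)
  attr(out, "focus") <- focus
  out
}
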