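# IUPAC degenerate-base algebra: code -> base-set mapping, motif validation,
# expansion into concrete words, degeneracy counting, reverse complement.

#' IUPAC nucleotide code table
#'
#' The 15 single-letter IUPAC nucleotide codes for DNA and the set of
#' concrete bases each stands for.  Base sets are kept in `A < C < G < T`
#' order so that expansions are deterministic.
#'
#' @return A named list: one character vector of bases per code.
#' @examples
#' iupac_bases()[["W"]]  # "A" "T"
#' @export
iupac_bases <- function() .iupac_table

.iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"),
  M = c("A", "C"), K = c("G", "T"),
  R = c("A", "G"), Y = c("C", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Watson-Crick complement lifted to codes: complement(code) has exactly the
# complements of bases(code).  W, S and N are self-complementary as sets.
.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A",
  W = "W", S = "S", M = "K", K = "M", R = "Y", Y = "R",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Validate a degenerate motif
#'
#' Checks that a raw motif string is a legal IUPAC DNA pattern and wraps it
#' as a `degenerate_motif` object.  Input is upper-cased; `U` (RNA), gap
#' characters (`-`, `.`) and anything outside the 15-code alphabet are
#' rejected with the offending character and its position.
#'
#' @param raw Motif as a character scalar, e.g. `"WGATAR"`.
#' @param motif_id Identifier attached to the motif (default `"motif"`).
#' @return An object of class `degenerate_motif` with elements `motif_id`
#'   and `pattern`.
#' @examples
#' m <- validate_motif("wgata", "m1")
#' m$pattern             # "WGATA"
#' motif_degeneracy(m)   # 2
#' @export
validate_motif <- function(raw, motif_id = "motif") {
  stopifnot(is.character(raw), length(raw) == 1L)
  pattern <- toupper(trimws(raw))
  if (!nzchar(pattern)) stop("empty motif", call. = FALSE)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.iupac_table))
  if (length(bad)) {
    stop(sprintf("motif '%s': illegal character '%s' at position %d (not an IUPAC nucleotide code)",
                 motif_id, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  structure(list(motif_id = as.character(motif_id), pattern = pattern),
            class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("<degenerate_motif> %s: %s (degeneracy %d)\n",
              x$motif_id, x$pattern, motif_degeneracy(x)))
  invisible(x)
}

.as_motif <- function(x, motif_id = "motif") {
  if (inherits(x, "degenerate_motif")) x else validate_motif(x, motif_id)
}

#' Degeneracy of a motif
#'
#' Number of concrete ACGT words a degenerate motif stands for: the product
#' over positions of the size of each position's base set.  Multiplicative
#' under concatenation.
#'
#' @param motif A `degenerate_motif` or a raw motif string.
#' @return A positive number (may exceed integer range for long N-runs).
#' @examples
#' motif_degeneracy("WSN")  # 2 * 2 * 4 = 16
#' @export
motif_degeneracy <- function(motif) {
  motif <- .as_motif(motif)
  chars <- strsplit(motif$pattern, "", fixed = TRUE)[[1L]]
  prod(lengths(.iupac_table[chars]))
}

#' Expand a degenerate motif into concrete words
#'
#' Cartesian product of the per-position base sets, in lexicographic order
#' over `A < C < G < T`.  Refuses motifs whose degeneracy exceeds
#' `expansion_cap`, since expansion is exponential in the number of
#' degenerate positions.
#'
#' @inheritParams motif_degeneracy
#' @param expansion_cap Maximum number of words to generate
#'   (default 65536, i.e. an all-`N` motif of length 8).
#' @return Character vector of `motif_degeneracy(motif)` distinct words.
#' @examples
#' expand_motif("RY")  # "AC" "AT" "GC" "GT"
#' @export
expand_motif <- function(motif, expansion_cap = 65536L) {
  motif <- .as_motif(motif)
  deg <- motif_degeneracy(motif)
  if (deg > expansion_cap) {
    stop(sprintf("motif '%s' has degeneracy %s, exceeding the expansion cap %s",
                 motif$motif_id, format(deg, scientific = FALSE),
                 format(expansion_cap, scientific = FALSE)), call. = FALSE)
  }
  chars <- strsplit(motif$pattern, "", fixed = TRUE)[[1L]]
  words <- ""
  for (set in .iupac_table[chars]) {
    # prefix-major append keeps the running list lexicographic
    words <- as.vector(t(outer(words, set, paste0)))
  }
  words
}

#' Reverse complement of a degenerate motif
#'
#' Reverses the pattern and complements each code; the complement of a code
#' is the code whose base set is the Watson-Crick complement of the
#' original's.  An involution, and it commutes with expansion:
#' the expansions of `reverse_complement(m)` are exactly the reverse
#' complements of the expansions of `m`.
#'
#' @inheritParams motif_degeneracy
#' @return A `degenerate_motif` (same `motif_id`).
#' @examples
#' reverse_complement("WGA")$pattern  # "TCW"
#' @export
reverse_complement <- function(motif) {
  motif <- .as_motif(motif)
  chars <- strsplit(motif$pattern, "", fixed = TRUE)[[1L]]
  rc <- paste(rev(unname(.iupac_complement[chars])), collapse = "")
  structure(list(motif_id = motif$motif_id, pattern = rc),
            class = "degenerate_motif")
}
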