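# Per-target-sequence suffix index: all suffixes of a sequence stored in a
# character trie with string tails, supporting exact word lookup that
# reports every (possibly overlapping) start position.

#' Build a suffix index for one target sequence
#'
#' Generates every suffix of the sequence (all `n` of them, including the
#' full sequence itself, so matches at position 1 are found) and inserts
#' them successively into a character trie with string tails; shared
#' prefixes split tails into nodes.  A word of length `m` is then located
#' by walking at most `m` child edges plus one tail comparison.
#'
#' Non-ACGT characters (e.g. assembly `N`s) are stored literally and
#' counted; concrete ACGT query words can never match across them.
#'
#' @param seq_id Identifier of the target sequence.
#' @param sequence DNA sequence as a character scalar; upper-cased on input.
#' @return An object of class `suffix_index` with fields `seq_id`, `length`,
#'   `n_non_acgt` and an external pointer to the tree.  The index is
#'   self-contained and freed when garbage-collected, so indexes for many
#'   targets can be built and dropped one at a time.
#' @examples
#' idx <- build_suffix_index("t1", "TACGA")
#' find_all(idx, "ACG")  # 2
#' @export
build_suffix_index <- function(seq_id, sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence for target '", seq_id, "'", call. = FALSE)
  n_non <- nchar(sequence) - sum(charToRaw(sequence) %in% charToRaw("ACGT"))
  structure(
    list(seq_id = as.character(seq_id),
         length = nchar(sequence),
         n_non_acgt = as.integer(n_non),
         ptr = .st_build(sequence)),
    class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat(sprintf("<suffix_index> %s: %d bp, %d nodes, %d non-ACGT\n",
              x$seq_id, x$length, .st_node_count(x$ptr), x$n_non_acgt))
  invisible(x)
}

#' Find all occurrences of a concrete word
#'
#' @param index A `suffix_index`.
#' @param word Concrete DNA word over `{A,C,G,T}`.
#' @return Sorted integer vector of 1-based start positions; overlapping
#'   occurrences are all reported.  A word longer than the indexed sequence
#'   simply yields an empty result.
#' @examples
#' find_all(build_suffix_index("s", "AAAA"), "AA")  # 1 2 3
#' @export
find_all <- function(index, word) {
  .check_word(word)
  .st_find(index$ptr, toupper(word))
}

#' Test whether a word occurs at all
#'
#' Equivalent to `length(find_all(index, word)) > 0` but stops the tree walk
#' at the first full match.
#'
#' @inheritParams find_all
#' @return Logical scalar.
#' @export
contains_word <- function(index, word) {
  .check_word(word)
  .st_contains(index$ptr, toupper(word))
}

#' Enumerate the suffixes stored in an index
#'
#' Spells every root-to-terminal string in the tree together with its
#' 1-based start position.  Intended for verification: the result must be
#' exactly the suffix set of the indexed sequence, each position appearing
#' once.
#'
#' @param index A `suffix_index`.
#' @return A data frame with columns `position` and `suffix`, sorted by
#'   position.
#' @export
index_suffixes <- function(index) {
  df <- .st_suffixes(index$ptr)
  df[order(df$position), , drop = FALSE]
}

#' Instrumented word lookup
#'
#' Like [find_all()] but also reports how much of the tree the walk
#' inspected: the number of child-edge descents (at most `nchar(word)`) and
#' the number of tail comparisons (at most one).  This is the operational
#' form of the O(m) lookup-cost contract.
#'
#' @inheritParams find_all
#' @return A list with `positions`, `path_chars` and `tail_comparisons`.
#' @export
lookup_profile <- function(index, word) {
  .check_word(word)
  .st_find_profiled(index$ptr, toupper(word))
}

.check_word <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (!nzchar(word)) stop("empty query word", call. = FALSE)
  invisible(TRUE)
}
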