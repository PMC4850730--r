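# Independent naive search oracle.  Deliberately shares no machinery with
# the suffix-tree engine: a positionwise IUPAC set-membership sliding
# window, linear in target length, with no motif expansion — so it also
# handles motifs whose degeneracy would be far over any expansion cap.

#' Naive sliding-window motif search (reference oracle)
#'
#' Slides the motif along the target and tests, position by position,
#' whether the target base is a member of the motif code's base set.  Its
#' hit set is by construction identical to [search_motifs()] restricted to
#' one motif and one target; it exists as an independent correctness
#' reference and for motifs too degenerate to expand.
#'
#' @inheritParams motif_degeneracy
#' @param target_id Identifier of the target sequence.
#' @param sequence Target DNA sequence (character scalar).
#' @param both_strands Also match the reverse-complement pattern
#'   (reported as `-`-strand hits at forward coordinates).
#' @return A hit data frame with the same columns and ordering as
#'   [search_motifs()].
#' @examples
#' naive_search("WGATAR", "t1", "TGATAAC")
#' @export
naive_search <- function(motif, target_id, sequence, both_strands = FALSE) {
  motif <- .as_motif(motif)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  pats <- list(`+` = motif$pattern)
  if (both_strands) pats[["-"]] <- reverse_complement(motif)$pattern
  rows <- list()
  for (s in names(pats)) {
    starts <- .naive_scan(pats[[s]], chars)
    if (!length(starts)) next
    m <- nchar(pats[[s]])
    rows[[s]] <- data.frame(
      motif_id = motif$motif_id,
      target_id = as.character(target_id),
      start = starts,
      end = starts + m - 1L,
      strand = s,
      matched_word = vapply(starts, function(p)
        paste(chars[p:(p + m - 1L)], collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_hits())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# start positions where every motif code's base set contains the target
# base; a non-ACGT target character is in no base set and never matches
.naive_scan <- function(pattern, chars) {
  m <- nchar(pattern)
  n <- length(chars)
  if (m > n) return(integer())
  codes <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  ok <- rep(TRUE, n - m + 1L)
  for (i in seq_len(m)) {
    ok <- ok & chars[seq_len(n - m + 1L) + i - 1L] %in% .iupac_table[[codes[i]]]
  }
  which(ok)
}
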