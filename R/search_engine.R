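# Multi-motif x multi-target exact search: expand each degenerate motif,
# build one suffix index per target, look up every expanded word, emit hits.

.hit_columns <- c("motif_id", "target_id", "start", "end", "strand", "matched_word")

.empty_hits <- function() {
  data.frame(motif_id = character(), target_id = character(),
             start = integer(), end = integer(), strand = character(),
             matched_word = character(), stringsAsFactors = FALSE)
}

# Normalize motif input: a list of degenerate_motif, a character vector
# (optionally named -> motif ids), or a single motif.
.as_motif_list <- function(motifs) {
  if (inherits(motifs, "degenerate_motif")) motifs <- list(motifs)
  if (is.character(motifs)) {
    ids <- names(motifs)
    if (is.null(ids)) ids <- paste0("motif", seq_along(motifs))
    motifs <- Map(validate_motif, motifs, ids)
  }
  if (!length(motifs)) stop("no motifs supplied", call. = FALSE)
  motifs <- lapply(motifs, .as_motif)
  ids <- vapply(motifs, `[[`, character(1), "motif_id")
  if (anyDuplicated(ids)) {
    stop("duplicate motif ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  motifs
}

# Normalize target input: a data frame with seq_id/sequence columns (as
# produced by read_fasta) or a named character vector.
.as_target_frame <- function(targets) {
  if (is.character(targets)) {
    ids <- names(targets)
    if (is.null(ids)) ids <- paste0("seq", seq_along(targets))
    targets <- data.frame(seq_id = ids, sequence = unname(targets),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(targets), all(c("seq_id", "sequence") %in% names(targets)))
  if (!nrow(targets)) stop("no target sequences supplied", call. = FALSE)
  targets$sequence <- toupper(targets$sequence)
  targets
}

#' Search degenerate motifs in target sequences
#'
#' For each target a suffix index is built (and dropped before the next
#' target), each motif is expanded into its concrete words, and every word
#' is looked up individually; each occurrence becomes one hit row.  With
#' `both_strands = TRUE` the expansions of each motif's reverse complement
#' are additionally searched and reported as `-`-strand hits, with
#' coordinates always on the forward strand.
#'
#' Hits are ordered by target input order, then start position, then motif
#' input order (`+` before `-` on ties), so identical inputs give
#' byte-identical output.
#'
#' @param motifs Motifs: a list of [validate_motif()] objects, or a
#'   (optionally named) character vector of IUPAC patterns.
#' @param targets Targets: a data frame with `seq_id` and `sequence`
#'   columns (see [read_fasta()]) or a named character vector.
#' @param both_strands Also search the reverse complement of each motif
#'   (default `FALSE`: forward strand only).
#' @param expansion_cap Per-motif limit on the number of expanded words; a
#'   motif over the cap is skipped with a warning while the remaining
#'   motifs are still searched.
#' @return A data frame of hits with columns `motif_id`, `target_id`,
#'   `start`, `end` (1-based, fully closed), `strand` and `matched_word`.
#' @examples
#' search_motifs(c(m1 = "RY"), c(t1 = "ACGT"))
#' @export
search_motifs <- function(motifs, targets, both_strands = FALSE,
                          expansion_cap = 65536L) {
  motifs <- .as_motif_list(motifs)
  targets <- .as_target_frame(targets)

  # expand once, up front; a cap violation disables that motif only
  plans <- vector("list", length(motifs))
  for (j in seq_along(motifs)) {
    m <- motifs[[j]]
    words <- tryCatch(expand_motif(m, expansion_cap), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(words)) next
    strands <- "+"
    word_sets <- list(`+` = words)
    if (both_strands) {
      word_sets[["-"]] <- expand_motif(reverse_complement(m), expansion_cap)
      strands <- c("+", "-")
    }
    plans[[j]] <- list(motif_id = m$motif_id, strands = strands,
                       words = word_sets)
  }

  chunks <- list()
  for (i in seq_len(nrow(targets))) {
    idx <- build_suffix_index(targets$seq_id[i], targets$sequence[i])
    acc_motif <- character(); acc_start <- integer(); acc_word <- character()
    acc_strand <- character(); acc_order <- integer()
    for (j in seq_along(plans)) {
      plan <- plans[[j]]
      if (is.null(plan)) next
      for (s in plan$strands) {
        words <- plan$words[[s]]
        pos_list <- .st_find_many(idx$ptr, words)
        nhit <- lengths(pos_list)
        if (!sum(nhit)) next
        acc_motif <- c(acc_motif, rep(plan$motif_id, sum(nhit)))
        acc_start <- c(acc_start, unlist(pos_list, use.names = FALSE))
        acc_word <- c(acc_word, rep(words, nhit))
        acc_strand <- c(acc_strand, rep(s, sum(nhit)))
        acc_order <- c(acc_order, rep(j, sum(nhit)))
      }
    }
    if (length(acc_start)) {
      ord <- order(acc_start, acc_order, acc_strand, method = "radix")
      chunks[[length(chunks) + 1L]] <- data.frame(
        motif_id = acc_motif[ord],
        target_id = targets$seq_id[i],
        start = acc_start[ord],
        end = acc_start[ord] + nchar(acc_word[ord]) - 1L,
        strand = acc_strand[ord],
        matched_word = acc_word[ord],
        stringsAsFactors = FALSE)
    }
    rm(idx)  # one index resident at a time
  }
  if (!length(chunks)) return(.empty_hits())
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

#' Summarize a hit table
#'
#' Per-motif and per-target hit counts plus the grand total; the total
#' always equals both column sums.
#'
#' @param hits A hit data frame from [search_motifs()], [naive_search()] or
#'   [scan_ppm()].
#' @param motif_ids,target_ids Optional full id sets, so that motifs or
#'   targets with zero hits appear with count 0.
#' @return A list with `total`, `per_motif` and `per_target` data frames.
#' @export
summarize_hits <- function(hits, motif_ids = NULL, target_ids = NULL) {
  stopifnot(is.data.frame(hits))
  if (is.null(motif_ids)) motif_ids <- unique(hits$motif_id)
  if (is.null(target_ids)) target_ids <- unique(hits$target_id)
  per_motif <- data.frame(
    motif_id = motif_ids,
    n_hits = as.integer(table(factor(hits$motif_id, levels = motif_ids))),
    stringsAsFactors = FALSE)
  per_target <- data.frame(
    target_id = target_ids,
    n_hits = as.integer(table(factor(hits$target_id, levels = target_ids))),
    stringsAsFactors = FALSE)
  list(total = nrow(hits), per_motif = per_motif, per_target = per_target)
}
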