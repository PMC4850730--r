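# FASTA readers/writers (via Biostrings), motif-file reading, and hit
# output in TSV and GFF3.

#' Read a FASTA file
#'
#' Reads (multi-)FASTA via `Biostrings::readDNAStringSet` and returns one
#' row per record: `seq_id` is the first whitespace-delimited header token,
#' `description` the remainder, `sequence` the concatenated upper-cased
#' residue lines.  Input order is preserved (hit ordering depends on it).
#' CRLF line endings are tolerated; duplicate ids and empty-sequence
#' records are rejected.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_check If `TRUE`, reject records containing characters
#'   outside the IUPAC DNA alphabet.  Off by default: targets may carry
#'   arbitrary characters, which simply never match.
#' @return A data frame with columns `seq_id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet_check = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(trimws(first), ">")) {
    stop("not FASTA (no '>' header): ", path, call. = FALSE)
  }
  # BStringSet keeps arbitrary residue characters verbatim (a DNA reader
  # would silently drop them); validation decides what is legal downstream
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not FASTA: ", path, " (",
                                           conditionMessage(e), ")", call. = FALSE))
  if (!length(set)) stop("no records in ", path, call. = FALSE)
  headers <- names(set)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(seq_id))) stop("record with empty id in ", path, call. = FALSE)
  if (anyDuplicated(seq_id)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "), call. = FALSE)
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty sequence record(s) in ", path, ": ",
         paste(seq_id[Biostrings::width(set) == 0L], collapse = ", "), call. = FALSE)
  }
  sequence <- toupper(as.character(set))
  if (alphabet_check) {
    ok <- !grepl(sprintf("[^%s]", paste(names(.iupac_table), collapse = "")), sequence)
    if (!all(ok)) {
      stop("non-IUPAC characters in record(s): ",
           paste(seq_id[!ok], collapse = ", "), call. = FALSE)
    }
  }
  data.frame(seq_id = seq_id, description = description, sequence = sequence,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTA file
#'
#' @param records A data frame as returned by [read_fasta()] (columns
#'   `seq_id`, `sequence`, optional `description`), or a named character
#'   vector.
#' @param path Output path.
#' @param width Residues per line (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- .as_target_frame(records)
  headers <- records$seq_id
  if (!is.null(records$description)) {
    headers <- ifelse(nzchar(records$description),
                      paste(records$seq_id, records$description), records$seq_id)
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read degenerate motifs from a FASTA file
#'
#' Each record's concatenated sequence is one IUPAC motif; the header token
#' up to the first whitespace is its id.  Every motif is validated
#' ([validate_motif()]); duplicate ids are rejected.
#'
#' @param path Path to the motif FASTA file.
#' @return A list of `degenerate_motif` objects, in file order.
#' @export
read_motifs <- function(path) {
  recs <- read_fasta(path)
  Map(function(s, id) validate_motif(s, id), recs$sequence, recs$seq_id,
      USE.NAMES = FALSE)
}

#' Write hits as TSV
#'
#' One header line, then one row per hit: `motif_id`, `target_id`, `start`,
#' `end`, `strand`, and either `matched_word` (exact search) or the
#' `raw_llr`/`norm_score` pair (matrix scan), scores rounded to 4 decimals.
#' Parsing the file back ([read_hits_tsv()]) recovers the hit table.
#'
#' @param hits Hit data frame from [search_motifs()], [naive_search()] or
#'   [scan_ppm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  out <- hits
  for (cl in intersect(c("raw_llr", "norm_score"), names(out))) {
    out[[cl]] <- round(out[[cl]], 4)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a hit TSV written by [write_hits_tsv()]
#'
#' @param path Path to the TSV.
#' @return A hit data frame.
#' @export
read_hits_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write hits as GFF3
#'
#' GFF3 with 1-based fully-closed coordinates (source `exactmotif`, type
#' `nucleotide_motif`), via `rtracklayer::export.gff3`.  The motif id goes
#' into `Name`, the matched word (exact search) into `matched_word`, and
#' the normalized score (matrix scan) into the `score` column.
#'
#' @inheritParams write_hits_tsv
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$target_id,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = hits$strand)
  S4Vectors::mcols(gr)$source <- "exactmotif"
  S4Vectors::mcols(gr)$type <- "nucleotide_motif"
  S4Vectors::mcols(gr)$Name <- hits$motif_id
  if (!is.null(hits$matched_word)) {
    S4Vectors::mcols(gr)$matched_word <- hits$matched_word
  }
  if (!is.null(hits$norm_score)) {
    S4Vectors::mcols(gr)$score <- round(hits$norm_score, 4)
  }
  rtracklayer::export.gff3(gr, path)
  # drop run-dependent pragmas so identical inputs give identical bytes
  lines <- readLines(path)
  writeLines(lines[!grepl("^##(date|source-version)", lines)], path)
  invisible(path)
}
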