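# k-order Markov background models over {A,C,G,T}, estimated from a
# sequence corpus with additive (pseudocount) smoothing.  A model of order
# k carries the conditional distributions of every order 0..k, so that
# window positions with fewer than k preceding bases can fall back on the
# lower-order marginals.

.base_order <- c("A", "C", "G", "T")

# integer codes 1..4 for A,C,G,T; NA for anything else
.encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]], .base_order)
}

# all k-mers in lexicographic order, matching the base-4 context encoding
.kmers <- function(k) {
  if (k == 0L) return("")
  sort(do.call(paste0, expand.grid(rep(list(.base_order), k),
                                   stringsAsFactors = FALSE)))
}

#' Build a k-order Markov background model
#'
#' Counts, over all sequences, every occurrence of a base following each
#' context of length `j` for `j = 0, ..., order`, skipping any window that
#' touches a non-ACGT character, and converts counts to conditional
#' probabilities with additive smoothing:
#' `P(b | context) = (count + pseudocount) / (total + 4 * pseudocount)`.
#'
#' @param sequences Character vector of DNA sequences, or a data frame with
#'   a `sequence` column (see [read_fasta()]).
#' @param order Markov order `k`, between 0 and 5.
#' @param pseudocount Additive smoothing constant `alpha >= 0`
#'   (default 1).  With `pseudocount = 0` every context of length `order`
#'   must be observed in the corpus, otherwise an error asks for a positive
#'   pseudocount.
#' @return An object of class `background_model`: a list with `order`,
#'   `pseudocount`, `initial` (distribution over k-mers) and `transition`
#'   (one `4^j x 4` row-stochastic matrix per order `j = 0..k`, contexts as
#'   row names).
#' @examples
#' bg <- build_background("AACC", order = 0, pseudocount = 1)
#' bg$transition[[1]][1, "A"]  # (2 + 1) / (4 + 4) = 0.375
#' @export
build_background <- function(sequences, order = 0L, pseudocount = 1) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  order <- as.integer(order)
  if (order < 0L || order > 5L) stop("order must be between 0 and 5", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  codes_list <- lapply(sequences, .encode_dna)
  if (!sum(vapply(codes_list, function(x) sum(!is.na(x)), integer(1))))
    stop("no usable (ACGT) sequence in the corpus", call. = FALSE)

  transition <- vector("list", order + 1L)
  for (j in 0:order) {
    counts <- matrix(0, nrow = 4L^j, ncol = 4L,
                     dimnames = list(.kmers(j), .base_order))
    for (codes in codes_list) {
      n <- length(codes)
      if (n < j + 1L) next
      # context index (1-based) from the j preceding bases, base-4
      ctx <- rep(0L, n - j)
      clean <- rep(TRUE, n - j)
      for (d in seq_len(j)) {
        b <- codes[seq_len(n - j) + d - 1L]
        clean <- clean & !is.na(b)
        ctx <- ctx * 4L + ifelse(is.na(b), 0L, b - 1L)
      }
      b_next <- codes[seq_len(n - j) + j]
      clean <- clean & !is.na(b_next)
      if (!any(clean)) next
      cell <- (b_next[clean] - 1L) * 4L^j + ctx[clean] + 1L
      counts <- counts + matrix(tabulate(cell, nbins = 4L^(j + 1L)),
                                nrow = 4L^j, ncol = 4L)
    }
    tot <- rowSums(counts)
    if (pseudocount == 0 && j == order) {
      if (all(tot == 0)) {
        stop(sprintf("the corpus contains no clean window of length %d; order %d is too large, or use pseudocount > 0",
                     order + 1L, order), call. = FALSE)
      }
      if (any(tot == 0)) {
        warning(sprintf("%d of %d order-%d contexts unseen at pseudocount 0; unseen contexts fall back to uniform",
                        sum(tot == 0), length(tot), j), call. = FALSE)
      }
    }
    probs <- (counts + pseudocount) / (tot + 4 * pseudocount)
    probs[is.nan(probs)] <- 0.25  # unseen context at alpha = 0
    transition[[j + 1L]] <- probs
  }

  # stationary-style initial distribution: frequency of clean k-mers
  km <- .kmers(order)
  init_counts <- stats::setNames(rep(0, length(km)), km)
  if (order == 0L) {
    init <- stats::setNames(1, "")
  } else {
    for (codes in codes_list) {
      n <- length(codes)
      if (n < order) next
      ctx <- rep(0L, n - order + 1L)
      clean <- rep(TRUE, n - order + 1L)
      for (d in seq_len(order)) {
        b <- codes[seq_len(n - order + 1L) + d - 1L]
        clean <- clean & !is.na(b)
        ctx <- ctx * 4L + ifelse(is.na(b), 0L, b - 1L)
      }
      if (!any(clean)) next
      tab <- tabulate(ctx[clean] + 1L, nbins = length(km))
      init_counts <- init_counts + tab
    }
    init <- (init_counts + pseudocount) /
      (sum(init_counts) + length(km) * pseudocount)
  }

  structure(list(order = order, pseudocount = pseudocount,
                 initial = init, transition = transition),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> order %d, pseudocount %g\n",
              x$order, x$pseudocount))
  print(round(x$transition[[1L]], 4))
  invisible(x)
}

#' Write a background model to a plain-text file
#'
#' Key-value text format: the order and pseudocount, the initial k-mer
#' distribution, then one conditional-probability table per order.
#' Readable back with [read_background()].
#'
#' @param bg A `background_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "background_model"))
  lines <- c("# Markov background model",
             paste("order:", bg$order),
             paste("pseudocount:", format(bg$pseudocount, digits = 17)),
             "[initial]",
             paste(names(bg$initial), format(bg$initial, digits = 17)))
  for (j in 0:bg$order) {
    tr <- bg$transition[[j + 1L]]
    lines <- c(lines, sprintf("[transition %d]", j),
               paste(ifelse(rownames(tr) == "", ".", rownames(tr)),
                     apply(format(tr, digits = 17), 1L, paste, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a background model written by [write_background()]
#'
#' @param path File path.
#' @return A `background_model`.
#' @export
read_background <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  get_kv <- function(key) {
    l <- lines[startsWith(lines, paste0(key, ":"))]
    if (!length(l)) stop("background file missing '", key, ":'", call. = FALSE)
    sub(paste0("^", key, ":\\s*"), "", l[1L])
  }
  order <- as.integer(get_kv("order"))
  pseudocount <- as.numeric(get_kv("pseudocount"))
  section <- function(name) {
    i <- which(lines == sprintf("[%s]", name))
    if (!length(i)) stop("background file missing [", name, "]", call. = FALSE)
    j <- i + 1L
    out <- character()
    while (j <= length(lines) && !startsWith(lines[j], "[")) {
      out <- c(out, lines[j]); j <- j + 1L
    }
    out
  }
  parse_init <- function(ls) {
    parts <- strsplit(ls, "\\s+")
    stats::setNames(vapply(parts, function(p) as.numeric(p[2L]), numeric(1)),
                    vapply(parts, function(p) if (p[1L] == ".") "" else p[1L],
                           character(1)))
  }
  init <- parse_init(section("initial"))
  transition <- vector("list", order + 1L)
  for (j in 0:order) {
    ls <- section(sprintf("transition %d", j))
    parts <- strsplit(ls, "\\s+")
    ctx <- vapply(parts, function(p) if (p[1L] == ".") "" else p[1L], character(1))
    tr <- t(vapply(parts, function(p) as.numeric(p[2:5]), numeric(4)))
    dimnames(tr) <- list(ctx, .base_order)
    transition[[j + 1L]] <- tr[order(rownames(tr)), , drop = FALSE]
  }
  structure(list(order = order, pseudocount = pseudocount,
                 initial = init[order(names(init))], transition = transition),
            class = "background_model")
}

#' Uniform order-0 background
#'
#' Convenience constructor: every base equally likely.  Useful as a neutral
#' reference when no corpus is available.
#'
#' @return A `background_model` of order 0 with all probabilities 0.25.
#' @export
uniform_background <- function() {
  tr <- matrix(0.25, 1L, 4L, dimnames = list("", .base_order))
  structure(list(order = 0L, pseudocount = 0,
                 initial = stats::setNames(1, ""), transition = list(tr)),
            class = "background_model")
}
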