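# Position probability matrix (PPM) scanning against Markov background
# models.  A window of width L is scored with the log-likelihood ratio
#   raw_llr = sum_i ln( ppm[i, b_i] / P_bg(b_i | context_i) )
# where the context of position i is the window's own preceding bases
# (positions with fewer than k preceding bases use the lower-order
# marginals), and normalized to [0,1] by the window-achievable extrema:
#   norm_score = (raw_llr - min_llr) / (max_llr - min_llr)
# with min/max taken per position over the four bases, keeping the
# window's actual contexts fixed.

#' Construct a position probability matrix
#'
#' Validates and regularizes an L x 4 probability table (columns in
#' A, C, G, T order).  Rows must already be near-stochastic: a row sum
#' outside `[0.98, 1.02]` is rejected as "not a probability matrix"
#' (count matrices are not silently converted).  Accepted rows are
#' renormalized, floored with a pseudocount of `1e-4`, and renormalized
#' again so every entry is strictly positive.
#'
#' @param probs Numeric L x 4 matrix of per-position base probabilities.
#' @param motif_id Identifier for the matrix.
#' @return An object of class `ppm` with `motif_id`, `width` and `probs`.
#' @examples
#' ppm(matrix(0.25, 4, 4), "uniform4")
#' @export
ppm <- function(probs, motif_id = "ppm") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("a PPM needs 4 columns (A, C, G, T)", call. = FALSE)
  if (!nrow(probs)) stop("empty PPM", call. = FALSE)
  if (any(probs < 0)) stop("negative entries: not a probability matrix", call. = FALSE)
  rs <- rowSums(probs)
  if (any(rs < 0.98 | rs > 1.02)) {
    stop(sprintf("row %d sums to %.4g: not a probability matrix",
                 which(rs < 0.98 | rs > 1.02)[1L], rs[which(rs < 0.98 | rs > 1.02)[1L]]),
         call. = FALSE)
  }
  probs <- probs / rs
  probs <- probs + 1e-4
  probs <- probs / rowSums(probs)
  dimnames(probs) <- list(NULL, .base_order)
  structure(list(motif_id = as.character(motif_id),
                 width = nrow(probs), probs = probs),
            class = "ppm")
}

#' @export
print.ppm <- function(x, ...) {
  cat(sprintf("<ppm> %s, width %d\n", x$motif_id, x$width))
  print(round(x$probs, 4))
  invisible(x)
}

#' Read position probability matrices (INCLUSive-style blocks)
#'
#' Parses motif model blocks: a line starting `#ID` (motif id), a line
#' starting `#W` (width), then W whitespace-separated rows of four
#' probabilities in A, C, G, T order.  Multiple blocks per file; other
#' `#` comment lines are ignored.  Each block passes through the [ppm()]
#' validation (row sums near 1, pseudocount flooring).
#'
#' @param path Path to the matrix file.
#' @return A list of `ppm` objects.
#' @export
read_ppm <- function(path) {
  lines <- trimws(readLines(path))
  id_at <- which(startsWith(lines, "#ID"))
  if (!length(id_at)) stop("no '#ID' motif block found in ", path, call. = FALSE)
  out <- vector("list", length(id_at))
  for (b in seq_along(id_at)) {
    i <- id_at[b]
    stop_at <- if (b < length(id_at)) id_at[b + 1L] - 1L else length(lines)
    block <- lines[i:stop_at]
    id <- .ppm_field(block[1L], "#ID")
    w_line <- block[startsWith(block, "#W")]
    if (!length(w_line)) stop("motif block '", id, "' has no '#W' width line", call. = FALSE)
    width <- suppressWarnings(as.integer(.ppm_field(w_line[1L], "#W")))
    if (is.na(width) || width < 1L) stop("bad width in motif block '", id, "'", call. = FALSE)
    rows <- block[nzchar(block) & !startsWith(block, "#")]
    if (length(rows) != width) {
      stop(sprintf("motif '%s': width %d declared but %d matrix rows found",
                   id, width, length(rows)), call. = FALSE)
    }
    vals <- lapply(strsplit(rows, "\\s+"), as.numeric)
    if (any(lengths(vals) != 4L) || anyNA(unlist(vals))) {
      stop("motif '", id, "': each matrix row needs 4 numbers", call. = FALSE)
    }
    out[[b]] <- ppm(do.call(rbind, vals), id)
  }
  ids <- vapply(out, `[[`, character(1), "motif_id")
  if (anyDuplicated(ids)) {
    stop("duplicate matrix ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

.ppm_field <- function(line, tag) {
  v <- trimws(sub(paste0("^", tag, "\\s*=?\\s*"), "", line))
  strsplit(v, "\\s+")[[1L]][1L]
}

#' Write position probability matrices
#'
#' Inverse of [read_ppm()]: INCLUSive-style `#ID` / `#W` blocks.
#'
#' @param ppms A `ppm` or list of `ppm` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(ppms, path) {
  if (inherits(ppms, "ppm")) ppms <- list(ppms)
  lines <- "#INCLUSive Motif Model"
  for (p in ppms) {
    lines <- c(lines, "",
               paste("#ID =", p$motif_id),
               paste("#W =", p$width),
               apply(format(p$probs, digits = 6), 1L, paste, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

# Per-position LLR values for a set of window starts S on encoded target
# `codes`: returns list(raw, minv, maxv), each length(S), summed over the
# L positions.  Contexts are the window's own preceding bases.
.llr_parts <- function(p, codes, S, bg) {
  L <- p$width
  k <- bg$order
  lp <- log(p$probs)
  ltr <- lapply(bg$transition, log)
  raw <- minv <- maxv <- numeric(length(S))
  for (i in seq_len(L)) {
    o <- min(i - 1L, k)
    ctx <- rep(1L, length(S))
    if (o > 0L) {
      ctx <- rep(0L, length(S))
      for (d in seq_len(o)) ctx <- ctx * 4L + (codes[S + (i - o) + d - 2L] - 1L)
      ctx <- ctx + 1L
    }
    lbg <- ltr[[o + 1L]]                       # 4^o x 4
    vals <- lp[rep(i, length(S)), , drop = FALSE] - lbg[ctx, , drop = FALSE]
    b <- codes[S + i - 1L]
    raw <- raw + vals[cbind(seq_along(S), b)]
    maxv <- maxv + pmax(vals[, 1L], vals[, 2L], vals[, 3L], vals[, 4L])
    minv <- minv + pmin(vals[, 1L], vals[, 2L], vals[, 3L], vals[, 4L])
  }
  list(raw = raw, minv = minv, maxv = maxv)
}

# Scan one strand of one encoded target; returns start/raw/norm for clean
# windows only.  `degenerate_flag` is an environment used to warn once.
.scan_one <- function(p, codes, bg, degenerate_flag) {
  L <- p$width
  n <- length(codes)
  if (L > n) return(NULL)
  bad <- cumsum(c(0L, is.na(codes)))
  S <- seq_len(n - L + 1L)
  S <- S[bad[S + L] - bad[S] == 0L]           # windows free of non-ACGT
  if (!length(S)) return(NULL)
  parts <- .llr_parts(p, codes, S, bg)
  denom <- parts$maxv - parts$minv
  degen <- denom < 1e-12
  norm <- ifelse(degen, 1, (parts$raw - parts$minv) / ifelse(degen, 1, denom))
  if (any(degen)) degenerate_flag$seen <- TRUE
  data.frame(start = S, raw_llr = parts$raw, norm_score = norm)
}

#' Score a single window against a background model
#'
#' The raw log-likelihood ratio (natural log) of one window of width
#' `ppm$width`; mostly useful for spot checks — [scan_ppm()] scores whole
#' targets.
#'
#' @param p A `ppm`.
#' @param window DNA word of length `p$width` over `{A,C,G,T}`.
#' @param bg A `background_model`.
#' @return The raw LLR (numeric scalar).
#' @examples
#' score_window(ppm(matrix(0.25, 3, 4)), "ACG", uniform_background())  # ~0
#' @export
score_window <- function(p, window, bg) {
  stopifnot(inherits(p, "ppm"), inherits(bg, "background_model"))
  codes <- .encode_dna(window)
  if (length(codes) != p$width) {
    stop(sprintf("window length %d != matrix width %d", length(codes), p$width),
         call. = FALSE)
  }
  if (anyNA(codes)) stop("window contains a non-ACGT base", call. = FALSE)
  .llr_parts(p, codes, 1L, bg)$raw
}

#' Scan targets with position probability matrices
#'
#' Slides each matrix over every target; windows containing non-ACGT
#' characters are skipped.  A window is reported when its normalized score
#' reaches `threshold`.  With `both_strands = TRUE` the reverse complement
#' of each target is scanned too and coordinates mapped back to the
#' forward strand.
#'
#' When a matrix/background pair is degenerate (window maximum equals the
#' window minimum, e.g. a uniform matrix over a uniform background) every
#' window's normalized score is defined as 1 and a warning is emitted, so
#' threshold semantics stay monotone.
#'
#' @param ppms A `ppm` or list of `ppm` objects (see [read_ppm()]).
#' @param targets Targets as for [search_motifs()].
#' @param bg A `background_model`.
#' @param threshold Normalized-score cutoff in `[0, 1]` (default 0.85).
#' @param both_strands Scan both strands (default `FALSE`).
#' @return A data frame with columns `motif_id`, `target_id`, `start`,
#'   `end` (1-based, fully closed, forward-strand), `strand`, `raw_llr`
#'   and `norm_score`, ordered by (target input order, start, matrix input
#'   order, strand).
#' @export
scan_ppm <- function(ppms, targets, bg, threshold = 0.85, both_strands = FALSE) {
  if (inherits(ppms, "ppm")) ppms <- list(ppms)
  stopifnot(length(ppms) >= 1L, inherits(bg, "background_model"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]", call. = FALSE)
  targets <- .as_target_frame(targets)
  widths <- vapply(ppms, `[[`, integer(1), "width")
  if (all(widths > max(nchar(targets$sequence)))) {
    warning("every matrix is wider than every target; no window to score",
            call. = FALSE)
  }
  flag <- new.env()
  flag$seen <- FALSE
  chunks <- list()
  for (i in seq_len(nrow(targets))) {
    seq_fwd <- targets$sequence[i]
    codes_fwd <- .encode_dna(seq_fwd)
    n <- length(codes_fwd)
    codes_rev <- if (both_strands) rev(5L - codes_fwd) else NULL
    acc <- list()
    for (j in seq_along(ppms)) {
      p <- ppms[[j]]
      d <- .scan_one(p, codes_fwd, bg, flag)
      if (!is.null(d) && nrow(d)) {
        d$strand <- "+"; d$motif_id <- p$motif_id; d$ord <- j; d$width <- p$width
        acc[[length(acc) + 1L]] <- d
      }
      if (both_strands) {
        d <- .scan_one(p, codes_rev, bg, flag)
        if (!is.null(d) && nrow(d)) {
          # start on the reverse strand -> forward-strand coordinates
          d$start <- n - (d$start + p$width - 1L) + 1L
          d$strand <- "-"; d$motif_id <- p$motif_id; d$ord <- j; d$width <- p$width
          acc[[length(acc) + 1L]] <- d
        }
      }
    }
    if (!length(acc)) next
    d <- do.call(rbind, acc)
    d <- d[d$norm_score >= threshold, , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(d$start, d$ord, d$strand, method = "radix"), , drop = FALSE]
    chunks[[length(chunks) + 1L]] <- data.frame(
      motif_id = d$motif_id, target_id = targets$seq_id[i],
      start = d$start, end = d$start + d$width - 1L,
      strand = d$strand, raw_llr = d$raw_llr, norm_score = d$norm_score,
      stringsAsFactors = FALSE)
  }
  if (flag$seen) {
    warning("degenerate normalization (max LLR equals min LLR): affected windows scored 1",
            call. = FALSE)
  }
  if (!length(chunks)) {
    return(data.frame(motif_id = character(), target_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      raw_llr = numeric(), norm_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}
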