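# Test-side reference implementations, deliberately independent of the
# package internals: plain loops and substring comparisons only.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random IUPAC motif with bounded degeneracy; singleton codes are favoured
# so typical motifs look like real binding sites with a few wobble positions
rand_motif <- function(len, max_deg = 256) {
  codes <- names(iupac_bases())
  weights <- c(rep(8, 4), rep(2, 6), rep(0.7, 4), 0.7)
  repeat {
    m <- paste(sample(codes, len, replace = TRUE, prob = weights), collapse = "")
    if (motif_degeneracy(m) <= max_deg) return(m)
  }
}

# brute-force exact word search by direct substring comparison
brute_find <- function(seq, word) {
  n <- nchar(seq)
  m <- nchar(word)
  if (m > n) return(integer())
  hits <- integer()
  for (p in seq_len(n - m + 1L)) {
    if (substr(seq, p, p + m - 1L) == word) hits <- c(hits, p)
  }
  hits
}

# brute-force suffix set of a sequence
brute_suffixes <- function(seq) {
  n <- nchar(seq)
  data.frame(position = seq_len(n),
             suffix = vapply(seq_len(n), function(p) substr(seq, p, n), ""),
             stringsAsFactors = FALSE)
}

# plain-R reverse complement of a concrete ACGT word
rc_word <- function(w) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(w, "")[[1]]]), collapse = "")
}

# window-by-window PWM scoring oracle: per-position log ratios with the
# window's own preceding bases as context, lower-order fallback below k
oracle_window_llr <- function(p, chars, s, bg) {
  L <- p$width
  k <- bg$order
  raw <- mn <- mx <- 0
  for (i in seq_len(L)) {
    o <- min(i - 1L, k)
    tr <- bg$transition[[o + 1L]]
    bg_row <- if (o == 0L) tr[1L, ] else
      tr[paste(chars[(s + i - 1L - o):(s + i - 2L)], collapse = ""), ]
    vals <- log(p$probs[i, ]) - log(bg_row)
    raw <- raw + vals[[chars[s + i - 1L]]]
    mx <- mx + max(vals)
    mn <- mn + min(vals)
  }
  c(raw = raw, mn = mn, mx = mx)
}

# full-target PWM scan oracle (forward strand): data.frame of every clean
# window with raw and normalized scores
oracle_scan <- function(p, seq, bg) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  L <- p$width
  rows <- list()
  if (L <= n) {
    for (s in seq_len(n - L + 1L)) {
      if (any(!chars[s:(s + L - 1L)] %in% c("A", "C", "G", "T"))) next
      v <- oracle_window_llr(p, chars, s, bg)
      denom <- v[["mx"]] - v[["mn"]]
      norm <- if (denom < 1e-12) 1 else (v[["raw"]] - v[["mn"]]) / denom
      rows[[length(rows) + 1L]] <- data.frame(start = s, raw_llr = v[["raw"]],
                                              norm_score = norm)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), raw_llr = numeric(),
                      norm_score = numeric()))
  }
  do.call(rbind, rows)
}

# random near-stochastic PPM rows via normalized uniforms
rand_ppm <- function(L, id = "p") {
  m <- matrix(stats::runif(L * 4, 0.05, 1), nrow = L)
  ppm(m / rowSums(m), id)
}

# reorder a hit data frame the way the engine orders per-target chunks
sort_hits <- function(h, target_levels, motif_levels) {
  h <- h[order(match(h$target_id, target_levels), h$start,
               match(h$motif_id, motif_levels), h$strand,
               method = "radix"), , drop = FALSE]
  rownames(h) <- NULL
  h
}
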