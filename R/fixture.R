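# Seeded synthetic fixtures: i.i.d. uniform-ACGT target sequences with
# concrete instances of degenerate motifs planted at known positions, plus
# the truth table of planted hits.  The background can of course create
# additional chance hits, so the truth table is a subset of — not equal
# to — what a correct engine reports.

#' Specify a planted-motif fixture
#'
#' @param n_targets Number of target sequences.
#' @param target_length Length of every target, in bases.
#' @param planted A list of plant requests; each element is a list with
#'   `motif` (IUPAC pattern or [validate_motif()] object) and optionally
#'   `positions` (integer vector of 1-based start positions used in every
#'   target, or a list of such vectors, one per target) or `n_sites`
#'   (number of random non-overlapping sites per target, default 1, used
#'   when `positions` is absent).  Element names become motif ids.
#' @param seed Integer seed; identical specs give byte-identical fixtures.
#' @return An object of class `fixture_spec`.
#' @examples
#' fixture_spec(1, 100, list(m1 = list(motif = "WGATAR", positions = 11)), seed = 7)
#' @export
fixture_spec <- function(n_targets, target_length, planted, seed) {
  stopifnot(n_targets >= 1L, target_length >= 1L, is.list(planted),
            length(planted) >= 1L, is.numeric(seed))
  ids <- names(planted)
  if (is.null(ids)) ids <- rep("", length(planted))
  ids[!nzchar(ids)] <- paste0("motif", which(!nzchar(ids)))
  planted <- lapply(seq_along(planted), function(j) {
    p <- planted[[j]]
    if (!is.list(p)) p <- list(motif = p)
    p$motif <- .as_motif(p$motif, ids[j])
    p$motif$motif_id <- ids[j]
    m <- nchar(p$motif$pattern)
    if (m > target_length) {
      stop("planted motif '", ids[j], "' is longer than the targets", call. = FALSE)
    }
    if (!is.null(p$positions)) {
      pos <- p$positions
      if (!is.list(pos)) pos <- rep(list(as.integer(pos)), n_targets)
      if (length(pos) != n_targets) {
        stop("positions for '", ids[j], "' must cover all ", n_targets,
             " targets", call. = FALSE)
      }
      bad <- vapply(pos, function(v) any(v < 1L | v + m - 1L > target_length),
                    logical(1))
      if (any(bad)) {
        stop("planted positions for '", ids[j], "' fall outside the targets",
             call. = FALSE)
      }
      p$positions <- lapply(pos, as.integer)
    } else if (is.null(p$n_sites)) {
      p$n_sites <- 1L
    }
    p
  })
  structure(list(n_targets = as.integer(n_targets),
                 target_length = as.integer(target_length),
                 planted = planted, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a planted-motif fixture
#'
#' Draws uniform-ACGT targets, overwrites each planted site with a random
#' concrete expansion of its motif (a uniformly chosen base from each
#' position's base set), and records every plant in a truth table with the
#' same columns and ordering as [search_motifs()] output.  Plants that
#' overlap are allowed only if the final sequence still matches every
#' planted motif at its site; contradictory overlaps raise an error.
#'
#' The caller's random-number state is left untouched.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `targets` (data frame as from [read_fasta()]),
#'   `motifs` (list of `degenerate_motif`) and `truth` (hit data frame,
#'   all `+` strand).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$target_length
  seqs <- character(spec$n_targets)
  truth_rows <- list()
  for (i in seq_len(spec$n_targets)) {
    chars <- sample(.base_order, n, replace = TRUE)
    taken <- integer()  # occupied base positions, used for random placement
    sites <- list()
    for (j in seq_along(spec$planted)) {
      p <- spec$planted[[j]]
      m <- nchar(p$motif$pattern)
      if (!is.null(p$positions)) {
        pos <- p$positions[[i]]
      } else {
        pos <- integer()
        free <- setdiff(seq_len(n - m + 1L), taken)
        for (r in seq_len(p$n_sites)) {
          ok <- free[vapply(free, function(s)
            !any((s:(s + m - 1L)) %in% taken), logical(1))]
          if (!length(ok)) {
            stop("cannot place ", p$n_sites, " non-overlapping sites of '",
                 p$motif$motif_id, "' in a ", n, " bp target", call. = FALSE)
          }
          s <- ok[sample.int(length(ok), 1L)]
          pos <- c(pos, s)
          taken <- c(taken, s:(s + m - 1L))
        }
        pos <- sort(pos)
      }
      codes <- strsplit(p$motif$pattern, "", fixed = TRUE)[[1L]]
      for (s in pos) {
        word <- vapply(.iupac_table[codes], function(b)
          b[sample.int(length(b), 1L)], character(1))
        chars[s:(s + m - 1L)] <- word
        taken <- union(taken, s:(s + m - 1L))
      }
      sites[[j]] <- pos
    }
    # contradictory overlaps: a later plant may have clobbered an earlier
    # one; every site must still match its motif positionwise
    for (j in seq_along(spec$planted)) {
      p <- spec$planted[[j]]
      codes <- strsplit(p$motif$pattern, "", fixed = TRUE)[[1L]]
      m <- length(codes)
      for (s in sites[[j]]) {
        w <- chars[s:(s + m - 1L)]
        if (!all(mapply(function(b, sets) b %in% sets, w, .iupac_table[codes]))) {
          stop(sprintf("overlapping planted sites conflict: '%s' at %d in target %d",
                       p$motif$motif_id, s, i), call. = FALSE)
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          motif_id = p$motif$motif_id, target_id = sprintf("target%03d", i),
          start = s, end = s + m - 1L, strand = "+",
          matched_word = paste(w, collapse = ""),
          motif_ord = j, target_ord = i, stringsAsFactors = FALSE)
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else .empty_hits()
  if (nrow(truth)) {
    truth <- truth[order(truth$target_ord, truth$start, truth$motif_ord), ,
                   drop = FALSE]
    truth$motif_ord <- truth$target_ord <- NULL
    rownames(truth) <- NULL
  }
  list(
    targets = data.frame(seq_id = sprintf("target%03d", seq_len(spec$n_targets)),
                         description = "", sequence = seqs,
                         stringsAsFactors = FALSE),
    motifs = lapply(spec$planted, `[[`, "motif"),
    truth = truth)
}

#' Write a fixture to disk
#'
#' Writes `targets.fa`, `motifs.fa` and `truth.tsv` under `outdir`.
#'
#' @param fixture Result of [generate_fixture()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(fixture, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$targets, file.path(outdir, "targets.fa"))
  motif_recs <- data.frame(
    seq_id = vapply(fixture$motifs, `[[`, character(1), "motif_id"),
    description = "",
    sequence = vapply(fixture$motifs, `[[`, character(1), "pattern"),
    stringsAsFactors = FALSE)
  write_fasta(motif_recs, file.path(outdir, "motifs.fa"))
  write_hits_tsv(fixture$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
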