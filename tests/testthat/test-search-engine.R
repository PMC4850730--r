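# Engine orchestration: expansion + per-target index + lookup

test_that("worked example: RY on ACGT", {
  hits <- search_motifs(c(m1 = "RY"), c(t1 = "ACGT"))
  expect_equal(hits, data.frame(
    motif_id = "m1", target_id = "t1", start = c(1L, 3L), end = c(2L, 4L),
    strand = "+", matched_word = c("AC", "GT"), stringsAsFactors = FALSE))
})

test_that("N matches every base; absent words give zero hits", {
  expect_equal(nrow(search_motifs(c(m = "N"), c(t = "ACGTA"))), 5L)
  expect_equal(nrow(search_motifs(c(m = "AC"), c(t = "GGGGG"))), 0L)
})

test_that("empty motif or target collections are errors", {
  expect_error(search_motifs(character(), c(t = "ACGT")), "no motifs")
  expect_error(search_motifs(c(m = "AC"),
                             data.frame(seq_id = character(),
                                        sequence = character())), "no target")
  expect_error(search_motifs(c(a = "AC", a = "GT"), c(t = "ACGT")),
               "duplicate motif ids")
})

test_that("a motif over the expansion cap is skipped, the rest still searched", {
  expect_warning(
    hits <- search_motifs(c(big = strrep("N", 9), small = "ACG"),
                          c(t1 = "TACGA")),
    "cap")
  expect_equal(hits$motif_id, "small")
  expect_equal(hits$start, 2L)
})

test_that("hits from the engine equal the union of naive-oracle hits", {
  set.seed(61)
  for (rep in 1:40) {
    n_mot <- sample(1:4, 1)
    n_tgt <- sample(1:3, 1)
    motifs <- stats::setNames(
      vapply(seq_len(n_mot), function(i) rand_motif(sample(1:15, 1)), ""),
      paste0("m", seq_len(n_mot)))
    targets <- stats::setNames(
      vapply(seq_len(n_tgt), function(i) rand_dna(sample(1:2000, 1)), ""),
      paste0("t", seq_len(n_tgt)))
    both <- rep %% 2 == 0
    got <- search_motifs(motifs, targets, both_strands = both)
    want <- list()
    for (t in names(targets)) for (m in names(motifs)) {
      want[[paste(t, m)]] <- naive_search(validate_motif(motifs[[m]], m), t,
                                          targets[[t]], both_strands = both)
    }
    want <- do.call(rbind, c(want, list(make.row.names = FALSE)))
    if (is.null(want)) want <- got[0, ]
    want <- sort_hits(want, names(targets), names(motifs))
    expect_equal(got, want)
  }
})

test_that("minus-strand hits are the plus-strand hits of the reverse complement", {
  set.seed(67)
  for (rep in 1:10) {
    m <- rand_motif(sample(2:10, 1))
    t <- rand_dna(500)
    hits <- search_motifs(c(m1 = m), c(t1 = t), both_strands = TRUE)
    minus <- hits[hits$strand == "-", c("start", "end", "matched_word")]
    rc_plus <- search_motifs(c(m1 = reverse_complement(m)$pattern),
                             c(t1 = t))[, c("start", "end", "matched_word")]
    rownames(minus) <- rownames(rc_plus) <- NULL
    expect_equal(minus, rc_plus)
  }
})

test_that("identical inputs give identical hit tables (determinism)", {
  set.seed(71)
  motifs <- c(a = rand_motif(6), b = rand_motif(8))
  targets <- c(t1 = rand_dna(800), t2 = rand_dna(300))
  h1 <- search_motifs(motifs, targets, both_strands = TRUE)
  h2 <- search_motifs(motifs, targets, both_strands = TRUE)
  expect_identical(h1, h2)
})

test_that("hit invariants hold: coordinates, word membership, substring", {
  set.seed(73)
  motifs <- c(m1 = rand_motif(7), m2 = rand_motif(5))
  targets <- c(t1 = rand_dna(1500))
  hits <- search_motifs(motifs, targets, both_strands = TRUE)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$start >= 1 & hits$start <= hits$end))
  expect_true(all(hits$end <= nchar(targets[hits$target_id])))
  expect_true(all(substr(targets[hits$target_id], hits$start, hits$end) ==
                    hits$matched_word))
  for (i in seq_len(nrow(hits))) {
    pat <- if (hits$strand[i] == "+") motifs[[hits$motif_id[i]]] else
      reverse_complement(motifs[[hits$motif_id[i]]])$pattern
    expect_true(hits$matched_word[i] %in% expand_motif(pat))
  }
})

test_that("the naive oracle handles motifs far beyond any expansion cap", {
  set.seed(79)
  t <- rand_dna(1000)
  m <- strrep("N", 12)  # degeneracy 4^12: expansion would be infeasible
  hits <- naive_search(m, "t1", t)
  expect_equal(nrow(hits), 1000 - 12 + 1)
})

test_that("summaries are consistent with the hit stream", {
  s <- summarize_hits(search_motifs(c(m1 = "RY"), c(t1 = "ACGT")))
  expect_equal(s$total, 2L)
  expect_equal(s$per_motif$n_hits, 2L)

  empty <- summarize_hits(search_motifs(c(m = "AC"), c(t = "GGG")),
                          motif_ids = "m", target_ids = "t")
  expect_equal(empty$total, 0L)
  expect_equal(empty$per_motif$n_hits, 0L)
  expect_equal(empty$per_target$n_hits, 0L)

  set.seed(83)
  hits <- search_motifs(c(a = "N", b = "WS"), c(x = rand_dna(50), y = rand_dna(80)))
  s <- summarize_hits(hits)
  expect_equal(sum(s$per_motif$n_hits), s$total)
  expect_equal(sum(s$per_target$n_hits), s$total)
})
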