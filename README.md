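# exactmotif

Exact search of degenerate DNA motifs in arbitrary target sequences, plus
position probability matrix (PPM) scanning against Markov background
models.

Molecular biologists routinely need to know whether a known
transcription-factor or RNA-binding-protein recognition element occurs in
the proximal promoters or 3′ UTRs of a set of genes. Binding elements are
usually written in IUPAC notation — e.g. the GATA element `WGATAR`, where
`W = A/T` and `R = A/G` — so a single motif stands for a family of concrete
words, and naive tooling either cannot take such patterns or forces the
user to expand them by hand. `exactmotif` does the whole job: it validates
and expands IUPAC motifs, indexes every target sequence in a suffix tree,
reports every (possibly overlapping) occurrence with 1-based fully-closed
coordinates, and writes TSV or GFF3.

## Method

**Exact degenerate search.** A degenerate motif over the 15-letter IUPAC
alphabet with base sets `B_1, ..., B_m` denotes the word set
`B_1 × ... × B_m` (its *expansion*; the *degeneracy* `∏|B_i|` is its
size). For each target sequence of length `n`, all `n` suffixes are
inserted successively into a character trie with string tails: a node
holds single-character child edges plus at most one uncompared suffix
remainder, which is split into nodes as soon as a second suffix shares its
prefix. Looking up a word of length `m` then walks at most `m` child edges
plus one tail comparison — O(m) per query word, independent of `n` — and
returns the start positions of every occurrence, overlaps included. Each
expanded word of each motif is searched individually; an independent
sliding-window oracle (`naive_search()`, positionwise IUPAC set
membership) provides a second route used throughout the test suite.

**PPM scanning.** A width-`L` position probability matrix is slid along
each target and every clean window scored with the natural-log likelihood
ratio

    raw_llr = Σ_{i=1..L} ln( ppm[i, b_i] / P_bg(b_i | context_i) )

against a k-order Markov background model estimated from a user-supplied
corpus with additive smoothing. Scores are normalized to [0, 1] by the
window-achievable extrema (best/worst base per position, the window's own
contexts held fixed), and windows at or above a normalized-score threshold
(default 0.85) are reported.

## Worked example

Using the bundled synthetic promoter fixtures (three 120 bp sequences with
planted GATA, E-box and W-box elements):

```r
library(exactmotif)
motifs  <- read_motifs(system.file("extdata", "example_motifs.fa", package = "exactmotif"))
targets <- read_fasta(system.file("extdata", "synthetic_promoters.fa", package = "exactmotif"))
hits <- search_motifs(motifs, targets, both_strands = TRUE)
head(hits, 5)
#>   motif_id            target_id start end strand matched_word
#> 1     Wbox synthetic_promoter_1    15  20      +       TTGACT
#> 2     GATA synthetic_promoter_1    26  31      +       AGATAA
#> 3     Ebox synthetic_promoter_1    44  49      +       CATATG
#> 4     Ebox synthetic_promoter_1    44  49      -       CATATG
#> 5     GATA synthetic_promoter_1    55  60      +       AGATAG
summarize_hits(hits)$per_motif
#>   motif_id n_hits
#> 1     Wbox      5
#> 2     GATA      8
#> 3     Ebox     10
```

Each row is one exact occurrence: `WGATAR` matched the concrete word
`AGATAA` at bases 26–31 of the first promoter; the palindromic-set E-box
match at 44 appears once per strand. The same fixtures scanned with a GATA
probability matrix against an order-1 background built from the targets
themselves:

```r
bg   <- build_background(targets, order = 1, pseudocount = 1)
ppms <- read_ppm(system.file("extdata", "example_matrices.mtrx", package = "exactmotif"))
head(scan_ppm(ppms, targets, bg, threshold = 0.85), 3)
#>   motif_id            target_id start end strand  raw_llr norm_score
#> 1 GATA_ppm synthetic_promoter_1    26  31      + 5.011595  0.9509332
#> 2 GATA_ppm synthetic_promoter_1    55  60      + 4.814885  0.9384603
#> 3 GATA_ppm synthetic_promoter_1    66  71      + 5.726005  0.9875693
```

`raw_llr` is the log-likelihood ratio of the window under the matrix vs
the background; `norm_score` rescales it into [0, 1] per window.

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "exactmotif", package = "exactmotif"))')
Rscript "$CLI" search --motifs motifs.fa --targets promoters.fa \
        --out hits.tsv --gff3 hits.gff3 --both-strands
```

Subcommands: `search`, `pwm-scan`, `build-background`, `make-fixture`.

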