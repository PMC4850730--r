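---
title: "Degenerate motif search and PPM scanning: models and design choices"
author: "exactmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate motif search and PPM scanning: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exactmotif)
```

## The problem

A biologist with a known binding element — say the GATA factor element
`WGATAR`, or the ABA-response element written with IUPAC wobble codes —
wants every exact occurrence of it in a set of sequences: typically the
1–2 kb proximal promoter regions upstream of a gene set, or 3′ UTRs bound
by translation regulators. Two things make this more than a `grep`:
degenerate positions multiply one pattern into a family of concrete words,
and realistic workloads pair hundreds of motifs with tens of thousands of
targets, where repeated naive scans become the bottleneck.

`exactmotif` addresses exactly this job (and only it): *exact*, ungapped
occurrence search of IUPAC motifs, plus the companion quantitative mode in
which a motif is a position probability matrix (PPM) scored against a
Markov background. Mismatch-tolerant matching, gapped alignment, motif
*discovery* and enrichment statistics are deliberately out of scope.

## Exact search model

### IUPAC algebra

Each of the 15 IUPAC codes denotes a non-empty subset of `{A, C, G, T}`
(`W` = A/T, `S` = C/G, `M` = A/C, `K` = G/T, `R` = A/G, `Y` = C/T,
`B` = C/G/T, `D` = A/G/T, `H` = A/C/T, `V` = A/C/G, `N` = any). A motif
of length `m` with base sets `B_1..B_m` matches a word `w` iff
`w_i ∈ B_i` at every position; equivalently `w` lies in the Cartesian
product of the base sets, the motif's *expansion*. The implementation
expands in lexicographic order over `A < C < G < T` so output is
deterministic and diff-able.

Because expansion is exponential in the number of degenerate positions, a
cap (default 65,536 words, i.e. an all-`N` 8-mer) protects memory; a motif
over the cap is skipped with a warning while the rest of the run proceeds.
The sliding-window oracle `naive_search()` needs no expansion and handles
arbitrarily degenerate motifs in linear time, so such motifs are not
unsearchable — only the expansion route refuses them.

Input hygiene choices: lowercase input is upper-cased; `U` is rejected
rather than silently mapped to `T` (the engine is DNA-only, and a stray
RNA motif is more likely a user error worth surfacing); gap characters
`-`/`.` are rejected because the matching model is exact and ungapped.
Duplicate motif ids in one file are rejected — ambiguous attribution in
the hit table is worse than a hard error.

### The suffix index

For each target sequence of length `n`, all `n` suffixes (including the
full sequence — see below) are inserted successively into a character trie
with string tails: each node carries single-character child edges, at most
one stored suffix remainder ("tail") with its start offset, and the start
offsets of suffixes ending exactly at that node. Insertion walks shared
prefix characters; the moment a second suffix shares the first character
of a stored tail, that character is popped into a child node and the walk
continues — the node-splitting construction. This is the naive successive
insertion algorithm, O(n²) worst case (realized on e.g. `AAAA...`), not a
linear-time construction: construction cost is dominated by lookup volume
in the intended workloads, and random 2 kb DNA gives near-linear behavior
in practice. The tree is built in C++ (Rcpp) and held behind an external
pointer; one index per target, built and dropped independently, so memory
scales with one sequence, not the corpus.

A lookup of a word of length `m` inspects at most `m` child edges plus one
tail comparison; `lookup_profile()` exposes these counters so the cost
contract is itself testable. When a word is fully matched along a path,
every suffix below the match point starts with the word, and their start
offsets are exactly the occurrence positions — overlapping occurrences
included (`AA` in `AAAA` → 1, 2, 3).

**n vs n−1.** Generating suffixes by repeatedly chopping one base off the
5′ end yields `n−1` proper suffixes and misses the full sequence itself —
which would silently lose any match flush with position 1. We index all
`n` suffixes; a plant-at-position-1 fixture regression-tests this.

**Non-ACGT characters** (assembly `N`s and anything else) are stored in
the tree literally and counted per sequence; query words are concrete
ACGT strings, so such characters simply never match. This is preferable to
rejecting real-world FASTA outright.

### Engine semantics

`search_motifs()` expands each motif once, then for each target builds the
index and looks up every expanded word individually. Hits are keyed by
motif: two motifs whose expansions share a word each report their own hit.
Ordering is (target input order, start, motif input order, `+` before
`-`), radix-sorted so the stream is byte-identical across locales and
runs.

Strand handling: the default searches the given strand only. With
`both_strands = TRUE`, the expansions of each motif's reverse complement
are searched and reported as `-`-strand hits *at forward-strand
coordinates* — the matched word is always the forward-strand substring, so
`substr(target, start, end) == matched_word` holds for every row. The
complement is lifted to codes (complement of a code is the code whose base
set is the Watson–Crick complement), making reverse complement an
involution that commutes with expansion — both properties are tested.

## PPM scanning model

### Background models

`build_background()` estimates a k-order Markov model (k ≤ 5) from a
corpus: `P(b | c) = (count(cb) + α) / (count(c·) + 4α)` with additive
smoothing α (default 1). Windows touching non-ACGT characters are skipped
in counting. The model stores the conditional tables of *every* order
0..k, so scoring positions with fewer than k preceding bases falls back to
the matching lower-order marginal. At α = 0 the estimate is the bare
frequency; contexts never observed then fall back to a uniform conditional
with a warning, and only a corpus with no clean (k+1)-window at all is an
error — this keeps small-corpus results well-defined (e.g. order 1 on
`AAAA` gives `P(A|A) = 1`) while still refusing genuinely unsupportable
orders. Models round-trip through a plain-text key–value format.

### Scoring and normalization

A clean window `b_1..b_L` scores

`raw_llr = Σ_i ln( ppm[i, b_i] / P_bg(b_i | context_i) )`

where `context_i` is the window's own preceding min(i−1, k) bases. Using
only the window's own bases as context (never target context outside the
window) keeps windows independent of their surroundings and makes the
window-by-window oracle exact.

The normalized score is `(raw − min) / (max − min)` with the extrema
computed *per window*: at each position, the best and worst base under the
window's actual context. The actual base is always among the four
candidates, so the normalized score is guaranteed to lie in [0, 1] for any
background order; at k = 0 this reduces to the usual global per-position
extrema. The score formula and [0, 1] normalization are this package's
own (conventional) design — the normalized log-likelihood scheme standard
in matrix-scanning tools — and the default threshold 0.85 is the
convention for that tool family, always user-overridable.

Degenerate case: if a window's max equals its min (uniform matrix over
uniform background), the normalized score is defined as 1 for all windows
and a warning is emitted, keeping threshold semantics monotone (threshold
0 keeps everything; raising it never adds windows).

Minus-strand scanning scores the reverse-complemented target and maps
coordinates back to the forward strand; with an order-0 background this
equals scanning with the column-reversed, base-complemented matrix
(tested), while for k > 0 the two differ because contexts reverse.

PPM input uses INCLUSive-style blocks (`#ID`, `#W`, then W rows of four
probabilities). Rows must sum to 1 within 2% — count matrices are rejected
rather than silently converted, since silent conversion hides unit errors —
then rows are renormalized and floored with a 1e−4 pseudocount so every
log is finite. Natural log throughout; file writers round scores to 4
decimals.

## The fixture generator

`generate_fixture()` draws i.i.d. uniform-ACGT targets and overwrites
planted sites with a uniformly drawn concrete expansion of each motif,
recording every plant in a truth table; a fixed seed gives byte-identical
fixtures, and the caller's RNG state is restored afterwards. Plants may
overlap only if the final sequence still matches every planted motif
positionwise; contradictory overlaps are an error rather than a silent
mis-truth. Uniform background means chance occurrences of the motifs also
appear, so the truth table is a *subset* of correct engine output — tests
assert containment, and full equality is asserted against the independent
oracle instead. What the generator does **not** emulate: the base
composition, repeat structure and CpG/motif clustering of real promoters.
Passing fixture tests therefore demonstrates search correctness, not
biological signal recovery — for an exact-matching engine that is the
property that matters.

## Problem sizes and verification

The shipped tests verify, among other properties: engine ≡ oracle on 200
random instances (targets up to 2 kb, motifs up to 15 codes, degeneracy ≤
256, mixed strand modes); expansion cardinality on 1,000 random motifs;
suffix-set equality against brute force on sequences up to 2 kb;
truth-recovery and engine ≡ oracle on 50 seeded fixtures (3 × 500 bp, 4
planted sites each); PPM scan ≡ re-scoring oracle on 100 random instances
with background orders 0–2; and one full 100-motif × 1,000-target × 2 kb
run (≈ 10 s on one CPU), the scale at which the suffix-tree route pays
off. `scripts/acceptance.R` recomputes the same quantities from scratch
under a caller-supplied seed.

## Known limitations

- Exact matching only: no mismatches, no gaps, no IUPAC codes in the
  *target* treated as wildcards (a target `N` matches nothing).
- The expansion route is exponential in degenerate positions; beyond the
  cap, only the linear-time oracle path is available.
- Naive construction makes a pathological low-complexity 100 kb+ target
  slow to index; the design target is many kb-scale flanks, not whole
  chromosomes.
- PPM scores are not calibrated to p-values; the normalized score is a
  ranking device, and thresholds are conventions, not significance levels.
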