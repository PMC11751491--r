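---
title: "Sparsified minimizer mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsified minimizer mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The idea

Seeding-based sequence search spends most of its time computing and
matching seeds: every base of a genome typically participates in many
overlapping k-mers, and every read re-derives seeds over its full length.
`sparsemap` instead *sparsifies* both sides of the comparison before any
seed exists. A repeating binary **diet pattern** `P` of length `p` and
weight `x` (number of 1s) is laid end-to-end along a sequence; bases under
a 1 are kept, bases under a 0 are dropped. The kept bases form the
*patterned sequence*, shorter by the reduction ratio `beta = p / x`
(pattern `"10"` halves the sequence; `"11"` is a no-op). Crucially, every
retained seed still *points back* at original coordinates, so downstream
base-level alignment sees the full, unmodified sequences.

Seeds are double-strand (w,k)-minimizers of the patterned sequence: each
k-mer of the patterned bases is packed 2 bits per base, hashed on its
canonical strand with the masked Thomas Wang 64-bit mix (a bijection on
`[0, 4^k)`), and within each window of `w` consecutive k-mers the k-mer(s)
of minimal hash are kept. Because a patterned k-mer spans roughly
`k * beta` original bases, each seed summarizes a wider genomic region than
a contiguous k-mer of the same cost — the property that makes this scheme
different from spaced seeding, which leaves the sequence intact, applies a
fixed mask to every seed, and extracts the same number of seeds regardless
of the mask. Under a diet pattern, consecutive seeds are effectively
masked by *different* rotations of the pattern, which preserves the
inverse relationship between seed matching rate and edit distance (the
`seed_benchmark` functions measure exactly this).

## The five-stage pipeline

1. **Compressed indexing** (`build_index`). The pattern is applied at
   shift 0 to each reference; minimizers are accumulated as (hash,
   location) records in a flat array, sorted once, and grouped into a
   lookup table — the array-then-sort construction of minimizer mappers,
   which is much cheaper than incremental hash-table insertion. Stored
   locations are original (unpatterned) coordinates, so no translation is
   ever needed. References longer than `batch_bases` are chunked with a
   `(k + w) * p` overlap; chunk masking keeps the global pattern phase, so
   batching never changes the result (this is tested).

2. **Pattern alignment** (`pattern_align`). A read sampled at an unknown
   offset `o` of the genome only shares patterned seeds with the index if
   it is masked with the matching phase, `a = o mod p`. For each of the
   `p` shifts the read prefix is masked, at most `t` minimizers are
   extracted, and their occurrence counts in the index are summed
   (hyper-frequent seeds contribute 0 so repeats cannot dominate). The
   shift with the highest sum wins; ties break to the smallest shift.

3. **Compressed seeding** (`compressed_seed`). The pattern, shifted by the
   alignment index, is applied to the read; minimizers of the patterned
   read query the index.

4. **Location voting** (`vote_short`, `vote_long`). Every hit is reduced
   to `delta = ref_pos - read_pos`; hits from the same true location agree
   on delta up to indel drift. After merging the per-seed (already
   sorted) location lists into one list ordered by (strand, reference,
   delta), a single greedy left-to-right pass clusters deltas within a
   distance `D`; clusters with at least `V` votes are candidate mapping
   locations. This replaces seed chaining entirely: patterned seeds are
   not exact anchors, so chain scoring is not meaningful, but vote counts
   are. For long reads each cluster also induces a *subsequence pair* —
   the reference interval spanned by its hits and the matching read
   interval — which is what gets aligned. When no cluster reaches `V`,
   the single best cluster is still reported (`rescue_location`) unless
   rescue is disabled.

5. **Alignment and output**. Short reads are aligned globally against the
   implied reference segment (after an exact-match fast path that skips
   DP entirely for identical segments — a large fraction of real short
   reads); long-read subsequence pairs are aligned locally, and pairs on
   the same reference/strand closer than 50 kb are concatenated into one
   CIGAR, bridging the gap either by a small global alignment or by pure
   I/D operations (how large indels and SVs enter a single record).
   The highest-scoring result of a read is the primary record; another
   result shorter than 80% of the primary's read interval is
   supplementary, otherwise secondary. Output is SAM 1.6 (or PAF).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pattern` | `"10"` | diet pattern; `10` is the best accuracy/speed trade-off for mapping, heavier sparsification (`100`) suits containment screening |
| `k` | 19 (21 sr / 19 hifi / 15 ont are the usual presets) | seed length, capped at 28 by 2-bit packing; hash values crossing into R are exact for k <= 26 |
| `w` | 16 | minimizer window; expected density is 2/(w+1) seeds per patterned base |
| `max_occ` | 500 | occurrence cap; more frequent seeds are invisible at query time |
| `t` | 10 | minimizers examined per shifted read during pattern alignment |
| `D` | sr: `0.1*len + 50`; hifi: 500; ont: 1000 | voting distance: the indel drift a cluster tolerates |
| `V` | sr: 2; long: 3 | vote threshold for a winning location |
| `cap` | 50 | winning-list size limit |
| `max_align` | 5 | top-voted locations actually aligned per read |
| scoring | 2/4/4/2 | match, mismatch, gap open, gap extend; a gap of length L costs `open + L*extend` |
| band | voting distance + `2*ceil(0.01*len)` + 16 | DP band; the voting distance bounds net indel drift, the margin covers sequencing-rate indels |

`max_align` is this package's own economy: the winning list is kept (and
capped at `cap`) but only the top few locations are refined by DP, which
does not change primary/secondary semantics in any tested scenario.

## Numerical and convention choices

* **Shift convention.** "Shift by `s`" means the mask applied at original
  position `i` is `bits[(i + s) mod p]`; the same definition serves
  reference masking (s = 0) and read-phase search, and makes
  `a = o mod p` the correct phase of a read at offset `o`.
* **Strand.** Each k-mer is hashed on the canonical strand (smaller of the
  packed forward/reverse-complement encodings); palindromic k-mers are
  skipped as strand-ambiguous. A hit's mapping strand is the XOR of the
  reference and read seed strands; reverse-strand read positions are
  re-measured from the reverse complement before delta formation. The
  pattern phase is chosen on the forward read only — seeding is canonical,
  so both strands are still matched.
* **Ties.** Window ties keep all minimal k-mers (preserves the window
  guarantee); vote ties break to the smallest anchor, then reference;
  equal-vote references in containment tally to the smallest id.
* **Ambiguous bases.** N is masked like any base; any window containing an
  N emits nothing and scanning restarts after it (keeps 2-bit packing).
* **Short runs.** A patterned run with fewer than `w` k-mers uses a single
  window over all of them, so short reads remain seedable.
* **Pattern-alignment counting** is per-occurrence: a seed appearing twice
  among the `t` prefix minimizers contributes twice.
* **Long-read pair widening.** Subsequence pairs are extended into the
  read flanks not covered by any other pair (plus a small pad mirrored on
  the reference side) before local alignment, so an exact full-length read
  yields a full-length alignment with an exact position instead of a
  seed-bounded fragment.
* **Ultra-long reads** are split into 30 kb segments, mapped separately,
  and lifted back with hard clips; the best-scoring segment record is the
  primary.
* **MAPQ** is a deterministic surrogate,
  `clamp(round(40*(1 - second/best)*min(1, votes/10) + 20*identity), 0, 60)`,
  not an empirically calibrated table; the SAM header says so. It is
  monotone in the best/second score gap, 60 for a unique perfect hit, and
  at most 20 when two candidates tie.
* **Index container.** Saved indexes are a versioned serialized wrapper
  whose magic string and version are checked on load; parameter mismatch
  between a saved index and a mapping run is a hard error.

## What the synthetic data does and does not emulate

`simulate_genome` draws i.i.d. bases at a chosen GC; `simulate_reads`
draws uniform origins, 50/50 strands, per-base substitutions and
geometric-length indels, and encodes the truth in read names. This gives
exact, controllable ground truth for recovery rates, but random genomes
have no repeat structure, no homopolymer error bias, no coverage bias and
no quality values. Passing the recovery tests therefore demonstrates the
*mechanics* (phase selection, voting, banded alignment, coordinate
bookkeeping) under realistic error rates — not performance on repetitive
real genomes, where `max_occ` filtering and vote ambiguity matter much
more.

Problem sizes used by the tests and the acceptance script — a 1 Mb genome
for index-reduction fractions, 5,000 reads (150 b and 5 kb halves) from a
500 kb genome for recovery, 500 benchmark pairs of 1 kb, and a
10-genome/10,000-read community at 10x for containment — are the
package's desk-scale study conditions; they keep every quantity
recomputable from scratch in minutes on one CPU.

## Known limitations

* Single-threaded reference implementation; no SIMD. The contracts (not
  the constant factors) follow the vectorized design they mirror.
* No paired-end logic, base-quality-aware scoring, or BAM/CRAM output.
* Containment abundance is the proportional read-count estimator; no
  unique/multi-map reweighting and no taxonomy integration.
* With `k` of 27–28, R-side hash keys may rarely collide (doubles carry 53
  bits); minimizer selection itself is exact at any `k <= 28`.
* The benchmark's mutation model is substitution-only by design (its edit
  distances then equal the substitution count almost always); the mapper's
  own tests cover indels.
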