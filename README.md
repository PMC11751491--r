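# sparsemap

Read mapping, containment search and seeding benchmarks over **sparsified
genomic sequences**.

Seeding-based tools compute seeds from every base of a genome and every
base of every read. `sparsemap` instead excludes bases *before* any seed
exists: a repeating binary **diet pattern** `P` (length `p`, weight `x`,
reduction ratio `β = p/x`) is laid along a sequence, keeping bases under
1s and dropping bases under 0s. The pattern `"10"` halves both the
reference and the reads; `"11"` disables sparsification. Double-strand
(w,k)-minimizers of the patterned sequence — 2-bit-packed k-mers hashed on
their canonical strand with the masked Wang 64-bit mix — are stored with
locations in the **original** coordinate system, so base-level alignment
still sees the full sequences.

Because a read is sampled at an unknown offset `o`, its seeds only match
the index if it is masked with the matching phase. The mapper therefore:

1. **indexes** the patterned reference (`build_index`),
2. picks each read's **alignment index** `a` — the pattern shift whose
   masked read prefix has the highest total seed occurrence in the index
   (`pattern_align`; for an exact read, `a ≡ o mod p`),
3. **seeds** the read masked at shift `a` (`compressed_seed`),
4. finds candidate locations by **location voting**: every hit is reduced
   to `Δ = ref_pos − read_pos`, deltas are merged into one sorted list and
   clustered within a distance `D`; clusters with ≥ `V` votes win
   (`vote_short` / `vote_long`) — no seed chaining,
5. refines winners by **banded affine-gap DP** (global for short reads
   with an exact-match fast path, local subsequence pairs concatenated
   across ≤ 50 kb gaps for long reads) into SAM/PAF records with
   primary/supplementary/secondary classification.

A voting-only mode (`classify_read_set`, `accept_targets`,
`relative_abundance`, `profile_metrics`) supports containment search and
simple taxonomic profiling; `run_benchmark` compares the sensitivity of
contiguous, minimizer, spaced and sparsified seeding against edit
distance; `simulate_genome` / `simulate_reads` provide truth-labelled
synthetic data.

## Worked example

```r
library(sparsemap)

genome <- simulate_genome(200000, seed = 11, name = "chr1")
idx <- build_index(genome, "10", k = 19, w = 16)
idx
#> <seed_index 1 refs, 11776 distinct hashes, 11776 locations, P=10 k=19 w=16>
unlist(index_stats(idx))
#> distinct_hashes total_locations         density
#>      1.1776e+04      1.1776e+04      5.8880e-02

reads <- simulate_reads(genome, 5, 1000, sub_rate = 0.01,
                        indel_rate = 0.001, seed = 12)
recs <- map_reads(reads, idx, mode = "map-hifi")
recs[recs$category == "primary",
     c("qname", "flag", "rname", "pos", "mapq", "votes", "score")]
#>                                                    qname flag rname    pos mapq votes score
#>     r000001|ref=chr1|pos=6745|strand=-|sub=7|ins=0|del=0   16  chr1   6746   60    44  1958
#>    r000002|ref=chr1|pos=35578|strand=+|sub=6|ins=0|del=2    0  chr1  35579   60    44  1948
#>  r000003|ref=chr1|pos=127692|strand=-|sub=13|ins=3|del=2   16  chr1 127693   44     6  1900
#>    r000004|ref=chr1|pos=4552|strand=-|sub=11|ins=5|del=0   16  chr1   4553   60    40  1920
#>     r000005|ref=chr1|pos=1656|strand=-|sub=8|ins=0|del=0   16  chr1   1657   60    55  1952
```

The index holds one location per stored minimizer at a density of
~0.059 seeds per reference base — about half the 2/(w+1) ≈ 0.118 of an
unsparsified minimizer index, which is exactly the `β = 2` saving of
pattern `"10"`. Every simulated read (names encode the truth) is placed
at its true origin (SAM `pos` is 1-based, so `pos − 1` equals the `pos=`
field), on the right strand (flag 16 = reverse), with votes, alignment
score and the surrogate MAPQ per record. `write_sam(recs, idx, "out.sam")`
emits the records; a command-line wrapper with `index`, `map`, `contain`,
`bench` and `simulate` subcommands is installed at
`system.file("cli", "sparsemap", package = "sparsemap")`.

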