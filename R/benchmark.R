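#' Mutate a sequence with a fixed number of substitutions
#'
#' Changes exactly `n_subs` positions, drawn without replacement, each to a
#' uniformly chosen different base; deterministic under `seed`.
#'
#' @param seq sequence string.
#' @param n_subs number of substitutions in `[0, nchar(seq)]`.
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @return mutated copy of `seq`.
#' @export
mutate_sequence <- function(seq, n_subs, seed = NULL) {
  L <- nchar(seq)
  n_subs <- as.integer(n_subs)
  if (n_subs < 0L || n_subs > L) stop("n_subs must be in [0, sequence length]")
  if (n_subs == 0L) return(seq)
  with_rng_seed(seed, {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    pos <- sample.int(L, n_subs)
    bases <- c("A", "C", "G", "T")
    for (i in pos) {
      alt <- setdiff(bases, chars[i])
      chars[i] <- alt[sample.int(length(alt), 1L)]
    }
    paste(chars, collapse = "")
  })
}

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance by dynamic programming; part of the
#' seeding benchmark, which relates seed matching rates to edit distance.
#'
#' @param a,b sequence strings.
#' @return integer edit distance.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) levenshtein_cpp(a, b)

# masks/params bundled for the four seeding algorithms
#' Preset spaced-seed masks
#'
#' Literature-standard spaced-seed masks for weights 13, 18 and 21; for other
#' weights a mask is derived by repeating a diet pattern until it holds `k`
#' ones (so spaced seeding samples the same layout the sparsified seeding
#' drops).
#'
#' @param k seed weight.
#' @param pattern diet pattern used to derive a mask when no preset exists.
#' @return mask string over `{0,1}` of weight `k`.
#' @export
spaced_seed_mask <- function(k, pattern = "10") {
  presets <- c(`13` = "1110110110111",
               `18` = "111001011001010111",
               `21` = "111101101101011101111")
  key <- as.character(k)
  if (key %in% names(presets)) return(presets[[key]])
  P <- parse_pattern(pattern)
  reps <- ceiling(k / P$x)
  bits <- rep(P$bits, reps)
  last_one <- which(cumsum(bits) == k)[1L]
  paste(bits[seq_len(last_one)], collapse = "")
}

#' Seed matching rate between two sequences
#'
#' Extracts seeds from `a` into a lookup set, extracts seeds from `b`, and
#' returns the fraction of `b`'s seeds whose hash occurs among `a`'s seeds.
#' Algorithms: `"all"` (every overlapping k-mer), `"minimizer"`
#' ((w,k)-minimizers of the unchanged sequences), `"spaced"` (spaced seeds
#' under `mask`), `"diet"` (both sequences sparsified at shift 0, then
#' minimizers) - the same paired pattern phases the mapper relies on.
#'
#' @param a,b sequence strings.
#' @param algorithm one of "all", "minimizer", "spaced", "diet".
#' @param k seed length (weight for "spaced").
#' @param w minimizer window ("minimizer" and "diet").
#' @param pattern diet pattern ("diet").
#' @param mask spaced-seed mask ("spaced"); default from [spaced_seed_mask()].
#' @return matching rate in `[0, 1]` (0 when no seeds can be extracted).
#' @export
seed_matching_rate <- function(a, b,
                               algorithm = c("all", "minimizer", "spaced",
                                             "diet"),
                               k = 8L, w = 6L, pattern = "10", mask = NULL) {
  algorithm <- match.arg(algorithm)
  seeds <- switch(algorithm,
    all = function(s) extract_all_seeds(s, k),
    minimizer = function(s) extract_minimizers(s, k, w)$hash,
    spaced = {
      if (is.null(mask)) mask <- spaced_seed_mask(k, pattern)
      function(s) extract_spaced_seeds(s, mask)
    },
    diet = {
      P <- parse_pattern(pattern)
      function(s) extract_minimizers(apply_pattern(P, 0L, s), k, w)$hash
    })
  ha <- seeds(a)
  hb <- seeds(b)
  if (length(hb) == 0L) return(0)
  mean(hb %in% ha)
}

#' Acceptance threshold for a benchmark run
#'
#' The minimum seed matching rate over all sequence pairs whose edit distance
#' is at most `ed_threshold`: accepting every pair at or above this rate
#' guarantees zero false negatives at that edit distance by construction.
#'
#' @param pairs benchmark table from [run_benchmark()] (needs
#'   `edit_distance` and a rate column per algorithm).
#' @param algorithm rate column to use.
#' @param ed_threshold edit-distance threshold.
#' @return the rate threshold (a number in `[0, 1]`).
#' @export
acceptance_threshold <- function(pairs, algorithm, ed_threshold) {
  qual <- pairs$edit_distance <= ed_threshold
  if (!any(qual)) stop("no pair with edit distance <= ", ed_threshold)
  min(pairs[[algorithm]][qual])
}

#' Run the four-way seeding benchmark
#'
#' For each pair: draw a random sequence, mutate it with a uniformly drawn
#' number of substitutions in `[0, max_subs]`, compute the Levenshtein
#' distance, and the seed matching rate under all four seeding algorithms.
#'
#' @param n_pairs number of sequence pairs.
#' @param length sequence length (default 1000).
#' @param k,w,pattern,mask seeding parameters (see [seed_matching_rate()]).
#' @param max_subs upper bound of the uniform substitution count.
#' @param gc GC content of the random sequences.
#' @param seed RNG seed for reproducible tables.
#' @return data.frame with one row per pair: `pair`, `n_subs`,
#'   `edit_distance`, and rate columns `all`, `minimizer`, `spaced`, `diet`.
#' @export
run_benchmark <- function(n_pairs, length = 1000L, k = 8L, w = 6L,
                          pattern = "10", mask = NULL, max_subs = 400L,
                          gc = 0.5, seed = NULL) {
  if (is.null(mask)) mask <- spaced_seed_mask(k, pattern)
  empty <- data.frame(pair = integer(0), n_subs = integer(0),
                      edit_distance = integer(0), all = numeric(0),
                      minimizer = numeric(0), spaced = numeric(0),
                      diet = numeric(0))
  if (n_pairs == 0L) return(empty)
  with_rng_seed(seed, {
    rows <- lapply(seq_len(n_pairs), function(i) {
      orig <- simulate_genome(length, gc = gc)[[1L]]
      ns <- sample.int(max_subs + 1L, 1L) - 1L
      mut <- mutate_sequence(orig, ns)
      data.frame(
        pair = i, n_subs = ns, edit_distance = levenshtein(orig, mut),
        all = seed_matching_rate(orig, mut, "all", k = k),
        minimizer = seed_matching_rate(orig, mut, "minimizer", k = k, w = w),
        spaced = seed_matching_rate(orig, mut, "spaced", k = k, mask = mask),
        diet = seed_matching_rate(orig, mut, "diet", k = k, w = w,
                                  pattern = pattern))
    })
    setDF(rbindlist(rows))
  })
}

#' Accepted pairs at an edit-distance threshold
#'
#' Applies [acceptance_threshold()] and reports, per algorithm, which pairs
#' are accepted (rate >= threshold) and the count of false negatives
#' (qualifying pairs rejected) - zero by construction of the threshold.
#'
#' @inheritParams acceptance_threshold
#' @param algorithms rate columns to evaluate.
#' @return data.frame with `algorithm`, `threshold`, `n_accepted`,
#'   `false_negatives`.
#' @export
benchmark_acceptance <- function(pairs, ed_threshold,
                                 algorithms = c("all", "minimizer", "spaced",
                                                "diet")) {
  rows <- lapply(algorithms, function(alg) {
    thr <- acceptance_threshold(pairs, alg, ed_threshold)
    acc <- pairs[[alg]] >= thr
    data.frame(algorithm = alg, threshold = thr, n_accepted = sum(acc),
               false_negatives = sum(!acc & pairs$edit_distance <= ed_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
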