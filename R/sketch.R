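#' Encode a DNA sequence as 2-bit base codes
#'
#' Bases are packed as A=0, C=1, G=2, T=3; ambiguous bases (N) are recorded
#' separately and their code slot is never read by the sketcher. Other symbols
#' are rejected.
#'
#' @param seq sequence string over `{A,C,G,T,N}`, case-insensitive.
#' @param name sequence name carried along for reporting.
#' @return an `encoded_sequence`: list with `codes` (integer, -1 at N),
#'   `ambiguous` (0-based N positions), `name`, `length`.
#' @examples
#' encode_sequence("ANT")$ambiguous
#' @export
encode_sequence <- function(seq, name = "") {
  stopifnot(is.character(seq), length(seq) == 1L)
  codes <- encode_bases_cpp(seq)
  structure(
    list(codes = codes, ambiguous = which(codes < 0L) - 1L,
         name = name, length = length(codes)),
    class = "encoded_sequence")
}

#' Decode an encoded sequence back to text
#'
#' @param x an [encode_sequence()] object (or raw integer code vector).
#' @return sequence string with N restored at ambiguous positions.
#' @export
decode_sequence <- function(x) {
  codes <- if (inherits(x, "encoded_sequence")) x$codes else as.integer(x)
  decode_bases_cpp(codes)
}

#' Hash a packed k-mer
#'
#' Applies Thomas Wang's 64-bit integer finalizer masked to 2k bits; the
#' masked mix is a bijection on `[0, 4^k)`, so distinct k-mers keep distinct
#' hashes while the hash order is effectively random (which is what makes
#' minimizer sampling unbiased).
#'
#' @param packed packed 2-bit k-mer value(s) in `[0, 4^k)`.
#' @param k k-mer length, `1 <= k <= 28`. Values returned to R are exact for
#'   `k <= 26` (double mantissa limit).
#' @return hash value(s) in `[0, 4^k)`.
#' @export
hash_kmer <- function(packed, k) {
  vapply(as.numeric(packed), hash_kmer_cpp, numeric(1), k = as.integer(k))
}

# Coerce the sketcher input to (codes, origin) form. Accepts a
# patterned_sequence, an encoded_sequence, or a plain string.
as_codes_origin <- function(x) {
  if (inherits(x, "patterned_sequence")) {
    list(codes = encode_bases_cpp(x$bases),
         origin = as.integer(x$origin_positions))
  } else if (inherits(x, "encoded_sequence")) {
    list(codes = x$codes, origin = seq_len(x$length) - 1L)
  } else if (is.character(x) && length(x) == 1L) {
    codes <- encode_bases_cpp(x)
    list(codes = codes, origin = seq_along(codes) - 1L)
  } else stop("expected a patterned_sequence, encoded_sequence or string")
}

#' Extract double-strand (w,k)-minimizers
#'
#' For each window of `w` consecutive k-mers over the patterned bases, emits
#' the k-mer(s) of minimal hash. Each k-mer is hashed on its canonical strand
#' (the lexicographically smaller of the packed forward and reverse-complement
#' encodings); k-mers equal to their own reverse complement are skipped as
#' strand-ambiguous. Ties within a window keep all minimal k-mers. Any N
#' terminates the current scan, which restarts after the N. Reported positions
#' are original coordinates of the seed's first included base; `span` is the
#' original-coordinate width covered by the k included bases.
#'
#' @param x a [apply_pattern()] result, an [encode_sequence()] object, or a
#'   plain sequence string (treated as unpatterned).
#' @param k seed length (`<= 28`).
#' @param w minimizer window size (`>= 1`); `w = 1` keeps every k-mer. If a
#'   run holds fewer than `w` k-mers, one window covering all of them is used.
#' @return data.frame with columns `hash`, `pos`, `span`, `strand`
#'   (0 = forward, 1 = reverse).
#' @export
extract_minimizers <- function(x, k, w) {
  co <- as_codes_origin(x)
  extract_minimizers_cpp(co$codes, co$origin, as.integer(k), as.integer(w))
}

#' All overlapping seed hashes of a sequence
#'
#' Canonical hash of every overlapping k-mer; used by the seeding benchmark
#' ("all seeds" algorithm). Runs are split at N.
#'
#' @param seq sequence string.
#' @inheritParams extract_minimizers
#' @return numeric vector of hashes, one per k-mer.
#' @export
extract_all_seeds <- function(seq, k) {
  extract_all_seeds_cpp(encode_bases_cpp(seq), as.integer(k))
}

#' Spaced-seed hashes of a sequence
#'
#' Classic spaced seeding: the sequence itself is unchanged and the binary
#' mask is applied to each extracted seed, sampling the bases under the 1s of
#' the mask; the seed count depends only on the mask span, not its weight.
#'
#' @param seq sequence string.
#' @param mask pattern string over `{0,1}`; its length is the seed span and
#'   its weight the number of sampled bases.
#' @return numeric vector of canonical seed hashes.
#' @export
extract_spaced_seeds <- function(seq, mask) {
  mp <- parse_pattern(mask)
  extract_spaced_seeds_cpp(encode_bases_cpp(seq), mp$bits)
}

#' Reverse complement
#'
#' @param seq sequence string over `{A,C,G,T,N}`.
#' @return reverse-complemented string (uppercase).
#' @export
reverse_complement <- function(seq) revcomp_cpp(seq)
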