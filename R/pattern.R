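#' Parse a diet pattern
#'
#' A diet pattern is a repeating binary string: when laid end-to-end along a
#' sequence, a 1 keeps the base and a 0 drops it. Its length is `p`, its
#' weight `x` is the number of 1s, and the reduction ratio `beta = p / x` is
#' the factor by which the sparsified sequence shrinks (`"11"` means no
#' sparsification, `"10"` keeps every other base, `beta = 2`).
#'
#' @param text pattern string over `{0,1}`, e.g. `"10"`; must contain at
#'   least one 1.
#' @return an object of class `diet_pattern` with fields `bits` (integer
#'   vector), `p`, `x` and `beta`.
#' @examples
#' parse_pattern("10")
#' parse_pattern("101001")$beta
#' @export
parse_pattern <- function(text) {
  if (inherits(text, "diet_pattern")) return(text)
  if (!is.character(text) || length(text) != 1L || nchar(text) == 0L)
    stop("pattern must be a single non-empty string")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("0", "1")))
    stop("pattern may contain only 0 and 1, got: ", text)
  bits <- as.integer(chars)
  x <- sum(bits)
  if (x == 0L)
    stop("all-zero pattern would drop every base")
  structure(
    list(bits = bits, p = length(bits), x = x, beta = length(bits) / x),
    class = "diet_pattern")
}

#' @export
format.diet_pattern <- function(x, ...) {
  sprintf("<diet_pattern %s p=%d x=%d beta=%.3g>",
          paste(x$bits, collapse = ""), x$p, x$x, x$beta)
}

#' @export
print.diet_pattern <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# Rotation of the pattern bits starting s positions into the repetition.
rotate_bits <- function(P, s) P$bits[((s + seq_len(P$p) - 1L) %% P$p) + 1L]

#' Shift a diet pattern
#'
#' Returns the cyclic rotation of `P` whose infinite repetition equals the
#' infinite repetition of `P` read from index `s`. Shifting is how the mapper
#' searches for the pattern phase of a read: the mask applied at original
#' position `i` under shift `s` is `bits[(i + s) mod p]`.
#'
#' @param P a [parse_pattern()] object (or pattern string).
#' @param s integer shift in `[0, p)`.
#' @return a `diet_pattern`.
#' @examples
#' shift_pattern(parse_pattern("101001"), 3)
#' @export
shift_pattern <- function(P, s) {
  P <- parse_pattern(P)
  s <- check_shift(P, s)
  parse_pattern(paste(rotate_bits(P, s), collapse = ""))
}

check_shift <- function(P, s) {
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 0L || s >= P$p)
    stop("shift must be an integer in [0, p)")
  s
}

# 0-based original positions included by pattern P at shift s over length L.
pattern_positions <- function(P, s, L) {
  if (L <= 0L) return(integer(0))
  mask <- rep_len(rotate_bits(P, s), L)
  which(mask == 1L) - 1L
}

#' Apply a diet pattern to a sequence
#'
#' Keeps exactly the bases at original positions `i` (0-based) where
#' `bits[(i + s) mod p] == 1`, and records the original coordinate of every
#' kept base so downstream seeds can report positions in the unpatterned
#' coordinate system. Lowercase (soft-masked) bases are uppercased; N bases
#' are masked like any other base and handled later by the sketcher.
#'
#' @inheritParams shift_pattern
#' @param seq a single sequence string over `{A,C,G,T,N}` (case-insensitive).
#' @return an object of class `patterned_sequence` with fields `bases`,
#'   `origin_positions` (0-based, strictly increasing), `source_length` and
#'   `shift`.
#' @examples
#' apply_pattern(parse_pattern("10"), 0, "ACGTAC")
#' @export
apply_pattern <- function(P, s, seq) {
  P <- parse_pattern(P)
  s <- check_shift(P, s)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  pos <- pattern_positions(P, s, L)
  bases <- if (L == 0L) "" else
    paste(strsplit(seq, "", fixed = TRUE)[[1L]][pos + 1L], collapse = "")
  structure(
    list(bases = bases, origin_positions = pos, source_length = L, shift = s),
    class = "patterned_sequence")
}

#' @export
format.patterned_sequence <- function(x, ...) {
  sprintf("<patterned_sequence %d/%d bases, shift=%d>",
          length(x$origin_positions), x$source_length, x$shift)
}

#' @export
print.patterned_sequence <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Closed-form length of a patterned sequence
#'
#' Number of bases `apply_pattern(P, s, seq)` keeps from any sequence of
#' length `L`, without materializing the mask.
#'
#' @inheritParams shift_pattern
#' @param L source sequence length (`>= 0`).
#' @return integer length of the patterned sequence.
#' @export
patterned_length <- function(P, L, s = 0L) {
  P <- parse_pattern(P)
  s <- check_shift(P, s)
  L <- as.integer(L)
  stopifnot(L >= 0L)
  rot <- rotate_bits(P, s)
  (L %/% P$p) * P$x + sum(rot[seq_len(L %% P$p)])
}
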