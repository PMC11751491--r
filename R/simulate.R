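#' Simulate a random genome
#'
#' I.i.d. bases with the requested GC fraction; deterministic under `seed`.
#'
#' @param length genome length (>= 1).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed optional RNG seed.
#' @param name sequence name.
#' @return named character vector of length 1.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL, name = "genome1") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  with_rng_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    setNames(paste(bases, collapse = ""), name)
  })
}

#' Simulate reads with known truth
#'
#' Reads are drawn uniformly from the genome(s) (references weighted by
#' length), 50/50 forward/reverse, with per-base substitutions at `sub_rate`
#' and indels starting at `indel_rate` per base (geometric lengths, mean 2;
#' insertions and deletions equally likely). Mutations are applied to the
#' forward-strand fragment before reverse-complementing. The truth is encoded
#' in each read name as
#' `r000001|ref=NAME|pos=P|strand=+|sub=S|ins=I|del=D`, with `pos` the
#' 0-based forward-strand origin and ins/del counting inserted/deleted bases;
#' [parse_read_truth()] recovers it.
#'
#' @param genomes named character vector of source sequences.
#' @param n number of reads.
#' @param length read length before indels.
#' @param sub_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base indel-start probability in `[0, 1)`.
#' @param seed optional RNG seed.
#' @return data.frame with `name`, `seq`, `qual` (NA).
#' @export
simulate_reads <- function(genomes, n, length, sub_rate = 0, indel_rate = 0,
                           seed = NULL) {
  genomes <- as_named_seqs(genomes)
  genomes <- setNames(toupper(genomes), names(genomes))
  glens <- nchar(genomes)
  if (any(glens < length)) stop("read length exceeds a genome length")
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  bases <- c("A", "C", "G", "T")
  rlen <- length
  with_rng_seed(seed, {
    ref_idx <- sample.int(base::length(genomes), n, replace = TRUE,
                          prob = glens / sum(glens))
    starts <- as.integer(floor(runif(n) * (glens[ref_idx] - rlen + 1)))
    is_rev <- runif(n) < 0.5
    seqs <- character(n)
    nsub <- nins <- ndel <- integer(n)
    for (i in seq_len(n)) {
      frag <- substr(genomes[[ref_idx[i]]], starts[i] + 1L, starts[i] + rlen)
      chars <- strsplit(frag, "", fixed = TRUE)[[1L]]
      if (sub_rate > 0) {
        at <- which(runif(rlen) < sub_rate)
        if (base::length(at) > 0L) {
          shift <- sample.int(3L, base::length(at), replace = TRUE)
          chars[at] <- bases[(match(chars[at], bases) - 1L + shift) %% 4L + 1L]
          nsub[i] <- base::length(at)
        }
      }
      if (indel_rate > 0) {
        sites <- which(runif(rlen) < indel_rate)
        for (s in rev(sites)) {   # right-to-left keeps coordinates valid
          g <- rgeom(1L, 0.5) + 1L
          if (runif(1) < 0.5) {
            ins <- sample(bases, g, replace = TRUE)
            chars <- append(chars, ins, after = s)
            nins[i] <- nins[i] + g
          } else {
            drop <- s:min(s + g - 1L, base::length(chars))
            chars <- chars[-drop]
            ndel[i] <- ndel[i] + base::length(drop)
          }
        }
      }
      s <- paste(chars, collapse = "")
      seqs[i] <- if (is_rev[i]) revcomp_cpp(s) else s
    }
    names_out <- sprintf("r%06d|ref=%s|pos=%d|strand=%s|sub=%d|ins=%d|del=%d",
                         seq_len(n), names(genomes)[ref_idx], starts,
                         ifelse(is_rev, "-", "+"), nsub, nins, ndel)
    data.frame(name = names_out, seq = seqs, qual = NA_character_,
               stringsAsFactors = FALSE)
  })
}

#' Parse truth fields from simulated read names
#'
#' @param names read names produced by [simulate_reads()].
#' @return data.frame with `ref`, `pos` (0-based), `strand` ("+"/"-"),
#'   `sub`, `ins`, `del`.
#' @export
parse_read_truth <- function(names) {
  out <- utils::strcapture(
    "\\|ref=([^|]+)\\|pos=([0-9]+)\\|strand=([+-])\\|sub=([0-9]+)\\|ins=([0-9]+)\\|del=([0-9]+)",
    names,
    proto = data.frame(ref = character(), pos = integer(),
                       strand = character(), sub = integer(),
                       ins = integer(), del = integer()))
  if (anyNA(out$pos)) stop("read names do not carry truth fields")
  out
}
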