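#' Alignment scoring scheme
#'
#' Positive match reward and positive penalties; a gap of length L costs
#' `gap_open + L * gap_extend`. Defaults are the usual short-read preset of
#' minimizer-based mappers.
#'
#' @param match,mismatch,gap_open,gap_extend non-negative integers
#'   (`match > 0`).
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = 4L, gap_open = 4L,
                           gap_extend = 2L) {
  s <- list(match = as.integer(match), mismatch = as.integer(mismatch),
            gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
  if (s$match <= 0L || s$mismatch < 0L || s$gap_open < 0L || s$gap_extend < 0L)
    stop("match must be > 0 and penalties >= 0")
  structure(s, class = "scoring_scheme")
}

as_codes <- function(x) {
  if (is.integer(x)) x
  else if (inherits(x, "encoded_sequence")) x$codes
  else encode_bases_cpp(x)
}

#' Exact-match filter
#'
#' Detects reads identical to their candidate reference segment so a
#' perfect-match record can be emitted without dynamic programming; a large
#' fraction of short reads map exactly, making this a cheap fast path.
#'
#' @param read,ref_segment equal-length sequences (strings or code vectors).
#' @return TRUE iff the segments are identical.
#' @export
exact_match_filter <- function(read, ref_segment) {
  a <- as_codes(read); b <- as_codes(ref_segment)
  if (length(a) != length(b)) stop("segments must have equal length")
  all(a == b)
}

aln_result <- function(r) {
  structure(list(score = r$score, cigar = r$cigar,
                 read_begin = r$a_begin, read_end = r$a_end,
                 ref_begin = r$b_begin, ref_end = r$b_end,
                 n_match = r$n_match, n_mismatch = r$n_mismatch,
                 n_ins = r$n_ins, n_del = r$n_del),
            class = "alignment_result")
}

#' Banded global alignment (Needleman-Wunsch, affine gaps)
#'
#' End-to-end alignment of the read against a reference segment, restricted
#' to a diagonal band; when `band >= len(read) + len(ref)` the result equals
#' the unbanded optimum. The mapper sets the band from the cluster's voting
#' distance plus a margin, since the spread of voting deltas bounds the net
#' indel drift.
#'
#' @param read,ref_segment sequences (strings or 2-bit code vectors).
#' @param scoring a [scoring_scheme()].
#' @param band band half-width in diagonals (`>= 1`).
#' @return an `alignment_result`: `score`, `cigar` (M/I/D), 0-based half-open
#'   `read_begin/read_end` and `ref_begin/ref_end`, and difference counts.
#' @export
banded_global_align <- function(read, ref_segment, scoring = scoring_scheme(),
                                band = 64L) {
  a <- as_codes(read); b <- as_codes(ref_segment)
  if (length(a) == 0L) stop("empty read")
  aln_result(banded_align_cpp(a, b, scoring$match, scoring$mismatch,
                              scoring$gap_open, scoring$gap_extend,
                              as.integer(band), FALSE))
}

#' Banded local alignment (Smith-Waterman, affine gaps)
#'
#' Local alignment of a read subsequence against a reference subsequence
#' within the band; used for long-read subsequence pairs.
#'
#' @inheritParams banded_global_align
#' @param read_sub,ref_sub sequences (strings or 2-bit code vectors).
#' @return an `alignment_result` (intervals are relative to the inputs).
#' @export
banded_local_align <- function(read_sub, ref_sub, scoring = scoring_scheme(),
                               band = 64L) {
  a <- as_codes(read_sub); b <- as_codes(ref_sub)
  if (length(a) == 0L) stop("empty read subsequence")
  aln_result(banded_align_cpp(a, b, scoring$match, scoring$mismatch,
                              scoring$gap_open, scoring$gap_extend,
                              as.integer(band), TRUE))
}

# --- CIGAR helpers -----------------------------------------------------------

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*")
    return(data.frame(len = integer(0), op = character(0)))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

cigar_string <- function(len, op) {
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (length(op) == 0L) return("")
  # merge adjacent identical ops
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  paste0(tapply(len, grp, sum)[as.character(unique(grp))],
         op[!duplicated(grp)], collapse = "")
}

cigar_concat <- function(...) {
  parts <- lapply(list(...), cigar_ops)
  all <- do.call(rbind, parts)
  cigar_string(all$len, all$op)
}

# query/reference lengths consumed by a CIGAR
cigar_consumes <- function(cigar) {
  ops <- cigar_ops(cigar)
  list(query = sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")]),
       ref = sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")]))
}

# --- pair concatenation ------------------------------------------------------

#' Concatenate the CIGARs of a long read's aligned subsequence pairs
#'
#' Aligned pairs of one read on the same reference and strand whose reference
#' gap is at most `max_gap` (default 50 kb) are merged into a single record:
#' when both the read gap and reference gap between two pairs are non-empty
#' and at most `2 * band`, the gap sequences are aligned globally and spliced
#' in; otherwise the gaps are emitted as pure insertion/deletion operations
#' (how large deletions/insertions enter the final CIGAR). Pairs farther
#' apart, or on different references/strands, stay separate records, later
#' classified as primary/supplementary. Pairs overlapping on the read keep
#' only the higher-scoring one.
#'
#' @param results data.frame of aligned pairs with columns `ref`, `strand`,
#'   `score`, `cigar`, `ref_begin`, `ref_end`, `read_begin`, `read_end`,
#'   `n_match`, `n_mismatch`, `n_ins`, `n_del`, `votes`.
#' @param read full read sequence (forward orientation).
#' @param refs character vector of reference sequences indexed by `ref`.
#' @param scoring a [scoring_scheme()].
#' @param band band half-width used when aligning bridge gaps.
#' @param max_gap maximum reference gap bridged into one record.
#' @return data.frame of merged results (same columns).
#' @export
concat_pair_cigars <- function(results, read, refs,
                               scoring = scoring_scheme(), band = 100L,
                               max_gap = 50000L) {
  qc <- list(`0` = encode_bases_cpp(read))
  qc$`1` <- rev_codes(qc$`0`)
  rc <- lapply(refs, encode_bases_cpp)
  concat_pairs_internal(results, qc, rc, scoring, band, max_gap)
}

rev_codes <- function(codes) {
  out <- rev(codes)
  ifelse(out < 0L, -1L, 3L - out)
}

concat_pairs_internal <- function(results, qcodes_by_strand, ref_codes,
                                  scoring, band, max_gap) {
  if (nrow(results) <= 1L) return(results)
  # drop read-overlapping pairs, highest score first
  o <- order(-results$score)
  keep <- rep(TRUE, nrow(results))
  for (i in seq_along(o)) {
    if (!keep[o[i]]) next
    ri <- results[o[i], ]
    for (j in seq_along(o)[-seq_len(i)]) {
      rj <- results[o[j], ]
      if (keep[o[j]] && rj$read_begin < ri$read_end &&
          ri$read_begin < rj$read_end)
        keep[o[j]] <- FALSE
    }
  }
  results <- results[keep, , drop = FALSE]
  results <- results[order(results$read_begin), , drop = FALSE]

  merged <- list()
  cur <- results[1L, ]
  for (i in seq_len(nrow(results))[-1L]) {
    nxt <- results[i, ]
    rgap <- nxt$ref_begin - cur$ref_end
    qgap <- nxt$read_begin - cur$read_end
    if (nxt$ref == cur$ref && nxt$strand == cur$strand &&
        qgap >= 0L && rgap >= 0L && rgap <= max_gap) {
      qc <- qcodes_by_strand[[as.character(cur$strand)]]
      bridge <- bridge_gap(qc, ref_codes[[cur$ref]], cur$read_end,
                           nxt$read_begin, cur$ref_end, nxt$ref_begin,
                           scoring, band)
      cur$cigar <- cigar_concat(cur$cigar, bridge$cigar, nxt$cigar)
      cur$score <- cur$score + bridge$score + nxt$score
      for (f in c("n_match", "n_mismatch", "n_ins", "n_del"))
        cur[[f]] <- cur[[f]] + bridge[[f]] + nxt[[f]]
      cur$read_end <- nxt$read_end
      cur$ref_end <- nxt$ref_end
      cur$votes <- cur$votes + nxt$votes
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- nxt
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

bridge_gap <- function(qc, refc, q0, q1, r0, r1, scoring, band) {
  qgap <- q1 - q0; rgap <- r1 - r0
  zero <- list(cigar = "", score = 0L, n_match = 0L, n_mismatch = 0L,
               n_ins = 0L, n_del = 0L)
  if (qgap == 0L && rgap == 0L) return(zero)
  if (qgap > 0L && rgap > 0L && qgap <= 2L * band && rgap <= 2L * band) {
    r <- banded_align_cpp(qc[(q0 + 1L):q1], refc[(r0 + 1L):r1],
                          scoring$match, scoring$mismatch, scoring$gap_open,
                          scoring$gap_extend, as.integer(qgap + rgap + 2L),
                          FALSE)
    return(list(cigar = r$cigar, score = r$score, n_match = r$n_match,
                n_mismatch = r$n_mismatch, n_ins = r$n_ins, n_del = r$n_del))
  }
  cig <- character(0); score <- 0L
  if (qgap > 0L) {
    cig <- c(cig, paste0(qgap, "I"))
    score <- score - scoring$gap_open - scoring$gap_extend * qgap
  }
  if (rgap > 0L) {
    cig <- c(cig, paste0(rgap, "D"))
    score <- score - scoring$gap_open - scoring$gap_extend * rgap
  }
  list(cigar = paste(cig, collapse = ""), score = score, n_match = 0L,
       n_mismatch = 0L, n_ins = if (qgap > 0L) qgap else 0L,
       n_del = if (rgap > 0L) rgap else 0L)
}

# --- classification and MAPQ -------------------------------------------------

#' Classify the alignment results of one read
#'
#' The highest-scoring result is the primary alignment; any other result
#' whose pair length is shorter than 80% of the primary's pair length is a
#' supplementary alignment (a distinct part of the read), otherwise a
#' secondary alignment (an alternative location for the same part).
#'
#' @param results data.frame with `score`, `read_begin`, `read_end`.
#' @return `results` with a `category` column; exactly one row is "primary".
#' @export
classify_alignments <- function(results) {
  stopifnot(nrow(results) >= 1L)
  len <- results$read_end - results$read_begin
  prim <- order(-results$score, -len)[1L]
  category <- ifelse(len < 0.8 * len[prim], "supplementary", "secondary")
  category[prim] <- "primary"
  results$category <- category
  results
}

#' Mapping quality (surrogate formula)
#'
#' Deterministic 0-60 confidence:
#' `clamp(round(40 * (1 - second/best) * min(1, votes/10) + 20 * identity))`.
#' A unique perfect hit scores 60; two equal-score candidates stay at or
#' below 20. This is a documented surrogate for the empirical per-mapper
#' table such tools calibrate; the SAM header carries a comment saying so.
#'
#' @param best list with `score`, `votes`, `identity` of the primary result.
#' @param second list with `score` of the runner-up, or NULL (treated as 0).
#' @return integer MAPQ in `[0, 60]`.
#' @export
compute_mapq <- function(best, second = NULL) {
  if (is.null(best$score) || is.na(best$score) || best$score <= 0) return(0L)
  s2 <- if (is.null(second) || is.null(second$score)) 0 else
    max(0, second$score)
  votes <- if (is.null(best$votes)) 10 else best$votes
  ident <- if (is.null(best$identity)) 1 else best$identity
  q <- 40 * (1 - s2 / best$score) * min(1, votes / 10) + 20 * ident
  as.integer(max(0L, min(60L, round(q))))
}

# --- SAM / PAF emission ------------------------------------------------------

sam_flag <- function(category, strand) {
  flag <- ifelse(category == "unmapped", 4L, 0L)
  flag <- flag + ifelse(category != "unmapped" & strand == 1L, 16L, 0L)
  flag <- flag + ifelse(category == "secondary", 256L, 0L)
  flag + ifelse(category == "supplementary", 2048L, 0L)
}

#' Write mapping records as SAM
#'
#' Emits an @HD/@SQ/@PG header (SAM 1.6, unsorted) followed by one line per
#' record; positions are 1-based and flags follow the SAM specification
#' (4 unmapped, 16 reverse, 256 secondary, 2048 supplementary).
#'
#' @param records data.frame of mapping records from [map_reads()].
#' @param ref_lengths named integer vector of reference lengths (or a
#'   `seed_index`).
#' @param file output path or connection ("" for stdout).
#' @param program_args command line recorded in the @PG line.
#' @return invisibly, the number of records written.
#' @export
write_sam <- function(records, ref_lengths, file = "", program_args = "") {
  if (inherits(ref_lengths, "seed_index")) ref_lengths <- ref_lengths$lengths
  bad <- !is.na(records$rname) & records$rname != "*" &
    !(records$rname %in% names(ref_lengths))
  if (any(bad)) stop("unknown reference id: ", records$rname[bad][1L])
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                      as.integer(ref_lengths)),
              sprintf("@PG\tID:sparsemap\tPN:sparsemap\tVN:%s\tCL:%s",
                      as.character(utils::packageVersion("sparsemap")),
                      program_args),
              "@CO\tMAPQ is a deterministic surrogate formula, not an empirically calibrated table")
  qual <- if (is.null(records$qual)) rep(NA_character_, nrow(records)) else
    records$qual
  qual[is.na(qual) | qual == ""] <- "*"
  nm <- if (is.null(records$nm)) rep(NA_integer_, nrow(records)) else
    records$nm
  tags <- ifelse(is.na(nm), "",
                 sprintf("\tNM:i:%d\tAS:i:%d", nm, as.integer(records$score)))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                   records$qname, records$flag, records$rname,
                   as.integer(records$pos), as.integer(records$mapq),
                   records$cigar, records$seq, qual, tags)
  writeLines(c(header, lines), con = file)
  invisible(nrow(records))
}

#' Write mapping records as PAF
#'
#' 0-based half-open intervals; query coordinates are reported on the
#' original read strand. Unmapped records are skipped (PAF has no unmapped
#' convention).
#'
#' @inheritParams write_sam
#' @return invisibly, the number of records written.
#' @export
write_paf <- function(records, ref_lengths, file = "") {
  if (inherits(ref_lengths, "seed_index")) ref_lengths <- ref_lengths$lengths
  r <- records[records$category != "unmapped", , drop = FALSE]
  if (nrow(r) == 0L) { writeLines(character(0), con = file); return(invisible(0L)) }
  qbeg <- ifelse(r$strand == 1L, r$qlen - r$qend, r$qbeg)
  qend <- ifelse(r$strand == 1L, r$qlen - r$qbeg, r$qend)
  aln_len <- r$n_match + r$nm
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   r$qname, r$qlen, as.integer(qbeg), as.integer(qend),
                   ifelse(r$strand == 1L, "-", "+"), r$rname,
                   as.integer(ref_lengths[r$rname]),
                   as.integer(r$pos) - 1L,
                   as.integer(r$pos) - 1L + vapply(r$cigar, function(cg)
                     cigar_consumes(cg)$ref, numeric(1)),
                   r$n_match, as.integer(aln_len), as.integer(r$mapq))
  writeLines(lines, con = file)
  invisible(nrow(r))
}
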