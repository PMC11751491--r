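#' Map reads against a sparsified seed index
#'
#' Runs the full pipeline per read: pattern alignment (phase selection),
#' compressed seeding, location voting, then banded base-level alignment of
#' the winning locations into SAM-ready records. Short-read mode votes on
#' whole-read locations and aligns the entire read globally (with an
#' exact-match fast path); the long-read modes vote subsequence pairs,
#' align them locally and concatenate nearby pairs into one CIGAR. Ultra-long
#' reads are first split into segments of at most `segment_limit` bases.
#'
#' @param reads named character vector of read sequences, or a data.frame
#'   with `name`/`seq` (and optionally `qual`) columns as returned by
#'   [read_sequences()] or [simulate_reads()].
#' @param idx a [build_index()] object (with sequences kept if `align`).
#' @param mode "sr" (short reads, global alignment, D = 0.1*len + 50, V = 2),
#'   "map-hifi" (D = 500, V = 3) or "map-ont" (D = 1000, V = 3).
#' @param pattern optional pattern cross-check: if given and different from
#'   the index pattern, mapping stops with an error.
#' @param D,V,cap voting distance, vote threshold and winning-list cap;
#'   `NULL` uses the mode preset.
#' @param t minimizer cap per shifted read in pattern alignment.
#' @param max_align at most this many top-voted locations are aligned per
#'   read (the rest of the winning list is dropped).
#' @param scoring a [scoring_scheme()].
#' @param align if FALSE, voting-only records (no CIGAR) are produced, as in
#'   containment mode.
#' @param rescue report the best sub-threshold cluster when no cluster
#'   reaches `V` (sensitivity rescue).
#' @param segment_limit maximum bases aligned at once for long reads.
#' @return data.frame of mapping records (one primary per mapped read):
#'   `qname`, `flag`, `rname`, `pos` (1-based), `mapq`, `cigar`, `seq`,
#'   `category`, `strand`, `score`, `votes`, `nm`, `qlen`, `qbeg`, `qend`.
#' @export
map_reads <- function(reads, idx, mode = c("sr", "map-hifi", "map-ont"),
                      pattern = NULL, D = NULL, V = NULL, t = 10L, cap = 50L,
                      max_align = 5L, scoring = scoring_scheme(),
                      align = TRUE, rescue = TRUE, segment_limit = 30000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(idx, "seed_index"))
  if (!is.null(pattern)) {
    Pq <- parse_pattern(pattern)
    if (!identical(paste(Pq$bits, collapse = ""), idx$params$pattern))
      stop("pattern mismatch: index built with ", idx$params$pattern,
           ", mapping requested ", paste(Pq$bits, collapse = ""))
  }
  if (align && is.null(idx$ref_codes))
    stop("index was built without sequences (keep_sequences = FALSE); ",
         "base-level alignment is unavailable")
  P <- parse_pattern(idx$params$pattern)
  reads <- as_read_table(reads)
  long <- mode != "sr"
  if (is.null(V)) V <- if (long) 3L else 2L
  Dfix <- if (!is.null(D)) D else if (mode == "map-hifi") 500 else
    if (mode == "map-ont") 1000 else NULL  # sr: per-read
  cfg <- pattern_align_config(t = t)

  out <- vector("list", nrow(reads) * 2L)
  n_out <- 0L
  for (i in seq_len(nrow(reads))) {
    recs <- map_one_read(reads$name[i], reads$seq[i], reads$qual[i],
                         idx, P, cfg, long, Dfix, V, cap, max_align,
                         scoring, align, rescue, segment_limit)
    if (!is.null(recs)) { n_out <- n_out + 1L; out[[n_out]] <- recs }
  }
  res <- rbindlist(out[seq_len(n_out)], fill = TRUE)
  setDF(res)
  res
}

as_read_table <- function(reads) {
  if (is.data.frame(reads)) {
    if (is.null(reads$qual)) reads$qual <- NA_character_
    reads[, c("name", "seq", "qual")]
  } else {
    if (is.null(names(reads)) && length(reads) > 0L)
      names(reads) <- paste0("read", seq_along(reads))
    data.frame(name = names(reads) %||% character(0),
               seq = as.character(reads),
               qual = rep(NA_character_, length(reads)),
               stringsAsFactors = FALSE)
  }
}

unmapped_record <- function(name, seq, qual) {
  data.frame(qname = name, flag = 4L, rname = "*", pos = 0L, mapq = 0L,
             cigar = "*", seq = seq, qual = qual, category = "unmapped",
             strand = 0L, score = NA_integer_, votes = 0L,
             n_match = NA_integer_, nm = NA_integer_,
             qlen = nchar(seq), qbeg = NA_integer_, qend = NA_integer_,
             stringsAsFactors = FALSE)
}

map_one_read <- function(name, seq, qual, idx, P, cfg, long, Dfix, V, cap,
                         max_align, scoring, align, rescue, segment_limit) {
  seq <- toupper(seq)
  L_full <- nchar(seq)
  if (L_full == 0L) return(unmapped_record(name, seq, qual))
  segs <- if (long && L_full > segment_limit)
    segment_ultralong(seq, segment_limit) else
    data.frame(seq = seq, offset = 0L, stringsAsFactors = FALSE)

  all_res <- list()
  for (si in seq_len(nrow(segs))) {
    res <- map_segment(segs$seq[si], idx, P, cfg, long, Dfix, V, cap,
                       max_align, scoring, align, rescue)
    if (!is.null(res) && nrow(res) > 0L) {
      res$seg_offset <- segs$offset[si]
      res$seg_len <- nchar(segs$seq[si])
      all_res[[length(all_res) + 1L]] <- res
    }
  }
  if (length(all_res) == 0L) return(unmapped_record(name, seq, qual))
  res <- do.call(rbind, all_res)

  if (!align) {
    res <- classify_alignments(res)
    return(voting_records(name, seq, qual, res, idx))
  }

  res <- classify_alignments(res)
  # across segments, non-primary best-of-segment records are supplementary
  if (nrow(segs) > 1L) {
    prim <- which(res$category == "primary")[1L]
    res$category[res$seg_offset != res$seg_offset[prim] &
                 res$category == "secondary"] <- "supplementary"
  }
  build_records(name, seq, qual, res, idx, L_full)
}

# Core per-segment pipeline; returns a results data.frame or NULL.
map_segment <- function(seq, idx, P, cfg, long, Dfix, V, cap, max_align,
                        scoring, align, rescue) {
  k <- idx$params$k; w <- idx$params$w
  codes <- encode_bases_cpp(seq)
  L <- length(codes)
  a <- if (P$p == 1L) 0L else which.max(pattern_align_sums(codes, P, idx, cfg)) - 1L
  pos <- pattern_positions(P, a, L)
  mm <- extract_minimizers_cpp(codes[pos + 1L], pos, k, w)
  if (nrow(mm) == 0L) return(NULL)
  hits <- adjust_and_sort_hits(mm, idx, L)
  if (nrow(hits) == 0L) return(NULL)
  D <- if (is.null(Dfix)) 0.1 * L + 50 else Dfix
  clusters <- cluster_hits(hits, D)
  win <- clusters[clusters$votes >= V, , drop = FALSE]
  win <- win[order(-win$votes, win$anchor, win$ref, win$strand), , drop = FALSE]
  win <- head(win, cap)
  if (nrow(win) == 0L) {
    if (!rescue) return(NULL)
    win <- rescue_location(clusters)
  }
  win <- head(win, max_align)

  if (!align) {
    return(data.frame(ref = win$ref, strand = win$strand, score = win$votes,
                      votes = win$votes, ref_begin = pmax(win$anchor, 0L),
                      ref_end = pmax(win$anchor, 0L) + L, read_begin = 0L,
                      read_end = L, cigar = "*", n_match = NA_integer_,
                      n_mismatch = NA_integer_, n_ins = NA_integer_,
                      n_del = NA_integer_, stringsAsFactors = FALSE))
  }

  rc_codes <- rev_codes(codes)
  if (!long) {
    rows <- lapply(seq_len(nrow(win)), function(i)
      align_global_cluster(win[i, ], codes, rc_codes, L, idx, scoring))
    res <- do.call(rbind, rows)
  } else {
    pairs <- widen_pairs(win, L, idx)
    rows <- lapply(seq_len(nrow(pairs)), function(i)
      align_local_pair(pairs[i, ], codes, rc_codes, idx, scoring))
    res <- do.call(rbind, rows)
    if (is.null(res) || nrow(res) == 0L) return(NULL)
    res <- concat_by_group(res, codes, rc_codes, idx, scoring)
  }
  res[!is.na(res$score), , drop = FALSE]
}

# Global alignment of the whole (oriented) read at a short-read vote cluster.
align_global_cluster <- function(cl, codes, rc_codes, L, idx, scoring) {
  qc <- if (cl$strand == 1L) rc_codes else codes
  ref_len <- idx$lengths[[cl$ref]]
  refc <- idx$ref_codes[[cl$ref]]
  start <- cl$anchor
  dist <- cl$last - cl$anchor
  row <- data.frame(ref = cl$ref, strand = cl$strand, votes = cl$votes,
                    read_begin = 0L, read_end = L, stringsAsFactors = FALSE)
  if (dist == 0L && start >= 0L && start + L <= ref_len &&
      all(qc == refc[(start + 1L):(start + L)])) {
    row$score <- scoring$match * L
    row$cigar <- paste0(L, "M")
    row$ref_begin <- start; row$ref_end <- start + L
    row$n_match <- L; row$n_mismatch <- 0L; row$n_ins <- 0L; row$n_del <- 0L
    return(row)
  }
  band <- dist + 2L * as.integer(ceiling(0.01 * L)) + 16L
  s0 <- max(0L, start - 4L)
  e0 <- min(ref_len, start + L + dist + 4L)
  if (e0 <= s0) return(cbind(row, score = NA_integer_, cigar = NA_character_,
                             ref_begin = NA_integer_, ref_end = NA_integer_,
                             n_match = NA_integer_, n_mismatch = NA_integer_,
                             n_ins = NA_integer_, n_del = NA_integer_))
  r <- banded_align_cpp(qc, refc[(s0 + 1L):e0], scoring$match,
                        scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend, band + 8L, FALSE)
  row$score <- r$score
  row$cigar <- r$cigar
  row$ref_begin <- s0 + r$b_begin; row$ref_end <- s0 + r$b_end
  row$n_match <- r$n_match; row$n_mismatch <- r$n_mismatch
  row$n_ins <- r$n_ins; row$n_del <- r$n_del
  row
}

# Extend long-read subsequence pairs into their unaligned read flanks,
# bounded by neighbouring pairs on the same strand, so local alignment can
# recover full-length matches; the reference interval is widened to match.
widen_pairs <- function(win, L, idx) {
  pairs <- vote_long_from_clusters(win, L)
  for (st in unique(pairs$strand)) {
    sel <- which(pairs$strand == st)
    sel <- sel[order(pairs$read_begin[sel])]
    for (i in seq_along(sel)) {
      r <- sel[i]
      lo <- if (i == 1L) 0L else max(0L, pairs$read_end[sel[i - 1L]])
      hi <- if (i == length(sel)) L else pairs$read_begin[sel[i + 1L]]
      lo <- min(lo, pairs$read_begin[r]); hi <- max(hi, pairs$read_end[r])
      pad <- 2L * as.integer(ceiling(0.01 * (hi - lo))) + 16L
      ref_len <- idx$lengths[[pairs$ref[r]]]
      pairs$ref_begin[r] <- max(0L, pairs$ref_begin[r] -
                                  (pairs$read_begin[r] - lo) - pad)
      pairs$ref_end[r] <- min(ref_len, pairs$ref_end[r] +
                                (hi - pairs$read_end[r]) + pad)
      pairs$read_begin[r] <- lo; pairs$read_end[r] <- hi
    }
  }
  pairs
}

vote_long_from_clusters <- function(cl, read_len) {
  data.frame(strand = cl$strand, ref = cl$ref, votes = cl$votes,
             anchor = cl$anchor, last = cl$last,
             ref_begin = cl$ref_lo, ref_end = cl$ref_hi,
             read_begin = cl$read_lo,
             read_end = pmin(cl$read_hi, as.integer(read_len)))
}

align_local_pair <- function(pr, codes, rc_codes, idx, scoring) {
  qc <- if (pr$strand == 1L) rc_codes else codes
  sub_q <- qc[(pr$read_begin + 1L):pr$read_end]
  refc <- idx$ref_codes[[pr$ref]]
  if (pr$ref_end <= pr$ref_begin)
    return(NULL)
  sub_r <- refc[(pr$ref_begin + 1L):pr$ref_end]
  band <- (pr$last - pr$anchor) +
    2L * as.integer(ceiling(0.01 * length(sub_q))) + 16L
  r <- banded_align_cpp(sub_q, sub_r, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend, band + 8L, TRUE)
  data.frame(ref = pr$ref, strand = pr$strand, votes = pr$votes,
             score = r$score, cigar = r$cigar,
             read_begin = pr$read_begin + r$a_begin,
             read_end = pr$read_begin + r$a_end,
             ref_begin = pr$ref_begin + r$b_begin,
             ref_end = pr$ref_begin + r$b_end,
             n_match = r$n_match, n_mismatch = r$n_mismatch,
             n_ins = r$n_ins, n_del = r$n_del, stringsAsFactors = FALSE)
}

concat_by_group <- function(res, codes, rc_codes, idx, scoring) {
  if (nrow(res) <= 1L) return(res)
  qcodes <- list(`0` = codes, `1` = rc_codes)
  groups <- split(seq_len(nrow(res)),
                  paste(res$ref, res$strand, sep = "_"))
  merged <- lapply(groups, function(rows) {
    concat_pairs_internal(res[rows, , drop = FALSE], qcodes, idx$ref_codes,
                          scoring, band = 100L, max_gap = 50000L)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

# Assemble SAM-ready records from classified results of one read.
build_records <- function(name, seq, qual, res, idx, L_full) {
  prim <- which(res$category == "primary")[1L]
  second_score <- if (nrow(res) > 1L) max(res$score[-prim]) else NULL
  aln_span <- res$n_match + res$n_mismatch + res$n_ins + res$n_del
  identity <- ifelse(aln_span > 0, res$n_match / aln_span, 0)
  mapq_prim <- compute_mapq(
    list(score = res$score[prim], votes = res$votes[prim],
         identity = identity[prim]),
    if (is.null(second_score)) NULL else list(score = second_score))

  recs <- lapply(seq_len(nrow(res)), function(i) {
    r <- res[i, ]
    seg_seq <- substr(seq, r$seg_offset + 1L, r$seg_offset + r$seg_len)
    oseq <- if (r$strand == 1L) revcomp_cpp(seg_seq) else seg_seq
    oqual <- qual
    if (!is.na(oqual) && nzchar(oqual)) {
      oqual <- substr(oqual, r$seg_offset + 1L, r$seg_offset + r$seg_len)
      if (r$strand == 1L)
        oqual <- paste(rev(strsplit(oqual, "")[[1L]]), collapse = "")
    }
    lead <- r$read_begin
    tail <- r$seg_len - r$read_end
    cig <- cigar_concat(if (lead > 0L) paste0(lead, "S") else "",
                        r$cigar,
                        if (tail > 0L) paste0(tail, "S") else "")
    # lift segment to full-read coordinates with hard clips
    pre_h <- if (r$strand == 1L) L_full - r$seg_offset - r$seg_len else
      r$seg_offset
    post_h <- L_full - r$seg_len - pre_h
    cig <- cigar_concat(if (pre_h > 0L) paste0(pre_h, "H") else "", cig,
                        if (post_h > 0L) paste0(post_h, "H") else "")
    mapq <- if (r$category == "secondary") 0L else mapq_prim
    data.frame(qname = name, flag = sam_flag(r$category, r$strand),
               rname = idx$ref_names[r$ref], pos = r$ref_begin + 1L,
               mapq = mapq, cigar = cig, seq = oseq, qual = oqual,
               category = r$category, strand = r$strand,
               score = r$score, votes = r$votes, n_match = r$n_match,
               nm = r$n_mismatch + r$n_ins + r$n_del,
               qlen = r$seg_len, qbeg = r$read_begin, qend = r$read_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

voting_records <- function(name, seq, qual, res, idx) {
  recs <- lapply(seq_len(nrow(res)), function(i) {
    r <- res[i, ]
    data.frame(qname = name, flag = sam_flag(r$category, r$strand),
               rname = idx$ref_names[r$ref], pos = r$ref_begin + 1L,
               mapq = 0L, cigar = "*", seq = seq, qual = qual,
               category = r$category, strand = r$strand, score = r$score,
               votes = r$votes, n_match = NA_integer_, nm = NA_integer_,
               qlen = nchar(seq),
               qbeg = r$read_begin, qend = r$read_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
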