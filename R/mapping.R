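#' Pattern-alignment configuration
#'
#' @param t cap on the number of minimizers examined per shifted read prefix.
#' @param freq_exclude occurrence threshold above which a seed contributes 0
#'   to the per-shift frequency sum; defaults to the index `max_occ`.
#' @return a `pattern_align_config` list.
#' @export
pattern_align_config <- function(t = 10L, freq_exclude = NULL) {
  t <- as.integer(t)
  if (t < 1L) stop("t must be >= 1")
  structure(list(t = t, freq_exclude = freq_exclude),
            class = "pattern_align_config")
}

# Internal: per-shift occurrence sums on the read prefix, over 0-based codes.
pattern_align_sums <- function(codes, P, idx, cfg) {
  k <- idx$params$k; w <- idx$params$w
  t <- cfg$t
  max_occ <- if (is.null(cfg$freq_exclude)) idx$params$max_occ else
    as.integer(cfg$freq_exclude)
  # patterned prefix long enough to yield ~t minimizers at density 2/(w+1)
  prefix <- k + w - 1L + as.integer(ceiling(t * (w + 1) / 2))
  L <- length(codes)
  sums <- numeric(P$p)
  for (s in seq_len(P$p) - 1L) {
    pos <- pattern_positions(P, s, L)
    if (length(pos) > prefix) pos <- pos[seq_len(prefix)]
    if (length(pos) < k) next
    mm <- extract_minimizers_cpp(codes[pos + 1L], pos, k, w)
    h <- mm$hash
    if (length(h) > t) h <- h[seq_len(t)]
    if (length(h) == 0L) next
    j <- hash_lookup(idx, h)
    occ <- ifelse(is.na(j), 0L, idx$occ[pmax(j, 1L)])
    occ[occ > max_occ] <- 0L
    sums[s + 1L] <- sum(occ)
  }
  sums
}

#' Choose the pattern phase of a read (pattern alignment)
#'
#' For each shift `s` in `[0, p)` the diet pattern is shifted and applied to
#' the read, at most `t` minimizers are extracted from the patterned prefix,
#' and their index occurrence frequencies are summed (hyper-frequent seeds
#' contribute 0). The returned alignment index is the shift with the highest
#' sum; ties break to the smallest shift and a read with no matching seeds
#' gets shift 0.
#'
#' @param read read sequence (string or [encode_sequence()] object).
#' @param P diet pattern used to build the index.
#' @param idx the [build_index()] object.
#' @param cfg a [pattern_align_config()].
#' @return integer alignment index `a` in `[0, p)`.
#' @export
pattern_align <- function(read, P, idx, cfg = pattern_align_config()) {
  P <- parse_pattern(P)
  codes <- if (inherits(read, "encoded_sequence")) read$codes else
    encode_bases_cpp(read)
  if (P$p == 1L) return(0L)
  sums <- pattern_align_sums(codes, P, idx, cfg)
  which.max(sums) - 1L
}

#' Sparsify and sketch a read at its alignment index (compressed seeding)
#'
#' Minimizers of `apply_pattern(P, a, read)` with positions in original read
#' coordinates.
#'
#' @inheritParams pattern_align
#' @param a alignment index from [pattern_align()].
#' @param k,w seed length and minimizer window.
#' @return minimizer data.frame as from [extract_minimizers()].
#' @export
compressed_seed <- function(read, P, a, k, w) {
  P <- parse_pattern(P)
  a <- check_shift(P, a)
  codes <- if (inherits(read, "encoded_sequence")) read$codes else
    encode_bases_cpp(read)
  pos <- pattern_positions(P, a, length(codes))
  extract_minimizers_cpp(codes[pos + 1L], pos, as.integer(k), as.integer(w))
}

#' Adjusted, merged and sorted seed hits of a read
#'
#' Each read minimizer retrieves its sorted index location list; every hit is
#' adjusted to `delta = ref_pos - read_pos` so that hits from the same mapping
#' location agree on delta. Reverse-strand matches (reference and read seed on
#' opposite canonical strands) measure the read position from the read's
#' reverse complement. The per-seed sorted lists are merged into one list
#' sorted by (strand, ref, delta) with duplicate (delta, ref_pos, read_pos)
#' triples dropped.
#'
#' @param read_minis minimizer data.frame from [compressed_seed()].
#' @param idx the seed index.
#' @param read_len read length in bases (needed for reverse-strand positions).
#' @return data.frame of hits: `strand` (0 forward / 1 reverse), `ref`,
#'   `delta`, `ref_pos`, `read_pos`, `span`.
#' @export
adjust_and_sort_hits <- function(read_minis, idx, read_len) {
  empty <- data.frame(strand = integer(0), ref = integer(0), delta = integer(0),
                      ref_pos = integer(0), read_pos = integer(0),
                      span = integer(0))
  if (nrow(read_minis) == 0L) return(empty)
  j <- hash_lookup(idx, read_minis$hash)
  occ <- ifelse(is.na(j), 0L, idx$occ[pmax(j, 1L)])
  keep <- !is.na(j) & occ > 0L & occ <= idx$params$max_occ
  if (!any(keep)) return(empty)
  jk <- j[keep]
  counts <- idx$occ[jk]
  rows <- sequence(counts, from = idx$start[jk])
  seed <- rep(which(keep), counts)

  ref <- idx$ref_id[rows]
  ref_pos <- idx$pos[rows]
  rstrand <- idx$strand[rows]
  qpos <- read_minis$pos[seed]
  span <- read_minis$span[seed]
  qstrand <- read_minis$strand[seed]

  strand <- as.integer(rstrand != qstrand)
  read_pos <- ifelse(strand == 1L, as.integer(read_len) - qpos - span, qpos)
  delta <- ref_pos - read_pos

  o <- order(strand, ref, delta, ref_pos, read_pos)
  strand <- strand[o]; ref <- ref[o]; delta <- delta[o]
  ref_pos <- ref_pos[o]; read_pos <- read_pos[o]; span <- span[o]
  n <- length(delta)
  dup <- c(FALSE, strand[-1L] == strand[-n] & ref[-1L] == ref[-n] &
                  delta[-1L] == delta[-n] & ref_pos[-1L] == ref_pos[-n] &
                  read_pos[-1L] == read_pos[-n])
  data.frame(strand = strand[!dup], ref = ref[!dup], delta = delta[!dup],
             ref_pos = ref_pos[!dup], read_pos = read_pos[!dup],
             span = span[!dup])
}

# Raw greedy clusters over a sorted hit table.
cluster_hits <- function(hits, D) {
  cluster_hits_cpp(hits$strand, hits$ref, hits$delta, hits$ref_pos,
                   hits$read_pos, hits$span, as.numeric(D))
}

#' Location voting for short reads
#'
#' Greedy left-to-right clustering of the sorted deltas: the first delta
#' anchors a cluster; every hit within `D` of the anchor joins and votes; the
#' first hit beyond `D` opens the next cluster. Clusters with at least `V`
#' votes are kept, sorted by votes (ties: smallest anchor), truncated to
#' `cap`.
#'
#' @param hits sorted hit table from [adjust_and_sort_hits()].
#' @param D maximum allowed distance between a hit and its cluster anchor.
#' @param V voting threshold (minimum votes to win).
#' @param cap maximum number of winning clusters kept.
#' @return data.frame of vote clusters: `strand`, `ref`, `anchor`, `last`,
#'   `votes`, plus the implicated reference/read intervals.
#' @export
vote_short <- function(hits, D, V, cap = 50L) {
  cl <- cluster_hits(hits, D)
  cl <- cl[cl$votes >= V, , drop = FALSE]
  cl <- cl[order(-cl$votes, cl$anchor, cl$ref, cl$strand), , drop = FALSE]
  head(cl, cap)
}

#' Location voting for long reads (subsequence pairs)
#'
#' Same greedy clustering as [vote_short()]; each winning cluster yields the
#' reference interval spanned by its hits (from the smallest implicated
#' reference position to the largest plus the span of that seed) and the
#' corresponding read interval, to be aligned locally.
#'
#' @inheritParams vote_short
#' @param read_len read length; read intervals are clipped to it.
#' @return data.frame of subsequence pairs: `strand`, `ref`, `votes`,
#'   `anchor`, `last`, `ref_begin`, `ref_end`, `read_begin`, `read_end`
#'   (0-based half-open).
#' @export
vote_long <- function(hits, D, V, cap = 50L, read_len) {
  cl <- vote_short(hits, D, V, cap)
  data.frame(strand = cl$strand, ref = cl$ref, votes = cl$votes,
             anchor = cl$anchor, last = cl$last,
             ref_begin = cl$ref_lo, ref_end = cl$ref_hi,
             read_begin = cl$read_lo,
             read_end = pmin(cl$read_hi, as.integer(read_len)))
}

#' Rescue mapping location
#'
#' When no cluster reaches the voting threshold, the single highest-vote
#' cluster is still reported (ties: smallest anchor), keeping sensitivity for
#' reads with few matching seeds. A read with no hits at all stays unmapped.
#'
#' @param all_clusters raw cluster table (e.g. `vote_short(hits, D, V = 1)`
#'   input side), regardless of `V`.
#' @return single-row cluster data.frame, or NULL if there were no clusters.
#' @export
rescue_location <- function(all_clusters) {
  if (is.null(all_clusters) || nrow(all_clusters) == 0L) return(NULL)
  o <- order(-all_clusters$votes, all_clusters$anchor, all_clusters$ref,
             all_clusters$strand)
  all_clusters[o[1L], , drop = FALSE]
}

#' Split an ultra-long read into bounded segments
#'
#' Consecutive non-overlapping segments of at most `limit` bases; offsets are
#' recorded so records can be lifted back to full-read coordinates.
#'
#' @param read read sequence string.
#' @param limit maximum segment length (default 30000 bases).
#' @return data.frame with `seq` and 0-based `offset` per segment.
#' @export
segment_ultralong <- function(read, limit = 30000L) {
  L <- nchar(read)
  limit <- as.integer(limit)
  if (limit < 1L) stop("limit must be >= 1")
  if (L <= limit) return(data.frame(seq = read, offset = 0L,
                                    stringsAsFactors = FALSE))
  starts <- seq(0L, L - 1L, by = limit)
  data.frame(seq = substring(read, starts + 1L, pmin(starts + limit, L)),
             offset = starts, stringsAsFactors = FALSE)
}
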