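# Independent reference implementations used as oracles. They are written
# against the definitions, not against the package internals: plain R loops,
# utils::adist, Biostrings::pairwiseAlignment.

random_seq <- function(n, gc = 0.5) {
  if (n == 0) return("")
  simulate_genome(n, gc = gc)[[1L]]
}

# Brute-force double-strand (w,k)-minimizer extraction over a patterned
# sequence: per N-free run, score every k-mer on its canonical strand and
# take the window minima by direct scanning (keeping ties).
oracle_minimizers <- function(bases, origin, k, w) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  out <- data.frame(hash = numeric(0), pos = integer(0), span = integer(0),
                    strand = integer(0))
  n <- length(chars)
  run_start <- 1L
  flush <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < k) return(NULL)
    codes <- match(chars[lo:hi], c("A", "C", "G", "T")) - 1L
    nk <- len - k + 1L
    hash <- rep(NA_real_, nk); strand <- integer(nk)
    for (i in seq_len(nk)) {
      cc <- codes[i:(i + k - 1L)]
      fwd <- sum(cc * 4^((k - 1L):0))
      rev <- sum((3 - rev(cc)) * 4^((k - 1L):0))
      if (fwd < rev) { hash[i] <- hash_kmer(fwd, k); strand[i] <- 0L }
      else if (rev < fwd) { hash[i] <- hash_kmer(rev, k); strand[i] <- 1L }
    }
    nw <- if (nk >= w) nk - w + 1L else 1L
    wl <- min(w, nk)
    emitted <- logical(nk)
    rows <- list()
    for (ws in seq_len(nw)) {
      win <- ws:(ws + wl - 1L)
      hv <- hash[win]
      if (all(is.na(hv))) next
      best <- min(hv, na.rm = TRUE)
      for (i in win[!is.na(hv) & hv == best]) {
        if (emitted[i]) next
        emitted[i] <- TRUE
        gi <- lo + i - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          hash = hash[i], pos = origin[gi],
          span = origin[gi + k - 1L] - origin[gi] + 1L, strand = strand[i])
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  for (i in seq_len(n + 1L)) {
    if (i > n || chars[i] == "N") {
      if (i > run_start) {
        blk <- flush(run_start, i - 1L)
        if (!is.null(blk)) out <- rbind(out, blk)
      }
      run_start <- i + 1L
    }
  }
  out
}

sort_minis <- function(df) {
  df <- df[order(df$pos, df$strand, df$hash), ]
  rownames(df) <- NULL
  df
}

# Quadratic greedy clustering oracle over a sorted hit table.
oracle_clusters <- function(hits, D) {
  rows <- list()
  key <- paste(hits$strand, hits$ref)
  for (g in unique(key)) {
    h <- hits[key == g, , drop = FALSE]
    i <- 1L
    while (i <= nrow(h)) {
      anchor <- h$delta[i]
      members <- i
      j <- i + 1L
      while (j <= nrow(h) && h$delta[j] - anchor <= D) {
        members <- c(members, j)
        j <- j + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strand = h$strand[i], ref = h$ref[i], anchor = anchor,
        last = h$delta[max(members)], votes = length(members))
      i <- j
    }
  }
  do.call(rbind, rows)
}

# Random sorted hit tables for voting tests.
random_hits <- function(n, n_ref = 2, span_max = 1000) {
  hits <- data.frame(
    strand = sample(0:1, n, replace = TRUE),
    ref = sample.int(n_ref, n, replace = TRUE),
    delta = sample.int(span_max, n, replace = TRUE),
    ref_pos = sample.int(span_max * 2L, n, replace = TRUE),
    read_pos = sample.int(200L, n, replace = TRUE),
    span = sample(15:40, n, replace = TRUE))
  hits <- unique(hits)
  hits[order(hits$strand, hits$ref, hits$delta, hits$ref_pos), ]
}

biostrings_score <- function(a, b, scoring, type) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = -scoring$mismatch, baseOnly = TRUE)
  sc <- Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = submat, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, type = type))
  if (type == "local") max(0, sc) else sc
}
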