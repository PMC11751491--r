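#' Build a sparsified seed index
#'
#' Applies the diet pattern at shift 0 to each reference, extracts
#' double-strand (w,k)-minimizers of the patterned sequence, accumulates
#' (hash, location) records in one array, sorts it once and groups it into a
#' lookup table - the array-then-sort construction used by minimizer read
#' mappers. Stored locations are always coordinates of the original,
#' unpatterned reference. References longer than `batch_bases` are processed
#' in chunks with a `(k + w) * p` overlap so no minimizer is lost; chunk
#' masking keeps the global pattern phase.
#'
#' @param refs named character vector of reference sequences (or a
#'   `DNAStringSet`, or a data.frame with `name`/`seq` columns).
#' @param pattern diet pattern (string or [parse_pattern()] object).
#' @param k,w seed length and minimizer window.
#' @param max_occ seeds occurring more than this many times are ignored at
#'   query time (repeat masking).
#' @param batch_bases maximum original bases processed per extraction batch.
#' @param keep_sequences keep the original sequences in the index (required
#'   for base-level alignment; disable for containment-only use).
#' @return a `seed_index` object.
#' @examples
#' idx <- build_index(c(chr1 = "ACGTACGTACGTACGTACGTACGT"), "10", k = 4, w = 2)
#' index_stats(idx)
#' @export
build_index <- function(refs, pattern, k = 19L, w = 16L, max_occ = 500L,
                        batch_bases = 1e8, keep_sequences = TRUE) {
  refs <- as_named_seqs(refs)
  if (length(refs) == 0L) stop("empty reference set")
  P <- parse_pattern(pattern)
  k <- as.integer(k); w <- as.integer(w)
  if (k > 28L) stop("k must be <= 28")
  if (batch_bases < k * P$p) stop("batch_bases must be >= k * p")
  refs <- toupper(refs)
  lengths <- nchar(refs)

  overlap <- (k + w) * P$p
  ref_codes <- vector("list", length(refs))
  recs <- list()
  for (j in seq_along(refs)) {
    codes <- encode_bases_cpp(refs[[j]])
    ref_codes[[j]] <- codes
    L <- lengths[[j]]
    starts <- seq(0L, max(L - 1L, 0L), by = as.integer(batch_bases))
    chunks <- lapply(starts, function(o) {
      end <- min(L, o + batch_bases + overlap)
      pos <- pattern_positions(P, o %% P$p, as.integer(end - o)) + o
      mm <- extract_minimizers_cpp(codes[pos + 1L], as.integer(pos), k, w)
      data.table(hash = mm$hash, ref = j, pos = mm$pos,
                 span = mm$span, strand = mm$strand)
    })
    recs[[j]] <- unique(rbindlist(chunks))
  }
  dt <- rbindlist(recs)
  dt <- dt[order(dt$hash, dt$ref, dt$pos, dt$strand), ]

  new_hash <- c(TRUE, dt$hash[-1L] != dt$hash[-nrow(dt)])
  if (nrow(dt) == 0L) new_hash <- logical(0)
  start <- which(new_hash)
  occ <- diff(c(start, nrow(dt) + 1L))
  structure(
    list(hash = dt$hash[new_hash], start = start, occ = as.integer(occ),
         ref_id = dt$ref, pos = dt$pos, span = dt$span, strand = dt$strand,
         params = list(pattern = paste(P$bits, collapse = ""), k = k, w = w,
                       max_occ = as.integer(max_occ)),
         ref_names = names(refs), lengths = setNames(lengths, names(refs)),
         sequences = if (keep_sequences) refs else NULL,
         ref_codes = if (keep_sequences) ref_codes else NULL),
    class = "seed_index")
}

as_named_seqs <- function(refs) {
  if (methods::is(refs, "DNAStringSet") || methods::is(refs, "BStringSet")) {
    out <- as.character(refs)
  } else if (is.data.frame(refs)) {
    out <- setNames(as.character(refs$seq), refs$name)
  } else out <- refs
  if (!is.character(out)) stop("references must be character sequences")
  if (length(out) == 0L) return(out)
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- paste0("ref", seq_along(out))
  out
}

#' @export
format.seed_index <- function(x, ...) {
  sprintf("<seed_index %d refs, %d distinct hashes, %d locations, P=%s k=%d w=%d>",
          length(x$ref_names), length(x$hash), length(x$pos),
          x$params$pattern, x$params$k, x$params$w)
}

#' @export
print.seed_index <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# Vectorized lookup: row index of each hash in the sorted table, NA if absent.
hash_lookup <- function(idx, h) {
  if (length(idx$hash) == 0L) return(rep(NA_integer_, length(h)))
  j <- findInterval(h, idx$hash)
  j[j == 0L | idx$hash[pmax(j, 1L)] != h] <- NA_integer_
  j
}

#' Query the index for one seed hash
#'
#' Returns the sorted location list of a hash, empty if the hash is absent or
#' occurs more than `max_occ` times (frequency filtering).
#'
#' @param idx a [build_index()] object.
#' @param h a single hash value.
#' @return data.frame with columns `ref`, `pos`, `span`, `strand`, sorted by
#'   (ref, pos).
#' @export
query_index <- function(idx, h) {
  j <- hash_lookup(idx, h[1L])
  empty <- data.frame(ref = integer(0), pos = integer(0),
                      span = integer(0), strand = integer(0))
  if (is.na(j) || idx$occ[j] > idx$params$max_occ) return(empty)
  rows <- idx$start[j] + seq_len(idx$occ[j]) - 1L
  data.frame(ref = idx$ref_id[rows], pos = idx$pos[rows],
             span = idx$span[rows], strand = idx$strand[rows])
}

#' Occurrence frequency of a seed hash
#'
#' The stored occurrence count, or 0 when the hash is absent or hyper-frequent
#' (`occ > max_occ`), so frequent seeds cannot dominate frequency sums in
#' pattern alignment.
#'
#' @inheritParams query_index
#' @param h hash value(s).
#' @return integer vector of counts.
#' @export
seed_occurrence <- function(idx, h) {
  j <- hash_lookup(idx, h)
  occ <- ifelse(is.na(j), 0L, idx$occ[pmax(j, 1L)])
  occ[occ > idx$params$max_occ] <- 0L
  as.integer(occ)
}

#' Summary statistics of a seed index
#'
#' @inheritParams query_index
#' @return list with `distinct_hashes`, `total_locations` and `density`
#'   (locations per original reference base).
#' @export
index_stats <- function(idx) {
  total_len <- sum(idx$lengths)
  list(distinct_hashes = length(idx$hash),
       total_locations = length(idx$pos),
       density = if (total_len > 0) length(idx$pos) / total_len else 0)
}

#' Save / load a seed index
#'
#' The index is written as a versioned serialized container; the magic string
#' and format version are checked on load, and [map_reads()] refuses an index
#' whose pattern or (k, w) disagree with the requested parameters.
#'
#' @param idx a `seed_index`.
#' @param path file path.
#' @return `load_index` returns the `seed_index`; `save_index` its path,
#'   invisibly.
#' @export
save_index <- function(idx, path) {
  stopifnot(inherits(idx, "seed_index"))
  saveRDS(list(magic = "sparsemap-seed-index", version = 1L, index = idx),
          path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a sparsemap index file: ", path))
  if (!is.list(obj) || !identical(obj$magic, "sparsemap-seed-index"))
    stop("not a sparsemap index file: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported index format version: ", obj$version)
  obj$index
}
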