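make_test_index <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- simulate_genome(100000, seed = 51, name = "chr1")
      cache <<- list(g = g, idx = build_index(g, "10", k = 15, w = 8))
    }
    cache
  }
})

test_that("pattern alignment recovers the phase of verbatim reads", {
  tc <- make_test_index()
  P <- parse_pattern("10")
  set.seed(52)
  n_ok <- 0L
  for (i in 1:100) {
    o <- sample(0:(100000 - 200), 1)
    read <- substr(tc$g[[1]], o + 1, o + 200)
    a <- pattern_align(read, P, tc$idx)
    if (a == o %% 2L) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 99L)
  # single-phase pattern always returns 0; so does an all-N read
  expect_equal(pattern_align(read, parse_pattern("1"), tc$idx), 0L)
  expect_equal(pattern_align(strrep("N", 100), P, tc$idx), 0L)
})

test_that("compressed seeding of an exact read finds indexed seeds", {
  tc <- make_test_index()
  P <- parse_pattern("10")
  read <- substr(tc$g[[1]], 5001, 5300)
  a <- pattern_align(read, P, tc$idx)
  mm <- compressed_seed(read, P, a, 15, 8)
  expect_gt(nrow(mm), 0)
  expect_gt(sum(seed_occurrence(tc$idx, mm$hash) > 0), 0)
  # patterned read shorter than k yields nothing
  expect_equal(nrow(compressed_seed("ACGTACGT", P, 0L, 15, 8)), 0L)
  # identity pattern reduces to plain sketching
  plain <- extract_minimizers(read, 15, 8)
  viaP <- compressed_seed(read, parse_pattern("11"), 0L, 15, 8)
  expect_equal(sort(viaP$hash), sort(plain$hash))
})

test_that("adjusted hits equal a comparison sort of the concatenation", {
  tc <- make_test_index()
  read <- substr(tc$g[[1]], 40001, 40400)
  mm <- compressed_seed(read, parse_pattern("10"), 0L, 15, 8)
  hits <- adjust_and_sort_hits(mm, tc$idx, nchar(read))
  expect_gt(nrow(hits), 0)
  # invariant delta = ref_pos - read_pos
  expect_equal(hits$delta, hits$ref_pos - hits$read_pos)
  # sortedness within (strand, ref)
  o <- order(hits$strand, hits$ref, hits$delta)
  expect_equal(o, seq_len(nrow(hits)))
  # no duplicated (strand, ref, delta, ref_pos, read_pos)
  expect_false(any(duplicated(
    hits[, c("strand", "ref", "delta", "ref_pos", "read_pos")])))
  # oracle: rebuild by naive concatenation + generic sort
  naive <- do.call(rbind, lapply(seq_len(nrow(mm)), function(i) {
    loc <- query_index(tc$idx, mm$hash[i])
    if (nrow(loc) == 0) return(NULL)
    strand <- as.integer(loc$strand != mm$strand[i])
    rp <- ifelse(strand == 1L, nchar(read) - mm$pos[i] - mm$span[i], mm$pos[i])
    data.frame(strand = strand, ref = loc$ref, delta = loc$pos - rp,
               ref_pos = loc$pos, read_pos = rp, span = mm$span[i])
  }))
  naive <- unique(naive[order(naive$strand, naive$ref, naive$delta,
                              naive$ref_pos, naive$read_pos), ])
  rownames(naive) <- NULL
  expect_equal(hits[, colnames(naive)], naive)
})

test_that("voting equals the quadratic clustering oracle on random hits", {
  set.seed(53)
  for (case in 1:100) {
    hits <- random_hits(sample(1:60, 1))
    D <- sample(c(5, 30, 100, 250), 1)
    got <- sparsemap:::cluster_hits(hits, D)
    want <- oracle_clusters(hits, D)
    expect_equal(got[, c("strand", "ref", "anchor", "last", "votes")],
                 want, ignore_attr = TRUE, info = paste("case", case))
    # cluster width never exceeds D
    expect_true(all(got$last - got$anchor <= D))
  }
})

test_that("vote_short applies threshold, ordering and cap", {
  hits <- data.frame(strand = 0L, ref = 1L,
                     delta = c(100L, 101L, 150L, 400L),
                     ref_pos = c(100L, 101L, 150L, 400L),
                     read_pos = 0L, span = 15L)
  cl <- vote_short(hits, D = 60, V = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$votes, 3L)
  expect_equal(cl$anchor, 100L)
  cl2 <- vote_short(data.frame(strand = 0L, ref = 1L, delta = c(0L, 200L),
                               ref_pos = c(0L, 200L), read_pos = 0L,
                               span = 15L), D = 100, V = 1)
  expect_equal(cl2$votes, c(1L, 1L))
  expect_equal(nrow(vote_short(hits, D = 60, V = 2, cap = 0L)), 0L)
})

test_that("voting is monotone in V and D", {
  set.seed(54)
  hits <- random_hits(80)
  for (D in c(10, 50, 200)) {
    n_prev <- Inf
    for (V in 1:4) {
      n <- nrow(vote_short(hits, D, V, cap = 1000L))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
  n_cl <- vapply(c(5, 20, 80, 320), function(D)
    nrow(sparsemap:::cluster_hits(hits, D)), numeric(1))
  expect_true(all(diff(n_cl) <= 0))
})

test_that("rescue returns the best sub-threshold cluster", {
  hits <- data.frame(strand = 0L, ref = 1L,
                     delta = c(10L, 11L, 500L),
                     ref_pos = c(10L, 11L, 500L), read_pos = 0L, span = 15L)
  all_cl <- sparsemap:::cluster_hits(hits, D = 50)
  expect_equal(nrow(vote_short(hits, D = 50, V = 3)), 0L)
  r <- rescue_location(all_cl)
  expect_equal(r$votes, 2L)
  expect_equal(r$anchor, 10L)
  # tie on votes -> smallest delta
  tie <- data.frame(strand = 0L, ref = 1L, delta = c(900L, 100L),
                    ref_pos = c(900L, 100L), read_pos = 0L, span = 15L)
  tie <- tie[order(tie$delta), ]
  expect_equal(rescue_location(sparsemap:::cluster_hits(tie, 50))$anchor, 100L)
  expect_null(rescue_location(sparsemap:::cluster_hits(tie[0, ], 50)))
})

test_that("vote_long emits subsequence pairs with sane intervals", {
  tc <- make_test_index()
  read <- substr(tc$g[[1]], 20001, 25000)
  mm <- compressed_seed(read, parse_pattern("10"), 0L, 15, 8)
  hits <- adjust_and_sort_hits(mm, tc$idx, nchar(read))
  pairs <- vote_long(hits, D = 500, V = 3, read_len = nchar(read))
  expect_gte(nrow(pairs), 1L)
  top <- pairs[1, ]
  expect_true(top$ref_begin >= 20000 - 50 && top$ref_end <= 25000 + 50)
  expect_true(top$read_begin >= 0 && top$read_end <= nchar(read))
  expect_true(all(pairs$read_end > pairs$read_begin))
  expect_true(all(pairs$ref_end > pairs$ref_begin))
})

test_that("ultralong reads are segmented losslessly", {
  read <- random_seq(65000)
  segs <- segment_ultralong(read, 30000)
  expect_equal(nchar(segs$seq), c(30000L, 30000L, 5000L))
  expect_equal(segs$offset, c(0L, 30000L, 60000L))
  expect_equal(paste(segs$seq, collapse = ""), read)
  one <- segment_ultralong(read, 70000)
  expect_equal(nrow(one), 1L)
})

test_that("exact reads recover their origin through the full pipeline", {
  tc <- make_test_index()
  reads <- simulate_reads(tc$g, 200, 150, seed = 55)
  recs <- map_reads(reads, tc$idx, mode = "sr")
  prim <- recs[recs$category == "primary", ]
  truth <- parse_read_truth(prim$qname)
  expect_gte(mean(prim$pos - 1L == truth$pos), 0.99)
  expect_equal(prim$strand == 1L, truth$strand == "-")
})
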