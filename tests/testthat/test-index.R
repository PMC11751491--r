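test_that("identity pattern reproduces the plain minimizer index", {
  g <- simulate_genome(10000, seed = 41, name = "chr1")
  idx <- build_index(g, "11", k = 15, w = 8)
  mm <- extract_minimizers(g[[1]], 15, 8)
  expect_equal(length(idx$pos), nrow(mm))
  expect_setequal(paste(idx$pos, idx$strand), paste(mm$pos, mm$strand))
  expect_equal(sum(idx$occ), nrow(mm))  # conservation
})

test_that("batched builds equal the unbatched build", {
  g <- simulate_genome(30000, seed = 42, name = "chr1")
  one <- build_index(g, "101001", k = 13, w = 5)
  two <- build_index(g, "101001", k = 13, w = 5, batch_bases = 7000)
  expect_equal(one$hash, two$hash)
  expect_equal(one$pos, two$pos)
  expect_equal(one$strand, two$strand)
  expect_equal(one$occ, two$occ)
})

test_that("query_index and seed_occurrence apply frequency filtering", {
  g <- c(chrA = paste(rep("ACGTGATC", 300), collapse = ""))
  idx <- build_index(g, "11", k = 8, w = 1, max_occ = 10)
  # highly repetitive genome: every hash exceeds max_occ
  expect_true(all(idx$occ > 10))
  expect_equal(nrow(query_index(idx, idx$hash[1])), 0L)
  expect_equal(seed_occurrence(idx, idx$hash[1]), 0L)
  # absent hash
  absent <- setdiff(0:100, idx$hash)[1]
  expect_equal(nrow(query_index(idx, absent)), 0L)
  expect_equal(seed_occurrence(idx, absent), 0L)
})

test_that("all genome minimizers query back to their own positions", {
  g <- simulate_genome(20000, seed = 43, name = "chr1")
  idx <- build_index(g, "10", k = 15, w = 8)
  ps <- apply_pattern(parse_pattern("10"), 0, g[[1]])
  mm <- extract_minimizers(ps, 15, 8)
  hit <- vapply(seq_len(nrow(mm)), function(i) {
    loc <- query_index(idx, mm$hash[i])
    any(loc$pos == mm$pos[i] & loc$strand == mm$strand[i])
  }, logical(1))
  # hyper-frequent seeds are legitimately filtered out
  occ <- seed_occurrence(idx, mm$hash)
  expect_true(all(hit[occ > 0]))
  # per-hash lists are sorted by (ref, pos)
  loc <- query_index(idx, mm$hash[1])
  expect_false(is.unsorted(loc$pos))
})

test_that("stored coordinates re-hash to their own key", {
  g <- simulate_genome(3000, seed = 44, name = "chr1")
  P <- parse_pattern("110")
  idx <- build_index(g, "110", k = 9, w = 4)
  ps <- apply_pattern(P, 0, g[[1]])
  for (j in seq_len(min(50, length(idx$hash)))) {
    pos <- idx$pos[idx$start[j]]
    i <- match(pos, ps$origin_positions)
    kmer <- substr(ps$bases, i, i + 8L)
    cc <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T")) - 1L
    fwd <- sum(cc * 4^(8:0))
    rev <- sum((3 - rev(cc)) * 4^(8:0))
    expect_equal(hash_kmer(min(fwd, rev), 9), idx$hash[j])
  }
})

test_that("index statistics and density behave", {
  expect_error(build_index(character(0), "10"), "empty reference")
  g <- simulate_genome(5000, seed = 45, name = "chr1")
  idx <- build_index(g, "11", k = 15, w = 1)
  st <- index_stats(idx)
  expect_equal(st$total_locations, 5000 - 15 + 1)
  dens <- vapply(c(2L, 6L, 12L), function(w)
    index_stats(build_index(g, "11", k = 15, w = w))$density, numeric(1))
  expect_true(all(diff(dens) < 0))  # density decreases with w
})

test_that("index round-trips through the serialized container", {
  g <- simulate_genome(8000, seed = 46, name = "chr1")
  idx <- build_index(g, "10", k = 15, w = 8)
  path <- tempfile(fileext = ".rds")
  save_index(idx, path)
  idx2 <- load_index(path)
  expect_equal(idx2, idx)
  reads <- simulate_reads(g, 20, 150, seed = 47)
  expect_equal(map_reads(reads, idx2), map_reads(reads, idx))
  # wrong container rejected
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(magic = "other"), bad)
  expect_error(load_index(bad), "not a sparsemap index")
})

test_that("an index built without sequences cannot align", {
  g <- simulate_genome(8000, seed = 48, name = "chr1")
  idx <- build_index(g, "10", k = 15, w = 8, keep_sequences = FALSE)
  reads <- simulate_reads(g, 3, 150, seed = 49)
  expect_error(map_reads(reads, idx), "without sequences")
  expect_silent(recs <- map_reads(reads, idx, align = FALSE))
  expect_true(all(recs$cigar == "*"))
})
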