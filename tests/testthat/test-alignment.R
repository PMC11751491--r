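test_that("exact-match filter agrees with character comparison", {
  a <- random_seq(150)
  expect_true(exact_match_filter(a, a))
  b <- mutate_sequence(a, 1, seed = 61)
  expect_false(exact_match_filter(a, b))
  set.seed(62)
  for (i in 1:20) {
    x <- random_seq(60)
    y <- if (runif(1) < 0.5) x else mutate_sequence(x, sample(1:3, 1))
    expect_equal(exact_match_filter(x, y),
                 identical(strsplit(x, "")[[1]], strsplit(y, "")[[1]]))
  }
  expect_error(exact_match_filter("ACG", "ACGT"), "equal length")
})

test_that("global alignment handles identity and single mismatches", {
  sc <- scoring_scheme(2, 4, 4, 2)
  a <- random_seq(80)
  r <- banded_global_align(a, a, sc, band = 8)
  expect_equal(r$score, 2L * 80L)
  expect_equal(r$cigar, "80M")
  b <- mutate_sequence(a, 1, seed = 63)
  r1 <- banded_global_align(a, b, sc, band = 8)
  expect_equal(r1$score, 2L * 79L - 4L)
  expect_equal(r1$cigar, "80M")
  expect_equal(r1$n_mismatch, 1L)
  expect_error(banded_global_align("", a, sc), "empty")
})

test_that("wide-band global alignment equals the full-matrix oracle", {
  set.seed(64)
  sc <- scoring_scheme(2, 4, 4, 2)
  for (i in 1:100) {
    m <- sample(5:200, 1)
    a <- random_seq(m)
    b <- if (runif(1) < 0.5) {
      bb <- mutate_sequence(a, sample(0:6, 1))
      # also exercise indels by dropping/adding a small slice
      if (runif(1) < 0.5) paste0(substr(bb, 1, m %/% 2),
                                 substr(bb, m %/% 2 + sample(1:3, 1), m))
      else bb
    } else random_seq(sample(5:200, 1))
    r <- banded_global_align(a, b, sc, band = nchar(a) + nchar(b))
    expect_equal(r$score, biostrings_score(a, b, sc, "global"),
                 info = paste("pair", i))
    cc <- sparsemap:::cigar_consumes(r$cigar)
    expect_equal(cc$query, nchar(a))
    expect_equal(cc$ref, nchar(b))
  }
})

test_that("local alignment finds embedded matches and ignores noise", {
  sc <- scoring_scheme(2, 4, 4, 2)
  core <- random_seq(50)
  ref <- paste0(random_seq(70), core, random_seq(70))
  r <- banded_local_align(core, ref, sc, band = 300)
  expect_equal(r$score, 100L)
  expect_equal(r$read_begin, 0L)
  expect_equal(r$read_end, 50L)
  # empirical null: unrelated pairs score near zero
  set.seed(65)
  null_scores <- replicate(30, {
    banded_local_align(random_seq(100), random_seq(100), sc, band = 200)$score
  })
  expect_lt(max(null_scores), 30)
  # wide band equals the unbanded oracle
  for (i in 1:30) {
    a <- random_seq(sample(20:120, 1)); b <- random_seq(sample(20:120, 1))
    r <- banded_local_align(a, b, sc, band = nchar(a) + nchar(b))
    expect_equal(r$score, biostrings_score(a, b, sc, "local"))
  }
})

test_that("pair concatenation bridges gaps and splits far-apart pairs", {
  sc <- scoring_scheme(2, 4, 4, 2)
  # construct a read whose two halves flank a clean 500-base deletion
  left <- random_seq(400); mid <- random_seq(500); right <- random_seq(400)
  ref <- c(ref1 = paste0(left, mid, right))
  read <- paste0(left, right)
  results <- data.frame(
    ref = 1L, strand = 0L, votes = c(10L, 10L),
    score = c(800L, 800L), cigar = c("400M", "400M"),
    ref_begin = c(0L, 900L), ref_end = c(400L, 1300L),
    read_begin = c(0L, 400L), read_end = c(400L, 800L),
    n_match = c(400L, 400L), n_mismatch = 0L, n_ins = 0L, n_del = 0L)
  merged <- concat_pair_cigars(results, read, ref, sc)
  expect_equal(nrow(merged), 1L)
  expect_match(merged$cigar, "500D")
  cc <- sparsemap:::cigar_consumes(merged$cigar)
  expect_equal(cc$query, 800)
  expect_equal(cc$ref, 1300)
  # merged score >= parts minus the bridged gap penalty
  expect_gte(merged$score, 1600 - (sc$gap_open + sc$gap_extend * 500))
  # beyond the 50 kb threshold the pairs stay separate
  far <- results; far$ref_begin[2] <- 60000L; far$ref_end[2] <- 60400L
  ref_far <- c(ref1 = paste0(left, strrep("A", 59200), right))
  expect_equal(nrow(concat_pair_cigars(far, read, ref_far, sc)), 2L)
  # overlapping read intervals keep the higher-scoring pair
  ovl <- results; ovl$read_begin[2] <- 100L; ovl$score[2] <- 300L
  expect_equal(concat_pair_cigars(ovl, read, ref, sc)$score, 800L)
})

test_that("classification follows the 80% pair-length rule", {
  res <- data.frame(score = 100, read_begin = 0L, read_end = 1000L)
  expect_equal(classify_alignments(res)$category, "primary")
  res2 <- data.frame(score = c(100, 60, 90),
                     read_begin = c(0L, 0L, 0L),
                     read_end = c(1000L, 500L, 950L))
  cl <- classify_alignments(res2)$category
  expect_equal(cl, c("primary", "supplementary", "secondary"))
})

test_that("MAPQ surrogate is bounded, deterministic and monotone", {
  expect_equal(compute_mapq(list(score = 300, votes = 15, identity = 1)), 60L)
  # two equal-score candidates cap at 20
  q <- compute_mapq(list(score = 300, votes = 15, identity = 1),
                    list(score = 300))
  expect_lte(q, 20L)
  qs <- vapply(seq(0, 300, by = 50), function(s2)
    compute_mapq(list(score = 300, votes = 15, identity = 1),
                 list(score = s2)), integer(1))
  expect_true(all(diff(qs) <= 0))
  expect_equal(compute_mapq(list(score = 0, votes = 1, identity = 0)), 0L)
})

test_that("SAM output is spec-conformant and parses externally", {
  skip_if_not_installed("Rsamtools")
  g <- simulate_genome(40000, seed = 66, name = "chrT")
  idx <- build_index(g, "10", k = 15, w = 8)
  reads <- simulate_reads(g, 40, 150, sub_rate = 0.01, seed = 67)
  reads <- rbind(reads, data.frame(name = "junk", seq = random_seq(150),
                                   qual = NA_character_))
  recs <- map_reads(reads, idx, mode = "sr", rescue = FALSE)
  # CIGAR consumption invariant on every mapped record
  mapped <- recs[recs$category != "unmapped", ]
  for (i in seq_len(nrow(mapped))) {
    cc <- sparsemap:::cigar_consumes(mapped$cigar[i])
    expect_equal(cc$query, nchar(mapped$seq[i]))
  }
  # reverse-strand primaries carry flag 16; junk read is flag 4
  expect_true(all(bitwAnd(mapped$flag[mapped$strand == 1L], 16L) == 16L))
  junk <- recs[recs$qname == "junk", ]
  expect_equal(junk$flag, 4L)
  sam <- tempfile(fileext = ".sam")
  write_sam(recs, idx, file = sam)
  expect_error(write_sam(transform(recs, rname = "nope"), idx, file = sam),
               "unknown reference")
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  ali <- Rsamtools::scanBam(bam)[[1]]
  prim <- recs[recs$category == "primary", ]
  got <- ali$pos[!is.na(ali$pos) &
                 !bitwAnd(ali$flag, 256L) & !bitwAnd(ali$flag, 2048L)]
  expect_setequal(got, prim$pos)
  # PAF coordinates round-trip the reference interval
  paf <- tempfile(fileext = ".paf")
  write_paf(recs, idx, file = paf)
  flds <- strsplit(readLines(paf), "\t")
  expect_true(all(vapply(flds, function(f)
    as.integer(f[9]) > as.integer(f[8]), logical(1))))
})

test_that("reads with substitutions and indels map to their origin", {
  g <- simulate_genome(60000, seed = 68, name = "chr1")
  idx <- build_index(g, "10", k = 15, w = 8)
  reads <- simulate_reads(g, 100, 150, sub_rate = 0.01, indel_rate = 0.001,
                          seed = 69)
  recs <- map_reads(reads, idx, mode = "sr")
  prim <- recs[recs$category == "primary", ]
  truth <- parse_read_truth(prim$qname)
  ref_end <- prim$pos - 1L + vapply(prim$cigar, function(cg)
    sparsemap:::cigar_consumes(cg)$ref, numeric(1))
  overlap <- prim$rname == truth$ref &
    prim$pos - 1L < truth$pos + 150L & ref_end > truth$pos
  expect_gte(mean(overlap), 0.95)
})
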