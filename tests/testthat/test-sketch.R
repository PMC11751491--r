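test_that("encoding round-trips and rejects bad symbols", {
  e <- encode_sequence("ACGT")
  expect_equal(e$codes, 0:3)
  expect_length(e$ambiguous, 0)
  expect_equal(encode_sequence("ANT")$ambiguous, 1L)
  s <- "ACGTNNACGTN"
  expect_equal(decode_sequence(encode_sequence(s)), s)
  expect_error(encode_sequence("ACGU"), "invalid base")
})

test_that("k-mer hashing is a deterministic bijection", {
  h <- hash_kmer(0:255, 4)
  expect_equal(sort(h), as.numeric(0:255))     # permutation of the domain
  expect_identical(h, hash_kmer(0:255, 4))     # deterministic
  # vectors frozen from an independent implementation of the Wang finalizer
  expect_equal(hash_kmer(c(0, 1, 12345, 9999999, 268435455), 14),
               c(268180411, 127891685, 243928645, 56741102, 140788883))
  expect_error(hash_kmer(0, 29), "k must be")
})

test_that("w=1 keeps every valid k-mer and N restarts the scan", {
  s <- random_seq(80)
  mm <- extract_minimizers(s, k = 7, w = 1)
  expect_equal(nrow(mm), nchar(s) - 7 + 1)
  expect_equal(mm$pos, 0:(nchar(s) - 7))
  # no minimizer spans the N
  sN <- paste0(substr(s, 1, 20), "N", substr(s, 22, 80))
  mmN <- extract_minimizers(sN, k = 7, w = 1)
  expect_false(any(mmN$pos <= 20 & mmN$pos + 6 >= 20))
  # all-seeds hashes equal w=1 minimizer hashes on palindrome-free odd k
  expect_setequal(extract_all_seeds(s, 7), mm$hash)
})

test_that("minimizer extraction matches the brute-force window oracle", {
  set.seed(21)
  for (case in 1:20) {
    pat <- sample(c("11", "10", "110", "101001"), 1)
    s <- random_seq(200)
    if (case %% 4 == 0)  # inject Ns
      s <- paste0(substr(s, 1, 90), "NN", substr(s, 93, 200))
    ps <- apply_pattern(parse_pattern(pat), 0, s)
    k <- sample(c(5L, 7L, 9L), 1)
    w <- sample(c(1L, 3L, 5L, 8L), 1)
    got <- sort_minis(extract_minimizers(ps, k, w))
    want <- sort_minis(oracle_minimizers(ps$bases, ps$origin_positions, k, w))
    expect_equal(got, want, info = sprintf("case=%d pat=%s k=%d w=%d",
                                           case, pat, k, w))
  }
})

test_that("minimizer density on random sequence is about 2/(w+1)", {
  s <- random_seq(200000)
  for (w in c(5L, 10L, 16L)) {
    d <- nrow(extract_minimizers(s, 15L, w)) / nchar(s)
    expect_lt(abs(d - 2 / (w + 1)) / (2 / (w + 1)), 0.2)
  }
})

test_that("chunked extraction with enough overlap preserves minimizers", {
  s <- random_seq(5000)
  k <- 15L; w <- 8L
  whole <- extract_minimizers(s, k, w)
  ov <- w + k - 1L
  cut <- 2500L
  left <- extract_minimizers(substr(s, 1, cut + ov), k, w)
  right <- extract_minimizers(substr(s, cut + 1L, 5000L), k, w)
  right$pos <- right$pos + cut
  merged <- unique(rbind(left, right))
  # interior minimizers unchanged; boundary windows may add a few extras
  expect_true(all(paste(whole$pos, whole$strand) %in%
                  paste(merged$pos, merged$strand)))
})

test_that("reverse complement yields the same canonical hash multiset", {
  s <- random_seq(3000)
  h1 <- sort(extract_minimizers(s, 15L, 1L)$hash)
  h2 <- sort(extract_minimizers(reverse_complement(s), 15L, 1L)$hash)
  expect_equal(h1, h2)
})

test_that("all seeds and spaced seeds honour their counting contracts", {
  s <- random_seq(200)
  expect_length(extract_all_seeds(s, 13), 200 - 13 + 1)
  # a span-10 mask on a length-15 run yields 6 seeds
  run15 <- random_seq(15)
  expect_length(extract_spaced_seeds(run15, "1010101011"), 6)
  # same seed count regardless of mask weight, for equal span
  expect_length(extract_spaced_seeds(run15, "1111111111"), 6)
  # all-ones mask reduces to contiguous k-mers
  expect_equal(extract_spaced_seeds(s, paste(rep("1", 9), collapse = "")),
               extract_all_seeds(s, 9))
  # N splits runs of all-seeds
  sN <- paste0(random_seq(30), "N", random_seq(30))
  expect_length(extract_all_seeds(sN, 10), 2 * (30 - 10 + 1))
})

test_that("spaced seeds equal a position-by-position sampling oracle", {
  set.seed(31)
  s <- random_seq(120)
  mask <- "110010011"
  ones <- which(strsplit(mask, "")[[1]] == "1")
  got <- extract_spaced_seeds(s, mask)
  chars <- strsplit(s, "")[[1]]
  k <- length(ones)
  want <- vapply(seq_len(nchar(s) - nchar(mask) + 1), function(st) {
    cc <- match(chars[st + ones - 1L], c("A", "C", "G", "T")) - 1L
    fwd <- sum(cc * 4^((k - 1):0))
    rev <- sum((3 - rev(cc)) * 4^((k - 1):0))
    hash_kmer(min(fwd, rev), k)
  }, numeric(1))
  expect_equal(got, want)
})
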