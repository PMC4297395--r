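test_that("candidate factor pairs follow the SA/LCP defining formulas", {
  ix <- indexed_word("AABABABB")
  fp <- enumerate_factor_pairs(ix)
  # rank 0: S_0 = "A" (start 0, len 1), S_1 = "AA" (start 0, len 2)
  expect_equal(fp[fp$id == 0L, c("start", "len")],
               data.frame(start = 0L, len = 1L), ignore_attr = TRUE)
  expect_equal(fp[fp$id == 1L, c("start", "len")],
               data.frame(start = 0L, len = 2L), ignore_attr = TRUE)
  expect_false(any(fp$skipped[fp$id %in% 0:1]))

  # all-zero LCP: every candidate is a single letter
  fp_ab <- enumerate_factor_pairs(indexed_word("AB"))
  expect_equal(fp_ab$len, rep(1L, 4L))
  expect_false(any(fp_ab$skipped))

  # ABAB: SA = 2 0 3 1, LCP = 0 2 0 1; at rank 0 the odd candidate has
  # length LCP[1]+1 = 3 > suffix length 2 and is skipped
  ix2 <- indexed_word("ABAB")
  expect_equal(ix2$sa, c(2L, 0L, 3L, 1L))
  expect_equal(ix2$lcp, c(0L, 2L, 0L, 1L))
  fp2 <- enumerate_factor_pairs(ix2)
  expect_true(fp2$skipped[fp2$id == 1L])
  expect_equal(fp2$len[fp2$id == 1L], 3L)
})

test_that("top-down pass stores predecessors seen at or before each rank", {
  ix <- indexed_word("AB")
  sets <- maw_top_down(ix)
  # factor id 2 is S_2 = "B" at rank 1; its only earlier-or-equal occurrence
  # (position 1) is preceded by A
  expect_equal(mask_to_letters(sets$b1[3L], ix$alphabet), "A")
  expect_lte(sets$counters$top_down$pushes, ix$n)

  # a word whose every suffix starts at a preceded position except rank of
  # position 0: no predecessor is ever recorded for position 0
  ix1 <- indexed_word("A")
  s1 <- maw_top_down(ix1)
  expect_equal(s1$b1, c(0L, 0L))

  # partial sets are subsets of the completed sets
  for (w in random_words(40, sigma = 3, min_len = 1, max_len = 60, seed = 11)) {
    ixw <- indexed_word(w)
    part <- maw_top_down(ixw)
    full <- maw_bottom_up(ixw, part)
    expect_identical(bitwAnd(part$b1, full$b1), part$b1)
    expect_identical(bitwAnd(part$b2, full$b2), part$b2)
    expect_lte(part$counters$top_down$pushes, ixw$n)
  }
})

test_that("completed sets equal the definitional preceding-letter sets", {
  words <- c("AB", "AABABABB", "ABAB", "AAAA", "A",
             random_words(40, sigma = 2, min_len = 2, max_len = 40, seed = 21),
             random_words(20, sigma = 4, min_len = 2, max_len = 40, seed = 22))
  for (w in words) {
    ix <- indexed_word(w)
    sets <- maw_preceding_sets(ix)
    fp <- enumerate_factor_pairs(ix)
    for (k in which(!fp$skipped)) {
      fac <- substr(w, fp$start[k] + 1L, fp$start[k] + fp$len[k])
      ref <- naive_b_sets(w, fac)
      expect_identical(mask_to_letters(sets$b1[k], ix$alphabet), ref$b1)
      expect_identical(mask_to_letters(sets$b2[k], ix$alphabet), ref$b2)
      # B1 subset of B2; sets never exceed the alphabet
      expect_identical(bitwAnd(sets$b1[k], sets$b2[k]), sets$b1[k])
    }
  }
})

test_that("bottom-up completion of the two-letter example enables emission", {
  ix <- indexed_word("AB")
  sets <- maw_preceding_sets(ix)
  # S_0 = "A": longest proper prefix is the empty word, so B2 = {A, B};
  # position 0 has no predecessor, so B1 = {}
  expect_equal(mask_to_letters(sets$b2[1L], ix$alphabet), c("A", "B"))
  expect_equal(sets$b1[1L], 0L)
  expect_equal(compute_maws("AB")$maw, c("AA", "BA", "BB"))
})

test_that("emission reproduces the worked example and honours length bounds", {
  ix <- indexed_word("AABABABB")
  sets <- maw_preceding_sets(ix)
  res <- emit_maws(ix, sets)
  expect_equal(res$maw,
               c("AAA", "AABABB", "AABB", "BAA", "BABABA", "BBA", "BBB"))
  # AABB arises as A prepended to the factor ABB at positions 5..7
  aabb <- res[res$maw == "AABB", ]
  expect_equal(aabb$letter, "A")
  expect_equal(decode_tuple("AABABABB", aabb$letter, aabb$start, aabb$end),
               "AABB")
  # the only length-4 MAW is AABB
  expect_equal(emit_maws(ix, sets, min_len = 4, max_len = 4)$maw, "AABB")
  expect_equal(emit_maws(ix, sets, min_len = 3, max_len = 3)$maw,
               c("AAA", "BAA", "BBA", "BBB"))
  expect_error(emit_maws(ix, sets, min_len = 1), "at least 2")
  expect_error(emit_maws(ix, sets, min_len = 4, max_len = 3), "max_len")
})

test_that("compute_maws matches the brute-force oracle on random words", {
  for (s in 1:4) {
    for (w in random_words(50, sigma = s, min_len = 1, max_len = 120,
                           seed = 30 + s)) {
      expect_identical(compute_maws(w)$maw, brute_force_maws(w))
    }
  }
  expect_equal(compute_maws("AAAA")$maw, "AAAAA")
})

test_that("every reported word is absent while its maximal proper factors occur", {
  for (w in random_words(60, sigma = 3, min_len = 2, max_len = 100, seed = 77)) {
    res <- compute_maws(w)
    expect_false(any(duplicated(res$maw)))
    for (x in res$maw) {
      m <- nchar(x)
      expect_gte(m, 2L)
      expect_false(grepl(x, w, fixed = TRUE))
      expect_true(grepl(substr(x, 1L, m - 1L), w, fixed = TRUE))
      expect_true(grepl(substr(x, 2L, m), w, fixed = TRUE))
    }
  }
})

test_that("output size, stack pushes and letter insertions stay linear", {
  for (w in c(random_words(30, sigma = 4, min_len = 1, max_len = 200, seed = 55),
              strrep("A", 120), strrep("ACGT", 40))) {
    res <- compute_maws(w)
    n <- attr(res, "n")
    sigma <- attr(res, "sigma")
    expect_lte(nrow(res), sigma * (n + 1L))
    ct <- attr(res, "counters")
    expect_lte(ct$top_down$pushes, n)
    expect_lte(ct$bottom_up$pushes, n)
    expect_lte(ct$top_down$insertions, n * sigma)
    expect_lte(ct$bottom_up$insertions, n * sigma)
    expect_lte(ct$top_down$pops, ct$top_down$pushes)
    expect_lte(ct$bottom_up$rem_moves, ct$bottom_up$pushes)
  }
})

test_that("the MAW set commutes with reverse complementation", {
  for (w in random_dna_words(25, min_len = 2, max_len = 150, seed = 91)) {
    fwd <- compute_maws(w)$maw
    rev <- compute_maws(reverse_complement(w))$maw
    expect_identical(rev, sort(rc_chr(fwd), method = "radix"))
  }
})

test_that("identical inputs give byte-identical results", {
  w <- random_words(1, sigma = 4, min_len = 300, max_len = 300, seed = 13)
  r1 <- compute_maws(w)
  r2 <- compute_maws(w)
  expect_identical(r1, r2)
})

test_that("decode_tuple validates intervals and decodes by concatenation", {
  expect_equal(decode_tuple("AABABABB", "A", 5, 7), "AABB")
  expect_equal(decode_tuple("AABABABB", "B", 6, 7), "BBB")
  expect_equal(decode_tuple("AABABABB", "B", 3, 3), "BA") # B + y[3]
  expect_error(decode_tuple("AABABABB", "A", 5, 8), "out of bounds")
  expect_error(decode_tuple("AABABABB", "A", -1, 2), "out of bounds")
})
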