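# Independent reference computations used to check the suffix structures and
# the two-pass letter sets. They work by direct string comparison only and
# share no code with the package internals.

# suffix array by sorting all suffixes as strings (byte order)
naive_sa <- function(word) {
  n <- nchar(word)
  order(substring(word, 1:n, n), method = "radix") - 1L
}

# LCP of consecutive sorted suffixes by character-by-character comparison
naive_lcp <- function(word, sa = naive_sa(word)) {
  n <- nchar(word)
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  lcp <- integer(n)
  for (r in seq_len(n - 1L)) {
    a <- sa[r] + 1L
    b <- sa[r + 1L] + 1L
    h <- 0L
    while (a + h <= n && b + h <= n && chars[a + h] == chars[b + h]) {
      h <- h + 1L
    }
    lcp[r + 1L] <- h
  }
  lcp
}

# all (possibly overlapping) occurrence start positions (0-based) of a factor
naive_occurrences <- function(word, factor) {
  n <- nchar(word)
  m <- nchar(factor)
  if (m > n) {
    return(integer(0))
  }
  starts <- 1:(n - m + 1L)
  which(substring(word, starts, starts + m - 1L) == factor) - 1L
}

# letters immediately preceding occurrences of a factor
naive_preceding <- function(word, factor) {
  occ <- naive_occurrences(word, factor)
  occ <- occ[occ > 0L]
  if (length(occ) == 0L) {
    return(character(0))
  }
  sort(unique(substring(word, occ, occ)))
}

# definitional B1/B2 of a factor; the longest proper prefix of a single
# letter is the empty word, which occurs everywhere, so B2 is then every
# letter of the word
naive_b_sets <- function(word, factor) {
  b1 <- naive_preceding(word, factor)
  b2 <- if (nchar(factor) == 1L) {
    sort(unique(strsplit(word, "", fixed = TRUE)[[1L]]))
  } else {
    naive_preceding(word, substr(factor, 1L, nchar(factor) - 1L))
  }
  list(b1 = b1, b2 = b2)
}

# decode a bitmask into alphabet letters
mask_to_letters <- function(mask, alph) {
  alph$letters[which(bitwAnd(mask, bitwShiftL(1L, 0:(alph$sigma - 1L))) != 0L)]
}

# every binary word over {A,B} of a given length
all_binary_words <- function(len) {
  if (len == 0L) {
    return(character(0))
  }
  vapply(0:(2L^len - 1L), function(k) {
    paste(c("A", "B")[bitwAnd(bitwShiftR(k, 0:(len - 1L)), 1L) + 1L],
          collapse = "")
  }, character(1))
}

# random_words draws over A,B,C,D; remap to the DNA alphabet
random_dna_words <- function(k, min_len, max_len, seed) {
  chartr("ABCD", "ACGT", random_words(k, sigma = 4L, min_len = min_len,
                                      max_len = max_len, seed = seed))
}

random_dna <- function(n, seed) {
  random_dna_words(1L, n, n, seed)
}

rc_chr <- function(x) vapply(x, reverse_complement, character(1), USE.NAMES = FALSE)
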