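# Brute-force reference implementations, kept deliberately independent of
# the suffix-array machinery: they enumerate factors by direct substring
# extraction and apply the definition of minimality verbatim. Quadratic in
# the word length, used for verification.

#' All distinct factors of a word
#'
#' @param word a single non-empty string.
#' @return Character vector of every distinct `y[i..j]` (at most
#'   `n(n+1)/2` of them), unordered.
#' @examples
#' sort(factor_set("AB")) # "A" "AB" "B"
#' @export
factor_set <- function(word) {
  stopifnot(is.character(word), length(word) == 1L, nzchar(word))
  n <- nchar(word)
  out <- vector("list", n)
  for (len in seq_len(n)) {
    out[[len]] <- unique(substring(word, 1:(n - len + 1L),
                                   len:n))
  }
  unique(unlist(out, use.names = FALSE))
}

#' Minimal absent words by brute force
#'
#' Direct application of the definition: `x` of length `m >= 2` is a minimal
#' absent word when `x` does not occur but its longest proper prefix and
#' longest proper suffix both do (then every proper factor occurs).
#' Candidates are the words `a . f` over factors `f`, which is exhaustive
#' because the longest proper suffix of any MAW is a factor.
#'
#' @param word a single non-empty string.
#' @param alphabet candidate first letters; inferred from `word` when
#'   `NULL`. Letters absent from `word` cannot appear in a MAW, so the
#'   result does not depend on extra letters.
#' @return Sorted character vector of all minimal absent words.
#' @examples
#' brute_force_maws("AB") # "AA" "BA" "BB"
#' @export
brute_force_maws <- function(word, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- infer_alphabet(word)
  }
  fs <- factor_set(word)
  res <- character(0)
  for (a in alphabet$letters) {
    x <- paste0(a, fs)
    # longest proper prefix of a.f drops the last letter of f; for |f| = 1
    # it is the single letter a, whose presence means "a occurs in word"
    pref <- paste0(a, substr(fs, 1L, nchar(fs) - 1L))
    keep <- !(x %in% fs) & (pref %in% fs)
    res <- c(res, x[keep])
  }
  sort_c(unique(res))
}

#' Reproducible random words
#'
#' Generates words over the first `sigma` letters of `A`, `B`, `C`, `D`,
#' with lengths drawn uniformly from `[min_len, max_len]`. A fixed seed
#' gives an identical sequence of words; the caller's RNG state is left
#' untouched.
#'
#' @param n_words how many words.
#' @param sigma alphabet size, 1 to 4.
#' @param min_len,max_len inclusive length range (lengths down to 1 are
#'   allowed, exercising the single-suffix edge case).
#' @param seed integer seed.
#' @return Character vector of `n_words` words.
#' @examples
#' random_words(3, sigma = 2, min_len = 1, max_len = 8, seed = 7)
#' @export
random_words <- function(n_words, sigma, min_len, max_len, seed) {
  stopifnot(sigma >= 1L, sigma <= 4L, min_len >= 1L, max_len >= min_len)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  letters <- c("A", "B", "C", "D")[seq_len(sigma)]
  lens <- sample.int(max_len - min_len + 1L, n_words, replace = TRUE) +
    min_len - 1L
  vapply(lens, function(l) {
    paste(sample(letters, l, replace = TRUE), collapse = "")
  }, character(1))
}
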