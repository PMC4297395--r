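#' Build the suffix array of an encoded word
#'
#' Returns the starting positions (0-based) of all suffixes of the word in
#' strictly increasing lexicographic order. Construction is by prefix
#' doubling over radix-ordered rank pairs, so no sentinel is ever appended
#' and the returned array covers exactly the `n` real suffixes. All
#' positions in this package are 0-based and intervals are inclusive
#' `[i..j]`, matching the usual `y[i..j]` factor notation.
#'
#' @param code integer vector of letter indices in `[1:sigma]` (see
#'   [indexed_word()] for encoding from a string).
#' @return Integer vector `sa` of length `n` with
#'   `y[sa[r]..] < y[sa[r+1]..]` for consecutive ranks.
#' @examples
#' w <- utf8ToInt("AABABABB") - utf8ToInt("A") + 1L
#' build_suffix_array(w) # 0 1 3 5 7 2 4 6
#' @export
build_suffix_array <- function(code) {
  code <- as.integer(code)
  n <- length(code)
  if (n == 0L) {
    stop("cannot build a suffix array of an empty word")
  }
  if (anyNA(code) || any(code < 1L)) {
    stop("letter codes must be positive integers")
  }
  rank <- match(code, sort.int(unique(code))) # dense initial ranks
  k <- 1L
  while (max(rank) < n) {
    key2 <- if (k < n) c(rank[(k + 1L):n], integer(k)) else integer(n)
    o <- order(rank, key2, method = "radix")
    r1 <- rank[o]
    r2 <- key2[o]
    changed <- c(TRUE, r1[-1L] != r1[-n] | r2[-1L] != r2[-n])
    rank[o] <- cumsum(changed)
    k <- k * 2L
  }
  sa <- integer(n)
  sa[rank] <- seq_len(n) - 1L
  sa
}

#' Invert a suffix array
#'
#' @param sa integer permutation of `[0:n-1]`.
#' @return Integer vector `isa` with `isa[sa[r] + 1] == r` (0-based ranks).
#' @examples
#' build_inverse(c(0L, 1L, 3L, 5L, 7L, 2L, 4L, 6L))
#' @export
build_inverse <- function(sa) {
  sa <- as.integer(sa)
  n <- length(sa)
  if (n == 0L || anyNA(sa) || !setequal(sa, seq_len(n) - 1L)) {
    stop("'sa' must be a permutation of 0:(n-1)")
  }
  isa <- integer(n)
  isa[sa + 1L] <- seq_len(n) - 1L
  isa
}

#' Build the LCP array (Kasai's algorithm)
#'
#' `lcp[r + 1]` (R indexing) is the length of the longest common prefix of
#' the suffixes at ranks `r - 1` and `r`; `lcp[1] = 0` by convention. The
#' boundary value for rank `n` is 0 and is applied implicitly where needed.
#' Positions are visited in text order so total character comparisons are
#' linear.
#'
#' @param code integer letter codes (as for [build_suffix_array()]).
#' @param sa the suffix array of `code`.
#' @param isa its inverse (see [build_inverse()]).
#' @return Integer vector of length `n`.
#' @examples
#' w <- utf8ToInt("AABABABB") - utf8ToInt("A") + 1L
#' sa <- build_suffix_array(w)
#' build_lcp(w, sa, build_inverse(sa)) # 0 1 4 2 0 1 3 1
#' @export
build_lcp <- function(code, sa, isa) {
  code <- as.integer(code)
  n <- length(code)
  if (length(sa) != n || length(isa) != n) {
    stop("'sa' and 'isa' must have the same length as the word")
  }
  if (any(isa[sa + 1L] != seq_len(n) - 1L)) {
    stop("'isa' is not the inverse of 'sa'")
  }
  lcp <- integer(n)
  h <- 0L
  for (p in 0L:(n - 1L)) {
    r <- isa[p + 1L] # 0-based rank of the suffix starting at p
    if (r > 0L) {
      q <- sa[r] # start of the suffix ranked just before
      while (p + h < n && q + h < n && code[p + h + 1L] == code[q + h + 1L]) {
        h <- h + 1L
      }
      lcp[r + 1L] <- h
      if (h > 0L) {
        h <- h - 1L
      }
    } else {
      h <- 0L
    }
  }
  lcp
}

#' Index a word with its suffix structures
#'
#' Encodes `residues` over `alphabet` and attaches the suffix array, inverse
#' suffix array and LCP array. This is the input to [compute_maws()]'s
#' passes.
#'
#' @param residues a single non-empty string.
#' @param alphabet a `"maw_alphabet"`; inferred from `residues` when `NULL`.
#' @return An object of class `"indexed_word"`: list with `residues`, `code`
#'   (integer letter indices), `alphabet`, `n`, and 0-based `sa`, `isa`,
#'   `lcp` arrays.
#' @examples
#' ix <- indexed_word("AABABABB")
#' ix$sa
#' ix$lcp
#' @export
indexed_word <- function(residues, alphabet = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) {
    stop("cannot index an empty word")
  }
  if (is.null(alphabet)) {
    alphabet <- infer_alphabet(residues)
  }
  code <- encode_word(residues, alphabet)
  sa <- build_suffix_array(code)
  isa <- build_inverse(sa)
  lcp <- build_lcp(code, sa, isa)
  structure(list(residues = residues, code = code, alphabet = alphabet,
                 n = length(code), sa = sa, isa = isa, lcp = lcp),
            class = "indexed_word")
}

#' @export
print.indexed_word <- function(x, ...) {
  cat(sprintf("indexed word: n = %d, sigma = %d\n", x$n, x$alphabet$sigma))
  if (x$n <= 25L) {
    cat(" word:", x$residues, "\n")
    cat(" SA: ", paste(x$sa, collapse = " "), "\n")
    cat(" LCP:", paste(x$lcp, collapse = " "), "\n")
  }
  invisible(x)
}

#' Longest common prefix of two ranked suffixes
#'
#' Range-minimum over the LCP array: for ranks `r != s` this is
#' `min(lcp[(min(r,s)+1)..max(r,s)])`; for `r == s` it is the full suffix
#' length. A testing utility (naive scan, not constant time).
#'
#' @param ix an `"indexed_word"`.
#' @param r,s 0-based suffix ranks.
#' @return Integer length.
#' @examples
#' ix <- indexed_word("AABABABB")
#' lcp_of_ranks(ix, 1, 2) # 4
#' lcp_of_ranks(ix, 3, 4) # 0
#' @export
lcp_of_ranks <- function(ix, r, s) {
  stopifnot(inherits(ix, "indexed_word"))
  r <- as.integer(r)
  s <- as.integer(s)
  if (anyNA(c(r, s)) || r < 0L || s < 0L || r >= ix$n || s >= ix$n) {
    stop(sprintf("ranks must lie in [0:%d]", ix$n - 1L))
  }
  if (r == s) {
    return(ix$n - ix$sa[r + 1L])
  }
  lo <- min(r, s)
  hi <- max(r, s)
  min(ix$lcp[(lo + 2L):(hi + 1L)])
}
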