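#' Ordered alphabets
#'
#' An alphabet is an ordered set of distinct single-character letters; its
#' order defines the lexicographic order used by the suffix array. Alphabets
#' of up to 31 letters are supported (letter sets are stored as bits of an R
#' integer).
#'
#' @param letters character vector of distinct single characters, or a single
#'   string whose characters are the letters. The letters are sorted into
#'   natural (byte) order.
#' @return An object of class `"maw_alphabet"`: a list with elements
#'   `letters` (ordered character vector) and `sigma` (its length).
#' @examples
#' alphabet("ACGT")
#' alphabet(c("B", "A"))$letters # "A" "B"
#' @export
alphabet <- function(letters) {
  if (length(letters) == 1L && nchar(letters) > 1L) {
    letters <- strsplit(letters, "", fixed = TRUE)[[1L]]
  }
  letters <- as.character(letters)
  if (length(letters) == 0L) {
    stop("an alphabet needs at least one letter")
  }
  if (any(nchar(letters) != 1L)) {
    stop("alphabet letters must be single characters")
  }
  if (anyDuplicated(letters)) {
    stop("alphabet letters must be distinct")
  }
  letters <- sort_c(letters)
  if (length(letters) > 31L) {
    stop("alphabets larger than 31 letters are not supported")
  }
  structure(list(letters = letters, sigma = length(letters)),
            class = "maw_alphabet")
}

#' Infer the alphabet of a set of sequences
#'
#' The alphabet is the set of distinct residues across all records, in
#' natural character order, so it is deterministic for fixed input.
#'
#' @param records a list of sequence records as returned by [read_fasta()],
#'   a character vector of sequences, or a single string.
#' @return A `"maw_alphabet"` object.
#' @examples
#' infer_alphabet("AABABABB") # letters A, B
#' infer_alphabet("ACGT")$sigma # 4
#' @export
infer_alphabet <- function(records) {
  seqs <- record_residues(records)
  if (length(seqs) == 0L || !any(nzchar(seqs))) {
    stop("cannot infer an alphabet from empty input")
  }
  chars <- unique(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE))
  alphabet(chars)
}

#' @export
print.maw_alphabet <- function(x, ...) {
  cat(sprintf("alphabet of %d letter(s): %s\n",
              x$sigma, paste(x$letters, collapse = " ")))
  invisible(x)
}

# Pull residue strings out of whatever holds them.
record_residues <- function(records) {
  if (inherits(records, "maw_record")) {
    return(records$residues)
  }
  if (is.list(records)) {
    return(vapply(records, function(r) {
      if (is.list(r)) r$residues else as.character(r)
    }, character(1)))
  }
  as.character(records)
}

# Locale-independent sort (byte order), so alphabets and output ordering do
# not depend on the session locale.
sort_c <- function(x) x[order(x, method = "radix")]

# Encode a string as integer letter indices in [1:sigma]; errors on residues
# outside the alphabet.
encode_word <- function(residues, alph) {
  stopifnot(inherits(alph, "maw_alphabet"))
  ints <- utf8ToInt(residues)
  code <- match(ints, utf8ToInt(paste(alph$letters, collapse = "")))
  if (anyNA(code)) {
    p <- which(is.na(code))[1L]
    stop(sprintf("residue '%s' at position %d is not in the alphabet",
                 intToUtf8(ints[p]), p))
  }
  code
}
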