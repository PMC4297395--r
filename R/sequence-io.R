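#' Read a (Multi)FASTA file
#'
#' Each `>` header starts one record; sequence lines up to the next header
#' are concatenated (arbitrary line wrapping) and uppercased, since genome
#' FASTA commonly soft-masks repeats with lowercase and the alphabet here is
#' case-free. Records are processed independently downstream: sequences are
#' never concatenated across records, which would create artificial factors
#' spanning record boundaries.
#'
#' @param file path to a FASTA file.
#' @return A list of records, each a list of class `"maw_record"` with
#'   elements `id` (first whitespace-delimited token of the header),
#'   `description` (remainder of the header, possibly `""`) and `residues`
#'   (the uppercased sequence).
#' @seealso [write_fasta()], [write_maws()]
#' @importFrom Biostrings readBStringSet
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1 demo", "AABAB", "ABB"), fa)
#' read_fasta(fa)[[1]]$residues # "AABABABB"
#' @export
read_fasta <- function(file) {
  if (!file.exists(file)) {
    stop(sprintf("input file '%s' does not exist", file))
  }
  first <- readLines(file, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L) {
    stop(sprintf("no records: '%s' is empty", file))
  }
  if (!startsWith(first[1L], ">")) {
    stop(sprintf(
      "malformed FASTA in '%s': sequence line before any '>' header (line 1)",
      file))
  }
  set <- Biostrings::readBStringSet(file)
  if (length(set) == 0L) {
    stop(sprintf("no records in '%s'", file))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    stop(sprintf("record %d in '%s' has an empty identifier",
                 which(!nzchar(ids))[1L], file))
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop(sprintf("record '%s' in '%s' has an empty sequence",
                 ids[which(!nzchar(seqs))[1L]], file))
  }
  records <- Map(function(i, d, s) {
    structure(list(id = i, description = d, residues = s),
              class = "maw_record")
  }, ids, desc, seqs)
  names(records) <- ids
  unname(records)
}

#' Write records as FASTA
#'
#' Counterpart of [read_fasta()] used for round-trip checks and for writing
#' derived sequences (e.g. reverse complements).
#'
#' @param records list of `"maw_record"` objects (or anything [read_fasta()]
#'   returns).
#' @param file output path.
#' @param width line-wrap width for sequences.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(records, file, width = 70L) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) {
      paste(r$id, r$description)
    } else {
      r$id
    }
    writeLines(paste0(">", header), con)
    n <- nchar(r$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$residues, starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(file)
}

#' Reverse complement of a DNA sequence
#'
#' Reverses the sequence and complements each base (A<->T, C<->G, N->N). The
#' minimal absent words of the reverse complement of `y` are exactly the
#' reverse complements of the minimal absent words of `y`.
#'
#' @param residues a single string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AACGT") # "ACGTT"
#' reverse_complement("ACGTN") # "NACGT"
#' @export
reverse_complement <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  bad <- regexpr("[^ACGTN]", residues)
  if (bad > 0L) {
    stop(sprintf(
      "cannot reverse-complement: symbol '%s' at position %d is not a DNA letter",
      substr(residues, bad, bad), bad))
  }
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", residues))))
}

#' Write minimal absent words for one record
#'
#' Emits a `>` header line with the record identifier followed by one
#' minimal absent word per line, sorted lexicographically so output is
#' deterministic and diffable (total lines = 1 + number of words).
#'
#' @param file output path or connection.
#' @param id record identifier for the header line.
#' @param maws character vector of (already length-filtered) minimal absent
#'   words.
#' @param append append to `file` instead of truncating it.
#' @return `file`, invisibly.
#' @examples
#' out <- tempfile()
#' write_maws(out, "y", c("BBB", "AAA"))
#' readLines(out) # ">y" "AAA" "BBB"
#' @export
write_maws <- function(file, id, maws, append = FALSE) {
  con <- if (inherits(file, "connection")) {
    file
  } else {
    f <- base::file(file, open = if (append) "at" else "wt")
    on.exit(close(f))
    f
  }
  writeLines(c(paste0(">", id), sort_c(as.character(maws))), con)
  invisible(file)
}

# Tuple-mode output: one "a<TAB>i<TAB>j" line per word (0-based inclusive
# interval into the record's residues).
write_maw_tuples <- function(file, id, tuples, append = FALSE) {
  con <- if (inherits(file, "connection")) {
    file
  } else {
    f <- base::file(file, open = if (append) "at" else "wt")
    on.exit(close(f))
    f
  }
  writeLines(c(paste0(">", id),
               sprintf("%s\t%d\t%d", tuples$letter, tuples$start, tuples$end)),
             con)
  invisible(file)
}

#' @export
print.maw_record <- function(x, ...) {
  n <- nchar(x$residues)
  preview <- if (n > 60L) paste0(substr(x$residues, 1L, 57L), "...") else x$residues
  cat(sprintf(">%s%s (%d residues)\n%s\n", x$id,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              n, preview))
  invisible(x)
}
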