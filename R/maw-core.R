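# Core two-pass computation of minimal absent words (MAWs).
#
# For every suffix-array rank i only two factors can be the tail x[1..m-1]
# of a MAW x: the prefixes of y[SA[i]..n-1] of lengths LCP[i]+1 and
# LCP[i+1]+1 (factor ids j = 2i and 2i+1, with LCP[n] = 0). For each factor
# S_j the passes accumulate, as sigma-bit masks,
#   B1[j]: letters immediately preceding occurrences of S_j,
#   B2[j]: letters immediately preceding occurrences of its longest proper
#          prefix,
# and every letter of B2[j] \ B1[j] starts exactly one MAW ending with S_j.
#
# Working state during a pass: a stack (LifoLCP) of LCP values, always
# increasing bottom to top with at most one push per iteration, and a table
# Interval with one letter set per prefix length; at the end of iteration i
# the entry for length l holds letters already seen immediately before the
# length-l prefix of y[SA[i]..n-1]. Entries are only materialised at lengths
# present on the stack; queries for other lengths resolve to the next stack
# value above (the sets are nested) or, above the stack top, to the current
# suffix's own preceding letter. The top-down pass covers occurrences at
# ranks <= i, the bottom-up pass ranks >= i; their union is complete. The
# bottom-up pass parks stack values above LCP[i] on LifoRem during the
# iteration and clears them at its end.

bit_mask <- function(letter) bitwShiftL(1L, letter - 1L)

# Letter indices present in a sigma-bit mask.
mask_letters <- function(mask, sigma) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(sigma - 1L))) != 0L)
}

# Mask of all letters occurring in the word: by convention the empty word
# occurs at every position 0..n, so the set of letters preceding its
# occurrences (B2 of any single-letter factor) is every letter of y.
present_letters_mask <- function(ix) {
  m <- 0L
  for (l in unique(ix$code)) {
    m <- bitwOr(m, bit_mask(l))
  }
  m
}

#' Candidate MAW tails per suffix-array rank
#'
#' For each rank `i` the two candidate factors are the prefixes of
#' `y[SA[i]..n-1]` of lengths `LCP[i] + 1` (id `2i`) and `LCP[i+1] + 1`
#' (id `2i + 1`, with the boundary `LCP[n] = 0`). A candidate whose length
#' would overrun the suffix (`length > n - SA[i]`) is marked skipped: every
#' MAW tail also has a witness occurrence lying fully inside the word, so
#' nothing is lost.
#'
#' @param ix an [indexed_word()].
#' @return A data frame with one row per factor id: `id` (0-based), `rank`,
#'   `start` (0-based), `len`, and logical `skipped`.
#' @examples
#' enumerate_factor_pairs(indexed_word("AB"))
#' @export
enumerate_factor_pairs <- function(ix) {
  stopifnot(inherits(ix, "indexed_word"))
  n <- ix$n
  lcpv <- c(ix$lcp, 0L)
  start <- rep(ix$sa, each = 2L)
  len <- as.vector(rbind(lcpv[seq_len(n)], lcpv[seq_len(n) + 1L])) + 1L
  data.frame(id = 0:(2L * n - 1L),
             rank = rep(0:(n - 1L), each = 2L),
             start = start,
             len = len,
             skipped = len > n - start)
}

# Empty per-factor letter sets for a word of length n.
maw_sets_init <- function(ix) {
  stopifnot(inherits(ix, "indexed_word"))
  list(b1 = integer(2L * ix$n), b2 = integer(2L * ix$n),
       counters = list())
}

#' Top-down pass over the suffix array
#'
#' Fills `B1`/`B2` with the letters preceding those occurrences whose
#' starting positions appear at or before each rank. At most one stack push
#' is made per iteration; the returned counters expose the pass's work
#' (`pushes`, `pops`, `insertions` of letters into Interval entries).
#'
#' @param ix an [indexed_word()].
#' @param sets letter sets from [maw_sets_init()]; created when `NULL`.
#' @return The updated sets: list with integer bitmask vectors `b1`, `b2`
#'   (length `2n`) and a `counters` list gaining a `top_down` entry.
#' @seealso [maw_bottom_up()], [maw_preceding_sets()]
#' @export
maw_top_down <- function(ix, sets = NULL) {
  stopifnot(inherits(ix, "indexed_word"))
  if (is.null(sets)) {
    sets <- maw_sets_init(ix)
  }
  check_sigma(ix)
  n <- ix$n
  code <- ix$code
  sa <- ix$sa
  lcpv <- c(ix$lcp, 0L)
  b1 <- sets$b1
  b2 <- sets$b2
  interval <- integer(max(lcpv) + 2L) # entry l+1 <-> prefix length l
  stackv <- integer(n + 1L)
  top <- 0L
  pushes <- 0L
  pops <- 0L
  insertions <- 0L
  carry <- 0L
  prev_mask <- 0L
  a_mask <- 0L
  suf_len <- 0L

  # letters seen before the length-l prefix of the current suffix (l >= 1)
  query <- function(l) {
    res <- 0L
    if (top > 0L) {
      idx <- findInterval(l - 0.5, stackv[seq_len(top)]) + 1L
      if (idx <= top) {
        res <- interval[stackv[idx] + 1L]
      }
    }
    if (l <= suf_len) {
      res <- bitwOr(res, a_mask)
    }
    res
  }

  for (ri in seq_len(n)) {
    lcp_i <- lcpv[ri]
    lcp_next <- lcpv[ri + 1L]
    start <- sa[ri]
    suf_len <- n - start
    a_mask <- if (start > 0L) bit_mask(code[start]) else 0L

    # step 1: factors deeper than LCP[i] are no longer prefixes of any
    # remaining suffix; pop and clear them, keeping the deepest popped set
    # (it collapses onto the length-LCP[i] prefix)
    while (top > 0L && stackv[top] > lcp_i) {
      v <- stackv[top]
      carry <- interval[v + 1L]
      interval[v + 1L] <- 0L
      top <- top - 1L
      pops <- pops + 1L
    }
    if (top == 0L || stackv[top] < lcp_i) {
      top <- top + 1L
      stackv[top] <- lcp_i
      pushes <- pushes + 1L
      interval[lcp_i + 1L] <- bitwOr(carry, prev_mask)
    } else {
      interval[lcp_i + 1L] <- bitwOr(interval[lcp_i + 1L],
                                     bitwOr(carry, prev_mask))
    }
    carry <- 0L

    # record the partial B sets for this rank's two candidate factors
    j1 <- 2L * ri - 1L # R index of factor id 2i
    if (lcp_i >= 1L) {
      b2[j1] <- bitwOr(b2[j1], query(lcp_i))
    }
    b1[j1] <- bitwOr(b1[j1], query(lcp_i + 1L))
    if (lcp_next + 1L <= suf_len) {
      j2 <- 2L * ri
      if (lcp_next >= 1L) {
        b2[j2] <- bitwOr(b2[j2], query(lcp_next))
      }
      b1[j2] <- bitwOr(b1[j2], query(lcp_next + 1L))
    }

    # step 2: propagate the current preceding letter down the stack until an
    # entry already contains it (the sets are nested, so deeper entries then
    # contain it too)
    if (a_mask != 0L) {
      t <- top
      while (t > 0L) {
        v <- stackv[t]
        cur <- interval[v + 1L]
        if (bitwAnd(cur, a_mask) != 0L) {
          break
        }
        interval[v + 1L] <- bitwOr(cur, a_mask)
        insertions <- insertions + 1L
        t <- t - 1L
      }
    }
    prev_mask <- a_mask
  }

  sets$b1 <- b1
  sets$b2 <- b2
  sets$counters$top_down <- list(pushes = pushes, pops = pops,
                                 insertions = insertions)
  sets
}

#' Bottom-up pass over the suffix array
#'
#' Completes the sets from [maw_top_down()] with the letters preceding
#' occurrences whose starting positions appear at or after each rank. Stack
#' values greater than `LCP[i]` are moved to the auxiliary LifoRem stack and
#' their Interval entries cleared at the end of each iteration; the letter
#' propagation step is performed for every letter already recorded in
#' `B1[2i]`, at the prefix lengths those letters are witnessed for. On
#' return, `B2` of every single-letter factor is set to all letters
#' occurring in the word (its longest proper prefix is the empty word, which
#' occurs at every position).
#'
#' @inheritParams maw_top_down
#' @param sets the partially filled sets returned by [maw_top_down()].
#' @return The completed sets, with a `bottom_up` counters entry
#'   (`pushes`, `rem_moves`, `insertions`).
#' @export
maw_bottom_up <- function(ix, sets) {
  stopifnot(inherits(ix, "indexed_word"), is.list(sets))
  check_sigma(ix)
  n <- ix$n
  code <- ix$code
  sa <- ix$sa
  lcpv <- c(ix$lcp, 0L)
  b1 <- sets$b1
  b2 <- sets$b2
  interval <- integer(max(lcpv) + 2L)
  stackv <- integer(n + 1L)
  top <- 0L
  pushes <- 0L
  rem_moves <- 0L
  insertions <- 0L
  carry <- 0L
  prev_mask <- 0L
  a_mask <- 0L
  suf_len <- 0L

  query <- function(l) {
    res <- 0L
    if (top > 0L) {
      idx <- findInterval(l - 0.5, stackv[seq_len(top)]) + 1L
      if (idx <= top) {
        res <- interval[stackv[idx] + 1L]
      }
    }
    if (l <= suf_len) {
      res <- bitwOr(res, a_mask)
    }
    res
  }

  for (ri in n:1L) {
    lcp_i <- lcpv[ri]
    lcp_next <- lcpv[ri + 1L] # shared with the previously visited rank i+1
    start <- sa[ri]
    suf_len <- n - start
    a_mask <- if (start > 0L) bit_mask(code[start]) else 0L

    # the previous iteration cleared everything above LCP[i+1]; (re)open the
    # entry at LCP[i+1] with the collapsed letters and the previous rank's
    # preceding letter
    if (top == 0L || stackv[top] < lcp_next) {
      top <- top + 1L
      stackv[top] <- lcp_next
      pushes <- pushes + 1L
      interval[lcp_next + 1L] <- bitwOr(carry, prev_mask)
    } else {
      interval[lcp_next + 1L] <- bitwOr(interval[lcp_next + 1L],
                                        bitwOr(carry, prev_mask))
    }
    carry <- 0L

    j1 <- 2L * ri - 1L
    if (lcp_i >= 1L) {
      b2[j1] <- bitwOr(b2[j1], query(lcp_i))
    }
    b1[j1] <- bitwOr(b1[j1], query(lcp_i + 1L))
    if (lcp_next + 1L <= suf_len) {
      j2 <- 2L * ri
      if (lcp_next >= 1L) {
        b2[j2] <- bitwOr(b2[j2], query(lcp_next))
      }
      b1[j2] <- bitwOr(b1[j2], query(lcp_next + 1L))
    }

    # propagation: the current preceding letter from the top of the stack;
    # additionally each letter of B1[2i] (known to precede the length
    # LCP[i]+1 prefix) from the deepest stack value not exceeding that length
    if (a_mask != 0L) {
      t <- top
      while (t > 0L) {
        v <- stackv[t]
        cur <- interval[v + 1L]
        if (bitwAnd(cur, a_mask) != 0L) {
          break
        }
        interval[v + 1L] <- bitwOr(cur, a_mask)
        insertions <- insertions + 1L
        t <- t - 1L
      }
    }
    extra <- bitwAnd(b1[j1], bitwNot(a_mask))
    if (extra != 0L && top > 0L) {
      t0 <- findInterval(lcp_i + 1L, stackv[seq_len(top)]) # last value <= LCP[i]+1
      for (letter in mask_letters(extra, ix$alphabet$sigma)) {
        lm <- bit_mask(letter)
        t <- t0
        while (t > 0L) {
          v <- stackv[t]
          cur <- interval[v + 1L]
          if (bitwAnd(cur, lm) != 0L) {
            break
          }
          interval[v + 1L] <- bitwOr(cur, lm)
          insertions <- insertions + 1L
          t <- t - 1L
        }
      }
    }

    # LifoRem step: park values above LCP[i], clear their entries; the
    # deepest cleared set collapses onto the next iteration's boundary
    while (top > 0L && stackv[top] > lcp_i) {
      v <- stackv[top]
      carry <- interval[v + 1L]
      interval[v + 1L] <- 0L
      top <- top - 1L
      rem_moves <- rem_moves + 1L
    }
    prev_mask <- a_mask
  }

  # empty-prefix convention for single-letter factors
  pres <- present_letters_mask(ix)
  pairs <- enumerate_factor_pairs(ix)
  one <- which(!pairs$skipped & pairs$len == 1L)
  b2[one] <- pres

  sets$b1 <- b1
  sets$b2 <- b2
  sets$counters$bottom_up <- list(pushes = pushes, rem_moves = rem_moves,
                                  insertions = insertions)
  sets
}

#' Preceding-letter sets of all candidate factors
#'
#' Runs the top-down and bottom-up passes; afterwards, for every
#' non-skipped factor id `j`, `b1[j]` holds exactly the letters immediately
#' preceding occurrences of `S_j` and `b2[j]` those preceding occurrences of
#' its longest proper prefix.
#'
#' @inheritParams maw_top_down
#' @return Completed sets (see [maw_bottom_up()]).
#' @export
maw_preceding_sets <- function(ix) {
  maw_bottom_up(ix, maw_top_down(ix))
}

check_sigma <- function(ix) {
  if (ix$alphabet$sigma > 31L) {
    stop("alphabets larger than 31 letters are not supported")
  }
  invisible(TRUE)
}

#' Emit minimal absent words from completed letter sets
#'
#' For every factor id `j` and letter `a` in `b2[j] \ b1[j]`, the word
#' `a . S_j` is a minimal absent word. The same word can arise from several
#' factor ids (the same factor can occur as different `S_j`); duplicates are
#' removed keeping the tuple with the smallest factor id. Only words with
#' `min_len <= m <= max_len` are retained; minimal absent words have length
#' at least 2 by definition.
#'
#' @param ix an [indexed_word()].
#' @param sets completed sets from [maw_preceding_sets()].
#' @param min_len,max_len inclusive length bounds on reported words;
#'   `max_len = NULL` means no upper bound (no MAW is longer than `n + 1`).
#' @return A data frame with one row per MAW: `letter` (the first letter
#'   `a`), 0-based inclusive interval `start`, `end` into the word spelling
#'   positions `1..m-1`, the decoded word `maw`, and its `length`; rows
#'   sorted lexicographically by `maw`.
#' @export
emit_maws <- function(ix, sets, min_len = 2L, max_len = NULL) {
  stopifnot(inherits(ix, "indexed_word"))
  n <- ix$n
  if (is.null(max_len)) {
    max_len <- n + 1L
  }
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (is.na(min_len) || min_len < 2L) {
    stop("'min_len' must be at least 2 (minimal absent words have length >= 2)")
  }
  if (is.na(max_len) || max_len < min_len) {
    stop("'max_len' must be at least 'min_len'")
  }
  sigma <- ix$alphabet$sigma
  letters <- ix$alphabet$letters
  pairs <- enumerate_factor_pairs(ix)
  diff <- bitwAnd(sets$b2, bitwNot(sets$b1))
  live <- which(diff != 0L & !pairs$skipped & pairs$len + 1L >= min_len &
                  pairs$len + 1L <= max_len)
  if (length(live) == 0L) {
    return(maw_frame(character(0), integer(0), integer(0), character(0)))
  }
  out_letter <- character(0)
  out_start <- integer(0)
  out_end <- integer(0)
  out_maw <- character(0)
  for (k in live) {
    start <- pairs$start[k]
    end <- start + pairs$len[k] - 1L
    tail <- substr(ix$residues, start + 1L, end + 1L)
    for (l in mask_letters(diff[k], sigma)) {
      out_letter <- c(out_letter, letters[l])
      out_start <- c(out_start, start)
      out_end <- c(out_end, end)
      out_maw <- c(out_maw, paste0(letters[l], tail))
    }
  }
  keep <- !duplicated(out_maw) # live is in ascending factor-id order
  o <- order(out_maw[keep], method = "radix")
  maw_frame(out_letter[keep][o], out_start[keep][o], out_end[keep][o],
            out_maw[keep][o])
}

maw_frame <- function(letter, start, end, maw) {
  data.frame(letter = letter, start = start, end = end, maw = maw,
             length = if (length(maw)) nchar(maw) else integer(0),
             stringsAsFactors = FALSE)
}

#' Compute all minimal absent words of a word
#'
#' Facade over indexing ([indexed_word()]), the two passes
#' ([maw_preceding_sets()]) and emission ([emit_maws()]): returns exactly
#' the minimal absent words of `residues` with lengths in
#' `[min_len, max_len]`, one deduplicated tuple each.
#'
#' @param residues a single non-empty string.
#' @param alphabet a `"maw_alphabet"`, inferred from `residues` when `NULL`.
#'   Letters absent from `residues` never start or occur in a MAW, so
#'   enlarging the alphabet does not change the result.
#' @param min_len,max_len inclusive length bounds (see [emit_maws()]).
#' @return A data frame of class `"maw_result"` (see [emit_maws()] for the
#'   columns) with attributes `n`, `sigma` and the pass `counters`.
#' @examples
#' compute_maws("AABABABB")$maw
#' # "AAA" "AABABB" "AABB" "BAA" "BABABA" "BBA" "BBB"
#' compute_maws("AB")$maw # "AA" "BA" "BB"
#' @export
compute_maws <- function(residues, alphabet = NULL, min_len = 2L,
                         max_len = NULL) {
  ix <- indexed_word(residues, alphabet)
  sets <- maw_preceding_sets(ix)
  res <- emit_maws(ix, sets, min_len = min_len, max_len = max_len)
  attr(res, "n") <- ix$n
  attr(res, "sigma") <- ix$alphabet$sigma
  attr(res, "counters") <- sets$counters
  class(res) <- c("maw_result", class(res))
  res
}

#' Decode a MAW tuple
#'
#' A minimal absent word is reported as the tuple `<a, (i, j)>`: its first
#' letter plus the 0-based inclusive interval of the word spelling its
#' positions `1..m-1`. Vectorised over tuples.
#'
#' @param residues the word the tuples refer to.
#' @param letter first letter(s) `a`.
#' @param start,end 0-based inclusive interval(s) into `residues`.
#' @return Character vector of decoded words.
#' @examples
#' decode_tuple("AABABABB", "A", 5, 7) # "AABB"
#' @export
decode_tuple <- function(residues, letter, start, end) {
  stopifnot(is.character(residues), length(residues) == 1L)
  n <- nchar(residues)
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end) || any(start < 0L) || any(end < start) ||
        any(end >= n)) {
    stop(sprintf("tuple interval out of bounds for a word of length %d", n))
  }
  paste0(letter, substring(residues, start + 1L, end + 1L))
}

#' @export
print.maw_result <- function(x, ...) {
  cat(sprintf("%d minimal absent word(s) of a word of length %d (sigma = %d)\n",
              nrow(x), attr(x, "n"), attr(x, "sigma")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.maw_result <- function(object, ...) {
  tab <- table(factor(object$length))
  cat(sprintf("word length n = %d, alphabet size sigma = %d\n",
              attr(object, "n"), attr(object, "sigma")))
  cat(sprintf("%d minimal absent words; counts by length:\n", nrow(object)))
  print(tab)
  invisible(tab)
}
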