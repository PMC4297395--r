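---
title: "Computing minimal absent words with suffix and LCP arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing minimal absent words with suffix and LCP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maws)
```

## The problem

Let `y` be a word of length `n` over an ordered alphabet of size `sigma`. A
word is an *absent word* of `y` if it does not occur as a factor
(substring) of `y`, and a *minimal absent word* (MAW) if additionally every
proper factor of it occurs in `y`. By definition a MAW has length at least
2. Although a word of length `n` can have exponentially many absent words,
it has at most `sigma * (n + 1)` minimal ones, which makes the MAW set a
practical alignment-free summary of sequence composition: two genomes can
be compared through the words each of them avoids, in time proportional to
their lengths.

`maws` computes the complete MAW set of a word. The running example
throughout is `y = AABABABB`, whose seven MAWs are

```{r}
compute_maws("AABABABB")$maw
```

## Characterisation

Write a MAW as `x = a x1` with first letter `a` and tail `x1 = x[1..m-1]`.
Collect, for any factor `w` of `y`,

* `B1(w)` — the letters immediately preceding occurrences of `w`, and
* `B2(w)` — the letters immediately preceding occurrences of the longest
  proper prefix of `w`.

Then `a x1` is a MAW exactly when `a` is in `B2(x1)` but not in `B1(x1)`:
membership in `B2(x1)` makes the longest proper prefix `a x1[0..|x1|-2]`
occur, absence from `B1(x1)` makes `a x1` itself absent, and `x1` occurs by
construction, so all proper factors occur. For `y = AABABABB` and
`w = ABB`, `A` precedes an occurrence of `AB` but never one of `ABB`, so
`AABB` is a MAW.

Not every factor needs checking. If `SA` is the suffix array of `y` and
`LCP` its longest-common-prefix array (`LCP[r]` = LCP of the suffixes
ranked `r-1` and `r`, `LCP[0] = 0`, and boundary `LCP[n] = 0`), the tail of
every MAW equals, for some rank `i`, one of the two prefixes of
`y[SA[i]..n-1]` of lengths `LCP[i] + 1` and `LCP[i+1] + 1` — the factor one
letter deeper than what the suffix shares with its sorted neighbours. That
gives `2n` candidate factors in total, ids `j = 2i` and `j = 2i + 1`:

```{r}
ix <- indexed_word("AABABABB")
ix
head(enumerate_factor_pairs(ix))
```

A candidate whose defining length would overrun its suffix (possible only
for the odd ids) is skipped; every MAW tail also has a witness occurrence
lying fully inside the word, so skipping loses nothing.

## The two passes

The sets `B1`, `B2` for all `2n` candidates are accumulated in two sweeps
over the suffix array — top-down, then bottom-up — so that each occurrence
of a candidate contributes its preceding letter exactly where needed: the
top-down pass covers occurrences at ranks at or before the current one, the
bottom-up pass those at or after it, and the union over both passes is the
complete set.

Each pass maintains:

* `Interval`, a table with one letter set per prefix length; at the end of
  iteration `i`, the entry for length `l` holds the letters already seen
  immediately before the length-`l` prefix of `y[SA[i]..n-1]`;
* `LifoLCP`, a stack of the LCP values at which `Interval` entries are
  live, always increasing from bottom to top, with at most one push per
  iteration;
* in the bottom-up pass only, `LifoRem`, which parks values above `LCP[i]`
  during the iteration; their entries are cleared when it ends.

Letter sets are bit vectors, here bits of one R integer, which caps the
alphabet at 31 letters (ample for nucleotide and protein alphabets; the
cap is checked and reported). Each iteration pops dead values (clearing
their entries), opens at most one new entry at the boundary LCP value,
reads off the partial `B1`/`B2` of its two candidates, and propagates the
current suffix's preceding letter down the stack, stopping at the first
entry that already contains it — the sets are nested downwards, so deeper
entries already agree. Pops are bounded by pushes (at most `n` per pass)
and each materialised entry absorbs at most `sigma` letters, so total work
is O(n·sigma). The counters carried on the result expose this surface:

```{r}
res <- compute_maws("AABABABB")
attr(res, "counters")
```

Emission then scans the `2n` candidates once: every letter in
`B2[j] \ B1[j]` yields one MAW, reported as the tuple `<a, (i, j))>` — first
letter plus the 0-based inclusive interval of `y` spelling the rest — and
decoded on the way out:

```{r}
res[res$maw == "AABB", ]
decode_tuple("AABABABB", "A", 5, 7)
```

## Conventions the definitions do not fix

A few boundary cases need a decision; the package resolves them as follows
and the test suite pins each one down against the brute-force definition.

* **Position 0 has no predecessor.** An occurrence starting at position 0
  contributes no letter to any `B` set; this is the only consistent reading
  of "the letter immediately preceding".
* **Single-letter candidates.** The longest proper prefix of a one-letter
  factor is the empty word, which occurs at every position `0..n`, so its
  `B2` is the set of all letters occurring in `y`. This makes the emission
  rule agree with the direct definition for length-2 MAWs (`compute_maws("AB")`
  returns `AA`, `BA`, `BB`), including letters whose only occurrence is the
  last position.
* **Duplicates.** The same factor can appear as several candidate ids (e.g.
  `A` in `ABAB`), so one MAW can be generated more than once; emission keeps
  the tuple from the smallest factor id. Any witness decodes to the same
  word, so the choice is presentation-only.
* **Interval state between passes.** The table and stacks are rebuilt from
  zero for the bottom-up pass.
* **Stack entries above the current boundary.** When an entry is popped, its
  letters collapse onto the entry at the new boundary length (they remain
  witnesses for the shorter prefix); queries for lengths between stack
  values resolve to the next live entry above, and queries above the stack
  top to the current suffix's own preceding letter. The bottom-up pass
  propagates the letters already recorded in `B1` of the even candidate, at
  the prefix lengths those letters are witnessed for (at most `LCP[i] + 1`).
* **Output order.** Within a record, words are reported lexicographically
  (byte order, locale-independent), for deterministic, diffable output.

## Suffix-array construction

The passes only require a correct `SA`/`LCP`; construction method is
interchangeable. `build_suffix_array()` uses prefix doubling on radix-sorted
rank pairs — O(n log n) with vectorised sorting, no sentinel appended, and
only the `n` real suffixes exposed — and `build_lcp()` is the classic
text-order computation with the amortised-linear comparison count.
`lcp_of_ranks()` (range minimum over `LCP`, full suffix length on the
diagonal) is provided for checking, not speed. The practical regime for
this pure-R implementation is words up to a few hundred kilobases;
chromosome-scale input is beyond its intended use.

## Sequence I/O and the command line

`read_fasta()` (Biostrings underneath) uppercases residues — genome FASTA
soft-masks repeats with lowercase, and the alphabet here is case-free — and
keeps records separate: concatenating them would fabricate factors spanning
record boundaries. Any symbol, including `N`, is a first-class alphabet
letter; the `dna_only` switch of `run_maw()` filters non-ACGT words from the
output instead of mangling the input. With `reverse_complement = TRUE` each
record is followed by a `_rc` block so the two DNA strands are reported
separately; the MAW set of the reverse complement is exactly the reverse
complement of the MAW set, a property the tests verify.

```{r}
fa <- tempfile(fileext = ".fa")
writeLines(c(">y", "AABABABB"), fa)
out <- tempfile()
run_maw(fa, out, min_len = 3, max_len = 3, quiet = TRUE)
readLines(out)
```

## Verification strategy and limits

`brute_force_maws()` implements the definition directly — enumerate all
distinct factors, test each `a·f` for absence while its longest proper
prefix occurs — in quadratic time and with no shared code. The suite checks
exact agreement exhaustively for every binary word up to length 12 and on a
thousand seeded random words (alphabet sizes 1–4, lengths up to 200), plus
the structural invariants: SA sortedness, LCP against character-by-character
comparison, the `sigma * (n + 1)` output bound, strand symmetry, and the
per-pass push bound. Random words are uniform i.i.d. letters; they exercise
the combinatorics of the algorithm, not the repeat structure, skewed
composition or ambiguity codes of real genomes, so passing them demonstrates
algorithmic correctness rather than anything biological. Genome-scale count
summaries (`maw_length_counts()`) are checked at a scale the quadratic
reference can confirm (kilobase simulated sequences); throughput on real
chromosomes is out of scope for this implementation.
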