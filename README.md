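# maws — minimal absent words from suffix and LCP arrays

`maws` computes all **minimal absent words** (MAWs) of a sequence. An absent
word of a word *y* is a word that does not occur in *y*; it is *minimal* when
every proper factor of it occurs in *y*. Equivalently, *awb* is a MAW of *y*
(for letters *a*, *b* and a factor *w*) when *aw* and *wb* occur in *y* but
*awb* does not. MAWs are "negative" sequence composition — what a genome
avoids — and are used in alignment-free sequence comparison, phylogeny
reconstruction, and studies of compositional bias; for a fixed alphabet of
size σ a word of length *n* has at most O(σ·n) of them, so they are cheap to
compare across whole genomes.

The package is aimed at people analysing DNA (or any small-alphabet text):
it reads (Multi)FASTA, handles both strands, filters by word length, and
reports each MAW either decoded or as a constant-size tuple ⟨a, (i, j)⟩
meaning "letter *a* followed by `y[i..j]`" (0-based, inclusive).

## Method

The word is indexed with its suffix array `SA` (starting positions of all
suffixes in lexicographic order) and LCP array (`LCP[r]` = longest common
prefix of the suffixes ranked `r-1` and `r`). Two facts drive the algorithm:

1. For a factor `w`, let `B1(w)` be the set of letters immediately preceding
   occurrences of `w`, and `B2(w)` the letters immediately preceding
   occurrences of its longest proper prefix. Then `x` is a MAW exactly when
   its first letter lies in `B2(x1) \ B1(x1)`, where `x1 = x[1..m-1]`.
2. The tail `x1` of any MAW is one of only `2n` candidate factors: for some
   rank `i`, the prefix of `y[SA[i]..n-1]` of length `LCP[i] + 1` or
   `LCP[i+1] + 1`.

Two passes over `SA`/`LCP` — top-down, then bottom-up — accumulate `B1` and
`B2` for all candidates, using a stack of live LCP values and a table of
σ-bit letter sets per prefix length, with at most one stack push per
iteration and O(σ) work per step. Emission then reads off `B2 \ B1` per
candidate. The package also ships a quadratic brute-force implementation of
the definition (`brute_force_maws()`), used purely as an independent check.

## Worked example

```r
library(maws)
res <- compute_maws("AABABABB")
res$maw
#> [1] "AAA"    "AABABB" "AABB"   "BAA"    "BABABA" "BBA"    "BBB"
```

The word `AABABABB` has exactly seven MAWs. Take `AABB`: the factor `AB`
occurs at positions 1, 3 and 5, preceded by {A, B} and followed by {A, B},
with `AAB` and `ABB` both present — but `AABB` itself never occurs, so it is
absent and all its proper factors occur. Each row of the result carries the
tuple encoding:

```r
res[res$maw == "AABB", ]
#> 1 minimal absent word(s) of a word of length 8 (sigma = 2)
#>  letter start end  maw length
#>       A     5   7 AABB      4
decode_tuple("AABABABB", "A", 5, 7)
#> [1] "AABB"
```

i.e. `A` prepended to `y[5..7] = "ABB"`. The underlying index is visible
too:

```r
ix <- indexed_word("AABABABB")
ix$sa   # 0 1 3 5 7 2 4 6
ix$lcp  # 0 1 4 2 0 1 3 1
```

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","maw.R",package="maws"))')" \
    -i genome.fa -o genome.maw -k 11 -K 24 -r
```

writes, per FASTA record, a `>id` block with one MAW per line (lengths 11 to
24 here), plus a `>id_rc` block for the reverse-complemented strand; one log
line per record (`id: n=... sigma=... maws=...`) goes to standard error.
`--tuples` switches to tuple output, `--dna-only` suppresses words containing
non-ACGT letters such as `N`.

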