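Package: maws
Title: Minimal Absent Words from Suffix and LCP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes all minimal absent words of a sequence: absent words of
    length at least two whose every proper factor occurs in the sequence.
    The computation indexes the sequence with a suffix array and an LCP array
    and completes two linear-work passes over them, maintaining per-factor
    sets of immediately preceding letters as bitvectors; the set difference
    between the sets for a factor and for its longest proper prefix yields
    the minimal absent words ending with that factor. Includes (Multi)FASTA
    input and text output, strand handling for DNA, a quadratic brute-force
    reference implementation for verification, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
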