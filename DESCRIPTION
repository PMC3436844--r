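Package: sansearch
Title: Suffix Array Neighborhood Search for Protein Sequence Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free retrieval of similar protein sequences by suffix
    array neighborhood search (SANS). A query set and a database are
    concatenated into indexed texts; each query suffix is merged into the
    database suffix order and the database proteins appearing in a fixed-width
    lexicographic window around the insertion point accumulate score. Includes
    the KSEARCH k-mer count dot-product baseline, greedy ungapped alignment
    (two-hit seeding, x-drop extension, colinear chaining under BLOSUM62) for
    rescoring hit lists, precision-recall evaluation of retrieval with
    per-query average-precision AUC and identity-binned relative sensitivity,
    and a deterministic synthetic benchmark generator with planted protein
    families at controlled identity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
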