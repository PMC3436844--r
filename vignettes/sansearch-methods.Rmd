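---
title: "Suffix array neighborhood search: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suffix array neighborhood search: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sansearch)
```

## The problem

Given a query set of protein sequences and a large protein database, we want
the nearest database neighbors of every query — the input a k-nearest-neighbor
function-annotation pipeline consumes — without computing alignments against
the whole database. Word filters solve this by ranking database sequences on
shared words. A fixed word length `k` is a compromise: long words are
selective but insensitive, short words the reverse. Suffix array neighborhood
search (SANS) sidesteps the choice by ranking on *suffix adjacency*: the
database suffixes that sort next to a query suffix share its longest common
prefix, whatever length that prefix happens to have, so the effective word
length adapts per position.

## Data model

The database is concatenated into a single text; each protein is followed by
a sentinel character that sorts below every residue letter (`$` in ASCII).
Because every suffix has a distinct length and the text ends in a sentinel,
lexicographic order over suffixes is strict, with the convention that a
proper prefix sorts before its extensions. Four arrays drive the search:

* `sa` — suffix array of the database text (SA-IS construction, linear time
  and space, implemented in C++),
* `isa` — its inverse (`isa[sa[l]] = l`),
* `sap` — the protein owning each suffix, in lexicographic order; sentinel
  suffixes are assigned to the preceding protein so the map is total,
* `isa_mapped` — for each query suffix, the largest database rank whose
  suffix is `<=` it, computed by a single merge pass over the two sorted
  suffix orders. A query suffix exactly equal to a database suffix maps onto
  that suffix's rank, so exact matches sit inside the left half of the window.

Offsets and ranks are 0-based half-open throughout these arrays, as is
conventional for suffix arrays (the text position vectors come straight out
of the C++ kernel); protein indices and output ranks are 1-based, as is
conventional in R. The on-disk artifacts store the text at one byte per
character, `sap` at 4 bytes and `isa_mapped` at 8 bytes per entry.

One layout choice deserves a note: `start` has `n_proteins + 1` entries with
the final entry equal to the text length (one past the last sentinel). This
is the only convention under which the slice rule
`protein i = txt[start[i] : start[i+1] - 1)` holds uniformly for every
protein including the last, and it is what the package uses everywhere.

## Scoring

For every unmasked query suffix with insertion rank `l`, the window is the
2W ranks `l-W+1, ..., l+W` clipped to the valid range — W ranks on each side
of the insertion point, so that the best-matching suffixes are covered
whether they sort below or above the query suffix. Each window rank adds 1
to the score of the protein owning that suffix (a binary identity function;
multiple suffixes of one protein inside a window each count). Scores
accumulate over all suffixes of the query protein, and the top `H` targets
(or all targets above a threshold `T`) are reported, ties broken by
ascending database index for determinism. `W = H` is the default coupling:
it guarantees at least `H` best-matching suffixes fall inside every window.

Tandem repeats would otherwise dominate the windows, so query suffixes whose
characters at positions (1,2,3) or (1,3,5) are identical are masked and
contribute nothing. For suffixes shorter than a pattern we compare only the
pattern positions available inside the suffix's own protein and mask when
those agree; in consequence suffixes of one or two residues are always
masked. This reading keeps the rule total without ever letting a pattern
cross a sentinel into the next protein, and it is the interpretation under
which an all-repeat query such as `AAAAA` scores zero everywhere.

### KSEARCH

The fixed-word-length baseline scores a (query, target) pair by the dot
product of their k-mer count vectors, `k = 6` by default — the word length
that historically performs best for protein retrieval. It is implemented
with an inverted k-mer table (a data.table join); the contract is the dot
product value, not the backend. Query k-mers starting at masked suffix
offsets are suppressed; this is the minimal reading of "masked suffixes are
ignored" (the alternative — masking whole repeat regions — would also drop
k-mers merely overlapping a repeat).

### Memory sectioning

For databases larger than memory, the database is split into contiguous
protein sections whose text fits a byte budget; each section is indexed and
searched independently and per-protein scores are summed before hit
selection. Windows are therefore computed per section. Every query suffix
contributes `2W` window hits in *every* section, so a section much smaller
than the others concentrates background score on its few proteins; the
sectioning is an approximation knob, and budgets should be chosen so
sections are of comparable size (as they are when a fixed budget tiles a
large database). Cross-section window stitching is deliberately not
attempted.

## Greedy alignment rescoring

Hit lists can be reranked by a fast ungapped alignment in the BLAST family:

1. **Seeding.** Exact 3-mer matches are grouped by diagonal; a seed is two
   non-overlapping hits on one diagonal with start-to-start distance at most
   40 residues. Exact identity (no neighborhood words) is the minimal
   seeding rule for this purpose.
2. **Extension.** From the seed span, the alignment extends left and right
   along the diagonal under BLOSUM62 scores; each direction stops when the
   running score drops more than `xdrop = 20` raw units below its running
   maximum (the standard stopping rule for ungapped extension) and the
   segment is trimmed to its maximal-scoring extent. Non-positive HSPs are
   discarded.
3. **Scan order.** The query is scanned left to right; seeds starting inside
   an accepted HSP are skipped, which is what makes near-identical pairs
   cheap: one long HSP covers the whole query and suppresses all further
   seed tests.
4. **Chaining.** HSPs are taken in descending score order and kept when
   colinear and non-overlapping with everything already kept. The total is
   the plain sum of member scores — no gap penalties. Greedy chaining can in
   principle be suboptimal; on HSP sets harvested from mutated sequence
   pairs it matches the exhaustive optimum in well over 90% of instances
   (the test suite measures this).

BLOSUM62 ships with the package as a plain NCBI-format text file and is
parsed at first use; the 20 standard-residue entries are verified in the
test suite against an independent copy. (Public matrix collections differ
slightly in the B/Z/X ambiguity rows; the bundled file follows the NCBI
distribution.) Ambiguous residues score via those B/Z/X rows; during FASTA
loading, rare residues (U, O, J) and anything non-standard are mapped to
`X`, keeping both indexing and scoring total.

## Evaluation

Retrieval is evaluated per query against an external truth table
(tab-separated query/target pairs, optionally with percent identity):

* precision `TP/P` and recall `TP/T` along the ranking;
* per-query AUC computed as average precision — the step-function
  convention, exact at rank granularity (trapezoidal integration of the
  same points differs only in interpolation and was the plausible
  alternative);
* mean AUC across queries;
* identity-binned sensitivity, each bin's recovered-pair fraction scaled so
  a reference method equals one (default bins <30, 30–50, 50–70, 70–90,
  >90% identity).

The default evaluation depth is the top 1000 hits per query. This package
never computes e-values; truth tables come from an external gold standard.

## The synthetic benchmark

The generator plants families in a background of i.i.d.-residue proteins:
family seeds are random proteins, co-members and queries are copies with
independent per-position substitutions (never to the same residue), so
planted identity is exactly `100(1-rate)` percent in expectation. Protein
lengths default to a log-normal distribution clipped to [50, 2000] with
mean about 330 residues, echoing the length statistics of curated protein
databases; an optional indel rate (default 0) exists because the suffix
mechanism tolerates indels through independent suffixes, but substitutions
alone give exact identity control.

The fixed benchmark used by the acceptance script
(`feasible_regime_spec()`) is 1000 database proteins of fixed length 300,
50 of them planted targets queried by 20 replicates each at 30%
substitution — squarely inside the 50–100% identity regime where a word
filter should place the true source at rank 1. With i.i.d. backgrounds this
is an easy instance by design: what it demonstrates is the mechanism (and
top-1 recall here is essentially 1), not performance on real data. Real
protein databases have correlated composition, domain repeats and families
at all identity levels; conclusions about the hard 30–50% regime cannot be
drawn from this generator.

Benchmark sizes throughout tests and the acceptance script (databases of
tens to a thousand proteins, texts up to ~300 kb) were chosen so the whole
suite re-verifies the brute-force oracles in well under a minute per module
while still exercising every code path at realistic sequence lengths.

## Numerical and degenerate-input choices

* Suffix comparisons cross sentinels; the sentinel is identical and minimal
  everywhere, so order within shared-prefix windows is driven by sequence
  content. Sentinel suffixes are indexed (clustered at the low ranks) and
  may appear in windows; they credit their assigned protein, keeping
  windows fixed-size, with negligible effect.
* Queries mapping before every database suffix get insertion rank −1; their
  window is clipped to the low end.
* Zero-score proteins are never reported; tie-breaks are by ascending
  database index after score (and after greedy score, then filter score,
  when rescoring).
* Records empty after cleaning are skipped with a warning rather than
  guessed at; duplicate identifiers are allowed and reported as-is.
* `k > sequence length` yields an empty k-mer vector, not an error.
* Empty hit lists evaluate to AUC 0 for queries with truth; queries absent
  from the truth table are skipped with a warning.

## Known limitations

* The SANS score has no statistical calibration (no e-values); it is a
  ranking device for the feasible 50–100% identity regime.
* Per-section windows make sectioned scores depend (mildly) on the section
  layout.
* Greedy chaining and x-drop extension are heuristics; the aligner is for
  reranking candidate lists, not for producing reference alignments.
* The generator's i.i.d. background understates the low-complexity and
  compositional structure of real sequence space; masking exists precisely
  because real data are worse.
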