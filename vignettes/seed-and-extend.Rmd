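---
title: "Seed-and-extend homology search with seqsmith: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-and-extend homology search with seqsmith: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsmith)
```

# The problem and the data model

Finding the homologs of a query protein in a large sequence database with a
rigorous Smith--Waterman alignment against every record is quadratic in the
database size and far too slow in practice.  Modern search tools therefore
organize the work as a *multi-stage filter*: cheap, permissive stages discard
most of the database, and the expensive, sensitive stages run only on the few
survivors.  seqsmith implements that architecture as a toolkit of composable
stages rather than a monolithic program, so each stage can be used, replaced
or tested on its own.

Everything rests on a numeric data model:

* An **Alphabet** fixes a bijection between symbols and integer *symbol
  codes* 0..q-1 (`A,C,G,T` maps to 0..3; the 24-symbol protein alphabet
  `ACDEFGHIKLMNPQRSTVWYBZX*` includes the BLOSUM ambiguity codes and the
  stop symbol so that BLOSUM matrices apply without remapping).  Rare
  residues U and O are folded into X on encoding, with a warning -- a lossy
  convenience for Swiss-Prot input, which contains selenocysteine.
* A **Sequence** is an alphabet plus a vector of symbol codes.  Positions
  are 0-based and intervals half-open everywhere in the package.
* An **Alignment** stores the aligned sequences plus an `L x n` *trace*
  matrix: row `l` gives each sequence's position in alignment column `l`,
  with -1 as the gap sentinel.  Non-gap positions increase strictly within
  each sequence, and every column shows at least one residue.  All aligners
  in the package emit traces satisfying these invariants, and the reported
  score of any pairwise alignment is reproducible from its trace with
  `scoreFromTrace()`.

# k-mer indexing

A `KmerTable` maps each k-mer code
\[
d = \sum_{i=0}^{k-1} q^i\, c_i , \qquad 0 \le d < q^k,
\]
to the sorted list of (reference, position) pairs where the k-mer occurs.
Construction is a counting sort: occurrence counts per code are determined
first, then fixed-size occurrence lists are filled, so no list ever grows
incrementally.  Internally one contiguous occurrence array plus per-code
offsets (a CSR-style layout over the sorted distinct codes) serves every
alphabet and k uniformly; lookup is a binary search over the distinct codes.
We chose this single sparse representation over a dense `q^k` directory
because the protein workflow's natural parameters (q = 24, k = 6) already
put a dense directory near 2 x 10^8 slots -- substantial memory for desk-scale
inputs -- while the sorted layout costs only the occurrences actually present
and has identical lookup semantics.  Codes are held as doubles, which are
exact integers up to 2^53; `q^k >= 2^53` is rejected as a configuration
error.

*Spaced seeds* generalize contiguous k-mers with "don't care" positions: a
boolean mask whose `TRUE` entries (first and last mandatory) enter the code.
Spaced patterns improve matching sensitivity at equal k because a single
mismatch no longer destroys every overlapping seed.  Per-sequence boolean
masks (e.g. from a low-complexity detector) remove a k-mer whenever *any*
informative position is masked; computing such masks is out of scope, they
are accepted as input.

Tables built over disjoint reference sets merge losslessly
(`mergeKmerTables()`), and `serializeKmerTable()` writes a self-describing
binary image (magic/version header, alphabet, pattern, references,
length-prefixed occurrence arrays), which together support building an index
in independent chunks.

Matching a query against the table is exact by default.  With a
substitution-score threshold, all k-mers scoring at least the threshold
against a query k-mer are enumerated by branch-and-bound over positions
(per-position suffix maxima as bounds) and looked up as well.  No similar-
k-mer lists are precomputed; enumeration happens per distinct query k-mer.

# Pairwise alignment stages

All aligners share one affine-gap model: a gap run of length L costs
`open + (L-1) * extend`, both parameters non-positive, via the Gotoh
three-state recursion.

* `alignOptimal()` explores the complete dynamic-programming table
  (Needleman--Wunsch--Gotoh globally, Smith--Waterman--Gotoh locally) and
  enumerates co-optimal alignments up to a cap (default 1000).  Traceback
  prefers diagonal moves over a gap in the second sequence over a gap in
  the first, making the first alignment deterministic.
* `alignLocalUngapped()` extends the diagonal through a seed pair left and
  right independently; each direction stops once its running score drops
  more than X below the running maximum, and keeps the maximal prefix.
  With X infinite this is exactly the best diagonal segment containing the
  seed.
* `alignLocalGapped()` grows the gapped table outward from the seed in both
  directions, pruning cells whose best state value falls more than X below
  the best score seen so far.  Pruning is evaluated against the global best
  so far in row-major processing order; with X infinite no cell is pruned
  and the score equals the rigorous local optimum whenever that optimum
  passes through the seed.
* `alignBanded()` restricts the table to diagonals `d_low <= j - i <=
  d_high`, bounding the number of gaps in either sequence.  Computation is
  limited to in-band cells; storage remains rectangular, a deliberate
  simplification that lets the banded and unbanded aligners share one
  traceback engine (the band's purpose here is to bound *time*, and the
  memory of desk-scale tables is negligible).  In global mode the band must
  contain diagonals 0 and `len(s2) - len(s1)`, otherwise no global path
  exists.

Numerical notes: DP values are compared with an absolute tolerance of 1e-6
during traceback (scores are integer sums for substitution matrices but
fractional for profile-column merges); ties beyond the deterministic
preference order are enumerated as distinct co-optimal alignments and
deduplicated.  Degenerate inputs are defined, not errors: a global alignment
against an empty sequence is an all-gap alignment, and a local alignment
with no positive-scoring pair is the empty alignment with score 0.

Two summary metrics are deliberately explicit because the literature rarely
defines them: `getIdentity()` counts identical columns and divides, by
choice of mode, by all columns, by columns excluding terminal gap runs
(default `not_terminal`), or by the shorter sequence length; `getCoverage()`
is the fraction of query positions present in the trace.  The defaults were
chosen so that a partially covering local alignment of a true homolog
reports the intuitive percentages (a full-length identical hit gives
100.0/100.0); other conventions are one argument away.

# E-values

Alignment scores of unrelated sequences follow an extreme-value (Gumbel)
distribution.  Instead of relying on precomputed Karlin--Altschul parameters
(which exist only for standard scoring schemes), the estimator samples
`nSamples` i.i.d. sequence pairs from a background distribution, computes
their rigorous local alignment scores, and fits by the method of moments:
\[
\hat\lambda = \frac{\pi}{\hat\sigma\sqrt{6}}, \qquad
\hat u = \bar s - \frac{\gamma}{\hat\lambda},
\]
with the Euler--Mascheroni constant gamma = 0.5772... and the sample standard
deviation (n-1 denominator).  The E-value of a score s for a query of
length m against a database of total length n is
\[
E = \frac{m\,n}{m_0\,n_0}\; e^{-\hat\lambda (s - \hat u)},
\]
where (m0, n0) are the lengths used during sampling.  The multiplicative
length rescaling is the standard m x n search-space dependence of local
alignment statistics; it is this module's *definition* of E, chosen because
the sampling procedure itself fixes only one search-space size.  Defaults:
1000 samples, sampling lengths (query length, mean database sequence
length), uniform background (with a bundled BLOSUM62 amino-acid frequency
vector and a uniform 20-standard-residue background as alternatives).
Sampling is seeded and fully deterministic.  A zero-variance sample (a
degenerate background with no positive self-score) is a fit error; the
sampler additionally warns when every sampled score is zero.

# The search pipeline

`runSearch()` chains the stages:

1. **k-mer matching** of the query against the database table (exact, or
   relaxed with `kmerThreshold`).
2. **Two-hit filter**: matches are grouped by (reference, diagonal), where
   diagonal = refPos - queryPos; only groups with at least `minHits`
   (default 2) distinct query positions survive, and each surviving group
   contributes one representative seed -- its lowest-query-position match.
   Requiring two hits on one diagonal suppresses the flood of isolated
   chance matches at small k.
3. **Ungapped X-drop extension** of each representative seed; seeds scoring
   below `ungappedThreshold` (default 20 raw score) are dropped.
4. **Banded gapped alignment** around each surviving seed's diagonal
   (band = diagonal +/- `bandWidth`, default W = 20, clipped to the table).
   W = 20 allows a net length difference of up to 20 residues between the
   aligned segments, ample for the point-mutation divergence this pipeline
   targets; it is a free parameter with no canonical published value.
5. **E-value ranking**: a Gumbel estimator is fitted once per query and
   scoring scheme, hits with E above `maxEvalue` are discarded, at most one
   hit (best E) is kept per reference, and ties are broken by score then
   reference id.

Default scoring is BLOSUM62 with gap open -11 / extend -1, the de facto
standard pairing for protein search.  Raising any stage threshold can only
shrink the hit set -- a monotonicity the tests verify explicitly.  The
per-stage defaults (`ungappedThreshold`, exact k-mer matching, W) are
exposed flags rather than constants, since published workflows vary in all
of them.

# Profiles

`sequenceProfile()` condenses an alignment into a position frequency matrix
(PFM) of per-column symbol counts `C_S` plus per-column gap counts; symbol
counts plus gaps always equal the number of sequences.  The probability
matrix (PPM) applies pseudocounts `c_p` spread uniformly over the alphabet
of size k:
\[
P(S) = \frac{C_S + c_p/k}{\sum_i C_i + c_p},
\]
so each row sums to one; gap counts never enter the probabilities.  The
weight matrix (PWM) is the base-2 log-odds `W(S) = log2(P(S)/B_S)` against a
positive background; `P(S) = 0` yields -Inf rather than an error, so the
score of an impossible sequence is -Inf while its probability is 0.
Sequence probability and score are the product of `P` and the sum of `W`
over positions, respectively.  The consensus takes the per-position maximum
count; nucleotide ties map the tied set to its IUPAC ambiguity code (the
consensus of a nucleotide profile therefore lives in the 15-symbol IUPAC
alphabet), any other alphabet resolves ties to the first symbol in alphabet
order.  IUPAC resolution is implemented for the 4-letter nucleotide alphabet
only.

# Guide trees and progressive MSA

`distanceMatrixFromSequences()` defines the guide-tree distance as
`1 - identity` of the rigorous global alignment (identity mode `all`) -- a
bounded, monotone-in-similarity dissimilarity; the choice is ours, as no
canonical formula exists.  `upgma()` performs average-linkage agglomeration
(ultrametric output; merge ties broken toward the lowest index pair, so
trees are deterministic), `neighborJoining()` the Saitou--Nei Q-criterion
agglomeration, which reconstructs additive matrices exactly.  NJ output is
rooted arbitrarily at the final three-way join, so its root has three
children; negative NJ branch lengths are kept as computed (they carry no
weight in progressive alignment, which uses only the topology).  Newick
serialization round-trips topology, labels and branch lengths; parsing
rejects unbalanced parentheses and dangling colons with the offending
position.

`alignMultiple()` implements the classical progressive scheme over the
guide tree (UPGMA by default): at each internal node the two child
alignments are merged by a global affine-gap DP over column pairs, scoring a
column pair as the *mean* of all pairwise substitution scores between
non-gap symbols, with gap-symbol pairs contributing zero.  The "simple
original" progressive algorithm admits several merge-scoring variants; the
mean-of-pairs variant was chosen because it is deterministic, reduces
exactly to the pairwise aligner for two sequences, and needs no sequence
weighting.  Terminal gaps are free during merges and gap penalties apply to
newly opened gaps only; previously inserted gaps are never removed ("once a
gap, always a gap").  The reported MSA score is the column-merge score of
the root join.

# Synthetic data: what it emulates and what it does not

The generators in this package are the fixtures for every simulation-based
test:

* `randomSequence()` draws i.i.d. symbols from a background distribution --
  the same null model the E-value estimator samples from.  The protein
  default for simulations is uniform over the 20 standard residues.
* `mutateSequence()` applies per-site substitutions (rate 0.15 in the
  planted-homolog benchmark, i.e. an expected 85% identity) and optional
  geometric-length indels, returning the true alignment alongside the
  mutant so recovered alignments can be compared against ground truth.
* `makeAdditiveMatrix()` generates random binary trees (uniform joins,
  branch lengths Uniform(0.5, 2)) and returns their exact leaf-path-length
  matrices -- additive by construction, the oracle for neighbor-joining.

These fixtures emulate composition and divergence, not biology: real
proteins have domain structure, composition bias, low-complexity regions
and indel hotspots, none of which i.i.d. sampling reproduces.  Passing the
planted-homolog benchmark therefore demonstrates that the pipeline's stages
compose correctly and lose nothing at 85% identity under the stated
parameters -- not that its sensitivity matches production search tools on
remote (< 30% identity) homology.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data at
desk scale, sizes chosen to exercise every code path while keeping a full
run in the minutes range on one CPU: 100 random pairs (lengths <= 60) for
banded-vs-rigorous equivalence, exhaustive-enumeration alignment oracles at
lengths <= 6, quadratic k-mer match scans at lengths <= 200, 50,000 draws
for Gumbel recovery, and 20 replicate databases of 200 length-300 proteins
for the planted-homolog recall benchmark.  Every stochastic component takes
an explicit seed and restores the ambient RNG state, so all results are
bit-reproducible.

# Known limitations

* Sensitivity-oriented refinements of production tools -- precomputed
  similar-k-mer lists, compositional score adjustment, island statistics,
  finite-size E-value corrections -- are out of scope; the E-value is the
  plain rescaled Gumbel tail.
* The gapped X-drop explores (and stores) the full rectangle between seed
  and sequence ends when X is infinite; it is a heuristic stage, not a
  memory-optimized kernel.
* Identity/coverage conventions differ across published tables; ours are
  documented above and configurable, but numeric comparisons against other
  tools must match conventions first.
* `mutateSequence()` is not an evolutionary model (no rate heterogeneity,
  no codon structure); it is a test-fixture generator.
* Multi-process index construction is enabled by `mergeKmerTables()` +
  serialization but not orchestrated by the package.
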