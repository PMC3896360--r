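---
title: "Key K-string phylogenetics: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key K-string phylogenetics: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keystrings)
```

## The model

A species is represented by its set of protein sequences — for metazoan
mitochondria the 13 protein-coding genes. Counting all length-K windows
(step 1, never across protein boundaries) gives observed frequencies
`p(s)` over the 20^K space of amino-acid K-strings. Raw counts mix
phylogenetic signal with neutral compositional drift, so each frequency is
compared with an order-(K−2) Markov prediction assembled from the species'
own (K−1)- and (K−2)-string frequencies:

$$p^0(a_1\dots a_K) \;=\; \frac{p(a_1\dots a_{K-1})\,p(a_2\dots a_K)}{p(a_2\dots a_{K-1})},
\qquad \mathrm{cv}(s) \;=\; \frac{p(s)-p^0(s)}{p^0(s)}.$$

The score is `0` by convention when `p^0 = 0`, and `−1` when a string is
predicted but unobserved; every score is ≥ −1. One useful consequence of
the subtraction is that a *novel* K-string whose two (K−1)-parts are
themselves unique is fully explained by the background (`p = p^0`,
score 0): the transform responds to strings whose parts are common but
whose combination is informative, not to arbitrary rare peptides.

Stacking the sparse score vectors of N species gives the CV matrix.
The variance of each column (population convention, divide by N; species
lacking a string contribute a score of 0) measures how much that string
could contribute to separating the species. Sorted variances form an
L-shaped curve, and the **critical point** at its corner is defined as a
90% reduction of the maximum variance: strings with variance strictly
greater than `0.1 · v_max` are the *key K-strings*. Because the threshold
is a fixed fraction of the maximum, selection is invariant both to the
population-versus-sample variance convention and to any uniform rescaling
of the CV rows — properties the test suite asserts.

Two refinements make selection stable rather than a one-shot cut:

* **subgroup intersection** (`extract_group_keys`): the group is randomly
  partitioned into subgroups (default 5; as many as the group supports,
  at least 2 species each), keys are selected per subgroup, and only
  strings selected in *every* subgroup survive. Strings whose variance is
  driven by a single species appear in at most one subgroup and are
  discarded.
* **repetition until containment** (`extract_broad_keys`): random test
  groups (default 20 species) are drawn repeatedly; extraction stops when
  a new group's keys are at least 95% contained in the running union, or
  after 10 groups. The intersection over groups is the *core* set, the
  union the *broad* set. Taxon-specific sets (`extract_specific_keys`)
  apply the same machinery inside each subtaxon and union the results
  with the broad set; with `reps > 1` the subgroup partition itself is
  repeated and unioned, which protects small subtaxa from an unlucky
  single partition. The 95% containment figure quantifies "almost totally
  represented", which the procedure's verbal description leaves open.

Trees are built from cosine distances `D = (1 − C)/2 ∈ [0, 1]` between
(optionally key-projected) vectors — the standard CV convention — by
Saitou–Nei neighbor joining. Support values come from a **gene-family
bootstrap**: each replicate redraws the G gene families with replacement
and the same draw is applied to all species. Resampling loci jointly,
rather than independently per species, is deliberate: independent
per-species draws would destroy the cross-species comparability of the
composition vectors that the distance relies on. With G families a
replicate keeps on average `1 − (1 − 1/G)^G` distinct genes (64.7% for
G = 13), which the tests verify against measured draws.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `K` | 5 | string length; 3–7 supported, 5 is the established optimum for protein CVs |
| `reduction` | 0.90 | variance reduction defining the critical point (threshold `0.1·v_max`) |
| `n_subgroups` | 5 | subgroups intersected within a test group |
| `group_size` | 20 | species per random test group in broad extraction |
| `max_reps` | 10 | maximum test groups / partition repetitions |
| `convergence` | 0.95 | containment fraction that stops the repetition |
| `n_replicates` | 100 | bootstrap replicates |
| `w`, `step`, `scale` | 5, 1, 15 | conservation window (aa), step, score ceiling |
| `conserved_cutoff` | 8 | window score above which a column counts as conserved |

## Numerical and policy choices

* **Sanitation**: sequences are upper-cased; the ambiguity codes B, Z, J,
  X and the stop `*` are removed (they can never match a string over the
  canonical alphabet); any other letter is a hard error. No U→C-style
  remapping is attempted.
* **Normalization**: each order's frequencies are divided by that order's
  own total window count. No end-correction factor is applied; it would
  alter scores by O(1/L) and cancels in variance ranking.
* **Ties**: selection uses strict `>` at the critical point, so ties at
  exactly `0.1·v_max` are excluded and identical species yield an empty
  key set rather than everything.
* **Degenerate cosines**: if a key projection leaves a vector all-zero,
  the cosine is defined as 0, giving the agnostic distance 0.5.
* **Negative NJ branches** are clamped to zero with the deficit moved to
  the sibling branch, preserving path lengths through the parent;
  sibling choice is deterministic (lowest node number).
* **Sharing bias**: the bias of phylum pair (row i, column j) is
  `100·(1 − shared/|set_j|)` — normalized by the *column* phylum's set
  size — rounded to one decimal, `NA` when the column set is empty. This
  is the convention that reproduces the published 11-phylum table; four
  printed cells of that table disagree with every simple formula and are
  treated as typographical anomalies by the tests.
* **Chi-square**: the classical Pearson statistic on observed versus
  `E(s) = total_windows · p^0(s)` counts with `k − 1` degrees of freedom
  for k tested strings; strings with `E = 0` are dropped (with a warning)
  before k is fixed. Calibration is checked at K = 3 under a first-order
  Markov null (`simulate_markov_sequence`, sequences of 20,000 residues,
  five probe strings chosen from mid-frequency residues with distinct
  cores), where 500 simulations keep the 5%-level rejection rate near
  nominal.
* **Conservativity**: the 0–15 window score is
  `round(scale·(m−1)/(n−1))` with m the multiplicity of the most frequent
  window segment — the simplest formula that meets the stated endpoints
  (15 iff all rows agree, 0 when all differ). Gaps are ordinary symbols,
  so only identically aligned gaps can score 15. Key-hit coverage is
  mapped through each row's residue-to-column index.
* **Topology comparison**: shared non-trivial bipartitions as a
  percentage of the larger bipartition set (100 iff identical; two stars
  count as identical), with the raw Robinson–Foulds distance attached.
  This replaces an external web tool's edge-matching score with a
  transparent, testable substitute.

## What the simulator emulates — and what it does not

`simulate_proteomes` draws a root proteome from mitochondrial-like residue
frequencies (hydrophobic-rich, so 3-string cores recur at realistic
rates — essential for CV scores to behave as on real data), then evolves
it down a balanced tree: a binary between-phyla backbone, per-phylum stems,
and within-phylum splits, each branch substituting sites with probability
`1 − exp(−rate·length)` and uniform replacement. Conserved blocks evolve at
a reduced rate; per-phylum discriminative motifs are written into the
phylum ancestor and held fixed below it, emulating clade-diagnostic
elements under purifying selection. Engineered motifs pair rare flanks
with a common core (e.g. `WLLLC`): the rare flanks make them unique to
their phylum, the common core makes their background prediction small and
their CV score large — the combination the selection machinery is built
to find.

The simulator deliberately omits: indels (so "alignments" of simulated
data are trivial), rate heterogeneity beyond the block multipliers, any
empirical amino-acid exchange matrix, codon structure, and gene
rearrangement. Passing tests on simulated data therefore demonstrate the
correctness and internal consistency of counting, selection, tree building
and localization — not robustness to alignment error, compositional
convergence, or heterotachy in real proteomes.

Fixture conditions were chosen once, as plausible desk-scale analogues:
`small4x5` (4 phyla × 5 species, full 13-gene complement, ~22% stem-level
and ~1% per-branch within-phylum site divergence, one engineered motif per
phylum) for selection and topology recovery; `vertebrate-like10x2`
(5 classes × 2 species, two conserved blocks per gene at a 10× reduced
rate covering about half of each gene, high background divergence) for
conservation localization; `twoclade-minimal` for fast end-to-end checks.
Test problem sizes (200 random proteomes for oracle equivalence, 100
additive matrices for NJ exactness, 500 chi-square simulations, 1000
bootstrap draws) keep the default suite in the tens of seconds while
leaving the statistical checks well-powered.

## Known limitations

* The variance threshold presumes an L-shaped variance spectrum; on very
  few species, or species with hardly any shared strings, `v_max` is
  driven by a handful of columns and selection can be unstable — the
  repetition-union machinery mitigates but does not eliminate this.
* Cosine distances are not additive; NJ on them is a heuristic (exact
  only on additive input, which the tests verify separately). Bootstrap
  supports inherit the usual caveats of resampling only 13 loci.
* The chi-square test treats tested strings as a fixed, data-independent
  set; choosing strings *because* they scored high inflates the
  statistic, so significance on selected key strings should be read as
  descriptive, not inferential.
* Memory and time scale with the number of distinct (K−1)-string pairs
  per species; K = 7 on large proteomes is workable but slow in pure R.
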