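---
title: "Classifying crystal lattice contacts versus biological interfaces"
author: "CrystalContacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying crystal lattice contacts versus biological interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrystalContacts)
```

## The problem

A protein crystal is a periodic packing of molecules, and every pair of
touching molecules buries some surface. Only a minority of those contacts
correspond to the physiological oligomer; the rest are artifacts of
crystallization. Telling the two apart from a single crystal structure is a
classical problem in structural biology: depositor annotations of the
"biological unit" are known to carry errors, and downstream analyses inherit
them.

`CrystalContacts` implements an evolution-plus-geometry classification stack
for this problem: it enumerates the unique pairwise interfaces a crystal
lattice generates, classifies the symmetry operator relating the two
partners, measures how much and how deeply surface is buried, scores the
evolutionary conservation of the buried patch against the rest of the
surface, and combines three indicators into a per-interface call of
biological (`BIO`) versus crystal contact (`XTAL`), with `NOPRED` where the
evidence is insufficient. Around the classifier it provides the automatic
benchmark-construction rules (crystal-form-conserved and NMR-validated
biological interfaces; infinite-assembly crystal contacts), assembly-level
call comparison and confusion-matrix metrics.

## Interface enumeration and operator classification

Chains are expanded into lattice images under all space-group operators and
unit-cell translations (shift range extended automatically when the cell is
smaller than the chain); a pair is an interface when any two heavy atoms lie
within the contact distance (default 5.9 Å, a common heavy-atom contact
bound; configurable). Symmetry-equivalent copies are deduplicated by the
unordered pair of canonical operator fingerprints — an interface seen from
partner A via operator $g$ and from partner B via $g^{-1}$ is the same
contact when both partners are images of the same chain — and by congruent
contact-residue sets for high-symmetry cells.

The operator between the two partners is classified geometrically. With
rotation part $R$ (fractional basis) and total translation $t$ (including
whole-cell shifts), a proper rotation's fold $n$ follows from
$\mathrm{tr}(R) = 1 + 2\cos(2\pi/n)$, and its intrinsic (screw) translation
is the average of $t$ over the cyclic group,

$$ w = \frac{1}{n} \sum_{k=0}^{n-1} R^k\, t , $$

which projects out the axis-location part. The vocabulary is: `AU`
(identity relating distinct chains of the asymmetric unit —
non-crystallographic contact), `XT` (whole cell translation), `FT`
(fractional/centering translation), pure rotations `2`, `3`, `4`, `6`,
screws `2S`, `3S`, `4S`, `6S`, and the improper types `-1`, `-4`, `GL`
(flagged anomalous for protein crystals; they can only occur in racemic
entries). Translations and screws generate open, non-closing assemblies —
iterating the operator never returns an image to its start — so such
interfaces can only be crystal contacts; this is exactly the
`isInfinite` flag, and the test suite checks it against a brute-force
iteration oracle over every embedded space group.

One subtlety is worth recording: the screw test uses the *unreduced*
intrinsic translation. A two-fold combined with a whole-cell translation
along its axis walks along the lattice when iterated, so between two
concrete chain instances it behaves as a screw even though its screw
component is zero modulo the lattice. Reducing $w$ modulo 1 would
misclassify such (rare) image relations as closed.

Space-group operators are read from the input file when present (PDB
`REMARK 290`, mmCIF equivalent positions) and otherwise resolved from the
Hermann–Mauguin symbol against an embedded table covering ten sohncke
groups (P1, P2₁, P2₁2₁2₁, P4₃2₁2, C2, P6₁, P3₁, P3₂21, P6₅22, I222) — the
chiral groups protein crystals actually use, sufficient for all fixtures
and tests without an external crystallography dependency.

## Buried surface and residue regions

Accessible surface area uses the Shrake–Rupley construction: each atom's
van der Waals sphere is expanded by the probe radius (default 1.4 Å,
water), sampled with a deterministic Fibonacci-spiral point set (default
960 points — no random number generation, so areas are exactly
reproducible), and a point counts as accessible when it lies outside every
neighbouring expanded sphere. The buried surface area of an interface is
$(\mathrm{ASA}_A + \mathrm{ASA}_B - \mathrm{ASA}_{AB})/2$; interfaces
below 35 Å² are dropped by default (the same bound used to catalogue
interfaces at all).

Per residue, the burial ratio $(\mathrm{ASA}_{free} -
\mathrm{ASA}_{complex})/\mathrm{ASA}_{free}$ assigns regions: **core**
(ratio at or above a threshold), **rim** (partially buried), **surface**
(untouched but exposed, at least 5 Å² free area), **interior** (no
meaningful exposure). Two core thresholds are used on purpose: 0.95 for
the geometric core count (a residue must be essentially engulfed) and a
laxer 0.70 for the evolutionary scores (which need a workable set of
clearly interface-committed residues). Both are configurable and logged in
every report.

## Sequence entropy and the three indicators

Each chain may carry an aligned-FASTA homolog alignment (query first).
Rows are filtered at an identity cutoff (default 50%, computed over
non-gap query columns with a homolog gap counting as mismatch), and each
observed residue maps to its alignment column. Column conservation is the
Shannon entropy over the 20-amino-acid alphabet (gaps and ambiguous
symbols excluded; reduced groupings are supported):
$s = -\sum_g p_g \log_2 p_g$. Profiles backed by fewer than 10 homologs
are flagged insufficient and the evolutionary indicators abstain — the
geometry indicator then decides alone.

* **Geometry**: the number of core residues (0.95 threshold, both partners
  summed); six or more call `BIO`. This indicator never abstains.
* **Core–rim**: mean core entropy over mean rim entropy (partners pooled,
  0.70 threshold); a biological core is conserved relative to its own rim,
  so `BIO` iff the ratio falls below 0.75. Abstains when core or rim is
  empty or rim entropy is degenerate.
* **Core–surface**: a sampling z-score. For each partner, random surface
  subsets of the size of its core are drawn (default 10,000 samples,
  seeded); the score is the pooled core mean entropy standardized against
  the sample-mean distribution. Strong conservation gives a negative
  score; `BIO` iff below −1.0. Abstains when a surface pool is smaller
  than its core or the sample distribution has zero spread.

The two evolutionary call cutoffs (0.75 and −1.0) are configuration
defaults inherited from the published classifier the indicators implement;
the robust-filter extremes below are the values this pipeline states
explicitly. The consensus is a majority vote over non-abstaining calls;
when both evolutionary indicators abstain the geometry call stands, and a
one-one tie with one abstention is broken by the core–surface call when
available — consistently the strongest single indicator — else by
geometry.

A **robust-call filter** marks the subset of calls safe enough for, e.g.,
estimating annotation error rates: resolution better than 2.5 Å, free
R-factor below 0.3, at least 30 homologs, a unanimous three-indicator call
(abstentions are non-unanimous), and a core–surface score below −3.3 for
`BIO` or above 0.15 for `XTAL`. An entry is judged multimeric when at
least one interface is called biological.

## Benchmark construction and comparison

`buildBioMany()` selects biological interfaces on two independent evidence
branches: conservation across crystal forms (at least 10 forms, present in
at least 80% of the known forms — cluster membership is an input
annotation) and NMR-validated dimers mapped onto X-ray structures
(resolution better than 2.5 Å, area at least 500 Å²); interfaces above
2,000 Å² are removed so the set concentrates on the hard-to-classify
range. `buildXtalMany()` selects homomeric interfaces generated by screw
or translational operators (necessarily crystal contacts), at least
600 Å², resolution better than 2.5 Å, excluding entries with helical
biological-unit annotations. Both sets are made non-redundant by greedy
single-linkage sequence clustering at 80% identity (global-alignment
identity over the shorter sequence — a reproducible, dependency-free
stand-in for the historical BLASTClust step with the same cutoff
semantics). "Better than" is read strictly, "at least" inclusively,
following the stated rules literally. `buildBenchmarkSets()` removes the
rare records selected by both rule systems from both sets, since
conflicting evidence makes them useless as labels either way.

Assembly-level predictions (e.g. PISA output) are mapped to per-interface
calls: unstable assemblies are dropped; a list containing only gray-region
assemblies yields `NOPRED` for every interface; otherwise the largest
stable assembly (first among equals) marks its member interfaces `BIO` —
matched by crystallographic operator, direction-independently — and all
others `XTAL`. The same machinery converts depositor biological-unit
annotations into per-interface calls. `confusionMetrics()` reports
sensitivity, specificity, accuracy and MCC with `BIO` as the positive
class and abstentions excluded but counted; `compareCalls()` tabulates
agreement by interface-area bin (default 200 Å² bins).

## The synthetic fixture generator

All tests run on generated toy data; nothing is downloaded. Two generators
cover the two statistical archetypes:

* `makeCrystalFixture()` builds a slab-like pseudo-protein (grid of
  two-atom residues with positional jitter) and places it in a requested
  space group. For `"LARGE"` targets the slab is centred on the group's
  screw axis with the cell's axial length set so successive screw images
  stack face-on (one big infinite-type interface, > 600 Å²); for
  `"SMALL"` the cell padding is shrunk by bisection until the closest
  lattice image sits at contact distance (~4 Å), which guarantees contact
  without interpenetration; `"NONE"` keeps generous padding. An
  independent brute-force all-images scan is returned as ground truth.
* `makeDimerFixture()` builds a biological-like two-chain complex: a
  protruding "finger" of one chain inserted into a ring-tube "socket" of
  the other, so a designed residue set is ≥ 95% buried — the geometry of a
  genuine binding site, schematically. The pseudo-atom geometry is
  deliberately not stereochemically valid protein; contact detection and
  surface burial, which is all the classifiers measure, do not require it.
* `makeAlignmentFixture()` emits homolog rows that are exact at designated
  conserved columns and uniform over a fixed symbol set elsewhere (column
  entropy converges to $\log_2 k$), or rows hitting an exact per-row
  identity target — used to make homologs that survive the 50% identity
  filter while keeping variable columns variable.

What passing these tests shows — and what it does not: the fixtures
exercise the full pipeline (file round-trips included) under controlled
truth, so they validate the symmetry algebra, enumeration completeness,
area computation, region assignment, entropy scoring and decision logic.
They do not emulate real protein shape complexity, conformational
variability, alignment errors, or the borderline biology of weak dimers;
measured accuracies on fixtures are properties of the construction, not
estimates of performance on the PDB.

## Numerical and design choices

* ASA point count 960 balances determinism, speed and ~0.3% pair error
  against a 9,600-point oracle; the point set is identical across runs.
* The "zero" tolerance for screw components and region ratios is 1e−6;
  operators are exact rationals so this only guards float paths.
* Surface sampling in the core–surface score draws per-partner subsets
  from disjoint pools and restores the caller's RNG state afterwards;
  identical inputs and seed give identical scores.
* Ties in cluster representatives go to the longest sequence, then
  lexicographic entry id. Equal-size stable assemblies resolve to the
  first encountered.
* Chains shorter than 10 residues are excluded from interface analysis by
  default (engineered tags and short peptides), configurable.
* Entries determined by NMR carry only the identity operator; only
  non-crystallographic (`AU`) contacts are enumerated for them.
* Problem sizes in the test suite and acceptance script (slab chains of
  16–49 residues, 40–500 homolog rows, 2,000 surface samples per score,
  50 fixtures per class) were chosen as the smallest sizes at which each
  property is stable and are stated in the scripts themselves.

## Limitations

The classifier makes per-interface calls only: no assembly graph is
reconstructed, so mutually exclusive interfaces are not reconciled into a
single quaternary model. Homolog search and alignment construction are out
of scope (alignments are inputs). The embedded space-group table covers
the sohncke groups used by the fixtures, not all 230 groups; files
carrying their own operator lists work regardless. Improper operators are
classified but flagged anomalous, and the infinite-assembly rule follows
the conservative reading that only translations and screws force open
assemblies.
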