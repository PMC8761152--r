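---
title: "Quality assessment of predicted transmembrane protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of predicted transmembrane protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep-learning structure predictors assign every residue a confidence score
(pLDDT, stored in the B-factor column of deposited models), but pLDDT alone
cannot tell whether an alpha-helical membrane protein has been built with a
physically sensible membrane topology: a model can be locally confident and
still thread its helices through the bilayer incorrectly.  `memqa`
implements a geometry-based check that needs nothing beyond the predicted
C-alpha trace and an independent membrane-topology annotation (consensus
predictions of which segments span the membrane and which side each
flanking loop faces), plus the structural-comparison machinery used to ask
the complementary question at higher resolution: does a predicted
transmembrane domain reproduce a known fold?

## The hydrophobic-thickness statistic

For each membrane-spanning helix the topology annotation gives two endpoint
residues, one on each side of the bilayer.  Collecting all endpoints into
two sets (side1 = inside, side2 = outside, fixed mapping for determinism)
and taking the Euclidean distance between the unweighted centroids of their
C-alpha coordinates yields the *hydrophobic thickness* of the model.  In a
correctly built structure this distance falls in the physiological
hydrophobic-slab range; the package flags models outside the closed band
**[15, 35] Angstrom** as `suspect`.  The statistic is deliberately crude —
it uses only 2 points per helix — which is what makes it robust: an
inverted helix, a collapsed bundle, or a sheared domain all pull the two
centroids together (or apart) regardless of how confident the predictor
was.

Because the annotation can itself be wrong, a flagged model is
cross-classified against the topology-prediction reliability score
(0-100):

| thickness      | reliability >= threshold | reliability < threshold |
|----------------|--------------------------|-------------------------|
| in [15, 35]    | `consistent`             | `consistent`            |
| outside        | `likely_af2_error`       | `twilight`              |

The reliability threshold for "high" is not a published constant; the
package pins the default at **90** (configurable, echoed in every output
header) so results are reproducible and the choice is visible.  Band
boundaries are inclusive on the ok side, i.e. exactly 15 or 35 Angstrom is
not flagged.

Open choices resolved here: per-region mean pLDDT weights residues, not
segments; all annotated spanning helices enter the thickness statistic,
including low-confidence ones; re-entrant (non-spanning) membrane segments
are excluded from side assignment and reported in diagnostics.

## Structural comparison

The comparison engine is self-contained:

* **Kabsch superposition** — closed-form SVD solution of the optimal
  proper rotation; degenerate (collinear, < 3 pairs) input is rejected.
* **TM-score** — `(1/L_norm) * sum_i 1/(1 + (d_i/d0(L_norm))^2)`,
  `d0(L) = 1.24 (L-15)^(1/3) - 1.8` floored at 0.5 Angstrom, maximized with
  the standard iterative fragment-seeded search: seed windows of length
  `L, L/2, L/4` (every contiguous window of length >= 4 when the problem
  has <= 32 pairs), each refined by re-superposing on the pairs inside a
  cutoff that shrinks from `d0` toward `d0/2 + 1` (floor 3 Angstrom) until
  the inclusion set stabilizes (20 rounds).  Normalization defaults to the
  reference (fold-library) length; both normalizations are reported by the
  pairwise driver.
* **GDT_TS** — mean over 1/2/4/8 Angstrom cutoffs of the maximum
  percentage of aligned pairs simultaneously inside the cutoff, searched
  with the same seed-and-extend scheme.  The denominator is the number of
  aligned pairs.
* **Sequence-independent alignment** — transmembrane folds repeat at
  sequence identities well below 30%, so the aligner never looks at the
  sequence: gapless threading seeds at a scan of offsets, then alternating
  rounds of dynamic programming over `S_ij = 1/(1+(d_ij/d0)^2)` (affine
  gap: open 0.6, extension 0, free end gaps; the DP kernel is compiled)
  and re-superposition, until the correspondence is stable.  Ties between
  equal-scoring seeds resolve to the first in scan order.  Secondary
  structure terms of the full TM-align heuristic are intentionally
  omitted; correctness is established against exhaustive-seed oracles and
  threshold behavior, not bit-compatibility with any external binary.

One numerical subtlety is worth recording.  The textbook identity "all
pairs at distance d0 gives TM-score 0.5" holds only *at a fixed
superposition*: the per-pair weight is convex at d0, so the free
maximization profitably collapses half the pairs at the cost of the rest
and scores strictly above 0.5 on such a construction.  `tm_score()` and
`gdt_ts()` therefore accept an explicit `superposition` argument used by
the identity checks; the free search remains the default everywhere else.

Verdicts follow the established TM-score scale: >= 0.5 same fold,
<= 0.3 unrelated, the open interval in between is the twilight zone (the
boundary assignment to the non-twilight sides is this package's pinned
choice).

## Fold classification and target selection

`classify_fold()` scores a query against every entry of a reference
library (by default named after the eight ABC transporter TM fold
families: Pgp, ABCG2, MalFG, BtuC, EcfT, LptFG, MacB, MlaE), keeps all
eight scores and assigns the argmax with a deterministic name-order
tie-break.  The bundled library is synthetic (eight structurally distinct
helix bundles); real libraries are supplied as `reference_fold()` entries
carved from experimental structures.

Target selection from hmmsearch output follows the standard stringent
recipe: per-domain independent E-value <= 0.001 and a match covering at
least 90% of the HMM profile length, both inclusive.  The coverage is
measured in HMM profile coordinates (`hmm_to - hmm_from + 1`), one of two
defensible readings of "match length"; the choice is pinned here.  Per
target, the lowest-E hit wins, making per-protein tallies single-count.

## What the synthetic generator does and does not emulate

`generate_bundle()` builds antiparallel ideal alpha-helix C-alpha traces
(rise 1.5 Angstrom/residue, 100 degree twist, 2.3 Angstrom helix radius)
on a circle, alternating direction, optionally tilted with tilt azimuths
spread evenly around the bundle, joined by loops that arc outside the
membrane slab, with confidence painted per region and a matching topology
annotation.  Defaults — 4 helices of 21 residues, 30 Angstrom target
thickness, 8 Angstrom bundle radius, zero tilt and noise, reliability 95 —
describe a typical single-domain alpha-helical membrane protein.  Because
the pinned rise conflicts with placing boundary residues exactly on the
slab faces for arbitrary lengths and tilts, each helix is compressed
axially by `T / (1.5 (L-1) cos tilt)` (validated <= 1) and the assembled
bundle is calibrated — endpoint-centroid axis rotated onto z and rescaled —
so the pre-noise ground-truth thickness is *exact* for every valid spec.
Decoys (`make_decoy()`) emulate characteristic failure modes: one helix
reflected through the membrane midplane, a z-collapse to 0.4x (thickness
12 Angstrom from a 30 Angstrom bundle, below the flag band), and a z-shear
of half the helices.

The generator emulates exactly what the statistics consume — geometry,
topology, painted confidence — and nothing else: no side chains, no
lipids, no energetics, no sequence-structure relationship, and its
confidence values are constants per region rather than the spatially
correlated pLDDT fields of real predictors.  Passing tests therefore
demonstrate that the *statistics and algorithms* are computed correctly
and that the flag separates the constructed failure modes; they do not
certify error rates on real predicted proteomes, which require the real
structure, topology and membrane databases.

All randomness is drawn from a per-spec integer seed through an RNG-state
preserving helper; there is no global-seed dependence, and identical seeds
give byte-identical structures.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run entirely on synthetic
data at deliberately modest sizes — bundles of 2-6 helices (roughly
50-150 residues), libraries of eight folds, 20-100 replicate seeds,
10^4 draws for bin-fraction checks — which keeps the full suite in the
low minutes on one core while leaving every statistic's sampling error
far below its test tolerance.  Key tolerances: PDB round-trips are exact
to the 1e-3 Angstrom field precision; isometry invariance holds to 1e-6
relative (the transforms themselves are exact, the tolerance absorbs
floating-point accumulation); Kabsch matches a quaternion/random-sampling
brute force to 1e-3 Angstrom; the TM-score search matches an
exhaustive-seed oracle to 1e-9 on problems small enough for the
exhaustive scan.

## Known limitations

* The thickness statistic presumes alpha-helical, membrane-spanning
  topology; beta-barrels and re-entrant architectures are out of scope.
* The aligner handles sequential (monotone) correspondences only; no
  circular permutations.
* GDT_TS uses aligned-pair counts as denominator, which matches the
  identity-correspondence use here but differs from target-length
  normalizations used by assessment servers when alignments are partial.
* Confidence is read from the C-alpha B-factor only; files whose B-factors
  are real displacement parameters (experimental references) produce
  values outside [0, 100], which are dropped with a warning rather than
  interpreted.
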