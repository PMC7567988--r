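---
title: "Predicting metamorphic proteins from secondary-structure uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metamorphic proteins from secondary-structure uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapred)
```

## The problem and the model

Metamorphic proteins adopt two or more distinct folds under native
conditions, typically with large differences in secondary structure between
folds — whole helices becoming strands and vice versa. Monomorphic proteins
keep one fold. The premise of this package is that a sequence compatible
with two secondary structures *confuses* secondary-structure predictors: at
residues inside the fold-switching region the predicted three-state
distribution (P(H), P(E), P(C)) is spread out rather than concentrated.

The per-residue **diversity index** quantifies that spread as the
reciprocal Simpson/Herfindahl concentration,

$$DI_i = \left(P_i(H)^2 + P_i(E)^2 + P_i(C)^2\right)^{-1} \in [1, 3],$$

equal to 1 when the predictor is certain and 3 at the uniform distribution.
At those two limits it coincides with the exponentiated Shannon entropy; in
between the two measures differ slightly, and the package asserts their
equality only at the limits. Fold-switching regions are contiguous, so the
decision statistic is not any single residue's index but the maximum moving
average over windows of `cr` consecutive residues restricted to the interior
of the chain; the sequence is called metamorphic when

$$\max_{i}\ \frac{1}{CR}\sum_{j=0}^{CR-1} DI_{i+j} \;>\; DI_{thre},$$

with a **strict** inequality — a window mean exactly at the threshold is
monomorphic. Windows are 1-based and inclusive; because the maximum of
window means is taken, ties inside the maximum are irrelevant.

## Parameters

* `cr` (residues): moving-average window length. Grid default 6–15. Short
  windows respond to brief uncertainty spikes; long windows demand extended
  ambiguous regions. The window maximum is *not* monotone in `cr`, so the
  package does not assume or assert any ordering across window lengths.
* `di_thre` (dimensionless, 1–3): decision threshold on the window-max
  index. Grid default 1.4–2.6 in steps of 0.05 (250 grid cells total).
* `terminal_exclude` (residues, default 5 per terminus): predictors are
  systematically uncertain at chain ends for reasons unrelated to fold
  switching, so windows are confined to positions
  `[terminal_exclude + 1, L − terminal_exclude]`. The default of 5 matches
  the eligibility arithmetic used for reference-set curation (a usable
  sequence must exceed the largest window plus 2 × 5 flanking residues). It
  is configurable because reasonable pipelines differ on whether the
  exclusion applies at prediction time or only during dataset screening;
  both behaviors are supported.

## Training and evaluation conventions

Metamorphic is the positive class everywhere. Quality is measured by the
Matthews correlation coefficient, with TPR/TNR/accuracy reported alongside;
accuracy is never used for training because it hides class imbalance.

* **Degenerate confusion matrices.** If any marginal (TP+FP, TP+FN, TN+FP,
  TN+FN) is zero the MCC denominator vanishes; such cells are assigned
  MCC 0, the standard convention, which keeps one-sided grid cells
  comparable rather than undefined.
* **Grid-search tie-breaking.** Separable data produce many MCC-1 cells.
  The search returns the lexicographically smallest `(cr, di_thre)` optimum
  so training is deterministic.
* **Cross-validation.** The dataset is shuffled once with a caller-supplied
  integer seed and split into `k` chunks whose sizes differ by at most one
  (the first `n mod k` chunks take the extra entry). Each fold grid-searches
  the other `k − 1` chunks and evaluates the selected cell on the held-out
  chunk; the summary reports means and sample SDs across folds. Small folds
  can end up single-class, in which case the held-out MCC is degenerate
  (0 by the convention above) — with the default six folds this matters only
  for very small datasets.
* **Two-descriptor discriminant.** Lines in the `(di_a, di_b)` plane are
  parameterized by their unit normal at integer angles 0°–179° plus an
  offset taken at every midpoint between consecutive projected points, each
  in both orientations. For any fixed angle this enumerates every distinct
  labeling a line with that normal can produce on the sample, so the search
  is exhaustive up to the 1° angular resolution and immune to vertical-line
  pathologies of slope/intercept grids. Scan order (angle, then offset,
  high side first) breaks ties deterministically.

## Profile ingest and numerical choices

Predictor output is parsed from PSIPRED `.ss2` files (columns: index,
residue, state letter, then coil/helix/strand probabilities; the state
letter is ignored) or from the package's normalized TSV (a
`# id=... source=...` header, then `position residue p_h p_e p_c` rows with
six-decimal probabilities, so a write/read round trip preserves values to
1e-6). Printed 3-decimal probabilities rarely sum exactly to one, so each
row is renormalized by its own sum; a row drifting more than 5% from 1 is
treated as corrupt and rejected. Renormalizing changes the index by well
under 0.01 for rounding-level drift, which is negligible against the 0.05
threshold grid. After ingest, rows sum to 1 within 1e-9 and the index
computation enforces that tolerance.

Eight-state DSSP strings are reduced with the standard convention
(H, G, I → H; E, B → E; everything else → C).

## Reference-set curation

The monomorphic ("parent/child") screen consumes locally supplied records —
aligned three-state secondary-structure strings and matched Cα coordinates —
and applies, in order:

1. **Metadata:** deposited ≥ 10 years ago; X-ray resolution ≤ 2.2 Å
   (non-X-ray entries carry no resolution and pass this gate, since the
   criterion is about X-ray model quality); more than 30 deposited
   structures at ≥ 50% sequence similarity; length strictly between 40 and
   250 residues. Each drop names the first failing criterion.
2. **Structure:** drop the parent if *any* pair exceeds 2.4 Å superposed
   RMSD or scores above 9 on the windowed mismatch. Both bounds are strict
   ("exceeds"), so a pair exactly at a bound is kept. RMSD uses least-squares
   Kabsch superposition (via `bio3d`); inputs with fewer than 3 points or
   collinear configurations are rejected since the optimal rotation is then
   ill-determined.
3. **Keywords:** case-insensitive substring screen of abstracts for
   fold-switching language.

The mismatch score slides a 30-column window over *alignment columns*;
gapped columns cost 0, because the score is a sum over aligned residues.
Alignments shorter than the window are scored over their full length. A
global-alignment utility (Needleman–Wunsch, BLOSUM62, gap open −10 /
extend −0.5, via Biostrings) is provided for building inputs, but the
filters accept pre-aligned strings so alignment settings never silently
change filter outcomes.

The metamorphic set uses eligibility rules (length ≥ 40; an annotated
switch region must not lie entirely within 20 residues of either terminus)
and audited list edits: `apply_list_edits()` reproduces a final count from a
base count plus removal/addition ledgers, e.g. 192 − 8 + 17 = 201 for the
reference metamorphic list.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces profiles with the qualitative structure that
motivates the classifier. Monomorphic sequences are runs of a dominant state
at probability `mono_confidence` (default 0.95, background DI ≈ 1.1) with a
single 50/50 row at each run boundary — mimicking the brief index spikes
real predictors show at secondary-structure element boundaries, which the
moving average must smooth away. Metamorphic sequences add one contiguous
segment (default 20 residues, placed away from the termini) whose rows sit
near the simplex point with index `meta_segment_di` (default 2.8). That
point is found in closed form by inverting the index along the edge-to-center
path of the simplex: `(p, 1−p, 0)` for targets ≤ 2 and `(p, p, 1−2p)`
above 2 — chosen for invertibility, not realism. Row jitter is Dirichlet
noise around the target with concentration `noise_scale` (default 200; the
boundary-jump rows are part of this noise model, so an infinite
concentration yields exactly-on-target rows and no jumps). Sequence lengths
are uniform on 60–120 residues, in the short-globular range the curation
rules target, and everything is deterministic given the seed.

These defaults make the two classes cleanly separable, which is the point:
they verify the *machinery* — that grid search finds a perfect cell when one
exists, that cross-validation folds behave, that monotonicity holds. Passing
them says nothing about performance on real predictor output, where
metamorphic signal is far weaker (published MCCs on real reference sets are
around 0.3–0.45) and uncertainty has structure the Dirichlet model lacks:
correlated errors along the chain, predictor-specific confidence
calibration, outermost-strand and short-subdomain artifacts, and genuinely
ambiguous monomorphic sequences. The generator also makes no attempt to
model amino-acid composition; residue letters are drawn uniformly.

`generate_curation_cluster()` builds the matching toy inputs for the
structural filters: a `monomorphic_like` cluster (children are rigid motions
of the parent with sub-angstrom jitter and ≤ 2-point secondary-structure
disagreement) that must be kept, and a `kaib_like` cluster containing one
child with a 14-residue helix-to-strand conversion (mismatch score 28) and
large non-rigid displacements (superposed RMSD far above 7 Å) that must be
dropped — the qualitative contrast seen between a real fold-switcher's
structure cluster and a well-behaved monomorphic one.

## Problem sizes and determinism in the shipped tests

The test suite exercises the full grid (250 cells) and six-fold
cross-validation on a 100-sequence synthetic dataset, brute-force window
enumeration on 1000 random traces up to length 200, the Pearson-correlation
identity for the MCC on 1000 random confusion matrices, 10,000-point simplex
sampling for the index bounds, and a quaternion-sampling rotation search as
an independent check on the Kabsch RMSD for small coordinate sets. All
stochastic steps take fixed seeds, so the suite is fully reproducible.

## Known limitations

* The classifier reports the window maximum but does not attempt to localize
  the fold-switching region beyond it.
* Running secondary-structure predictors, and generating the PSSM/HMM
  profiles they consume, is out of scope; the package starts from their
  emitted probabilities.
* The monomorphic curation screen can only be as good as the deposited
  structures: a protein whose alternate fold has never been solved will pass
  every filter.
* Dirichlet-jittered synthetic profiles are a deliberately idealized
  stand-in for predictor output; conclusions about real-data performance
  require real predictor profiles and the curated reference sets.
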