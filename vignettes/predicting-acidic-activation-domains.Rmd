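---
title: "Predicting acidic activation domains from sequence composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting acidic activation domains from sequence composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadpred)
```

## The model

Transcription factors activate gene expression through activation
domains: intrinsically disordered regions that recruit coactivators.
The largest known class is acidic. Under the *acidic exposure* model,
the residues that contact coactivators are aromatic (W, F, Y) and
leucine residues; left to themselves these hydrophobic residues collapse
onto each other, and it is the interspersed acidic residues (D, E) that
repel one another and keep the hydrophobic side chains exposed to
solvent. The operative signal is therefore not a motif but a *balance of
composition*: enough acidity and enough hydrophobic residues within a
short disordered stretch.

`tadpred` turns that balance into a classifier. Every protein is
decomposed into sliding windows ("tiles") of 39 residues spaced every
residue, so a region of length $L \ge 39$ becomes $L - 38$ tiles (a
45-residue region becomes 7). Each tile is summarized by two numbers:

* **net charge** $c = \#K + \#R - \#D - \#E$ (histidine and nonstandard
  letters count zero), and
* **hydrophobic count** $h$, the number of residues from a configurable
  set, W+F+Y+L by default.

A *boundary model* is a region of the $(c, h)$ plane. The package ships
three presets, all anchored by two reference 39-residue tiles with known
strong activity: a CITED2 tile at $(-9, 10)$ and a VP16 H1 tile at
$(-13, 7)$.

* `original` — diagonal geometry:
  $c \le -9 \;\wedge\; h \ge 7 \;\wedge\; (c + 9) - (h - 10) \le 0$.
  The third term is a slope-1 line through the CITED2 anchor that
  interpolates between the two anchors; it removes tiles that are only
  mildly acidic without compensating hydrophobicity.
* `corner` — the same two thresholds without the diagonal.
* `improved` — trapezoid geometry over W+F+L:
  $-13 \le c \le -8 \;\wedge\; h_{\mathrm{WFL}} \ge 6$. Both charge
  bounds are inclusive. Relative to `original` it relaxes each threshold
  by one, drops Y (which contributes little predictive power), and adds
  a lower charge bound so that extremely acidic tiles — which in real
  proteomes are almost never activation domains — are excluded.

Tiles passing the model are aggregated: tiles overlapping by at least
one residue are chained transitively (single-linkage over intervals) and
each chain becomes one predicted domain spanning the union of its
members. Abutting but non-overlapping tiles are never chained. Interior
tiles of a long chain need not individually pass; the first and last
members always do.

```{r presets}
preset_model("original")
grid <- expand.grid(net_charge = -15:-7, hydro_count = 5:12)
grid$region <- assign_region(grid$net_charge, grid$hydro_count)
table(grid$region)
```

`assign_region()` dissects the plane into the sub-regions used to study
*which* part of the boundary carries predictive power: A (CITED2-like,
high hydrophobic count), B (balanced), C (VP16-like, strongly acidic), D
(passes the corner but fails the diagonal), and the one-step relaxations
E (hydrophobic threshold lowered by one) and F (charge threshold raised
by one). The exact A/B/C split is configurable via `region_scheme()`;
the defaults split the original region at the CITED2 hydrophobic count
(A: $h \ge 10$) and the VP16 net charge (C: $c \le -13$), an explicit
approximation chosen because the published split is defined only
graphically.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window` | 39 residues | tile length; the length-scale of the underlying activity experiments |
| `step` | 1 residue | tile spacing |
| `charge_max` | −9 (`original`), −8 (`improved`) | least-acidic accepted net charge |
| `charge_min` | −13 (`improved` only) | most-acidic accepted net charge (trapezoid) |
| `hydro_min` | 7 (`original`), 6 (`improved`) | minimum hydrophobic count |
| `slope` | 1 (`original` only) | diagonal slope; `NULL` means corner geometry |
| `residue_set` | WFYL (`original`), WFL (`improved`) | hydrophobic axis |
| acidic threshold | net charge < −3, strict | classifies a whole annotated region as acidic |
| richness rule | ≥ 15% of one letter | Q-/P-/S-/A-/G-rich classes |
| `min_overlap` | 1 residue | overlap needed for any interval match |

Whole annotation regions are classified directly on their full sequence,
never via their tiles: many curated domains are shorter than one window,
and the acidic rule is defined on domains, not tiles.

`from_anchors()` re-derives thresholds from anchor *sequences* when the
residue set or window changes, which is how variant scans
(`variant_scan()`) sweep alternative hydrophobic alphabets: the anchors
are recounted under the new set, `charge_max` is the less acidic anchor
charge, `hydro_min` the smaller anchor count, and the diagonal is
re-anchored accordingly.

## Evaluation machinery

Benchmarking against curated domain lists uses interval overlap with a
deliberately permissive 1-residue minimum. `evaluate_predictions()`
counts prediction-level true positives (predictions hitting at least one
truth entry) and truth-level sensitivity (truth entries hit at least
once) separately, because one prediction can span two annotated domains
and one domain can attract two predictions. True negatives are counted
at the protein level — proteins with neither predictions nor annotated
domains — since residue-level negatives are not meaningful for sparse
interval sets. F-scores use the standard harmonic mean and are defined
as 0 when precision and recall are both 0. A caution that applies to
every benchmark here: curated lists are incomplete, so "false
positives" include genuinely novel domains, and measured precision is a
lower bound.

`permutation_test()` asks whether predictions overlap a truth list more
than random regions would. The null preserves the *structure* of the
prediction set: each permutation samples (without replacement) as many
proteins as there are distinct predicted accessions, and re-creates each
accession's profile — its number of predictions and their exact lengths
— inside one sampled protein at uniformly random positions. Keeping
multiple regions on the same sampled protein is more stringent than
scattering them independently. The p-value uses the add-one convention
$p = (r + 1)/(N + 1)$, so it is never exactly zero and is conservative
under ties. A sampled protein too short for a required region is
resampled from the proteins not currently in the sample, with bounded
retries.

Composition enrichment between two tile populations
(`composition_ttest()`) uses the Welch unequal-variance two-sample test
with Bonferroni correction over the features tested; the unequal-variance
form is a deliberate choice because the compared tile sets differ wildly
in size and spread. Features constant in both groups are flagged rather
than tested. Motif enrichment (`motif_shuffle_enrichment()`) compares
observed motif counts (overlapping matches allowed, plain strings) to a
null that shuffles each sequence uniformly — composition preserved,
arrangement destroyed — which is the right null for a composition-driven
model: a motif is only "grammar" if it beats sequences with identical
composition.

## The synthetic generator

`generate_proteome()` builds transcription-factor-like proteomes in
which ground truth is known by construction, so the whole pipeline is
testable without downloading anything. Background sequences are drawn
letterwise from configurable frequencies; the default is near-uniform
with a mild K/R excess, mimicking the slight positive charge of real
transcription factor tiles (DNA binding domains are basic), and excludes
tryptophan so that boundary-crossing background windows are rare at
small sample sizes. Planted segments are constructed deterministically —
D/E letters supply the target net charge, residue-set letters the target
hydrophobic count, charge-free non-set letters fill the rest — then
shuffled, so their composition is exact while their arrangement is
random, mirroring the composition-over-grammar character of the model
itself.

Default study conditions: 50 proteins of 250–400 residues, 20 planted
39-residue segments at net charge −10 with 9 W/F/Y/L residues. The
planted point $(-10, 9)$ lies on the diagonal of the original model
($(c+9)-(h-10) = 0$), the most adversarial position that still passes
it; any planted point must satisfy $h \ge c + 19$ to be recoverable by
the diagonal geometry at its exact window, and $(-10, 9)$ is the minimal
such point at that charge. With these defaults the original predictor
recovers all 20 plants (sensitivity 1.0) and the permutation p attains
its minimum $1/(N+1)$.

`generate_null_proteome()` instead places truth intervals uniformly at
random, independent of composition. Calibration experiments use it with
constant protein lengths so that observed and permuted placements are
exactly exchangeable; the package's calibration check (500 replicates,
$N = 199$, 120 proteins of length 300, 180 truth intervals of length 60,
300 random "prediction" regions) uses a dense-overlap regime on purpose:
the overlap count is a discrete statistic, and when it takes only a few
values the add-one p is markedly conservative at nominal 0.05. In the
dense regime the null count spans many values and the lattice effect
shrinks below about one percentage point, putting the empirical type-I
error a little *below* 0.05 — which is the expected direction for a
conservative test, not an error.

What the synthetic data does **not** emulate: real residue-order
statistics beyond first-order frequencies, disorder structure, domain
architecture, homology between proteins, and the long acidic runs of
real proteomes. Passing the planted-recovery and calibration checks
therefore demonstrates that the machinery is correct, not that the
biological error rates measured on synthetic data transfer to real
transcription factors; for real proteomes the published benchmark
numbers (reproduced by `evaluation_metrics()` from their confusion
counts) are the relevant reference.

## Numerical and design choices

* **Coordinates.** 1-based inclusive everywhere internally (the UniProt
  convention all curated lists use); conversion to 0-based half-open
  happens only when writing BED.
* **Merging semantics.** Both tile aggregation and annotation merging
  chain overlaps of ≥ 1 residue transitively and never merge abutting
  intervals. Merging is idempotent and order-independent; outputs per
  accession are pairwise disjoint.
* **Nonstandard letters.** X/U/B/Z are accepted with a warning,
  contribute zero charge, never count as hydrophobic, and do count in
  composition denominators — conservative and deterministic. Any other
  letter is rejected loudly.
* **Ties and degenerate inputs.** Sequences shorter than the window
  yield zero tiles, never padding. Identical anchors give a degenerate
  but well-defined model. Empty prediction sets are legal everywhere
  except the permutation test, which requires at least one prediction
  and a nonempty truth list.
* **Vertical boundary.** A vertical diagonal (infinite slope) is
  expressed as corner mode rather than a special slope value.
* **Long predictions.** `split_predictions()` exists for capping
  prediction lengths before experimental testing but is never applied
  automatically, because no principled split rule is available.
* **Determinism.** Every stochastic routine takes a seed and is
  bit-reproducible under it; proteome-level prediction is invariant to
  input order.

## Known limitations

The predictor targets one subclass of acidic activation domains — those
well described by the acidic exposure model. It does not and cannot find
Q-, P-, or S-rich domains (analogous composition rules for those classes
have no predictive power), domains whose activity depends on
post-translational modification (a phosphorylated domain can cross the
boundary that its resting sequence misses), or acidic domains relying on
residues outside the hydrophobic set. The binary decision is by design:
no per-tile activity score is produced. Window-length and residue-set
sweeps via `variant_scan()` are the supported way to probe these
boundaries, not to tune past them — the presets are fixed, interpretable
reference models.
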