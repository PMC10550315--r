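# tadpred

Mechanistic prediction of acidic transcriptional activation domains
from protein sequence.

## The problem

Transcription factors switch genes on with activation domains —
intrinsically disordered, poorly conserved regions that bind
coactivators. Unlike DNA binding domains, they resist profile-HMM
annotation, and in metazoans they have been hard to predict at all.
Strong acidic activation domains, the largest class, follow a simple
compositional logic (*acidic exposure*): aromatic and leucine residues
make the coactivator contacts, while interspersed acidic residues keep
those hydrophobic residues exposed to solvent instead of collapsed on
each other. `tadpred` is for anyone who wants to annotate candidate
activation domains on a proteome, benchmark prediction sets against
curated domain lists, or study the composition rules themselves.

## The predictor

Each protein is decomposed into 39-residue windows spaced every residue.
A window with net charge $c = \#K + \#R - \#D - \#E$ and hydrophobic
count $h = \#W + \#F + \#Y + \#L$ is accepted by the original boundary
model when

$$(c \le -9)\;\wedge\;(h \ge 7)\;\wedge\;\big((c + 9) - (h - 10) \le 0\big),$$

a region of the $(c, h)$ plane anchored by two reference tiles, CITED2
at $(-9, 10)$ and VP16 H1 at $(-13, 7)$. Accepted windows overlapping by
at least one residue are merged into predicted domains. Two further
presets are included: `corner` (the first two terms only) and the
expanded `improved` trapezoid $(-13 \le c \le -8) \wedge
(h_{\mathrm{WFL}} \ge 6)$, which trades a little precision for many more
predictions. Around the classifier the package provides annotation-list
curation and composition classes (acidic, Q/P/S/A/G-rich),
interval-overlap benchmarking, a length-distribution-preserving
permutation null, residue-set/window variant scans, intersection with
external (e.g. CNN-exported) prediction sets, and a synthetic proteome
generator with planted domains.

## Worked example

Simulate a transcription-factor-like proteome with 20 planted
boundary-passing segments, predict, and benchmark:

```r
library(tadpred)

syn <- generate_proteome(synthetic_spec(seed = 1))
preds <- predict_proteome(syn$proteome, preset_model("original"))
head(preds, 3)
#> # A tibble: 3 × 5
#>   accession start   end n_tiles tile_starts
#>   <chr>     <int> <int>   <int> <list>
#> 1 SYN0002      33    88      13 <int [13]>
#> 2 SYN0002     126   174       8 <int [8]>
#> 3 SYN0008     113   161      11 <int [11]>
attr(preds, "n_passing_tiles")
#> [1] 101

evaluate_predictions(preds, syn$truth, syn$proteome)
#> <ad_evaluation>
#>   predictions: 20   truth entries: 20
#>   TP 20  FP 0  FN 0  TN 33
#>   PPV 1.000  TPR 1.000  F 1.000

permutation_test(preds, syn$truth, syn$proteome,
                 n_permutations = 999, seed = 2)
#> <ad_permtest>
#>   observed overlap count: 20
#>   null mean: 2.08 (N = 999 permutations)
#>   p = 0.001  [(r + 1)/(N + 1) convention]
```

101 windows crossed the boundary and merged into 20 predicted domains,
one per planted segment (`n_tiles` counts a prediction's member
windows). Every plant was recovered (TPR 1.0) with no false predictions
(PPV 1.0); 33 of the 50 proteins correctly carry neither predictions
nor domains. The permutation test re-places size-matched random regions
999 times and never matches the observed 20 overlaps, giving the
minimal add-one p-value, 1/1000.

On real proteomes run `predict_proteome()` on a FASTA read with
`read_fasta()`, benchmark with `read_annotations()` +
`evaluate_predictions()`, and see the vignette
(`vignettes/predicting-acidic-activation-domains.Rmd`) for the model's
assumptions and limits.

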