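---
title: "Annotating untargeted LC-MS features against metabolic-model predictions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzFBA)
options(mzFBA.quiet = TRUE)
```

## The annotation model

`mzFBA` annotates untargeted LC-MS features — (m/z, retention time)
signals with per-growth-phase mean intensities and a differential
p-value — against compound lists by accurate mass. The underlying
assumptions are the usual ones of electrospray small-molecule
annotation:

* a metabolite appears not as its neutral mass but as one or more
  **ion species**: protonated/deprotonated molecules, alkali and
  ammonium adducts, neutral losses (water), and multimers;
* instrument mass accuracy is high enough that a narrow relative
  tolerance separates most isobars (5 ppm on a QTOF);
* co-eluting features are likely ion species of the same molecule, so
  retention-time **peak groups** carry corroborating structure;
* the **M+1 isotope ratio** measured in the raw spectra approximates
  the value implied by the molecular formula, dominated by the ~1.1 %
  per-carbon contribution of ¹³C.

Each ion rule is a row (name, polarity, multimer $n$, mass shift
$\Delta$, charge $z$) and the theoretical ion mass of a formula with
neutral monoisotopic mass $M$ is $(nM + \Delta)/z$. All $\Delta$ values
are assembled from one pinned atomic-mass table (NIST isotopic
compositions) and are **electron-corrected**: a proton is
$1.007276$ Da. At $m/z$ 100 the electron mass alone is 5.5 ppm, larger
than the matching tolerance, so this correction is not optional.

A feature may match several compounds (exact isomers such as the
hexoses, and near-isobars inside the tolerance) and a compound several
features; nothing is collapsed automatically, because only standards
(retention time, MS/MS) can resolve isomers. The ranked report orders
matches by isotope confirmation first, then absolute ppm error.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `ppm_tol` | 5 | ppm | typical calibrated QTOF accuracy |
| `alpha` | 0.05 | — | differential-significance cut on the upstream p-value; strict `<` so the boundary value is excluded (pinned for determinism; practically irrelevant) |
| `rt_window` | 10 | s | co-elution window for peak groups |
| `isotope_rel_tol` | 0.20 | relative | isotope-ratio pass band; QTOF M+1/M measurements are commonly reliable to 10–20 % |
| `n_scans` | 3 | scans/sample | pooled around the feature RT for the M+1 measurement |
| `mz_min`, `mz_max` | 50, 1000 | m/z | acquisition mass range |
| detectability `margin` | 5 | Da | see below |
| isotope extraction window | 10 | ppm | wider than `ppm_tol` so the whole centroid is integrated |

The adduct list is user-replaceable (`readAdductTable()`); the built-in
positive list is [M+H]+, [M+Na]+, [M+K]+, [M+NH4]+, [M−H2O+H]+,
[2M+H]+, [2M+Na]+ and the negative list [M−H]−, [M+Cl]−, [M−H2O−H]−,
[M+HCOO]−, [M+CH3COO]−, [2M−H]−. Deliberately absent are trimers and
fragment-specific neutral losses (e.g. carboxyl loss): which in-source
fragments occur depends on the functional groups of each metabolite,
and a static list that tried to cover them would mostly generate false
positives. This is why, on the glutamic-acid worked example, four of
the six co-eluting species are annotated and the carboxyl loss and
trimer are left for the user to add explicitly.

### Compound-list preparation

Model and database exports are filtered to what an LC-MS run could
report (`filterDetectableCompounds()`): compounds must contain carbon
(removing metal ions and inorganics) and have a neutral mass within
`[mz_min − margin, mz_max]`. The margin is 5 Da: it admits species
pushed into range by proton transfer while still excluding the small
inorganics (CO₂ at 43.99 Da, NH₃ at 17.03 Da) that motivate the filter.
A much larger margin would readmit exactly those molecules.

Database formulas are often stored at physiological charge (glutamate
as C5H8NO4⁻). When a `charge` column is present the neutral form is
recovered by adding $-z$ hydrogens before mass computation; without
one, the formula is used as stored and the caveat is logged. Formulas
with R-groups, parentheses or charge notation are skipped and counted
in a load report rather than guessed.

## Isotope prediction and validation

The predicted M+1/M ratio is the linear per-atom sum
$r_1 = \sum_e c_e \cdot (a^{+1}_e / a^0_e)$ over the +1 Da isotopes
(¹³C, ²H, ¹⁵N, ¹⁷O, ³³S, …). This equals the ratio of the +1 and 0
coefficients of the exact isotopologue expansion, so nothing is lost
relative to a full convolution at the M+1 peak; the test suite checks
agreement with an independent polynomial-convolution oracle over random
CHNOPS formulas (C ≤ 40) to well within 5 % relative. For a multimer
ion, $[kM+X]$, the ion contains $k$ copies of the molecule and the
predicted ratio is scaled by $k$ (adduct atoms contribute negligibly);
the dimer of a five-carbon acid is expected near 0.12, not 0.06.

The observed ratio integrates intensity in ±10 ppm windows at the
feature m/z and at m/z + 1.00335/z over the `n_scans` scans nearest the
feature RT in each sample, forms one ratio per sample, and takes the
**median across samples** — robust to individual replicates where the
M+1 peak drops below the signal-to-noise limit. When no sample yields a
measurable M+1 intensity the result is `NA` and the match is flagged
`not_evaluated`, never failed: an undetected isotope peak is an absence
of evidence. The reported `isotope_ratio_difference` is the absolute
difference (observed − predicted) while the pass criterion is relative
(|difference| ≤ 0.20 × predicted); the report carries both observed and
predicted ratios so users can apply either convention.

## Peak grouping

Grouping is single-linkage on retention time: sort features by RT and
cut wherever the gap to the previous feature exceeds `rt_window`. This
partitions the feature set deterministically and avoids the boundary
splits of fixed binning (two features 1 s apart can never land in
different groups). The trade-off is chaining — a dense RT region can
link into one long group; the within-group span is bounded by
(group size − 1) × window, which the tests assert.

## Numerical and degenerate-input choices

* All masses derive from one pinned NIST table; no mass is ever typed
  twice in the package (ion shifts are assembled from element masses
  plus the electron mass).
* Matching sorts the compound×adduct theoretical grid once and
  range-searches each feature with `findInterval`; the test suite
  proves equality with an exhaustive scan over all triples.
* Ties and ordering: match tables are sorted by (feature ID, |ppm
  error|); peak-group numbering follows elution order; both are stable
  across runs.
* Empty inputs flow through: an empty feature set, an empty match set
  and a header-only table are all valid, and plots of empty selections
  produce an empty-axes image plus a warning rather than an error.
* Retention-time units: stored internally in seconds. Files whose
  largest RT is below 60 are interpreted as minutes under
  `rt_units = "auto"` (no LC gradient finishes within a minute), with
  the decision logged and an explicit override available.
* Raw files are read through Bioconductor `mzR`; profile-mode scans
  are rejected unless local-maximum centroiding is requested.

## The synthetic-data generator

`generateDataset()` emulates the inputs of a timed-extraction bacterial
growth experiment at these default conditions: 50 compounds drawn from
a bundled pool of ~110 real metabolite formulas, 20 planted (compound,
adduct, feature) triples, 100 noise features, mass error
Normal(0, 1.5 ppm) truncated at ±4 ppm (inside the 5 ppm tolerance),
M+1 ratio noise 5 % relative, five biological-replicate raw files,
retention times uniform over 60–1200 s, and a 30 % chance per planted
compound of one extra co-eluting adduct feature. Class means follow
rise–fall, monotone-up or monotone-down growth-curve patterns. Real
formulas (rather than random ones) give a realistic mass distribution
and genuine isomer collisions, which exercise the
one-feature-many-compounds reporting path.

Noise features avoid a 15 ppm exclusion zone around **every**
theoretical compound×adduct m/z of the emitted list — not merely around
the planted masses — so the expected match set is known exactly and the
manifest's counts (significant features, matched features, matched
compounds including isomer co-matches) are reproduced by the pipeline
without slack. Everything is a deterministic function of the seed, down
to file bytes.

What the generator does **not** emulate: chromatographic peak shapes
and tailing, retention-time drift between replicates, ion suppression,
in-source fragmentation beyond the configured adduct list, background/
contaminant ions near real metabolite masses, and MS2. Passing tests
therefore demonstrate correctness of the annotation arithmetic and
bookkeeping under realistic mass and isotope noise — not robustness to
every artifact of real chromatography; on real data the false-positive
rate at 5 ppm is set by database density, not by this package.

Test and acceptance problem sizes were chosen to exercise the code well
past its defaults while staying quick on a laptop: matcher-oracle
equivalence on 100 random instances up to 500 features × 100 compounds
× 12 adducts, isotope-prediction checks on 1000 random formulas, and
end-to-end recovery over 20 generator seeds.

## Known limitations

* No false-discovery-rate estimate is attached to matches; with a
  dense database, chance isobaric hits at 5 ppm are expected and the
  isotope flag is the only built-in corroboration.
* Annotation is at the level of (feature, compound, adduct) records; a
  metabolite-level rollup is provided only implicitly through compound
  identity in the summaries, and isomers cannot be distinguished.
* Singly charged ions are the default; the adduct table accepts z > 1
  but the isotope spacing and envelope handling for multiply charged
  species is simplistic (spacing 1.00335/z, no envelope deconvolution).
* One polarity per run; cross-polarity integration happens only at the
  compound-overlap report (`runCompare()`).
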