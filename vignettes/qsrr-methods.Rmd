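---
title: "QSRR methods: descriptors, selection, models and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSRR methods: descriptors, selection, models and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrr)
```

This vignette records the modelling conventions the package implements
and the reasoning behind the deliberate design decisions. The running
example is the embedded dataset: 39 phenolic compounds with experimental
reversed-phase retention times (RT, minutes), split 25 train / 5 test /
9 validation.

## Molecules and their representation

A `molecule()` is an atom table (element, x, y, z), a bond table and a
`has_3d` flag. Structures can come from SDF/MOL V2000 files, SMILES
strings or the embedded fixture:

```{r}
mol <- fixture_molecules("Gallic acid")[["Gallic acid"]]
mol
```

**Molecules parsed from SMILES carry `NA` coordinates.** A SMILES string
specifies constitution, not geometry, so inventing placeholder
coordinates would silently corrupt the 3D descriptors. Instead,
constitutional and graph descriptors work immediately, while the 3D
families (`disp()`, `morse()`) refuse un-embedded molecules with an
explicit error until `embed_structures()` (Open Babel, `--gen3d`)
supplies a conformer. 3D descriptor values therefore depend on the
embedding program's conformer; the graph and constitutional columns do
not.

Implicit hydrogens are filled to standard valences at parse time because
every atom-weighted descriptor here (notably `mp()`) averages over *all*
atoms including hydrogens.

## Descriptors

Atomic weights come from a shipped reference table (mass, van der Waals
volume, Sanderson electronegativity, polarizability), each scaled on
carbon, plus the unit weighting: codes `u`, `m`, `v`, `e`, `p`.

* **HNar**, the Narumi harmonic index: `A / sum(1/degree_i)` over heavy
  atoms of the hydrogen-suppressed graph.
* **IDM**, mean information content on the distance magnitude: Shannon
  entropy `-sum((d/W) log2(d/W))` over the upper-triangle topological
  distances, `W` the Wiener sum.
* **Mp**, mean carbon-scaled polarizability over all atoms (hydrogens
  included). For gallic acid (18 atoms) this gives `r round(mp(mol), 4)`,
  matching the published 0.64.
* **GATS** (Geary autocorrelation) at lag *k*: the variance-normalized
  mean squared weight difference over heavy-atom pairs at topological
  distance *k*. Two degenerate cases return a 0 sentinel with a warning
  rather than an error: zero weight variance (e.g. an all-carbon
  skeleton under any carbon-scaled weighting) and no pair at the lag
  (lag beyond the graph diameter). A sentinel keeps descriptor matrices
  rectangular over heterogeneous compound sets; the warning keeps the
  degeneracy visible, and pretreatment removes such columns when they
  are constant across a dataset.
* **DISP**: the Euclidean distance between the property-weighted
  centroid and the plain geometric centroid, all atoms.
* **3D-MoRSE** signal *k* (1–32): `sum_{i<j} w_i w_j sinc(s r_ij)` with
  scattering parameter `s = k - 1` per inverse ångström and
  `sinc(0) = 1`; signal 1 (s = 0) is therefore the weight
  autocorrelation sum. The `s = k - 1` convention makes "signal 1 … 32"
  map onto the conventional scattering grid `s = 0 … 31`.

`compute_matrix()` assembles named descriptor columns
(`GATS2v`, `Mor32e`, `DISPe`, …) for a list of molecules, failing with
the compound and descriptor named if any single cell fails.

```{r}
x <- compute_matrix(embed_structures(fixture_molecules(
  c("Gallic acid", "Caffeic acid"))), paper_descriptor_set())
round(x, 3)
```

## Pretreatment and feature selection

`pretreat()` removes all-zero columns, columns sharing one value in at
least half the rows, and columns with sample variance below 0.0005 (the
study settings; both thresholds are arguments), recording the reason per
removed column.

`ufs()` (unsupervised forward selection) reduces multicollinearity
without looking at the response: it seeds with the least-correlated
column pair, then repeatedly rejects every remaining column whose
squared multiple correlation against the span of the selected set
exceeds `r2max = 0.90` and admits the remaining column with the smallest
R². Internals use modified Gram–Schmidt with re-orthogonalization; ties
resolve to the lower column index, so the procedure is deterministic and
column-order invariant.

A consequence worth knowing: the selected set can hold at most
`n - 1` linearly independent directions, so with many more columns than
rows (e.g. 100 columns, 39 compounds) UFS saturates and the retained set
is a near-basis of column space, not a list of "true" variables. On
synthetic data with planted signal columns, a *representative* of each
signal direction (the column itself or a near-copy) survives, but which
representative is data-dependent. The tests assert exactly the
procedure's contract — threshold compliance verified by brute-force
regressions — rather than recovery claims the procedure does not make.

`smlr()` is stepwise multiple linear regression with partial-F control:
enter the best candidate while its F-to-enter is at least 6, then remove
any included descriptor whose F-to-remove falls below 3. Entries are
refused when they would exhaust the degrees of freedom (`n <= p + 2`) or
make the design rank deficient. With the F-to-enter at 6, a marginal
third descriptor occasionally enters alongside a planted two-descriptor
signal — standard stepwise behaviour, which is why the recovery tests
assert containment of the planted signal rather than exact set equality.

## Models

`fit_ols()` returns a `qsrr_lm` (coefficients on standardized
descriptors by default, with standard errors, T statistics and the
usual methods). `smlr()` returns its final fit as the same class.

`train_ann()` is a hand-written one-hidden-layer perceptron trained by
BFGS on the sum-of-squares error plus quadratic weight decay (biases
unpenalized). Inputs are min-max scaled to [0, 1]; the response is
min-max scaled into the output activation's comfortable range
([0.1, 0.9] for logistic/exponential/identity, [−0.8, 0.8] for tanh) and
back-transformed at prediction time, so saturating output activations
remain usable for regression. Optimization runs in short segments;
after each segment the held-out test-subset error is evaluated and the
best-so-far weights are kept (early stopping). With identity activations
and zero decay the network's function class contains the OLS solution,
and training recovers it — the linear-limit check used in the tests.

`train_ann_ensemble()` draws architectures at random (3–8 hidden units,
all activation pairs), trains each with its own seed derived from the
master seed, and selects the network with the smallest test-subset error
(`select_on = "test"`, the default). `select_on = "validation"`
reproduces the published protocol of picking the network that predicts
the external set best — the package allows it but warns, since it leaks
the validation set into model choice and the selected model's external
statistics are then no longer strictly external.
`sensitivity_ranking()` ranks inputs by the error ratio when each input
is frozen at its training mean.

## Validation conventions

* `press()` is the plain sum of squared prediction errors.
* `q2()` is `1 - PRESS / sum((y - reference_mean)^2)`. **The reference
  mean is the training-set mean for both internal and external Q²** —
  the shared-standard-reference convention; `external_validate()` can
  also report the validation-mean convention, and `run_pipeline()`
  records both.
* `loo_cv()` is an explicit refit loop (no hat-matrix shortcut in the
  implementation; the closed form is used only as a test oracle).
* `y_scramble()` refits the model on permuted responses with the
  descriptor subset held fixed, and reports the intercept of the
  regression of scrambled R² on |cor(permuted, observed)| — near zero
  when the original fit is not a chance correlation.

```{r}
fx <- load_fixture()
ds <- fx$dataset
external_validate(ds$rt_smlr, ds$split, ds$rt_exp)
```

## The embedded dataset and reproduction scope

`load_fixture()` returns the 39-compound table (experimental RT, the
four published models' per-compound predictions, split labels, curated
SMILES) and the published model summaries (coefficient sets with
uncertainties, network architectures, the 22 descriptors retained by
UFS, printed Mp values). File integrity is checksum-verified. The SMILES
are curated from the compounds' standard nomenclature (structures are
not printed in the original data source) and were cross-validated
against an independent cheminformatics toolkit.

What is reproducible from shipped data — the training R² and external
PRESS/Q² of all four models, and the printed Mp values — is reproduced
by `reproduce_paper_statistics()` within printed-rounding tolerance.
The published regression coefficients, the 1519 → 915 → 22
descriptor-count reductions, internal Q², scrambling intercepts and T
statistics all depend on descriptor values computed with commercial
software and never printed; they are stored verbatim for reference, and
the corresponding machinery is verified against independent oracles and
planted-signal synthetic data instead.

## Synthetic data

`synth_spec()` / `synth_generate()` produce descriptor matrices with
independent standard-normal base columns, a sparse linear signal, and
designated columns replaced by noisy copies of parent columns at a
target squared correlation — the collinearity structure UFS exists to
handle. `paperlike_scenario()` fixes the study-shaped defaults: 39 rows
split 25/5/9, 100 columns, 4 informative with population R² 0.95, and
30 copy columns at copy–parent R² between 0.92 and 0.99. These defaults
are the study conditions used throughout the tests.

```{r}
d <- synth_generate(paperlike_scenario(), seed = 1)
head(d$truth$copies, 3)
```
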