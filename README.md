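# qsrr

Quantitative structure–retention relationship (QSRR) modelling for
phenolic compounds in reversed-phase liquid chromatography (RPLC).

## The scientific problem

In RPLC, a compound's retention time (RT) is governed by how it
partitions between a nonpolar stationary phase and a polar mobile phase:
bulkier, more polarizable, less polar solutes are retained longer. QSRR
models predict RT from numbers computed directly from a compound's
structure — *molecular descriptors* — so that retention can be estimated
for compounds that have never been injected, and so that the structural
drivers of retention can be read off the model.

This package implements the full pipeline used in a published QSRR study
of 39 naturally occurring phenolic compounds (phenolic acids, flavonoids
and catechins; experimental RTs between 1.63 and 6.06 min, split
25 train / 5 test / 9 validation):

1. **Structures** — SDF/MOL/SMILES input, implicit-hydrogen filling, 3D
   embedding via Open Babel (`read_structures()`, `parse_smiles()`,
   `embed_structures()`, `write_sdf()`).
2. **Descriptors** — the nine descriptors the published models use,
   computed from scratch: Narumi harmonic index `hnar()`, mean
   information content on the distance magnitude `idm()`, mean
   carbon-scaled atomic polarizability `mp()`, Geary autocorrelations
   `gats()`, centre-of-property displacement `disp()`, and 3D-MoRSE
   signals `morse()`, each under unit/mass/volume/electronegativity/
   polarizability atomic weighting (`compute_matrix()`,
   `paper_descriptor_set()`).
3. **Pretreatment and feature selection** — constant/low-variance
   filtering (`pretreat()`), unsupervised forward selection that caps the
   mutual squared multiple correlation of the retained columns
   (`ufs()`), and stepwise multiple linear regression with partial-F
   entry/removal (`smlr()`).
4. **Models** — ordinary least squares with inference (`fit_ols()`) and
   hand-written one-hidden-layer neural networks trained by BFGS with
   weight decay and early stopping, searched as a random-architecture
   ensemble (`train_ann()`, `train_ann_ensemble()`,
   `sensitivity_ranking()`).
5. **Validation** — PRESS and Q² (`press()`, `q2()`), an explicit
   leave-one-out refit loop (`loo_cv()`), external validation with the
   training-mean reference convention (`external_validate()`), and
   y-scrambling (`y_scramble()`).
6. **Pipeline** — `run_pipeline()` chains all stages under a
   `qsrr_config()` whose defaults are the study settings (variance
   filter 0.0005, constant fraction 0.5, UFS R²max 0.90, F-to-enter 6,
   F-to-remove 3, 500 networks, 500 scrambles) and writes JSON/CSV
   reports.

Everything is base R; fitting functions return classed S3 objects with
`print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods.

## Worked example

### The embedded dataset and the published statistics

The curated 39-compound retention fixture ships with the package,
together with the published per-compound predictions of the four models
(SMLR, UFS–SMLR and their neural counterparts) and the published model
summaries:

```r
library(qsrr)
fx <- load_fixture()
fx
#> Phenolics retention fixture: 39 compounds (25 train / 5 test / 9 validation)
#> experimental RT range: 1.63 - 6.06 min
```

Recompute the training R² and the external PRESS/Q² of all four models
from the printed per-compound predictions and compare with the printed
statistics (tolerances are forced by the 2-decimal predictions):

```r
reproduce_paper_statistics()
#>           model statistic recomputed printed tolerance within_tolerance
#> 1          smlr        R2     0.9461  0.9460     0.005             TRUE
#> 2          smlr PRESS_ext     1.8492  1.8470     0.010             TRUE
#> 3          smlr    Q2_ext     0.7702  0.7700     0.005             TRUE
#> 4      ufs_smlr        R2     0.8776  0.8770     0.005             TRUE
#> 5      ufs_smlr PRESS_ext     1.9093  1.9060     0.010             TRUE
#> 6      ufs_smlr    Q2_ext     0.7627  0.7630     0.005             TRUE
#> 7      smlr_ann PRESS_ext     1.4822  1.4841     0.010             TRUE
#> 8      smlr_ann    Q2_ext     0.8158  0.8145     0.005             TRUE
#> 9  ufs_smlr_ann PRESS_ext     1.1003  1.1021     0.010             TRUE
#> 10 ufs_smlr_ann    Q2_ext     0.8633  0.8622     0.005             TRUE
```

### Descriptors from structures

```r
mol <- fixture_molecules("Gallic acid")[["Gallic acid"]]
mol
#> <molecule 'Gallic acid'> 18 atoms (12 heavy), 18 bonds, no 3D coordinates (embed first)
mp(mol)     # mean carbon-scaled polarizability, all 18 atoms
#> [1] 0.6417929   # rounds to the published 0.64
hnar(mol)
#> [1] 1.565217
idm(mol)
#> [1] 5.878418
```

Constitutional and topological descriptors need no geometry; the 3D
families (`disp()`, `morse()`) refuse molecules without coordinates
until they are embedded:

```r
mols <- fixture_molecules(c("Gallic acid", "Caffeic acid", "Quercetin"))
x <- compute_matrix(embed_structures(mols), paper_descriptor_set())
round(x, 4)
#> <descriptor matrix> 3 compounds x 9 descriptors
#>                HNar    IDM     Mp GATS2v  DISPe  DISPm  Mor22v Mor28e  Mor32e
#> Gallic acid  1.5652 5.8784 0.6418 1.7748 0.0146 0.1482 -0.0061 0.3075 -0.3541
#> Caffeic acid 1.6596 6.0596 0.6597 1.5294 0.0588 0.2347  0.0436 0.0517 -0.2862
#> Quercetin    1.7838 7.6408 0.6869 1.9556 0.0436 0.1907 -0.0358 0.2947 -0.7470
```

(3D values depend on the Open Babel conformer; graph/constitutional
columns are conformer-free.)

### The full pipeline on synthetic data

The synthetic generator plants a known sparse signal plus collinear copy
columns, mirroring the study's shape (39 rows, 100 descriptors, 4
informative, split 25/5/9):

```r
d <- synth_generate(paperlike_scenario(), seed = 1)
res <- run_pipeline(d$x, d$y, d$split,
                    qsrr_config(use_ufs = FALSE, n_scrambles = 500))
res$model
#> QSRR linear model (5 descriptors, n = 30)
#> RT = +1.3424 D72 +2.6795 D3 +1.7492 D71 -1.9176 D89 +0.3626 D90 +0.4429
#> R2 = 0.9692
res$summary$q2_ext_train_ref
#> [1] 0.841
res$scrambling
#> y-scrambling (500 permutations): mean scrambled R2 = 0.167, line intercept = 0.120 (original R2 = 0.969)
```

Here `D71` and `D72` are, by construction, near-copies of the true
signal columns `D1` and `D2` (`d$truth$copies` records the map), so the
stepwise model recovered the planted signal through its collinear
proxies — exactly the situation `ufs()` exists to disentangle.

## Reproduction

* `reproduce_paper_statistics()` recomputes every published statistic
  that is recomputable from the shipped data (see above; all ten are
  reproduced within printed-rounding tolerance).
* The acceptance script recomputes the published mean-polarizability
  value for gallic acid from the curated structure:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
  # Mp(gallic acid) = 0.64 (n = 18) -> results/acceptance.json
  ```

* The published regression coefficients, descriptor-count reductions
  (1519 → 915 → 22), internal Q² values, scrambling intercepts and T
  statistics depend on descriptor values from commercial software that
  were never printed, so they cannot be recomputed from shipped data;
  they are stored verbatim in the fixture
  (`load_fixture()$models`) and the corresponding machinery is verified
  against independent brute-force oracles and planted-signal synthetic
  data instead (see `tests/testthat/`).

## Testing

```r
testthat::test_dir("tests/testthat", package = "qsrr",
                   load_package = "installed")
```

The suite covers every module with hand-computed cases, independent
oracle implementations, invariance properties (rigid motions, atom
permutations, column order) and end-to-end pipeline runs; the methods
vignette (`vignettes/qsrr-methods.Rmd`) documents the modelling
conventions and deliberate design decisions.
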