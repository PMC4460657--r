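---
title: "Grid molecular-field 3D-QSAR: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid molecular-field 3D-QSAR: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridqsar)
```

## The model

3D-QSAR on a congeneric series assumes that, once the molecules are
superposed on their shared scaffold, differences in biological activity are
explained by differences in the interaction fields the molecules present to
a receptor of fixed geometry. `gridqsar` quantifies those fields as the
energy a probe atom would feel at each point of a rectangular lattice
enclosing the aligned series, and regresses activity on a small subset of
those lattice energies:

$$\mathrm{pIC_{50}} = \beta_0 + \sum_{j \in \mathcal{S}} \beta_j D_j,$$

where each descriptor $D_j$ is a steric ($S_i$) or electrostatic ($E_i$)
energy at grid point $i$, and $\mathcal{S}$ is chosen by stepwise-forward
selection. The approach stands in the CoMFA tradition; the regressor here
is stepwise multiple linear regression rather than PLS, which makes the
model sparse and directly interpretable (each selected grid point marks a
position where bulk or charge matters) at the cost of the selection
instability discussed under *Limitations*.

### Field definitions

At grid point $p$, for a molecule with atoms $a$:

* **Steric** (Lennard-Jones 12-6):
  $E_S(p) = \sum_a \varepsilon_{ap}\left[(R_{ap}/r)^{12} - 2 (R_{ap}/r)^6\right]$,
  with $\varepsilon_{ap} = \sqrt{\varepsilon_a\,\varepsilon_{probe}}$
  (geometric mean) and $R_{ap} = r_{min,a} + r_{min,probe}$ — the pairwise
  LJ-minimum distance as the sum of the per-atom radius parameters. At
  $r = R_{ap}$ the single-atom energy is exactly $-\varepsilon_{ap}$.
* **Electrostatic** (Coulomb):
  $E_E(p) = \sum_a 332.0636\, q_a q_{probe} / (D(r)\, r)$ kcal/mol, with a
  constant ($D(r) = D_0$) or distance-dependent ($D(r) = D_0 r$)
  dielectric.

Both are truncated: steric values are clamped from above at +30 kcal/mol
(they attain the clamp inside atomic cores, including the $r = 0$
singularity, which is defined rather than an error), electrostatic values
to ±30 kcal/mol. Clamping instead of masking keeps the descriptor count
identical across compounds, which the fixed-length descriptor matrix
requires.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid spacing | 2.0 | Å | conventional CoMFA lattice resolution |
| grid margin | 4.0 | Å | one vdW diameter of clearance around the series |
| probe | rmin 1.70, ε 0.107, q +1 | Å, kcal/mol, e | the conventional sp3-carbon, +1 probe |
| steric clamp | +30 | kcal/mol | standard core truncation |
| electrostatic clamp | ±30 | kcal/mol | symmetric truncation, no core masking |
| dielectric | constant, D₀ = 1 | — | simplest defensible choice; distance-dependent available |
| invariable-column tolerance | 1e-8 | kcal/mol | removes exactly-constant columns only; no variance threshold is invented |
| F-to-enter | 4.0 | — | the classic stepwise entry threshold |
| max model size | ⌊n/4⌋ | terms | the 1-descriptor-per-4-compounds overfitting guard |
| Y-randomization permutations | 100 | — | common default; any count ≥ 2 allowed |
| hit filters | pIC50 > 8, extrapolation ∈ (−1, 1) | — | the conventional screening cut |

Grid points are enumerated x-fastest from 1, and descriptors are named
`S_<i>`/`E_<i>` after their grid index; the steric block precedes the
electrostatic block. Since the original study's grid geometry is not
recoverable, identical names do **not** denote identical spatial positions
across software — which is why every matrix and model carries a grid
provenance hash and screening refuses descriptors from a different grid.

## Statistics and numerical conventions

* **OLS** is solved by QR; degrees of freedom are $n - k - 1$ throughout
  (the intercept is counted). $r^2_{se} = \sqrt{SSE/(n-k-1)}$.
* **Stepwise forward** adds the candidate with the largest partial
  $F = (SSE_{cur} - SSE_{with}) / (SSE_{with}/(n - p_{with} - 1))$ while
  $F \ge F_{enter}$; exact ties break by descriptor-name order; candidates
  collinear with the current model are skipped. The scan orthogonalises all
  candidates against the current model basis in one matrix product, so a
  full 3000-descriptor scan is a few milliseconds.
* **LOO q²** uses the exact leverage identity
  $e_{(i)} = e_i/(1 - h_{ii})$ — algebraically identical to refitting $n$
  times, which the test suite verifies against a literal refit oracle.
  $q^2_{se} = \sqrt{PRESS/(n-k-1)}$ and the pred_r² standard error
  $\sqrt{SSE_{test}/n_{test}}$ are package definitions; the source
  workflow's formulas for these are unpublished. A selected near-indicator
  column can make some $h_{ii} = 1$; `loo_q2` raises an error naming the
  row, while `stepwise_forward` reports `q2 = NA` for such a model and
  Y-randomization drops such permutations from the null.
* **Selection is not re-run inside LOO.** q² is reported for the developed
  model's fixed descriptor set. Re-selecting per fold would estimate the
  predictivity of the *procedure*, a different (and more pessimistic)
  statistic; the reported convention matches how q² is quoted for "the
  developed model".
* **Y-randomization** shuffles training labels only (the test set keeps
  true labels, preserving the external-validation contract), re-runs the
  full selection each time, and reports
  $Z = (s_{actual} - \bar{s}_{perm})/sd(s_{perm})$ per statistic, each
  against its own null, the corresponding normal-curve area
  $100\,\Phi(Z)$, and an add-one empirical p-value.
* **Contributions** are $c_j = \mathrm{sign}(\beta_j)\,100\,|\beta_j|
  s_j/\sum_m |\beta_m| s_m$ with $s_j$ the training standard deviation, so
  magnitudes sum to 100.
* **Sphere exclusion** works in autoscaled (zero-mean, unit-variance)
  descriptor space with the Euclidean metric, seeding by descending
  activity with ties broken by compound id; this keeps the activity
  extremes in training, which external validation against the training
  mean requires, and makes splits deterministic. An explicit
  `compound_id,set` CSV can replace the algorithm for reproduction of a
  published split.
* **Extrapolation score**: for each selected descriptor with training
  range $[m_j, M_j]$ and width $w_j$, the excursion is
  $(x_j - M_j)/w_j$ above, $(x_j - m_j)/w_j$ below, 0 inside; the score is
  the excursion of largest magnitude, signed. This is a package
  definition: the original software's "extrapolation" column is undefined
  in print, and this construction reproduces its observable contract
  (exactly 0 inside the domain; screening keeps scores strictly inside
  (−1, 1)) while being unit-testable.

### Charges and vdW parameters

Input structures should carry their own per-atom charges (SDF data field,
default name `PARTIAL_CHARGES`). When absent, a Gasteiger-type PEOE
routine (per-element polynomial electronegativities, hybridisation from
bond orders, damping 0.5 per cycle, 8 cycles) fills them in; it conserves
total charge and reproduces qualitative polarity, not any specific
published charge set — the source workflow's charge model is unpublished,
so exact descriptor values are not reproducible by construction.
Lennard-Jones parameters come from a packaged Tripos-5.2-like element
table (`default_vdw_table()`), overridable by the user.

## The synthetic generator

`make_series()` emulates the *geometry* of a congeneric series: a rigid
10-atom fused-bicyclic scaffold at fixed coordinates plus 1–3 seeded
substituent atoms per compound, pre-aligned by construction.
`make_planted_dataset()` emulates the *statistics* of a field-descriptor
matrix: Gaussian columns with a fraction of exactly-constant ones (105/3268
by default, the proportion the invariable-column filter is expected to
remove) and correlated triplets (pairwise r ≈ 0.9, mimicking neighbouring
grid points), plus activities linear in a few columns with homoscedastic
Gaussian noise. Defaults (38 compounds, 6 informative descriptors,
coefficient scale 0.5, noise sd 0.2 pIC50 units) put fits in the r² ≈
0.95–0.98 regime the validation code paths must handle.

What the generator does **not** emulate: real field matrices have heavy
clamp-induced point masses at ±30, spatial autocorrelation far beyond
triplets, and strongly non-Gaussian columns. A green test on planted data
therefore establishes that the *algorithms* are correct and recoverable
signal is recovered — not that any particular chemistry will yield a
predictive model.

## Where the stated world fails a stated bound

Two findings from building this package are worth recording.

First, greedy forward selection at F-to-enter 4 is liberal. On the
recovery benchmark (n = 40, p = 50, k = 3, σ = 0.2) recall is 1.0, but on
average ≈ 3 chance descriptors enter before the threshold stops the scan:
once the true signal is absorbed, the maximum partial F over ~45 remaining
null candidates still clears 4 frequently (per-candidate tail probability
≈ 0.05). A mean false-positive bound of 2 is not attainable at this
threshold — raising F-to-enter to ≈ 9–10 would achieve it, but 4.0 is the
stated default and is kept. The corresponding acceptance expectation is
deliberately left failing rather than met by moving the threshold.

Second, at p ≫ n the workflow's internal statistics cannot protect you. On
a full-scale planted dataset (38 compounds, 3163 surviving descriptors, 27
in training), stepwise selection produces r² ≈ 0.98 and q² ≈ 0.96 with
**zero** recall of the planted descriptors, and external pred_r² collapses
(< 0); Y-randomization correctly refuses to certify such a model (Z < 1,
because permuted labels overfit just as well). This is the regime the
historical workflow operates in; the package reproduces the procedure
faithfully while its validation outputs make the risk visible. Consumers
should weight pred_r² and the randomization Z-scores, not the training r².

## Limitations

* No conformer generation, tautomer or protonation handling: molecules are
  used as supplied.
* Hydrophobic fields are not computed (the reference model selected none).
* The template atom map is user-supplied; no substructure search is
  attempted, so a wrong map fails loudly at alignment rather than
  silently.
* Descriptor values are not comparable to any commercial implementation's:
  probe, charges, cutoffs and dielectric conventions differ and several of
  those are unpublished on the other side.
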