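---
title: "Randomized multiresolution scanning for E/MEG source reconstruction"
author: "ramus package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized multiresolution scanning for E/MEG source reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramus)
set.seed(1)
```

## The problem

Electro- and magnetoencephalography (E/MEG) measure, at a few hundred
sensors, the fields generated by the brain's primary current
distribution. Reconstructing that distribution is a severely ill-posed
linear inverse problem,

$$ y = L x + n, \qquad L \in \mathbb{R}^{m \times 3K}, $$

where $x$ stacks three Cartesian current components for each of $K$
candidate source positions and $n$ is Gaussian sensor noise with
covariance $\sigma^2 I$. Most solvers carry a *depth bias*: superficial
cortical sources dominate the reconstruction while deep (for example
thalamic) activity is invisible. This package implements a maximum a
posteriori (MAP) estimation strategy designed to recover simultaneous
deep and superficial activity without any depth weighting: a
hierarchical Bayesian model optimized by the iterative alternating
sequential (IAS) algorithm, wrapped in a randomized multiresolution
scan (RAMUS) of the source space.

## Hierarchical model and the IAS optimizer

Each current component $x_j$ gets its own prior variance $\theta_j$,
itself drawn from a long-tailed hyperprior — inverse gamma
$\mathrm{IG}(\beta, \theta_0)$ by default, or gamma. The joint negative
log posterior

$$ F(x, \theta) = \frac{\|L x - y\|^2}{2\sigma^2}
   + \sum_j \left[ \frac{x_j^2}{2\theta_j} + \mathrm{pen}(\theta_j) \right] $$

is minimized by exact alternating half-steps:

* $\theta$-step: componentwise,
  $\theta_j = (\theta_0 + x_j^2/2)/(\beta + 3/2)$ for the inverse-gamma
  family, and
  $\theta_j = \theta_0\,(\eta/2 + \sqrt{\eta^2/4 + x_j^2/(2\theta_0)})$
  with $\eta = \beta - 3/2$ for the gamma family;
* $x$-step: the ridge solution
  $x = \Theta L^\top (L \Theta L^\top + \sigma^2 I)^{-1} y$, evaluated
  in the $m \times m$ data space so the cost scales with the sensor
  count.

Both half-steps are exact minimizers, so $F$ is non-increasing — the
test suite asserts this on every half-step, and checks both updates
against brute-force scalar maximization and dense solves. A single
iteration from a zero start is the classical minimum norm estimate
(MNE) with constant prior variance $\theta_0/(\beta + 3/2)$; many
iterations with the inverse-gamma (gamma) hyperprior approach minimum
support (minimum current) estimates.

The gamma family needs $\beta > 3/2$ to be usable from a zero start: at
$\beta = 3/2$ the zero-signal fixed point of the $\theta$-step is zero
and the iteration never leaves the origin. Its default here is
$\beta = 2$; the inverse gamma uses $\beta = 3/2$, the smallest stable
value.

### The scale parameter and lead-field normalization

$\theta_0$ has units of $x^2$, so its numeric value is only meaningful
relative to the lead-field magnitude: running IAS on $L/a$ with scale
$\theta_0$ is *exactly* equivalent to running it on $L$ with
$\theta_0/a^2$. To make the parameter transferable,
`ramusReconstruct()` first scales the lead field to unit mean column
norm (a single global scalar — no depth weighting) and interprets
$\theta_0$ on that scale; estimates are returned in the units of the
input lead field.

On the normalized scale the workable window of $\theta_0$ for the
spherical pipeline is roughly $[10^{-6}, 10^{-4}]$. Below it the
minimum-norm first step is shrunk so strongly that no component ever
crosses the inverse-gamma threshold $\sqrt{2\theta_0}$ — minimum-norm
amplitudes scale linearly with $\theta_0$ while the threshold scales
with its square root, so the frozen regime cannot be escaped from
below. Far above the window, focality is lost. The default
$\theta_0 = 10^{-6}$ is the smallest stable value, which also treats
the deep sources best; orientation artifacts (estimates locking onto a
Cartesian axis) appear when the parameter is pushed below the window.

## Coarse-to-fine multiresolution scanning

A single-resolution sparse MAP estimate finds the superficial source
and loses the deep one: the deep field pattern can be mimicked by
combinations of shallower sources, and the iteration, started from the
depth-biased MNE, settles there. The remedy has two parts.

**Coarse-to-fine optimization.** A nested random hierarchy of
resolution levels $\ell = 1, \dots, L$ is drawn: level $\ell$ keeps
$K_\ell = \mathrm{round}(K s^{\ell - L})$ positions ($s > 1$ the
sparsity factor; the finest level is the full space), each coarser
level's positions being a random subset of the next finer level's.
Every fine position is assigned to its nearest selected center, which
partitions the space into subsets of average size $s^{L-\ell}$. The
level-$\ell$ inverse problem uses the selected positions' own
lead-field columns — regularization by discretization: with a few
hundred coarse positions (comparable to the sensor count) the deep
source must and can carry its own share of the data. The IAS estimate
at each level initializes the next level through subset means, and each
level estimate is interpolated back to the fine grid by
nearest-neighbor copy. Since copying a coarse value to all members of
its subset multiplies the represented source count by about
$s^{L-\ell}$, the level estimates are combined as the *normalized
mean*

$$ \bar{x} = \sum_{\ell=1}^{L} x^{(\ell)} \Big/ \sum_{\ell=1}^{L} s^{(L-\ell)} , $$

whose denominator (73 for $L = 3$, $s = 8$) balances exactly that
multiplication: the vector sum of moments over a region — the quantity
the evaluation uses for amplitude and orientation — is preserved for a
source detected at all levels.

An alternative reading of "the unknown is constant within each
subset", in which the coarse system sums the member columns, is
available as `restriction = "aggregate"` and as the standalone
operation `restrictLeadfield()` (whose consistency identity
$L_c x_c = L_f P x_c$ is part of the test suite). It is not the
default because the summed columns change the effective regularization
scale per level, and in calibration runs the resulting estimator
either buried the coarse contribution entirely or inflated it to the
point where even a minimum-norm estimate appeared to "detect" the deep
source — at odds with the detection pattern the method is supposed to
produce.

**Randomized scanning.** A single decomposition biases the estimate by
its particular center choice. The scan therefore draws $D$ independent
decompositions, reconstructs each, and averages:
$\bar{\bar{x}} = D^{-1} \sum_k \bar{x}^{(k)}$. The $k$-th
reconstruction starts its coarsest level from the previous
decomposition's normalized mean (a Markov chain of warm starts), which
keeps each optimization near the basin found so far; the random
center draws then average the discretization error out at the usual
$O(D^{-1/2})$ Monte Carlo rate. Chaining can be disabled
(`chain = FALSE`) for diagnostics, making decompositions independent.

## Spherical forward model

The forward simulator replaces a finite-element pipeline with the
classical analytic three-shell sphere (Ary geometry: 87/92/100 mm,
conductivities 0.33/0.0042/0.33 S/m):

* **EEG** — multilayer-sphere Legendre series with per-layer scaled
  radial basis functions (all matrix entries are radius ratios
  $\le 1$, keeping the per-degree boundary systems well conditioned),
  point electrodes, average reference, units Ohm/m. The series is
  truncated at relative tail $10^{-8}$ or degree 160, whichever comes
  first; degree 160 is needed because sources are allowed up to
  86.5 mm, where the tail at degree 100 is still $\sim 10^{-5}$. The
  homogeneous-sphere closed form (all conductivities equal) serves as
  an independent oracle in the tests.
* **MEG** — radial magnetometers at 1.2 times the electrode radius,
  full Sarvas closed form for the spherically symmetric conductor,
  units 1/m$^2$ (field over $\mu_0$). Radial dipoles are silent, and
  the radial field equals the free-space field of the primary dipole
  alone; the tests assert both against an independent implementation.
* **Sensors** — 102 positions per modality, quasi-uniform on the upper
  hemisphere via a deterministic golden-angle spiral (the study does
  not publish coordinates; any quasi-uniform layout is acceptable).
* **Sources** — positions uniform in a shell inside the brain
  compartment. `buildSourceSpace()` defaults to [0, 85] mm; the
  experiment assets use [0, 86.5] mm so the near-cortex test dipole
  (at radius 87.15 mm, nominally just outside the brain sphere) has
  candidates on all sides. Dipoles are snapped to the nearest source
  position with a warning above 5 mm.

Measurements add white Gaussian noise with standard deviation a fixed
percentage (default 3%) of the maximal clean amplitude, and are
max-normalized to one; the noise level is carried on the normalized
scale and used as $\sigma$ in the likelihood. For combined E/MEG the
MEG lead field *and data* are scaled by
$c = \|L_{EEG}\|_F / \|L_{MEG}\|_F$ on the raw (pre-normalization)
scale and the stacked data are then max-normalized jointly — scaling
the two separately normalized datasets instead would make the blocks
imply source magnitudes differing by their normalization-factor ratio
and effectively silence one modality. The pooled $\sigma$ is the
row-count-weighted RMS of the per-block noise levels.

## The two-dipole validation study

The built-in experiment battery models simultaneous thalamic (P14/N14)
and somatosensory (P20/N20) activity after median-nerve stimulation:

* deep dipole at (7, 0, 5) mm, moment elevated 68° from the tangential
  plane (near-radial, as a thalamic source), amplitude 10;
* superficial dipole at (−50, 7, 71) mm, 1° elevation (tangential, the
  textbook character of the somatosensory cortical source),
  amplitude 5 (7 in some cases).

The coordinate and angle values are best-effort parses of an
ambiguously printed table; the angle is deliberately read as elevation
from the *tangential* plane because the deep/thalamic component is
described as radial and the somatosensory one as tangential. Both
dipoles are overridable per configuration.

Cases (A)–(I) vary modality (EEG or E/MEG), sparsity factor (8 or 5),
decomposition count (100 or 20), hyperprior (IG or G) and the two
amplitudes; see `caseTable()`. Each case runs `nRealizations`
independent noise realizations, reconstructs with RAMUS, and scores
two 60 mm spherical regions of interest (ROIs) centered at the true
positions:

* position error — distance from the amplitude-weighted center of
  mass of the ROI to the true position;
* orientation error — angle between the vector sum of ROI moments and
  the true direction (the scalar amplitude sum is exported alongside
  for sensitivity checks);
* amplitude error — $\log_{10}$ of the net ROI moment norm over the
  true amplitude, compared on the normalized data scale;
* relative maximum — largest ROI amplitude over the global maximum; a
  source is *detected* when this strictly exceeds 0.1;
* sample summaries — medians and 5th–95th percentile intervals
  (linear interpolation), and the detection percentage.

## Problem sizes and reproducibility

The reference study uses $K = 10000$ source positions, $D = 100$
decompositions and 50 noise realizations per case. The package's
acceptance script (`scripts/acceptance.R`) reproduces cases (A), (B),
(D) and (H) at $K = 3000$, $D = 25$ and 25 realizations — sizes chosen
so a complete run stays in the tens of minutes on a single CPU while
the coarsest level (about 47 positions) still resolves the deep
source. The test suite runs a further-reduced battery ($K = 2000$,
12–25 realizations). Two scale-dependent effects are worth knowing
about when comparing with full-size runs: the gamma hyperprior's
deep-source suppression sharpens with $K$ (at desk scale a residual
deep blob may still graze the 0.1 detection threshold), and ROI
center-of-mass errors carry a floor set by the source grid spacing
(about 9 mm at $K = 3000$).

Every stochastic step — source-space sampling, noise draws,
decomposition draws, case batteries — takes an explicit seed, and
fixed seeds reproduce results bit-identically. What the synthetic
study does *not* emulate of real data: realistic head geometry and
conductivity inhomogeneity, correlated sensor noise, temporal
structure, and the complete-electrode model (point electrodes are
used); passing tests therefore validate the algorithmic machinery and
its behavior under the stated spherical model, not clinical
performance.

## Known limitations

* The analytic sphere is a stand-in for subject-specific FEM forward
  models; absolute accuracy numbers shift with the forward model, and
  deep-orientation estimates are the most sensitive quantity.
* E/MEG fusion adds little deep-position accuracy here because the
  near-radial deep dipole is almost silent for radial magnetometers
  and the EEG-only deep localization is already near its grid floor.
* The scan is sequential by construction when chaining is enabled;
  parallel evaluation of decompositions is only admissible with
  `chain = FALSE`.
* The gamma hyperprior at $\beta = 3/2$ is degenerate from a zero
  start (see above); use $\beta > 3/2$ or a warm start.
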