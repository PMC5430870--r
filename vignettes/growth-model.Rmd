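---
title: "Modelling post-surgery glioma growth with treatment and viscoelasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-surgery glioma growth with treatment and viscoelasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaRD)
```

## The model

Low-grade gliomas are diffusely infiltrating tumors: imaging shows a visible
core, but tumor cells extend well beyond the contour, preferentially along
white-matter fiber tracts, faster in white matter (WM) than in gray matter
(GM), and not at all through cerebrospinal fluid (CSF). After a resection,
the residual tumor regrows under adjuvant radiotherapy and/or chemotherapy.
`gliomaRD` simulates this process on a voxel grid with the reaction-diffusion
equation

$$\frac{\partial u}{\partial t}
  = \nabla\!\cdot\!\big(\bar{D}(x)\nabla u\big)
  + \nabla\!\cdot\!\big(\hat{D}\nabla\sigma\big)
  + u\big[(\rho - r)(1-u) - \bar{k}\big],$$

where

* `u(x, t)` is tumor cell density as a fraction of carrying capacity
  (`0 <= u <= 1`);
* $\bar{D}(x)$ is the growth diffusion tensor (mm²/day), built from DTI in
  WM as $E\,\mathrm{diag}(e_1 D_{WM}, D_{GM}, D_{GM})\,E^T$ (eigenvectors
  `E` sorted by descending eigenvalue, `e_1` the normalized largest
  eigenvalue), isotropic $D_{GM} I$ in GM, and zero in CSF and outside the
  brain — CSF and the skull act as barriers;
* $r(x,t)$ is the per-fraction radiotherapy kill `1 - S` from the
  linear-quadratic survival $S = e^{-\alpha d - \beta d^2}$, applied on
  fraction days over brain tissue but not in the resection cavity, in the
  logistic form $r\,u(1-u)$;
* $\bar{k}(x,t)$ is the chemotherapy death rate on active days: the nominal
  `k` in GM and $k/(k+\omega)$ in WM, with $\omega$ the local WM proportion
  in a small window — tissue heterogeneity modulates drug absorption;
* $\sigma$ is a Maxwell-Weichert viscoelastic stress driven by tumor-induced
  strain, and $\hat{D}$ a small negative diagonal stress-diffusion tensor.

A no-flux (Neumann) condition holds at the brain boundary: tumor mass cannot
leave the brain, and density is pinned to zero in CSF and outside the brain
(both statements hold simultaneously because diffusivity vanishes there).

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `d_gm` | diffusivity in GM | 0.0013 | cm²/day |
| `d_wm` | diffusivity in WM | `5 * d_gm` | cm²/day |
| `rho` | proliferation rate | 0.012 | 1/day |
| `alpha` | LQ linear coefficient | 0.027 | 1/Gy |
| `alpha_beta_ratio` | LQ ratio (`beta = alpha/ratio`) | 10 | Gy |
| `k_chemo` | chemotherapy death rate | 0.0196 | 1/day |
| `e1`, `e_inf` | Maxwell / free-spring moduli (`e_inf = e1/6`) | 3156, 526 | Pa |
| `eta1` | Maxwell dashpot viscosity | 8.9e-8 | Pa s |
| `d_hat` | stress diffusion (diagonal) | −1e-14 | cells/(Pa day) |
| `u_detect` | imaging detection threshold | 0.4 | — |

All diffusivities are converted to mm²/day internally (`x 100`) because voxel
spacing is carried in mm. Therapy calendars follow the standard of care:
radiotherapy delivers 60 Gy in 30 daily 2 Gy fractions; chemotherapy runs 6
cycles of 5 active days every 28 days (30 active days spanning 145 days).
`load_config()` reads YAML overrides on top of these defaults and rejects
unknown keys and inconsistent `alpha`/`beta`/ratio triples.

Two consequences of taking the literature values literally are worth
flagging. First, the Maxwell relaxation time is
$\tau_1 = \eta_1/E_1 \approx 2.8\times10^{-11}$ s — the element relaxes
instantaneously on the day scale; the recursive update is exact in this
limit, and with $|\hat D| = 10^{-14}$ the stress term is numerically
negligible for low-grade disease (the ablation harness confirms the
viscoelastic variant changes nothing at detection-mask resolution). Second,
a 2 Gy fraction kills $1-e^{-0.0648}\approx 6.3\%$ of proliferating cells
per day and `k = 0.0196`/day both exceed `rho = 0.012`/day, so the modelling
assumption that treatment is weaker than proliferation does not hold on
therapy days; the solver checks this and warns rather than silently
proceeding.

## Numerical scheme

Time stepping is explicit first-order with steps that divide one day (so
day-resolved therapy calendars are honored exactly), at or below the bound
`stable_dt()`: $\Delta t \le 0.9\,\big(\sum_i 2 D_{\max}/h_i^2\big)^{-1}$
with $D_{\max}$ the largest local eigenvalue.

The anisotropic diffusion term uses a non-negativity oriented directional
discretisation. Diagonal tensor entries become conservative axis fluxes with
*harmonic* face means, so a face with a zero-diffusivity side (CSF, skull,
or a sealed cavity) carries exactly zero flux — the no-flux boundary is
structural, and total mass telescopes to machine precision. Each
off-diagonal entry $D_{ij}$ is discretised by a second difference along the
plane diagonal $e_i + e_j$ (for $D_{ij} > 0$; $e_i - e_j$ otherwise), and
the axis weights are compensated by $(h_i/h_j)|D_{ij}|$. All stencil
weights are then non-negative whenever the tensor is diagonally dominant in
the weighted sense; where strong off-axis anisotropy would make an axis
weight negative it is clamped at zero (the count is reported as
`clamped_aniso`). The payoff is a discrete maximum principle: under the
`stable_dt()` bound the density provably stays in `[0, 1]` with no
clipping, which the test suite verifies over 20 randomized anisotropic
phantoms for 10⁴ steps each. The cost is a controlled consistency error at
the few strongly mixed-orientation voxels where the clamp engages. With a
diagonal tensor or scalar map the scheme reduces exactly to the standard
7-point variable-coefficient stencil, and the solver then agrees step-by-step
(≤ 1e-10) with an independently coded sparse-operator reference — the plain
Swanson-style reaction-diffusion model it generalizes.

Clipping events (density leaving `[0,1]` by more than 1e-9 before clamping)
are logged per step; persistent clipping aborts the run as a stability
violation rather than being absorbed silently. Densities are checked for
NaN/Inf each step.

The Boltzmann stress integral is advanced by one recursive exponential
accumulator per Maxwell element, exact for piecewise-linear strain, with
`expm1`-based weights that remain accurate from $\Delta t \ll \tau$ to
$\tau \ll \Delta t$; memory does not grow with history length. The strain
source is the minimal coupling $\varepsilon = \kappa u$ (`kappa = 0.01` by
default): the constitutive law consumes strain, but no strain origin is
prescribed by the continuum formulation, so this choice is deliberately
exposed and switchable (`kappa = 0` disables the pathway bit-for-bit). The
constitutive convolution is applied to the scalar strain field and the
spatial gradient enters through $\nabla\cdot(\hat D\nabla\sigma)$; an
alternative "memoryless coefficient" reading of the stress term is
available via `stress_formulation = "memoryless"`.

### Degenerate inputs and tie-breaks

* DTI eigenvalues are sorted descending; ties are broken by lexicographic
  eigenvector comparison and a fixed sign convention, so `build_growth_tensor`
  is deterministic.
* `e_1` is normalized by the maximum largest-eigenvalue over the WM mask
  (per-volume); trace normalization is available via `e1_normalization`.
* Non-positive-semidefinite DTI voxels are replaced by the isotropic
  GM tensor and counted (`repaired` attribute).
* An all-zero diffusivity field makes `stable_dt()` fall back to the output
  cadence (pure-reaction runs).
* Both-empty masks make Jaccard/Dice an error, not 1 — degenerate scenarios
  fail loudly.
* The resection cavity is tumor-permeable with GM diffusivity by default and
  receives no therapy effect; proliferation there is configurable
  (`cavity_proliferation`), since the continuum model does not specify it.

## The phantom generator

Clinical MR volumes cannot be redistributed, so every experiment runs on a
parametric-analytic brain phantom: an ellipsoidal brain with a GM cortical
ribbon, WM interior, ellipsoidal CSF ventricles, an optional spherical
resection cavity adjacent to the tumor seed, and fiber bundles defined by
polyline center-lines with Gaussian anisotropy falloff (trace-one tensors,
eigenvalue ratio up to 5:1:1 along the bundle tangent — smooth fields avoid
discretization artifacts in solver tests). Everything is deterministic given
the spec; `random_phantom_spec(seed)` draws randomized geometries for
property sweeps.

What the phantom reproduces: multi-tissue geometry with barriers, a single
connected brain, fiber-aligned anisotropy, post-surgical cavities, and
day-resolved standard therapy calendars. What it does not: real cortical
folding, atlas anatomy, MRI intensities, registration/segmentation errors,
or patient-specific parameter variation. Passing tests therefore validate
the numerics and the model mechanics, not clinical accuracy on real images;
the published per-patient overlap scores require the original MR data and
are out of reach of any synthetic reconstruction.

## Verification experiments and problem sizes

The suite ties every model component to an independent oracle, at sizes
chosen to keep a full run in minutes on one core:

* **Logistic law** (0D, diffusion-free, `dt = 0.1`, 100 days): matches the
  closed form within 1e-3.
* **Fisher-KPP front speed** (1D, `D = 0.13` mm²/day, `rho = 0.012`/day,
  `h = 0.5` mm): pulled fronts approach the asymptotic speed
  $2\sqrt{D\rho}$ only like $c - 3/(2\lambda t)$, a ~14% deficit at
  600 days with these parameters, so the run uses 4000 days (356 mm
  domain) and measures the front slope over the second half: −2.6%
  observed, within the 5% band.
* **Mass conservation** (32³ phantom with ventricles, cavity and an
  anisotropic bundle, `rho = 0`): relative drift at machine level over
  120 steps (bound 1e-6).
* **Swanson reduction** (16³, scalar heterogeneous `D(x)`, no therapy or
  stress): ≤ 1e-10 per step against the independent sparse-matrix solver.
* **Hereditary integral** (random piecewise-linear strain, 1000 steps):
  recursion vs direct trapezoid quadrature ≤ 1e-5 relative.
* **Therapy monotonicity** (48³ phantom, standard calendars, 365 days —
  the one-year horizon of the synthetic growth experiments): the treated
  run is pointwise ≤ the untreated run at every saved time and its
  `u = 0.4` contour is nested inside the untreated contour.
* **Metric identities** (200 random mask pairs): `DC = 2 JS/(1+JS)` to
  machine precision, `JS <= DC`, threshold-nested masks.
* **Stability sweep** (20 random anisotropic phantoms, ~10⁴ steps each at
  `stable_dt()`): zero post-transient clipping events, as the maximum
  principle predicts.

`scripts/acceptance.R` recomputes all of these from scratch.

## Ablations

`run_ablation()` mirrors the treatment-variant experimental design on
synthetic scenarios: the full model provides the reference mask and each
reduced variant (`no_chemo`, `no_rt`, `no_treatment`, `no_dti`,
`no_viscoelastic`) is scored against it with Jaccard/Dice at `u_detect`.
Because the reference is the full model rather than clinical ground truth,
the reported decreases are self-consistency measures of each component's
influence — the *design* of the published ablation tables, not a
reproduction of their values. On treated scenarios the harness verifies the
expected ordering: removing both therapies degrades the overlap at least as
much as removing either one (a consequence of the pointwise monotone-kill
property and mask nesting).

A practical note on horizons: with the default parameters the per-fraction
kill exceeds the proliferation rate, so a treated tumor falls below the 0.4
detection threshold during therapy and only re-crosses it after regrowth;
ablation scenarios therefore use follow-up horizons of ~250-365 days
(clinical follow-ups in this setting span ~81-686 days).

## Known limitations

* No mass effect or tissue displacement: the viscoelastic pathway perturbs
  diffusion through a stress gradient; it does not deform anatomy.
* No pharmacokinetics: chemotherapy is binary per calendar day at constant
  `k`; radiotherapy dose is spatially uniform unless a dose-weight map is
  supplied.
* The clamped directional stencil trades a small consistency error at
  strongly mixed-orientation anisotropic voxels for unconditional
  positivity.
* Explicit time stepping only; very fine grids would want an implicit or
  operator-splitting scheme, which is out of scope.
* Parameters are population defaults; patient-specific calibration of `D`
  and `rho` is deliberately not addressed.
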