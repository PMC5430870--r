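# gliomaRD

Simulation of post-surgery low-grade glioma growth on voxel grids, for
researchers studying how residual tumor evolves under adjuvant therapy and
for anyone who needs a tested, self-contained reaction-diffusion brain
tumor solver with treatment terms.

Low-grade gliomas infiltrate far beyond their imaging-visible contour,
migrate preferentially along white-matter fiber tracts, and — after partial
resection — regrow under radiotherapy and/or chemotherapy. `gliomaRD`
models the tumor cell density `u(x, t)` (fraction of carrying capacity,
`0 ≤ u ≤ 1`) with

```
∂u/∂t = ∇·(D̄(x) ∇u) + ∇·(D̂ ∇σ) + u[(ρ − r)(1 − u) − k̄]
```

* **Anisotropic diffusion** `D̄(x)`: built from DTI in white matter as
  `E diag(e₁ D_WM, D_GM, D_GM) Eᵀ` (fastest along the fiber direction),
  isotropic `D_GM·I` in gray matter, zero in CSF and outside the brain —
  barriers the tumor cannot cross (no-flux boundary).
* **Radiotherapy** `r`: per-fraction linear-quadratic kill
  `1 − exp(−αd − βd²)` on fraction days, acting on the proliferating
  fraction `u(1 − u)`; no effect in the resection cavity.
* **Chemotherapy** `k̄`: log-kill rate on active days, `k` in gray matter
  and `k/(k + ω)` in white matter, where `ω` is the local white-matter
  proportion — tissue heterogeneity modulates drug absorption.
* **Viscoelasticity** `σ`: Maxwell-Weichert (generalized Maxwell) stress
  advanced by an exact recursive form of the Boltzmann hereditary integral,
  coupled through a small negative stress-diffusion tensor `D̂`.

Because clinical MR data cannot be bundled, the package ships a parametric
brain-phantom generator (tissue labels, fiber-aligned tensor fields,
ventricles, resection cavity, standard therapy calendars: 60 Gy in 30 daily
fractions; 6 × 5-day temozolomide cycles every 28 days), plus Jaccard/Dice
overlap evaluation and an ablation harness. All volumes travel as NIfTI,
therapy plans as JSON, configuration as YAML.

## Worked example

Grow a resected tumor for 450 days on a synthetic brain, with and without
the standard adjuvant therapy:

```r
library(gliomaRD)

spec <- phantom_spec(
  shape = c(32, 32, 32), spacing = c(2, 2, 2),
  fibers = list(list(points = rbind(c(10, 40, 31), c(52, 24, 31)),
                     radius = 6, anisotropy = 5)),
  cavity = list(center = c(40, 31, 31), radius = 6))
vol  <- make_brain_phantom(spec)          # labels: outside/CSF/GM/WM/cavity
dti  <- make_tensor_field(vol, spec)      # fiber-aligned DTI-like tensors
D    <- build_growth_tensor(dti, vol, tissue_params())
init <- seed_tumor(vol, center = c(26, 31, 31), radius = 7)

rt <- make_therapy_calendar("radiotherapy")    # 30 x 2 Gy from day 0
ch <- make_therapy_calendar("chemotherapy")    # 6 cycles, 5/28 days

res_tx  <- simulate_growth(init, vol, D, rt_plan = rt, chemo_plan = ch,
                           days = 450, save_every = 450)
res_off <- simulate_growth(init, vol, D, days = 450, save_every = 450)
res_tx
res_off
overlap_report(extract_mask(res_tx), extract_mask(res_off))
```

```
<growth_result> 450 days, dt = 0.5 d (900 steps), 2 snapshots
  final: max u = 0.5538, mask voxels = 1952, total clipped = 0
<growth_result> 450 days, dt = 0.5 d (900 steps), 2 snapshots
  final: max u = 0.8587, mask voxels = 8474, total clipped = 0
<overlap_report> JS = 0.2304, DC = 0.3744 (|S| = 1952, |GT| = 8474, |S∩GT| = 1952)
```

Reading the numbers: both runs are integrated at the stability-safe step
(`dt = 0.5` day; `total clipped = 0` confirms the density never left
`[0, 1]`). Therapy keeps the detection mask (`u ≥ 0.4`, the conventional
imaging-visibility threshold) at 1 952 voxels versus 8 474 untreated — and
the intersection equals the treated mask, i.e. the treated contour is
nested strictly inside the untreated one, the qualitative signature of
treatment in this model. (The run warns that the per-fraction kill exceeds
the proliferation rate — with the standard parameters treatment is locally
stronger than growth, and the solver surfaces that assumption check.)

Component ablations on a scenario (`run_ablation()`) and the command-line
front end (`inst/cli/gliomaRD.R` with subcommands `phantom`, `simulate`,
`evaluate`, `ablate`) wrap the same functions.

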