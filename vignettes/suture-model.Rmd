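---
title: "A moving-interface model of suture pattern formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A moving-interface model of suture pattern formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(suturesim)
```

## The model

`suturesim` treats a suture as the strip of undifferentiated mesenchyme
(`u = 0`) between two plates of bone (`u = 1`), in two dimensions.  Two
fields evolve:

* **Bone differentiation degree `u(x, y, t)`.**  The bone–mesenchyme
  boundary (osteogenic front) moves in its normal direction with speed

  $$V = f(v) - \sigma\,\kappa, \qquad f(v) = \alpha\,(v - v_c),$$

  positive toward the mesenchyme.  `α` is the efficacy of the
  osteopromoting factor (front speed per unit concentration excess), `v_c`
  the critical concentration at which osteogenesis and resorption balance,
  `σ` a surface tension, and `κ` the front curvature (positive where bone
  is locally convex).

* **Osteopromoting factor `v(x, y, t)`** (FGF-like), produced by
  mesenchyme, diffusing and decaying:

  $$\partial_t v = D_v \nabla^2 v + k_p (1 - u) - k_d v.$$

* **Passive soft-tissue expansion** at speed `c` (brain- or organ-driven
  stretching of the suture), implemented on a fixed lattice by inserting
  duplicated columns into the suture at rate `c/Δx` and deleting outer
  bone columns — a frame co-moving with the expanding tissue.

The pattern-forming feedback: a bone protrusion reaches into regions of
higher `v` and accelerates, so small perturbations amplify into
interdigitation; `σκ` opposes this; the balance between production/decay
geometry (`√(D_v/k_d)` is the factor's decay length) and `v_c` sets the
equilibrium width.  With growth on, the width steadies when the per-side
front speed equals `c/2`, which raises `v` at the front and both widens
the suture and strengthens interdigitation.

All quantities are dimensionless model units.  The lattice and step sizes
(`128 × 128`, `Δx = 50`, `Δt = 2`, run length `6000`) follow the source
model's stated configuration; physical units for `Δx` and the
concentration scale are not defined, so none are claimed.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `alpha` | 4 | front speed per unit `v − v_c`; sets how fast the front tracks the factor field and how strongly protrusions amplify |
| `sigma` | 100 | curvature penalty; the screened range `10–1000` spans visible interdigitation to complete suppression |
| `v_c` | 0.35 | balance concentration; feasible band is narrow — below ≈0.29 the equilibrium strip approaches the interface width and can fuse, above 0.5 no equilibrium exists (`v` at a front saturates at `k_p/2k_d`) |
| `D_v` | 9e4 | with `k_d = 1`, decay length `ℓ = 300` = 6 lattice sites; sets the width scale via `v(a) = (1 − e^{−2a/ℓ})/2` at a front distance `a` from the midline |
| `c` | 0 | expansion speed; `c · t_end/Δx` columns are inserted per run |
| `k_p`, `k_d` | 1, 1 | factor kinetics (nondimensionalised) |
| `eps` | `2Δx` | diffuse-interface width; the minimum the lattice can resolve |
| `noise_amp` | `Δx` | sd of the initial per-row interface perturbation |

The defaults are a calibrated baseline chosen once: `ℓ = 6` sites and
`v_c = 0.35` give an equilibrium suture of ~8 sites (a thin strip, as in
juvenile calvarial preparations); `α = 4` makes the width relax within
`t ≈ 1000` (a sixth of the run) and places the baseline near the
interdigitation onset, so both the amplifying and the suppressed regime
are reachable within the screened `σ` decade on either side.

## Numerical scheme

Both solves are semi-implicit and spectral.  The lattice is reflecting in
`x` (across the suture) and periodic in `y` (along it, making the strip
effectively infinite); even extension in `x` makes the 5-point Laplacian
diagonal in Fourier space, so the backward-Euler operators
`(I + Δt k_d − Δt D_v L)` and `(I − Δt_s M₀ L)` are inverted *exactly*
(residual at machine precision) and unconditionally stably, in C++
(Armadillo FFT).  Per-step splitting: factor solve, then phase-field
update (the front sees the current-step `v`), then growth.

The front law is realised as a forced Allen–Cahn equation

$$\partial_t u = M_0\left(\nabla^2 u - \frac{W'(u)}{\varepsilon^2}\right)
  + \big[f(v) - (\sigma - M_0)\,\kappa\big]\,\frac{2u(1-u)}{\varepsilon},$$

with `W(u) = 2u²(1−u)²`, whose standing profile is
`(1 + tanh(x/ε))/2`.  Because the forcing bump `2u(1−u)` is proportional
to the profile derivative, the planar travelling wave is **exact** with
speed `f(v)` — no thin-interface error in continuum.  Design choices worth
recording:

* **Hybrid curvature.**  A single-mobility Allen–Cahn (well strength tied
  to `σ`) fails at both ends of the screened `σ` range: at `σ = 10` the
  well is too weak to keep `u = 0` metastable where `v > v_c` (bone
  nucleates inside the suture and it fuses), and at `σ = 1000` a fully
  explicit curvature term violates its stability limit at `Δt = 2`.  The
  package therefore gives the Allen–Cahn pair a clamped mobility
  `M₀ = clamp(σ, 100, 300)` — contributing curvature flow `−M₀κ`
  intrinsically and implicitly — and applies the remainder
  `−(σ−M₀)κ` explicitly through the interface bump, subcycled so that
  `Δt_sub·|σ−M₀| ≤ 250`.  Both channels are validated against the
  shrinking-circle law.
* **Curvature discretisation.**  `κ = −div(∇u/|∇u|)` by the direct
  second-derivative formula, with a gradient floor, and **masked to the
  interface band** (`|∇u|·ε ≥ 0.02`): outside the band — bulk plateaus and
  the mid-suture gradient flip — the normalised gradient is noise, and an
  unmasked κ there nucleates bone at the suture midline at high `σ`.
* **Calibration.**  At `ε = 2Δx` the finite-difference tanh profile moves
  ~4% slow; two constants (`1.0443` on the forcing, `1.0413` on `M₀`)
  were measured once so the planar-front and circle laws sit on target,
  and the oracle tests re-derive them within 5%.
* **Growth operator.**  Insertion columns are drawn among
  mesenchyme-containing columns with probability proportional to their
  soft-tissue content — a uniform dilation of the soft tissue (each soft
  site equally likely to stretch).  A deterministic min-`v` site was
  evaluated and rejected: near-ties between the two equally starved front
  edges resolve systematically to one side, drifting the suture off-centre
  and making width *decrease* with `c`, the opposite of the behaviour the
  model is meant to reproduce.  The outer-bone deletion keeps the suture
  centred by removing from the wider flank (strict alternation cannot
  re-centre an asymmetric insertion stream).
* **Decay** of `v` is uniform in space (bone and mesenchyme alike); the
  source term alone is restricted to mesenchyme.
* **`v` initialisation**: the steady profile for the frozen initial `u`
  (iterated implicit solves), so runs start on the factor field's slow
  manifold rather than with a burn-in transient.
* **Steady-state detection** compares trailing half-window means of the
  mean suture width, because growth insertions impose a `±Δx`-scale
  sawtooth on the width that a range-based detector would never call
  steady.
* **Degenerate inputs**: a fused suture skips growth with a warning; a
  uniform field yields an all-invalid interface curve rather than an
  error; `t_end = 0` returns only the initial condition.

## Morphometrics

Measurements mirror how sutures are measured on calibrated photographs,
and run identically on binarized images and on simulated fields
(`u < 0.5`, pixel size `Δx`):

* **width**: suture pixels per transect × pixel size (transects are
  lattice rows perpendicular to the suture axis, matching pixel-counting
  practice, not local normals);
* **centerline**: midpoints of the outermost suture pixels per transect;
  the *reference* centerline is their least-squares straight fit —
  "farthest point" needs a fixed axis, and a straight fit matches the use
  of amplitude as a deviation measure.  Consequently the image should
  cover whole wavelengths: a fractional period tilts the fit and inflates
  amplitude;
* **max_amplitude**: farthest suture pixel from that line (so a straight
  band of width `w` reads `w/2`); measured from boundary pixels by
  default, with a skeleton-based variant (`from = "skeleton"`) since the
  source procedure does not specify which.  All three sweep-direction
  tests use `max_amplitude` (the source's definition); the
  `centerline_amplitude` variant, which excludes the half-width offset,
  is reported alongside, but in the strongly fingered low-`σ` regime the
  suture becomes a labyrinth whose outer-envelope midpoints are not a
  meaningful centerline, so it is not used for direction claims;
* **skeleton**: Zhang–Suen thinning (8-connected, ImageJ-like), with
  reflect-padding at borders so bands running off the crop keep their
  endpoints.  Two length figures are reported: the raw
  `skeleton_pixel_count` (the classical proxy) and the geometric
  `skeleton_length` (per-transect mean skeleton positions joined as a
  polyline).  The pixel count *undercounts* steep diagonal runs by up to
  ~18%, so the geometric figure is the one compared against arc length;
  this deliberately departs from the naive `length = count × pixel_size`
  identity.

## What the synthetic fixtures do and do not establish

The sinusoidal-band generator provides exact ground truth (width by
construction, amplitude `A + w/2`, arc length by quadrature) and a seeded
noise model.  The sinusoid is phase-centred on the image mid-row: a
least-squares straight line fitted to a few-period window of a generic-phase
sinusoid is measurably tilted (the amplitude reference would inflate by
`~2Aλ/ny` at the window ends), whereas the even-phase window makes the fit
exactly level.  It emulates a binarizable dark suture band of constant
along-`x` width; it does **not** emulate constant *normal* thickness (at
slopes beyond ~45° the along-`x` convention thins the band in the normal
direction and can fragment its rasterisation), bone texture, staining
gradients, or out-of-plane effects.  A green morphometric test therefore
establishes correctness of the measurement definitions on clean bands,
not robustness to photographic artefacts.  Simulated fields are validated
against cross-oracles instead (pixel widths vs interpolated `u = 0.5`
spans).

## Known limitations

* 2-D only; no mechanical-stress formulation (an alternative model class,
  out of scope).
* The linear `f(v) = α(v − v_c)` is the minimal admissible response;
  `forcing()` is the single place to swap a saturating law.
* Whether the four-parameter screens of the source used `c = 0` is
  unstated; the package assumes `c = 0` there.
* Interdigitation amplitudes at fixed `t_end` are seed-dependent;
  replicate means over ≥3 seeds are used for direction claims, and the
  absolute grid values of the source's phase diagrams (unprinted) are not
  reproduced.
* The `v_c` screening grid spans factor 1.1 steps (not a decade): the
  feasible `v_c` band is intrinsically narrow, bounded by fusion below
  and unbounded widening above.
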