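---
title: "Phase compensation for non-telecentric off-axis DHM: model, estimators and design choices"
author: "holophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase compensation for non-telecentric off-axis DHM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holophase)
```

## The imaging model

An off-axis digital holographic microscope records, in a single frame, the
interference between the field scattered by the sample and a tilted plane
reference wave:

$$h(x,y) \;=\; |u_{IP} + r|^2
  \;=\; |u_{IP}|^2 + |r|^2 + u_{IP}^{*}r + u_{IP}\,r^{*},$$

with $r(x,y) = \exp\!\big[i\,\tfrac{2\pi}{\lambda}(x\sin\theta_x +
y\sin\theta_y)\big]$ of unit intensity. When the distance $z$ between the
objective's aperture stop and the tube lens differs from the tube-lens
focal length $f_{TL}$ (the *non-telecentric* case), the image-plane field
acquires a spherical (paraxial, i.e. parabolic) phase factor

$$u_{IP}(x,y) \;\propto\; \exp\!\Big[i\,\frac{\pi}{\lambda C}(x^2+y^2)\Big]\,
  o(x,y), \qquad C = \frac{f_{TL}^2}{f_{TL}-z},$$

where $o = a_0 e^{i\varphi_0}$ is the (magnified) object field. We treat
the aperture stop as infinite, so the pupil convolution drops out; the
lateral magnification and the constant optical-path phase only rescale and
offset the result and are ignored throughout. With $z = f_{TL}$ the factor
is unity — the telecentric limit, represented in the package by an explicit
flag rather than an infinite curvature.

Estimating $\varphi_0$ therefore requires removing two phase terms from the
filtered cross-term $h_F = r^* u_{IP}$: the tilt
$t(x,y)=\tfrac{2\pi}{\lambda}(x\sin\theta_x+y\sin\theta_y)$ and the sphere
$s(x,y)=\tfrac{\pi}{\lambda C}(x^2+y^2)$.

Both parameters can be read off the hologram spectrum. The +1 order is the
object spectrum convolved with a quadratic-phase kernel: its **centroid**
sits at the carrier frequency, giving

$$\theta_x = \arcsin\!\Big(\frac{(u_0-P)\,\lambda}{X\,\Delta_{xy}}\Big),
\qquad
\theta_y = \arcsin\!\Big(\frac{(v_0-Q)\,\lambda}{Y\,\Delta_{xy}}\Big),$$

and its **compact support** is a rectangle whose size grows linearly with
$1/C$:

$$M = \frac{(X\Delta_{xy})^2}{\lambda C_x}
\;\;\Longleftrightarrow\;\;
C_x = \frac{(X\Delta_{xy})^2}{\lambda M},$$

and likewise $C_y$ from $N$ and $Y$. These two closed forms are the heart
of the method: everything else is plumbing around them.

## Coordinate and unit conventions

* Matrices are stored rows = $y$ (index $n$), columns = $x$ (index $m$),
  both 0-based in the documentation; the centred spectrum places DC at
  $(u_0, v_0) = (\lfloor X/2\rfloor, \lfloor Y/2\rfloor)$. For the even
  sensor sizes of real cameras this coincides with the familiar 1-based
  $(X/2+1, Y/2+1)$ convention; odd sizes work but warn.
* All lengths are micrometres. The reference configuration used throughout
  the documentation and tests is $\Delta_{xy} = 5.86$ µm and
  $\lambda = 0.532$ µm.
* Spatial coordinates are centred on the DC pixel,
  $x = (m-u_0)\Delta_{xy}$; the spherical factor is parameterized by its
  own centre $(h, g)$ in pixels because the distorting wavefront need not
  be centred in the field of view.
* The FFT is unnormalized (`stats::fft`), so
  $\sum |S|^2 / (XY) = \sum h^2$; the inverse transform carries the
  $1/(XY)$ factor.
* Phase is wrapped to $(-\pi, \pi]$, the range of `Arg()`.

## The pipeline and its estimators

`reconstruct()` chains: spectrum → ROI (given or suggested) → +1 filtering
→ tilt compensation → curvature from the ROI → sphere-centre estimation →
sign resolution → optional cost-driven refinement → phase extraction →
optional unwrapping. Each stage is exported on its own.

**ROI suggestion.** The published workflow leaves the +1 rectangle to the
user; `suggest_roi()` provides a deterministic seed: mask a disc of radius
$\max(X,Y)/20$ around DC, compress with $\log(1+|\cdot|)$, threshold at
Otsu's level, and return the bounding box of the largest connected
component whose centroid lies in the upper half-plane (rows above DC) —
the convention that defines which sideband we call +1. The box is *not*
padded; users who want the recommended slight overestimate (to keep object
detail) should enlarge M and N themselves. Note the coupling: a padded box
improves the retained object bandwidth but biases the curvature estimate
low, which is precisely what the optimization stage is there to repair.

**Filtering.** A hard rectangular crop by default, faithful to the classic
rectangle filter. `apodize` optionally tapers the mask edge with a raised
cosine (fraction of the half-width); this trades a slightly wider
transition band for much less ringing on sharp objects.

**Sphere centre.** After tilt compensation the wrapped phase of a
non-telecentric field is a concentric ring pattern around $(h,g)$. The
phase is normalized to $[0,1]$, binarized at Otsu's global threshold,
components are labelled, and among regions with area ≥ 0.1 % of the image
the one with the **lowest eccentricity** is chosen (ties → largest area);
the centre of its bounding box is the estimate. On clean simulated rings
this is pixel-exact; with fewer than ~3 wraps no ring survives
segmentation and `reconstruct()` falls back to the image centre with a
warning, leaving refinement to the optimizer.

**Sign.** The spectrum gives only $|C|$; converging and diverging
wavefronts compensate with opposite signs. We compensate with both signs
and keep the one with the smaller mean wrapped phase gradient: the wrong
sign *doubles* the residual ring frequency, so the gradient separates the
two robustly even when the curvature seed is far off (the phase-SD cost
saturates in that regime and is kept only as a tie-breaker).

**Unwrapping.** A reliability-sorting unwrapper (compiled): per-pixel
reliabilities from wrapped second differences, edges processed in
decreasing reliability, groups merged with the integer multiple of $2\pi$
that makes neighbours differ by their wrapped gradient. The output is
congruent to the input modulo $2\pi$ at every pixel; the global piston is
anchored so the median offset is zero.

## Cost functions and minimizers

Residual aberration after manual estimation is removed by minimizing, over
a box of ±50 % around the seed curvatures (`bounds_fraction = 0.5`):

* **J1** — the count of non-white pixels in the Otsu-binarized normalized
  phase (a perfectly compensated map binarizes all-white; a constant map
  returns 0 by convention);
* **J2** — the standard deviation of the wrapped phase over all pixels
  (the default: smooth, cheap, and it produces the most uniform
  backgrounds).

Eight minimizers are provided: bounded and unbounded quasi-Newton,
Nelder–Mead simplex, simulated annealing, a threshold-accepting randomized
pattern search, a deterministic compass pattern search, a real-coded
genetic algorithm (tournament selection, blend crossover, shrinking
Gaussian mutation, elitism, population 15), and the hybrid **GA + PS** —
GA to convergence (relative best-cost improvement < 10⁻⁶ over 10
generations, cap 100), then pattern search from its best point. The hybrid
with J2 is the default configuration. All stochastic members are
reproducible from `rng_seed`, and the hybrid can never return a worse cost
than its GA stage.

**Centre refinement is a block scheme.** With `refine_center = TRUE` the
chosen algorithm first searches the two curvatures with the centre held at
its ring-based estimate, and a deterministic pattern search then polishes
all four parameters jointly. The split reflects the landscape: away from
the optimum the wrapped-phase costs are nearly flat in the curvatures (the
SD of a many-ring map saturates at $2\pi/\sqrt{12}$), so keeping the
global stage two-dimensional concentrates its samples where the basin
actually is; near the optimum the cost is smooth in $(h,g)$ (a centre
error leaves a linear ramp, not extra rings), which a local compass search
descends reliably. A single four-dimensional GA+PS was observed to stall
on the flat region.

## The simulator

`simulate_hologram()` evaluates the model above exactly on the sensor
grid: unit-amplitude plane reference, object field multiplied by the
spherical factor (sign selectable, centre arbitrary), squared modulus,
optional additive Gaussian intensity noise (clipped at zero, seeded). It
enforces the Nyquist bound on the carrier and warns — rather than fails —
when the +1 support has no guard pixel to DC, because the estimators then
degrade gracefully and some validation scenarios (wide supports at small
C) legitimately operate there. Phase targets: `star` (16 sectors, radius
0.4·size), `bars` (three-bar groups at two scales), `wedding_cake`
(stacked discs, equal steps), `blobs` (smooth Gaussian bumps), `disc`.
The default step height 2.1497 rad is the nominal phase of a 350 nm step
of refractive index 1.52 in air at 532 nm. Ground truth, including the
pattern descriptor and the noise seed, round-trips through a JSON manifest
(doubles at JSON precision, ~15 significant digits).

What the simulator does *not* emulate: the finite pupil (no band-limit
beyond the spectral crop), partial coherence, speckle, shot noise or
camera quantization (an optional rounding stage exists but defaults off).
Passing tests therefore demonstrate correctness of the *estimators and
compensation algebra* under the stated model, not robustness to every
artefact of a physical instrument.

## Numerical choices

* **Support-edge rule.** The linear M–1/C relation needs an operational
  definition of the support edge, which the literature leaves unstated. The +1 term of a finite chirp has slowly decaying Fresnel
  tails — a threshold at 1 % of the peak overestimates M by hundreds of
  pixels at 1024². `measure_support_width()` instead thresholds at **half
  the plateau level** (median magnitude among bins above quarter-peak),
  which is robust both to the edge-ringing overshoot and to the tails and
  reproduces the closed-form M within ±2 px across C ∈ [10⁵, 10⁶] µm.
* **Minimum ring area** for centre estimation: 0.1 % of pixels, rejecting
  speckle-scale components while keeping genuine innermost rings.
* **DC exclusion radius** for ROI suggestion: max(X, Y)/20 px (scales with
  the sensor).
* **SSIM**: standard constants K₁ = 0.01, K₂ = 0.03 on maps jointly
  rescaled to [0, 1], 11 × 11 Gaussian window (σ = 1.5), circular boundary
  handling.
* **Degenerate inputs**: constant phase maps yield J1 = 0 and an explicit
  centre-not-found error; a telecentric flag short-circuits the spherical
  stage; ROIs touching DC or the spectrum edge are rejected with named
  errors; non-finite costs abort optimization naming the offending
  parameters.
* **Problem sizes.** The validation suite uses 256² grids for most
  properties, 512² for carrier recovery and the end-to-end optimization
  study, and 1024² for the support-width/curvature study — sizes at which
  each effect is comfortably resolved while the whole suite runs in
  minutes on one core.

## Known limitations

* **The all-pixels J2 cost is biased by large objects.** For a target
  covering a substantial area at a positive phase height (the star target
  at ~25 % fill, 2.15 rad), the J2 optimum does not sit exactly at the
  true curvature: a slight under-compensation bows the background toward
  the object's phase level, merging the two modes of the histogram and
  lowering the overall SD. On a *sphere-only* field both costs bottom out
  exactly at the truth (the acceptance script verifies this on a ±50 %
  grid at 1 % steps), but on the star scenario the GA+PS optimum lands
  about 1 % from the true curvature, which leaves a visible background bow
  (the `e2e_*` quantities in the acceptance output quantify this). A
  background-restricted or gradient-based cost would remove the bias at
  the price of needing a background segmentation; we keep the literal
  all-pixels definition.
* **SSIM against ground truth is bandwidth-limited for binary targets.**
  Single-sideband filtering band-limits the object to roughly the ROI
  minus the chirp support; sharp-edged binary patterns (disc, star, bars)
  then carry Gibbs ringing and blur that cap SSIM near 0.9 at 256²–512²
  *even when the true parameters are supplied*. Smooth or large-featured
  targets (blobs, wedding cake) reach ≥ 0.95. This is a property of
  off-axis filtering, not of the compensation.
* The ROI suggester picks the upper half-plane sideband by convention;
  carriers whose +1 order lies below DC are recovered with conjugated
  sign. Supply the ROI explicitly in that case.
* Only tilt and parabolic spherical aberration are modelled; no Zernike
  terms, no refocusing (the image plane is assumed at the sensor).

## Session info

```{r}
sessionInfo()
```
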