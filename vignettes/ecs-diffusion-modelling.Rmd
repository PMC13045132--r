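---
title: "Modelling transmitter diffusion in brain extracellular space from accessibility maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transmitter diffusion in brain extracellular space from accessibility maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
library(difflux)
```

## The model

The brain extracellular space (ECS) is a connected network of
interstitial-fluid-filled sheets and tunnels between neural cell membranes.
Transmitters released from point sources (synaptic vesicles) diffuse through
it before reaching receptors, and the local ECS geometry shapes where they
go. Super-resolution shadow imaging labels the interstitial fluid with an
extracellular dye, so pixel brightness reports how much of each pixel is
diffusionally accessible ECS rather than cellular structure.

`difflux` works entirely on that *accessibility map*: after background/maximum
normalisation of the raw image (`normalize_image()`, then
`alpha_from_image()`), each pixel carries the local ECS volume fraction
$\alpha_{pix} = F_{pix}/255 \in [0, 1]$. The key modelling assumption, an
extrapolation of Fick's law to the pixel scale, is a linear mapping from
accessibility to effective local diffusivity,

$$D_{pix}(x, y, z) = \alpha_{pix} \cdot D_{free},$$

with $D_{free}$ the free-solution diffusion coefficient of the molecule
(glutamate $0.75\,\mu m^2/ms$, GABA $1.1\,\mu m^2/ms$;
`diffusivity_um2_ms()` converts from $m^2/s$). Diffusion is free in pure-ECS
pixels, impossible in pure-structure pixels, and partially hindered in
partial-volume pixels. Because the information is carried in the analogue
pixel value, the approach does not require optically resolving the ECS: a
smooth, under-resolved map is still a valid input, which is what makes 2D
imaging usable at all (binarised maps of 2D planes produce closed mazes).

Two engines consume the map:

**Bulk solver.** The heterogeneous diffusion equation with sources and a
clearance sink,

$$\frac{\partial C}{\partial t} = \nabla \cdot \left(D_{pix} \nabla C\right) + S - \kappa C,$$

is integrated by the explicit forward-Euler method (`difflux_simulate()`).
An instantaneous release of $n$ molecules deposits
$S = n / (N_A\, \Delta x \Delta y \Delta z)$ mol/L into its source voxel at
its event time. $C$ is the interstitial concentration on the full grid.

**Single-particle walker.** A lattice Monte Carlo walk
(`simulate_walk()`): at each step an axis is drawn uniformly
($p_{dir} = 1/2$ in 2D, $1/3$ in 3D), a direction uniformly ($p_i = 1/2$),
and the move into the target pixel is accepted with probability
$\alpha(\text{target})$ — with probability $p_b = 1 - \alpha$ the particle
"bounces" off the obstacle and stays. Borders wrap toroidally. Unwrapped
positions feed mean-squared-displacement (MSD) analysis (`msd()`,
`fit_gamma()`).

## Numerical choices

**Stencil and face diffusivity.** The solver uses the 5-point (2D) / 7-point
(3D) flux form with the face diffusivity taken as the arithmetic mean of the
two adjacent $D_{pix}$, with one exception: a face adjacent to an
$\alpha = 0$ pixel carries zero conductance. Pure cellular structure must
not transport mass — with a plain arithmetic mean a wall one pixel thick
would leak, with the hard zero an $\alpha = 0$ column blocks flux exactly.
The flux form guarantees discrete conservation: with closed borders and no
clearance, total mass is conserved to rounding ($\sim 10^{-14}$ relative
over $10^5$ steps; the suite asserts $10^{-9}$).

**Stability.** The explicit update requires
$\Delta t \le \min(\Delta x, \Delta y, \Delta z)^2 / (2\, n_{dims} \max
D_{pix})$; `difflux_simulate()` refuses a larger step and suggests the
bound, and by default uses 90% of it. With 50 nm pixels and
$D = 0.75\,\mu m^2/ms$ the bound is $\approx 0.8\,\mu s$ — time steps on the
microsecond scale.

**Leaky frame borders.** To emulate an infinite surround, every border pixel
is overwritten each step with $ef$ times its previous-step inward neighbour
($C_t^{1,y} = ef \cdot C_{t-\Delta t}^{2,y}$, corners use the diagonal
neighbour), with the standard escape factor $ef = 0.9$, i.e. 10% of the
border content escapes per step. The rule is applied verbatim as an
overwrite; the cumulative escaped mass is accounted in the run's mass audit.
Closed (no-flux) and periodic (toroidal, for comparison with the walker)
variants are available.

**Simplified 3D.** Full-3D stacks are expensive and often unavailable; mode
`"3D_smpl"` models a single imaged plane and replaces the axial term by a
per-pixel sink $\kappa_{pixel} = \alpha \cdot \kappa(t)$ with

$$\kappa(t) = 15000 \cdot dt \cdot e^{-6000\, t} + 75 \cdot 10^6 \cdot dt^2,$$

($t$, $dt$ in seconds) interpreted as a per-step loss fraction,
$C \leftarrow C (1 - \alpha \kappa(t))$ — the only reading consistent with
the constants' $dt$ and $dt^2$ scaling. $t$ is measured since the most
recent release (reset on every event of a train): axial escape is strongest
right after a release, when out-of-plane gradients are steepest, and decays
to the floor $\kappa_{min} = 75 \cdot 10^6\, dt^2$. In our homogeneous-stack
comparisons the sink moves the plane simulation from the 2D extreme toward
the full-3D result (peak and decay ordering 2D > 3D_smpl > 3D, asserted in
the tests) but does not reproduce full-3D probe metrics quantitatively: at
$\alpha = 0.25$ the simplified peak remains several-fold above full 3D. The
constants were externally calibrated against conditions (probe geometry,
voxel sizes) that are not fully published; treat `"3D_smpl"` results as
comparative between scenarios run in the same mode, not as absolute 3D
predictions.

**Walker time base.** The lattice step is the pixel size $h$ and the step
time $\Delta t = h^2 / (2\, n_{dims}\, D_{free})$, so an always-accepted
walk reproduces $D_{free}$ exactly; the bounce rule then scales the
long-time diffusivity linearly with $\alpha$ (the calibration test recovers
$D = \alpha D_{free}$ within 3% with $10^4$ particles). The RNG is a
counter-seeded PCG32 with one substream per particle, so runs are
reproducible irrespective of evaluation order.

**Walker versus solver.** The walk's stationary per-voxel density is
proportional to $\alpha$ (molecules accumulate where there is volume to hold
them), while the bulk equation equilibrates to uniform interstitial
concentration. The consistent comparison is therefore *molecules per voxel*:
binned particle counts against $\alpha \cdot C$. On a blob-neuropil phantom
the two engines agree at Pearson $r \approx 0.98$ over the occupied region
at matched time.

**MSD convention.** MSD is measured from each particle's release point at
$t = 0$ (per-source averaging); a sliding-lag estimator is available
(`msd(..., method = "sliding")`). The anomaly exponent $\gamma$ in
$\langle r^2 \rangle \sim t^\gamma$ is fitted on log-log axes over a window
that by default drops the first two lags (single-lattice-step artefacts) and
the final 10% (poor averaging).

## Structure statistics

`radial_psd()` computes the radially averaged spatial power spectral
density: mean-subtracted 2D FFT (no taper by default, optional Hann), power
normalised so that the summed spectrum equals the image variance (a
Parseval identity asserted in the tests), averaged over annuli one
frequency-grid step of the shorter axis wide. `fit_psd_band()` fits
$PSD \sim 1/f^\beta$ by log-log regression within a band; the analysis
bands are 0.13–0.5 cycles/µm (somas, large dendrites) and 0.5–2 cycles/µm
(finer ECS); frequencies above 2 cycles/µm are dominated by detector noise
and excluded. Recovering a prescribed exponent in the low band needs a wide
field of view — on a 12.8 µm frame the band holds only a handful of
annuli, so the acceptance script uses a 51.2 µm frame (512² at 100 nm)
there.

`dispersion_index()` quantifies anisotropy around a source: concentrations
are sampled on rings of accessible pixels (centre distance within half a
pixel of the radius) and summarised by the index of dispersion
(variance/mean). The "normalised" variant divides once more by the ring
mean, making it invariant under $C \to cC$; the raw index is also returned
since the normalisation convention in the field is not standardised —
absolute published values of this statistic should not be expected to
reproduce under a different convention.

## Diffusion tensors

`tensor_grid()` condenses local anisotropy into a vector field: from every
grid source on accessible pixels a short test release is simulated (default
snapshot 100 µs; directionality depends on the chosen diffusion time, so
this is configurable) and the resulting cloud — the connected component
above 1% of the field peak — is reduced to a tensor. The perimeter is
taken as the sub-pixel iso-concentration contour enclosing the source;
integer-pixel boundaries would make even a perfect circle look weakly
anisotropic (half-pixel quantisation), which previously floored the
uniform-map magnitudes an order of magnitude higher.

* **direction**: principal axis (orthogonal regression) of the perimeter
  points, oriented toward the furthest perimeter point (ties broken by
  lowest row, then column); the goodness of fit is the eigenvalue contrast
  $(\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2)$, 0 for a circle, 1 for
  a line.
* **directionality coefficient**: the perimeter distance distribution is
  normalised by its maximum and the area above its cumulative distribution
  taken, which reduces to $1 - \bar d / d_{max}$. A circular cloud gives
  exactly 0; elongation drives it toward 1.
* **magnitude** = furthest distance × coefficient (µm), so isotropic spread
  yields a vanishing tensor; **strength** additionally weighs by the
  direction goodness of fit. (Weighting by reach rather than reach/time is a
  convention choice; at a fixed snapshot the two differ by a constant.)

On dendrite-tube phantoms the recovered tensor angles track the tube angle
with unit slope, and uniform maps yield median magnitudes a few percent of
tube-map medians. `summarize_angles()` bins full angles into 30° sectors
and reports folded (modulo-180°) statistics against a reference
orientation.

## The virtual experiments

`crosstalk_experiment()` releases one vesicle at a source synapse and
records what reaches neighbouring synapses, on the structured map and on
its `homogenize()`d control — a uniform map at the frame-mean $\alpha$
(the mean, not the median, so total ECS volume is conserved; both
statistics are exposed by `frame_alpha()`). The per-neighbour
homogenised/structured peak ratio measures how much real geometry
suppresses crosstalk relative to the volume-averaged prediction. The ratio
is exactly 1 on an already-uniform map, and scales out of the molecule
count (linearity is asserted in the tests).

`spillover_experiment()` drives synchronous periodic release trains
(`release_train()`, events at $0, 1/f, \dots$ strictly before the duration)
across many sites and reports per-probe steady-state plateaus (mean over
the final 20% of the run, with the residual slope so stationarity can be
checked) and structured/homogenised concentration ratios at snapshot times.
Trains are synchronous across sites; release phase is not randomised.

## What the phantoms emulate

All tests and the acceptance script run on synthetic accessibility maps
(`make_uniform()`, `make_blob_neuropil()`, `make_tube()`,
`make_spine_scene()`, `make_soma_rim()`); no microscopy data is required.

**Blob neuropil.** Dense neuropil at super-resolution pixel sizes is not a
set of ECS blobs: the ECS is the thin *connected* sheet network between
cellular structures. The generator therefore places accessibility along the
zero-level contour network of a smoothed Gaussian random field
($\alpha = \alpha_{max} e^{-f^2/2w^2}$), which percolates like real
interstitial sheets; the channel width $w$ is set from the Gaussian
expectation so the frame mean hits the target (realised mean within 0.01,
by construction). A thresholded-blob construction was rejected: at
$\alpha \approx 0.25$ its ECS does not percolate in 2D and walkers are
trapped ($\gamma \approx 0.2$) — the closed-maze failure mode of binarised
maps. On the contour-channel phantom at target $\alpha = 0.25$ the walker
shows clear sub-diffusion ($\gamma \approx 0.85$–0.90 over 100 ms windows),
and $\gamma \to 1$ as the target $\alpha$ rises — the qualitative behaviour
of imaged neuropil. Pixel-level partial-volume values arise directly from
the smooth mapping. What these phantoms do *not* reproduce: the full
lognormal ECS width distribution, 3D connectivity, or exact tissue PSD
levels, so tissue-derived numbers (e.g. a specific $\gamma$ or $\beta$)
should be compared in direction and rough magnitude only.

**Dendrite tube.** An $\alpha = 0$ cylinder at a chosen angle with a bright
ECS rim in uniform or blob background: the canonical fixture for
directionality (rim tensors align with the tube) and rotation-equivariance
checks.

**Spine scene.** A shaft with three spines; the source synapse above the
central spine head, neighbours 2 µm to each side, and partial obstacle
walls forcing diffusional detours between them — the structural situation
in which volume averaging overestimates crosstalk.

**Soma rim.** An impermeable soma disc with a thin bright perisomatic
sheet, *confined on its outer side* by a low-accessibility shell with a few
openings (abutting cell bodies), in uniform neuropil; release sites every
~5 µm along the membrane plus a matched neuropil column, and probes at
equal distance (1.2 µm) from their nearest site. The outer confinement
matters: it is the restriction of the perisomatic space that lets repeated
release pile GABA up along the membrane. With an unconfined bright rim, the
$\alpha$-scaled clearance sink (which drains high-$\alpha$ pixels fastest)
can cancel the geometric advantage at high release rates; with the
realistic sandwich geometry the membrane probe plateau exceeds the
neuropil probe at all tested frequencies (10–100 Hz).

## A worked run

```{r example}
map <- make_blob_neuropil(target_alpha = 0.25, correlation_length_um = 0.5,
                          shape = c(128, 128), pixel_size_nm = 50, seed = 7)
summary(map)

# release from an accessible channel pixel near the centre; probe ~1 um away
open <- which(map$alpha > 0.5, arr.ind = TRUE)
src <- open[which.min((open[, 1] - 64)^2 + (open[, 2] - 64)^2), ]
d <- sqrt((open[, 1] - src[1])^2 + (open[, 2] - src[2])^2)
bystander <- open[which.min(abs(d - 20)), ]

cfg <- difflux_config(D_free = 0.75, mode = "3D_smpl")
sim <- difflux_simulate(map, release_event(src[1], src[2],
                                           n_molecules = 10000),
                        cfg, duration_ms = 2,
                        probes = rbind(source = src, bystander = bystander))
probe_metrics(sim)

tr <- simulate_walk(map, src, walk_config(D_free = 0.75, n_particles = 500,
                                          duration_ms = 50, seed = 1))
fit_gamma(msd(tr))
```

## Problem sizes and runtime

The test-suite and acceptance computations are sized for a single CPU:
$256^2$ grids for conservation and the analytic oracle ($10^5$ and
250 steps), $10^4$ walkers for calibration, $10^5$ walkers for the
engine-equivalence check, 5 seeds × 10 sources × 200 walkers × 100 ms for
the anomaly estimate, six 160² tube phantoms for the angle sweep, and the
full four-frequency spillover sweep at 200 ms on a 128² soma scene. The
complete acceptance script runs in about three minutes.

## Known limitations

* The model is purely structural: no interstitial viscosity variation, no
  binding/uptake, no advective flow, no receptor kinetics downstream of the
  simulated concentrations.
* `"3D_smpl"` is comparative, not an absolute 3D surrogate (see above).
* The dispersion-index normalisation and the cloud-boundary threshold (1%
  of peak) are conventions; sensitivity to the threshold can be probed via
  the `threshold` arguments.
* Background and maximum intensities for normalisation are user-supplied
  measurements, not estimated from the image.
* Phantom geometries are deliberately minimal; quantitative tissue numbers
  require real accessibility maps.
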