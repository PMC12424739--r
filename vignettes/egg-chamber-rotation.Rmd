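---
title: "A mechanochemical model of egg-chamber rotation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanochemical model of egg-chamber rotation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggspin)
```

## The biological problem

The follicular epithelium of the *Drosophila* egg chamber is a closed
epithelium with no free edge, yet it polarizes itself and migrates
collectively along the surrounding basement membrane (BM), rotating the whole
chamber about its anterior–posterior (AP) axis.  Two features make this
system unusual among collective-migration models.  First, the apical
surfaces of the follicle cells adhere to the germ cells inside, so the
tissue translates none of its activity into internal shear: the chamber
moves as a *rigid body*, and a single angular velocity synchronizes every
cell.  Second, the planar-polarity protein Fat2 localizes to each cell's
trailing edge and orients the protrusions of the cell behind it, and this
localization is itself *mechanosensitive*: tissue motion recruits Fat2 to
the trailing side.  Together these close a positive feedback loop —
polarity orients force, force produces rotation, rotation re-polarizes —
that can break chiral symmetry from a perfectly isotropic start.

`eggspin` implements this model, its 3-D extensions (a free sphere and a
stage-1 chamber held against stationary pre-stalk cells), and the
quantification layer used on centroid-track and edge-intensity tables, plus
a synthetic-data generator that stands in for segmented microscopy movies.

## The model

The chamber is a rigid ellipsoid, lengths rescaled by the equatorial radius,
long axis along the body AP axis $\hat d_3$, aspect ratio $e \ge 1$.  Cell
$i$ sits at anchor $r_i$ and exerts a tangent crawling force $b_i$.  In the
overdamped limit, with the BM elastically confining every degree of freedom
except rotation about the long axis, the torque balance reduces to

$$\Pi(e)\,\omega_3 = \sum_i (r_i \times b_i)\cdot \hat d_3, \qquad
  \Pi(e) = \frac{N\pi\,(40 + 26\,(e-1))}{15},$$

with $\omega = \omega_3 \hat d_3$.  $\Pi(e)$ is used as a closed form; it is
linear in the cell count $N$ and increasing in $e$, with
$\Pi(1) = 8N\pi/3$.

Each cell carries a Fat2 concentration field $c_i(\beta, t)$ over the
in-plane angle $\beta$, discretized into $M$ bins.  $\beta$ is measured from
$t_1$ (the tangent projection of $\hat d_3$) towards $t_2 = t_1 \times
\hat n$ (the right-handed azimuthal direction), so counterclockwise rotation
($\omega_3 > 0$) moves cells along $+t_2$ and their trailing edge is at
$\beta = -\pi/2$.

The crawling force relaxes towards the direction *opposite* the
Fat2-enriched edge of the same cell:

$$\frac{\partial b_i}{\partial t} = \omega \times b_i
  - \tau_1\,\big(\eta_i(t) + b_i\big), \qquad
  \eta_i = (\cos\beta_i,\ \sin\beta_i)\ \text{in the tangent frame},$$

where $\beta_i(t)$ is drawn stochastically from the distribution
proportional to $c_i(\beta, t)$ — protrusive activity is noisy, and Fat2
biases where it appears.  The fixed point for frozen $\eta$ is
$b = -\eta$.  Because $b_i$ is stored in each cell's co-rotating tangent
frame, the advective $\omega \times b_i$ term is carried by the frame
itself and does not appear explicitly in the update.

Fat2 is recruited to the side of the cell facing away from its own motion
$v_i = \omega \times r_i$ and saturates through a quadratic decay:

$$\frac{\partial c_i(\beta)}{\partial t} =
  -\tau_2\,\big[\tau_3\, v_i \cdot m(\beta, r_i) + c_i(\beta)\big]\,
  c_i(\beta),$$

with $m(\beta, r_i) = \cos\beta\, t_1 + \sin\beta\, t_2$.  Bins on the
trailing side ($v \cdot m < 0$) grow towards $c^* = -\tau_3\, v\cdot m$;
leading bins decay.  The equations do not conserve Fat2 mass; sampling
normalizes the distribution on the fly, and a small floor `c_floor` keeps
the sampling weights strictly positive rather than renormalizing the field
(renormalization would silently change the dynamics).

Runs start from the isotropic state $c_i = 1/(2\pi)$, $b_i = 0$,
$\omega_3 = 0$, so any rotation is spontaneously generated.

### Why symmetry breaks, and the role of each parameter

Linearizing around the isotropic state: a small angular-velocity
fluctuation $\omega_3$ gives every cell an azimuthal velocity
$\omega_3\,a_i$ ($a_i$ = distance from the axis), Fat2 accumulates at the
trailing bin at rate $\tau_2 \tau_3 c_0 \cdot |v|$, the biased sampling
tilts $\langle\eta\rangle$ trailing-ward, the force $b = -\eta$ tilts
leading-ward, and the torque reinforces $\omega_3$.  The loop closes
against the saturation decay $-2\tau_2 c_0$.  At the default geometry
($e = 1.2$, $N = 200$) the loop gain crosses the decay near
$\tau_3 \approx 10$; the defaults

| parameter | default | meaning |
|---|---|---|
| `tau1` | 1 | force relaxation rate towards the Fat2-set direction |
| `tau2` | 1 | Fat2 turnover rate |
| `tau3` | 40 | mechanosensitive gain relative to saturation |
| `dt`   | 0.01 | Euler step (stability needs `dt*tau1 < 1` and, in practice, `dt*tau2*tau3*max|v| < 1`) |
| `T`    | 200 | run length, in units of the rotation-onset time |
| `M`    | 64 | angular bins per cell |
| `resample_every` | 1 | steps between protrusion-angle redraws |

place the whole four-fold sweep $\tau_k/4 \dots 4\tau_k$ comfortably above
threshold, which is the robustness regime the model is meant to occupy:
`tau3 = 40` was chosen so that even `tau3/4 = 10` still breaks symmetry,
rather than sitting exactly at the critical point.  With these defaults
symmetry breaks around $t \approx 7$–$13$ and the run spends most of its
length in the steady rotating state.

A property worth knowing when interpreting output: the *steady* rotation
speed is almost independent of $\tau_{1..3}$.  Once saturated, the Fat2
profile has the universal shape $c^*(\beta) \propto \max(-\sin\beta, 0)$ —
the gain $\tau_3$ scales its amplitude but not its shape, and the sampling
distribution only sees the shape.  The steady $|\omega_3|$ ($\approx 0.065$
at $e=1.2$, $N=200$) is therefore set by geometry, while the $\tau$'s
control whether and how fast symmetry breaks.

### Stochastic integration and exact chirality symmetry

The integrator is explicit Euler.  The only stochasticity is the per-cell
protrusion angle, redrawn every `resample_every` steps by inverse-CDF
sampling over the $M$ bins; no white-noise term exists, so no
higher-order stochastic scheme is needed.  Halving `dt` while doubling
`resample_every` preserves the redraw times *and* the consumed RNG stream,
which is how the first-order convergence test is phrased.

The model is exactly chiral: reflecting every drawn angle
($\beta \to -\beta$) must flip $\omega_3$ and mirror the Fat2 field.  The
compiled integrator preserves this at the bitwise level, not merely to
rounding: forces are stored in tangent components, torque and velocity use
the azimuthal lever arm $(\hat z \times r_i)\cdot t_2$ (meridional force
components exert no axial torque on a surface of revolution), and the
$\beta$ grid is built sign-symmetrically so `centers[M+1-k]` is the exact
negation of `centers[k]`.  `run_base_model(..., mirror = TRUE)` runs the
reflected realization of the same seed, and
`identical(traj$omega3, -mirrored$omega3)` holds exactly.  The exported R
step functions (`step_forces()`, `step_fat2()`, `compute_omega3()`,
`sample_protrusion_angles()`) implement the unreduced vector algebra and
serve as the reference the compiled loop is tested against.

### Geometry

Cells are placed by a deterministic Fibonacci lattice on the unit sphere,
scaled by $(1, 1, e)$ — approximately equi-areal, reproducible without
randomness (a `jitter_sd` option exists for perturbed lattices).  Normals
come from the implicit-surface gradient.  At the poles, where the AP axis
is parallel to the normal and $t_1$ is undefined, $t_1$ falls back to the
projected body x-axis.

## Free sphere and the pre-stalk interface

Young chambers are essentially spherical, and on a sphere ($e = 1$) the BM
confinement argument no longer pins the axis: the model still breaks
symmetry, but the rotation axis is free.  `run_free_sphere()` integrates
the full orientation with a unit quaternion (body-to-lab), advanced by the
exponential map of $\omega\,dt$ and renormalized each step, with the
isotropic balance $\omega = \sum_i (R r_i) \times (R b_i) / \Pi(1)$.
Across seeds the final axes scatter over the sphere (mean resultant length
$\approx 0.08$ over 100 seeds in our runs).

At stage 1 the anterior cap of the chamber presses against stationary
pre-stalk cells across a flattened interface.  `run_prestalk_model()`
represents that interaction with two implementer-chosen terms realizing its
qualitative mechanics — elastic resistance to motion normal to the
interface, viscous resistance to tangential sliding:

* a restoring torque $k_s\,(\hat d_3 \times \hat e_3)$ that rotates the
  co-moving AP axis towards the fixed pre-stalk axis $\hat e_3$, and
* a drag torque $-\mu_s \sum_{j \in \mathrm{cap}} r_j' \times (\omega
  \times r_j')$ summed over cells within polar angle $\theta_s$ of
  $\hat e_3$ ($r_j' = R\,r_j$), entering the balance as a
  positive-semidefinite operator so the solve
  $[\Pi(1) I + A_{\mathrm{drag}}]\,\omega = T$ is always well posed and the
  drag can only dissipate.

Because these functional forms are the package's own construction, only
their qualitative contract is asserted: the rotation axis ends aligned with
the pre-stalk axis, faster for stiffer $k_s$, and with $k_s = \mu_s = 0$
the model reduces bitwise to the free sphere.  Defaults
($\theta_s = 0.6$ rad, $k_s = 500$, $\mu_s = 30$) were set once so the
interface torques are commensurate with the BM drag
$\Pi(1) \approx 1.7 \times 10^3$ at $N = 200$; a design sweep
($k_s$ 200–1000, $\mu_s$ 10–100) aligns the axis to under a degree
throughout, with alignment time decreasing in $k_s$, so conclusions do not
hinge on the particular default.  Alignment is measured on the *undirected*
axis (angles folded at 90°): the model is chiral-symmetric, so $\omega$
ends parallel or antiparallel to $\hat e_3$ with equal probability, and
both are rotation about the AP axis.

## Quantification of tracks and edges

The analysis functions mirror the standard live-imaging pipeline on plain
tables (`cell_id, frame, t_min, x_um, y_um, boundary`):

* `filter_tracks()` keeps each cell's longest run of consecutive frames,
  discards cells with fewer than 10 consecutive frames, and drops
  boundary-flagged cells.  Boundary status is a caller-supplied flag
  (detected from tissue masks upstream in a real pipeline; the synthetic
  generator flags cells within one median nearest-neighbour spacing of the
  field edge).
* `center_tracks()` subtracts the per-frame mean cell position — a
  centroid-table proxy for centering on the tissue-mask centroid, which is
  not recoverable from tables.  Note a limitation of planar synthetic data:
  a rigid *translational* drift (how the generator encodes migration) is
  removed by centering, whereas in images the migration is flow past a
  stationary tissue outline.  Centering is therefore an explicit,
  optional step, intended for stage/XY drift, not a hard-wired part of the
  polar-order or rate computations.
* `polar_order()` computes
  $\alpha = \big|\sum_{j,i} p^j_i\big| / \sum_{j,i} |p^j_i|$ over
  displacements $p^j_i$ between consecutive sampling times (default 1-min
  spacing over 30 min, decimated by frame selection, not averaging), for
  cells present at both endpoints; $\alpha = 1$ means perfectly aligned
  movement, $\alpha \to 0$ isotropic movement.
* `displacement_stats()` (net first-to-last distance per cell) and
  `migration_rate()` (per-cell path length over elapsed time by default;
  `method = "net"` is available since either convention is defensible and
  the path/net distinction only matters for tortuous tracks).
* `fat2_polarity_ratio()` is the mean edge intensity at angles 0–10° from
  the AP axis (leading/trailing edges) over the mean at 80–90° (lateral
  edges), both bins closed, other edges ignored.  Edges are undirected, so
  angles are folded into [0°, 90°].

## The synthetic-data generator

`gen_tracks()` emulates three regimes observed at the basal surface:
`rotating` (common drift of 0.2 µm/min — the measured stage-1 rotation
rate — plus small jitter), `pre_rotation` (no drift, large zero-mean
jitter: protrusion-driven local motility before rotation starts) and
`null_like` (near-static, as in tissue that never migrates).  Frames default
to 15-s intervals over 30 min.  Jitter is independent isotropic Gaussian
noise per frame — deliberately the simplest null; it reproduces the polar
order and rate statistics the analysis consumes but *not* the spatial
correlations of protrusion-driven neighbour displacement, cell shape, or
segmentation noise.  Passing tests on these fixtures therefore validates
the arithmetic of the pipeline, not its behaviour on every artefact of real
microscopy.  `gen_edges()` draws edge angles uniformly and lognormal
intensities whose mean interpolates from `ratio` (angle ≤ 10°) to 1
(angle ≥ 80°), so the target polarity ratio is recovered in expectation.

## Numerical choices, degenerate inputs, problem sizes

* Ties in inverse-CDF sampling resolve to the first bin whose cumulative
  weight reaches the target; all-floor fields sample uniformly.
* `onset_time()` is the first time $|\omega_3|$ exceeds half the steady
  magnitude (the mean over the final 20% window) and stays above; runs
  without sustained rotation are classified `"none"` and have no onset.
* Degenerate analysis inputs fail loudly: all-static tracks (undefined
  $\alpha$), empty polarity bins, empty post-filter track sets, all-floor
  Fat2 distributions.
* A divergence guard aborts integration if $|\omega|$ exceeds `omega_max`.
* The test-suite problem sizes are the package's reference study
  conditions: 200-seed base-model ensembles at $N = 200$, $e = 1.2$,
  $T = 200$; 30-seed pre-stalk and 100-seed free-sphere ensembles at
  shorter $T = 60$ (axis behaviour is settled well before then); property
  checks on smaller lattices.  A full default run integrates
  $2\times10^4$ steps in well under a second via the compiled loop.

## Known limitations

* Rigid-body only: no elastic deformation of the tissue, no neighbour
  exchange, no trans-cellular Fat2 coupling (Fat2's effect is treated as
  cell-autonomous), no forces normal to the surface.
* The pre-stalk interface is a rigid cap with phenomenological
  elastic/viscous coefficients, not a mechanical model of the pre-stalk
  cells; only direction and monotonicity claims are made.
* The ellipsoidal case constrains rotation to the long axis as a hard
  1-DOF reduction (the elastic-confinement limit), not as a soft restoring
  torque.
* The protrusion persistence time is unknown; `resample_every` exposes it,
  and the default (redraw every step) is the memoryless choice.
* Steady-state speed in physical units depends on the non-dimensionalizing
  scales, which the package does not set; comparisons to measured µm/min
  rates go through the track-analysis layer, not the simulation.
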