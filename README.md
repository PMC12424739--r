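# eggspin

Simulation and quantification of spontaneous rotational migration in the
*Drosophila* egg chamber.

The egg chamber is a closed epithelial tissue: follicle cells crawl along the
basement membrane that encases them, and because their apical surfaces adhere
to the germ cells inside, the whole chamber rotates as a rigid body.  Rotation
starts from an unpolarized state, picks clockwise or counterclockwise at
random, and then persists about the anterior–posterior (AP) axis.  `eggspin`
implements a minimal mechanochemical model of how this symmetry breaking
works, and the track/edge statistics used to quantify it, for researchers
studying collective cell migration, planar polarity, and self-organized
tissue movement.

## The model

The chamber is an overdamped rigid ellipsoid (aspect ratio *e*, lengths in
units of the equatorial radius) with *N* cells at anchors *rᵢ*, each exerting
a tangent crawling force *bᵢ*.  Rotation about the long axis obeys the torque
balance

    Π(e) ω₃ = Σᵢ (rᵢ × bᵢ) · d̂₃,    Π(e) = N π (40 + 26(e−1)) / 15.

Each cell carries a Fat2 concentration field *cᵢ(β, t)* over the in-plane
angle β.  The crawling force relaxes towards the direction opposite a
stochastically sampled Fat2-enriched edge,

    ∂bᵢ/∂t = ω × bᵢ − τ₁ (ηᵢ + bᵢ),    ηᵢ = (cos βᵢ, sin βᵢ),
    βᵢ ~ distribution ∝ cᵢ(β, t),

and Fat2 is mechanosensitively recruited to the side facing away from each
cell's motion *vᵢ = ω × rᵢ*:

    ∂cᵢ(β)/∂t = −τ₂ [τ₃ vᵢ·m(β, rᵢ) + cᵢ(β)] cᵢ(β).

From a perfectly isotropic start (*cᵢ = 1/2π*, *bᵢ = 0*) this feedback loop
breaks chiral symmetry and sustains rotation, with the Fat2 distribution
polarizing to β = −π/2 (the trailing edge) for counterclockwise runs and
+π/2 for clockwise ones.  Two 3-D variants integrate the full orientation
with a quaternion: an unconstrained sphere, whose rotation axis is free, and
a stage-1 model in which an elastic/viscous interface with stationary
pre-stalk cells pulls the axis onto the AP axis.

The analysis layer implements the standard quantifications on centroid-track
tables (10-consecutive-frame filter, boundary-cell removal, per-frame
centering, polar order parameter α = |Σ pᵢʲ| / Σ |pᵢʲ|, net displacement and
migration rate) and on cell-edge intensity tables (leading-trailing [0°,10°]
vs lateral [80°,90°] Fat2 polarity ratio).  A synthetic generator produces
track and edge tables emulating the rotating, pre-rotation, and
never-migrating regimes.

## Worked example

```r
library(eggspin)

geom <- make_geometry(e = 1.2, N = 200)
geom
#> <egg_geometry> N = 200 cells on ellipsoid with aspect ratio e = 1.2
#>   rotational drag Pi(e) = 1893.3332

traj <- run_base_model(model_params(seed = 7), geom)
rotation_direction(traj)
#> [1] "CW"
onset_time(traj)
#> [1] 8.8
fat2_circular_mean(traj$snapshots[nrow(traj$snapshots), ], traj$beta_centers)
#> [1] 1.570796
```

This seed breaks symmetry clockwise (ω₃ < 0) around t ≈ 9 (in units of the
rotation-onset time) and settles at a steady mean ω₃ of −0.065 over the final
fifth of the run; the cell-averaged Fat2 distribution ends polarized at
+π/2, the trailing edge for clockwise motion.  Other seeds choose either
direction with equal probability.

The quantification layer works on plain data frames:

```r
tracks <- filter_tracks(gen_tracks(track_gen_config("rotating", seed = 1)))
polar_order(tracks)
#> [1] 0.8807422
migration_rate(tracks)
#> [1] 0.3074228

edges <- gen_edges(500, ratio = 1.5, noise_cv = 0.2, seed = 1)
fat2_polarity_ratio(edges)
#> [1] 1.538913
```

The rotating-mode tracks drift at 0.2 µm/min under 0.05 µm/frame jitter:
coherent drift dominates (α ≈ 0.88), and the path-integrated rate (0.31
µm/min) sits above the drift speed because jitter adds path length.  The
noisy edge set recovers its target polarity ratio of 1.5.

A thin command-line front end is installed at `inst/cli/eggspin`
(`simulate`, `generate`, `analyze`, `ensemble` subcommands).

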