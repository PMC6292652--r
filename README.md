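# neurowaves

Detection and analysis of spatiotemporal wave patterns — plane waves,
widespread synchrony, sources, sinks, spirals and saddles — in
population-level neural recordings sampled on a regular 2D lattice
(multi-electrode LFP grids, optical voltage-imaging movies).

## Who this is for

Systems and computational neuroscientists who have a movie-like recording
`z[x, y, t, trial]` and want to know *what is propagating where*: whether
the activity is a coherent travelling wave, a rotating spiral, an
expanding source or contracting sink, how long each pattern lives, how
patterns succeed one another, and which spatiotemporal structures dominate
the recording overall.

## The method

1. **Analytic signal.** The recording is band-pass filtered (8th-order
   Butterworth applied forward and reverse + Hilbert transform, or a
   complex Morlet wavelet) to an analytic signal *A·e^{iθ}*, separating
   oscillation amplitude *A* (group-velocity patterns) from phase *θ*
   (phase-velocity patterns).
2. **Velocity vector fields.** Between consecutive frames, the velocity
   field **w** = (u, v) minimises a variational optical-flow functional

       E[u,v] = Σ ρ(E_d²) + α ρ(E_s²),   E_d = D_x u + D_y v + D_t,
       E_s² = |∇u|² + |∇v|²,   ρ(s) = √(s + β²)

   with smoothness weight α (default 0.1) and Charbonnier constant β
   (default 10; β ≫ 1 reduces to the quadratic Horn–Schunck penalty).
   Phase data use circular derivatives so wraps at ±π are invisible.
3. **Pattern detection.** Critical points (u = v = 0, located by bilinear
   zero-contour intersection at sub-grid resolution) are classified by the
   Jacobian's trace τ and determinant Δ: node (Δ>0, τ²≥4Δ), focus (Δ>0,
   τ²<4Δ), saddle (Δ<0), with the sign of τ giving expansion (source /
   spiral-out) vs contraction (sink / spiral-in).  Each pattern's spatial
   extent is the largest set of concentric rings on which the winding
   number (+1 nodes/foci, −1 saddles) stays consistent.  Global patterns
   use order parameters φ = ‖Σw‖/Σ‖w‖ (plane waves, threshold 0.85) and
   R = |Σe^{iθ}|/N (synchrony, threshold 0.8).
4. **Tracking and dynamics.** Per-frame detections are linked over time
   (gates: displacement ≤ 0.5 grid spaces, gaps ≤ 1 step; filters:
   duration ≥ 5 steps, extent ≥ 2 spaces) and pattern transitions are
   counted against the random-times expectation
   n_exp = n_A · n_B · w / t_trial with paired t-tests (Bonferroni).
5. **Spatiotemporal modes.** Stacked velocity fields are decomposed by
   SVD, either real ([ũ | ṽ]) or complex (ũ + iṽ); the complex variant
   merges modes that differ only by rotation of all vectors, so one mode
   captures a plane wave travelling in any direction.

A synthetic-pattern generator (sources/sinks, spirals, saddles, plane
waves with Gaussian envelopes, drifting centres and white noise) and a
site-wise white-noise surrogate generator make the whole pipeline testable
without any experimental data.

## Worked example

```r
library(neurowaves)

# a slowly drifting expanding source on a 12x12 grid, 10 frames
sp  <- pattern_spec("source_sink", x0 = 5.5, y0 = 5.5, vx = 0.02,
                    sign = 1, A0 = 1.5)
sim <- simulate_patterns(list(sp), n_steps = 10, noise_sigma_rel = 0)

res <- run_pipeline(sim$z, cfg = list(flow = list(alpha = 0.5)))
subset(res$patterns, select = -trajectory)
#>   trial  ptype t_start t_end duration mean_extent
#> 1     1 source       1     9        9           4
head(res$critical_points, 3)
#>   trial t        x   y         cls  motion        tau       delta extent
#> 1     1 1 5.001016 5.5 stable_node outward 0.06688551 0.001117482      4
#> 2     1 2 5.016540 5.5 stable_node outward 0.06644014 0.001102828      4
#> 3     1 3 5.031929 5.5 stable_node outward 0.06599959 0.001088418      4
```

The planted source is recovered as a single tracked `source` instance
spanning all 9 velocity-field steps: an outward node (`tau > 0`,
`delta > 0`) whose fitted centre tracks the planted drift (0.016 grid
spaces per step), with spatial extent 4 grid spaces — the largest ring
radius fitting inside the array.  The constant ~0.5-space offset from the
planted centre is the lab-frame displacement a drifting source's
stagnation point genuinely has: the drift partially cancels the slow
side's outward flow.
`res$order_parameters` holds the per-frame φ and R series,
`res$transitions` the transition counts (multi-trial input), and
`res$svd$real` / `res$svd$complex` the spatiotemporal modes.

A command-line front end is installed at
`system.file("cli", "neurowaves-cli.R", package = "neurowaves")` with
subcommands `run`, `simulate`, `evaluate` and `surrogate`.

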