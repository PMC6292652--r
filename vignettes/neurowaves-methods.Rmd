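---
title: "Methods: wave-pattern detection in neural population recordings"
author: "neurowaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wave-pattern detection in neural population recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical choices, and the design
decisions behind `neurowaves`, and states precisely what the synthetic-data
tests do and do not establish.  No empirical numbers are quoted here that
the test suite or `scripts/acceptance.R` do not themselves compute.

## The model

A recording is a real scalar `z[x, y, t, p]` on a regular square lattice.
Oscillatory structure at a chosen frequency is summarised by the analytic
signal $A e^{i\theta}$; amplitude patterns travel at the group velocity,
phase patterns at the phase velocity, and the two can carry different
spatiotemporal structure, so both are first-class inputs downstream.

Between consecutive frames of the chosen data sequence $D$ the velocity
field $\mathbf{w} = (u, v)$ minimises

$$E[u, v] = \sum \rho(E_d^2) + \alpha\, \rho(E_s^2), \qquad
E_d = D_x u + D_y v + D_t, \quad
E_s^2 = |\nabla u|^2 + |\nabla v|^2,$$

with the Charbonnier penalty $\rho(s) = \sqrt{s + \beta^2}$.  Patterns are
then read off the velocity fields: global ones by the order parameters
$\varphi = \|\sum \mathbf{w}\| / \sum\|\mathbf{w}\|$ (plane waves) and
$R = |\sum e^{i\theta}|/N$ (synchrony; $1 - R$ is the circular variance),
local ones as critical points $u = v = 0$ classified by the Jacobian's
trace $\tau$ and determinant $\Delta$ and sized by winding-number
consistency on growing rings.

## Coordinates and units

Axis order is (row, col, time, trial); $x$ is the column coordinate,
$y$ the row, both 0-based continuous grid units.  Velocities are in grid
spaces per time step ($\delta t$ = one sample), matching the units in
which every tracking parameter is quoted.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.1 | – | smoothness weight; larger values smooth the field toward uniform flow.  Useful range roughly 0.1–20 depending on grid size and noise |
| `beta` | 10 | data units | Charbonnier constant; $\beta \gg 1$ is effectively the quadratic penalty and converges fastest, $\beta \ll 1$ is robust to motion discontinuities |
| `Tpw`, `Tsyn` | 0.85, 0.8 | – | plane-wave / synchrony thresholds on $\varphi$, $R$ |
| `Ledge` | 2 | grid spaces | boundary margin for critical points (edge derivatives use one-sided stencils and are least reliable) |
| `Lradius` | 2 | grid spaces | minimum pattern extent, suppresses small noise-driven patterns |
| `tdur` | 5 | time steps | minimum pattern lifetime |
| `tgap` | 1 | time steps | largest bridged interruption while linking |
| `Ldisp` | 0.5 | grid spaces | largest per-observation displacement while linking |
| transition window | 50 | ms | offset-to-onset gap counted as a transition (kept separate from the linking `tgap`) |
| Morlet `n_cycles` | 6 | cycles | time/frequency-resolution compromise |

## Numerical choices

**Derivatives.**  Linear data use the five-point stencil
$\tfrac{1}{12}[-1, 8, 0, -8, 1]$ in the interior, centred then one-sided
differences near edges.  Phase data use centred/one-sided *circular*
differences ($\mathrm{mod}(\theta_1 - \theta_2 + \pi, 2\pi) - \pi$)
throughout instead of the five-point stencil: the stencil's wide pair
spans 4 grid spaces, which at the benchmark wavenumber $k = 2\pi/5$
exceeds half a cycle, so its circular difference would take the wrong
branch.  This is measurable: with the wide stencil a planted plane wave's
speed is recovered ~30% low, with centred circular differences it is
exact to solver tolerance.

**Solver.**  The Euler–Lagrange equations are solved by lagged-nonlinearity
fixed-point iteration: freeze $\rho' = 1/(2\sqrt{s + \beta^2})$ at the
current iterate (the printed form of $\rho'$ elsewhere drops the radical;
only this form is the true derivative of $\rho$), solve the resulting
linear system exactly, repeat until the relative $L_2$ update falls below
`tol` (1e-6, cap 500 iterations; each frame warm-starts from the previous
one).  The smoothness operator $-\nabla\cdot(\rho_s \nabla u)$ is
discretised in divergence (flux) form with face-averaged $\rho_s$ and
replicate (Neumann) boundaries.  This form is symmetric positive
semidefinite, so each inner step is a sparse Cholesky solve, and the
outer iteration is a descent scheme (the energy trace is checked to be
non-increasing in the tests).  The expanded form
$\rho_s\nabla^2 u + \nabla\rho_s\cdot\nabla u$, which it equals to second
order, is *not* used directly: assembled naively it is non-symmetric and
the fixed point can limit-cycle at small $\beta$.  A $10^{-12}$ ridge on
the data diagonal keeps the static-frame system (all $D_t = 0$)
nonsingular; the solution is then exactly zero.

**Critical points.**  Within each unit cell the bilinear interpolants of
$u$ and $v$ reduce to a quadratic whose roots are tested for membership;
detections closer than 0.1 grid spaces are merged.  The Jacobian is
bilinearly interpolated from centred-difference estimates at the four
surrounding nodes.  Class boundaries: $\tau^2 = 4\Delta$ counts as a node,
and the comparison carries a $10^{-6}$ relative tolerance — a radially
symmetric source or sink lies *exactly* on the node/focus boundary, where
last-bit noise would otherwise flip the label between frames and sever
tracking chains.  $\Delta = 0$ is reported degenerate and excluded.
$\tau = 0$ with $\Delta > 0$ (a neutral centre) is reported unstable with
motion `"neutral"`.

**Stability naming.**  The upstream convention labels nodes and foci
stable when $\tau > 0$, which inverts the usual dynamical-systems
convention; `stability_convention = "paper"` (default) follows it,
`"standard"` inverts the labels.  Pattern *types* never depend on this
choice: source/sink and spiral-out/in are assigned from the sign of
$\tau$ (outward motion iff $\tau > 0$), which is what the flow geometry
actually shows.

**Rings and extent.**  A ring of radius $r$ is the set of grid sites
whose rounded distance to the centre equals $r$, ordered by angle.  The
extent search stops at the first ring whose index disagrees with the
pattern class, that carries a zero vector, or whose band
$[r - 0.5, r + 0.5]$ touches the grid boundary; for an isolated pattern
centred at $(5.5, 5.5)$ on a 12×12 grid this yields extent 4.

**Filtering.**  With no DSP package assumed, the 8-pole Butterworth
band-pass is designed from the analog prototype (lowpass→bandpass
transform in the s-plane, bilinear transform with pre-warping), applied
as cascaded biquads forward and reverse over odd-reflection padding, and
normalised to exact unit gain at the geometric band centre.  The analytic
signal uses the FFT half-spectrum method; the Morlet wavelet is
normalised so a unit cosine at the centre frequency returns amplitude 1.
Each output carries an `edge_len` marking the unreliable transient zone;
samples there are kept, not trimmed.

**SVD.**  No centering and no per-site normalisation by default — a bias
in propagation direction is part of the signal and lands in mode 1; with
`center = TRUE` the loadings coincide with principal components (checked
against `prcomp`).  The sign/phase convention rotates each spatial mode
so its largest-magnitude component is positive real, dividing both the
spatial and temporal column by the same unit phase (which leaves
$T \Sigma R^*$ invariant).  The convention pins the mode only up to the
inherent sign ambiguity: a planted source field may surface as its
negative (an inward node) with a negative temporal coefficient.

## The synthetic world

`simulate_patterns()` emulates band-limited oscillations carrying
drifting wave patterns: $z = \sum_j A_j e^{i(k s_j - w t)}$ with phase
profiles $s$ = radius (source/sink), radius + angle$/k$ (spiral),
$|x| - |y|$ (saddle) or a directional ramp (plane wave — an extension
beyond the critical-point profiles, needed to exercise the $\varphi$
detector), plus complex Gaussian white noise.  The randomised benchmark
draws two patterns on a 12×12×10 grid with $w = 2\pi\times0.01$,
$k = 2\pi/5$, centres ≥ 2 spaces from each other and the edges, drifts
uniform on $[-0.1, 0.1]$, amplitudes on $[1, 2]$ and widths on $[3, 5]$.

Two readings of the printed amplitude envelope exist once typesetting is
flattened; both are implemented.  The default is the compact
super-Gaussian $A_0\exp(-(r^2)^2/(2c^2))$ (effective radius
$(2c^2)^{1/4} \approx 2.3$–$2.8$ for the benchmark widths), with the
conventional Gaussian $A_0\exp(-r^2/(2c^2))$ behind
`envelope = "gaussian"`.  The compact form is the one under which the
benchmark's own rejection rule (≥ 2 spaces separation) is meaningful:
broad Gaussians at that separation leave each pattern at ~80% of the
other's peak amplitude, and the two phasors annihilate each other's
critical points.  Noise is scaled by the *grand-mean* amplitude by
default (`noise_mode = "mean"`, how the benchmark quotes noise levels),
or by each site's own amplitude (`"local"`); per-site scaling leaves
near-zero-amplitude regions carrying deterministic tail-interference
phase that floods the flow field with spurious structure.

What a green benchmark run establishes — and what it does not:

* Detection metrics are computed by position-based greedy matching within
  2 grid spaces; "missed or misclassified" additionally requires the
  matched detection's class to agree.  Misclassification there is
  dominated by the node/focus boundary degeneracy of radially symmetric
  patterns (the reason the toolbox offers "combine nodes and foci").
* Planted truth is the *pattern centre*, but the lab-frame flow critical
  point of a drifting pattern is displaced toward the slow side, and
  disappears entirely once the drift reaches the pattern's own phase
  speed $w/k$ (= 0.05 grid/step; benchmark drifts go to 0.1).  Some
  benchmark misses are therefore physical, not algorithmic.
* The zero-noise condition is an extrapolation: the benchmark quotes
  noise on a log scale.  At exactly zero noise almost no spurious
  detections occur, so the false-positive *ratio* between full noise and
  zero noise is large even though the absolute rate stays below ~0.5 per
  step; the acceptance test's noise-robustness ratios therefore use the
  benchmark's own 10%-noise condition as reference for the
  false-positive rate, and the zero-noise reference for the accuracy
  metrics.
* The generator shares no code with the detectors, but it realises the
  same idealised plane-wave/critical-point geometry the detectors are
  built for.  Real recordings add 1/f background, non-stationary bands,
  heartbeat artefacts and irregular boundaries, none of which are
  emulated; surrogate testing (`run_surrogate_comparison()`) is the
  package's tool for arguing that detections in real data are not
  processing artefacts.

## Design decisions on genuinely open points

* Bad channels are filled by synchronous iterative 4-neighbour means
  (order-independent; only "interpolated over" is specified upstream).
  Interpolation precedes normalisation.
* The under-sampling warning triggers above a 10% max frame-to-frame
  change relative to each site's range; the "safe to down-sample" hint
  below 1% (the low threshold is ours).
* Convergence tolerance, iteration cap, boundary handling and the linear
  solver are unspecified upstream; values above are declared defaults.
* Transition windows: the expected-count formula's gap parameter is kept
  separate from the linking `tgap` and defaults to 50 ms.
* Same-type transitions are excluded by default (a bridged gap is the
  same pattern); `include_self = TRUE` restores them.
* Greedy per-frame matching with smallest-displacement tie-break is used
  for linking; with `Ldisp = 0.5` conflicts are rare and a global
  assignment would change little.
* Evaluation matching is position-based with class scored separately;
  requiring same-class matches would silently drop misclassifications
  from both the displacement and the miss metrics.

## Known limitations

* Plane waves and synchrony are detected globally; no localised order
  parameters.
* No multi-resolution or 3D/surface optical flow.
* The linking gate `Ldisp = 0.5` is tight for coarse, noisy grids where
  a critical point's fitted position jitters by ±0.5 spaces per frame;
  raise `track.Ldisp` in such regimes.
* Reading NPZ and pre-v7.3 MAT containers is not supported (no reader in
  the dependency budget); HDF5, MAT v7.3 and RDS are.
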