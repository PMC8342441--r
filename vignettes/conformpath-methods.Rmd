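---
title: "Methods: modelling receptor activation pathways with conformpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling receptor activation pathways with conformpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Class A G-protein-coupled receptors activate through large intracellular
rearrangements — the outward swing of TM6, the approach of TM5 and TM7 —
that can be summarized by two collective variables: the Cα distance between
generic positions 5.55 and 7.46 (Ballesteros–Weinstein numbering) and the
Cα angle 6.34–6.47–2.41. In this 2-D order-parameter space, the angiotensin
II type 1 receptor's inactive state sits near (21.3 Å, 37°), a metastable
intermediate near (18 Å, 48°), and the fully active state near
(17.4 Å, 69.4°). `conformpath` implements the full analysis chain that
turns sampled conformations in this space into a quantitative activation
model: free-energy landscapes, nudged-elastic-band (NEB) minimum-energy
paths, Markov state models (MSMs) with PCCA+ macrostates and
Chapman–Kolmogorov (CK) validation, transition-path-theory (TPT) kinetics,
tICA slow-mode analysis, and operational-model quantification of biased
signaling from dose-response data.

Because hundreds of microseconds of all-atom trajectories cannot be shipped
or recomputed at desk scale, the package also contains a first-class
synthetic-data module that generates trajectories with the statistical
structure the analysis assumes. Every downstream stage is tested against
that generator and against independent oracles (closed forms, brute-force
enumeration, Monte-Carlo simulation).

# The synthetic world

## Potential surface

`make_three_basin_potential()` builds a smooth surface
$$V(x) = \sum_{b=1}^{3} -A_b\,
  \exp\!\Big(-\tfrac12\sum_k \frac{(x_k-c_{bk})^2}{\sigma_{bk}^2}\Big)
  + \kappa \sum_k \Big(\frac{x_k - m_k}{s_k}\Big)^2$$
with exactly three minima placed exactly on the basin centres
(the Gaussian centres are shifted by a fixed-point iteration to cancel the
confinement tilt). Defaults:

* centres (21.3, 38.0), (18.0, 48.5), (17.4, 69.4) — the inactive,
  intermediate and active regions of the landscape;
* depths (2.60, 1.60, 1.85) kcal/mol and widths (1.0, 3.2), (0.8, 3.0),
  (0.85, 4.2) (Å, degrees). These were chosen, once, so that (i) the
  Boltzmann basin weights at kT = 0.596 kcal/mol are approximately
  0.43 / 0.31 / 0.25, matching the reported proportions of the three
  conformational states; (ii) the inactive–intermediate saddle is low while
  the intermediate–active saddle is the highest point of the path, making
  the intermediate→active step rate-limiting; and (iii) all barriers are
  2.5–4 kT so that a 10^6-step trajectory crosses every barrier on the
  order of a hundred times — the regime where equilibrium populations are
  recoverable at desk scale;
* confinement κ = 0.6 kcal/mol at the domain half-width, domain
  (14–26 Å) × (25–85°).

## Langevin generator

`simulate_langevin()` integrates overdamped (Brownian) dynamics,
$x_{t+1} = x_t - \nabla V\,\Delta t\,D/kT + \sqrt{2D\Delta t}\,\xi$, with
reflecting bounds, at kT = 0.596 kcal/mol (300 K). The diffusion
coefficient is per-axis, default D = (1.5, 8): the angle axis spans roughly
five times the length scale of the distance axis, and an isotropic D makes
angle exploration the bottleneck while the stability limit of the
integrator is set by the much stiffer distance axis. Anisotropic D restores
comparable dynamics per axis; it was capped at 8 (rather than the ~25 that
squared-scale matching would suggest) because beyond that the fastest
distance-axis relaxations mix into the slow spectrum and the
three-metastable-state structure of the transition matrix degrades.
`diffusion = 0` is interpreted as a zero-temperature quench (deterministic
steepest descent) rather than a frozen walker.

The time step dt = 0.02 (dimensionless units) keeps the per-step drift
below a third of the narrowest well width; the Euler–Maruyama
discretization bias at this dt is below the sampling noise of a 10^6-step
run (checked by comparing against dt/2 runs during design).

What the generator does *not* emulate: atomistic degrees of freedom,
non-Markovian memory from projected coordinates, correlated noise, or
force-field inaccuracies. A green synthetic test therefore establishes the
correctness of the estimators — not the realism of any particular
molecular system.

## Equilibrium oracle

`boltzmann_populations()` integrates $e^{-V/kT}$ on a dense grid and
assigns every grid cell to a basin by a discrete steepest-descent watershed
(each cell points to its lowest 8-neighbour; sinks are the minima). It is
the independent reference for MSM population recovery. Note that the
watershed ridge is an equilibrium construction; kinetic partitions (PCCA+)
can legitimately split the low-population transition corridors slightly
differently, which contributes a systematic ~0.02–0.04 to any comparison
between the two. At 10^6 steps the sampling noise contributes another
±0.02–0.05 depending on the realization; the package's acceptance test
uses the canonical seed 1. Some seeds exceed the 0.05 band — this is
sampling-limited, and documented rather than hidden.

# Free-energy landscapes

`estimate_landscape()` histograms two feature columns (default 100×100
bins over (15–25 Å) × (30–80°)) and applies Boltzmann inversion
$F = -kT\ln(p/p_{\max})$, so the most populated bin has F = 0. Empty bins
carry an infinite sentinel, never 0 — a zero would create spurious basins.
No smoothing is applied by default; optional Gaussian bin smoothing sits
behind `smooth_sd`. `landscape_convergence()` splits the data (by time or
by round), re-estimates landscapes on a common grid and reports the RMS
free-energy difference over bins occupied in all splits with F ≤ 5
kcal/mol.

# Nudged elastic band

`init_band()` interpolates replicas linearly between two endpoint
conformations (optionally removing the rigid-body difference by Kabsch
superposition). `neb_forces()` decomposes forces exactly as in the
standard NEB formulation: the potential force acts only perpendicular to
the path, the spring force (default k = 10 during heating, 50 afterwards,
in kcal mol⁻¹ per squared coordinate unit) only parallel, with the upwind
energy-weighted tangent at extrema. Tangents are normalized to unit length
before projection — the projection formulas are only well-scaled for unit
tangents.

`anneal_band()` runs Langevin dynamics on the interior replicas through a
heat / equilibrate / anneal / cool schedule and finishes with a FIRE
(fast inertial relaxation engine) zero-temperature relaxation until
max |F⊥| < 10⁻³. Two numerical choices matter:

* the annealing ladder's top temperature defaults to kT = 0.05 kcal/mol —
  far below the sampling temperature. On a smooth 2-D surface the band
  only needs enough noise to escape kinks, and replica chains tangle
  (adjacent replicas swap order, tangents flip chaotically, the chain
  diverges) once the thermal spread approaches the replica spacing;
* plain fixed-step descent chatters near saddles because the upwind
  tangent switches discretely; FIRE converges in a few thousand steps
  where fixed-step descent stalls at residuals of ~2×10⁻³.

The barrier estimate `band_apex()` refines the apex by a parabola through
the three highest replicas, which removes most of the replica-spacing
discretization error. `select_replicas()` thins a band to the most
mutually distinct structures by greedily dropping the interior replica
with the smallest adjacent-distance sum — endpoints are always retained.

# Markov state models

`cluster_microstates()` is seeded k-means++ with Lloyd iterations capped
at 200 (the reference protocol's maximum iteration count), on per-axis
z-scored features by default: the Å and degree axes differ by an order of
magnitude in spread, and unstandardized Euclidean clustering would
tessellate only the angle axis. On very long trajectories the centres are
fitted on an even subsample (default cap 2×10^5 frames in the pipeline)
and all frames are then assigned to the fitted centres — k-means on 10^6
points is unnecessary for 200 centres.

Transition counting is sliding-window within each trajectory; estimation
restricts to the largest strongly connected component and row-normalizes
(the default nonreversible maximum-likelihood estimator); a
detailed-balance (reversible) estimator is available by flag. PCCA+
follows the inner-simplex algorithm on the m dominant eigenvectors of the
π-symmetrized transition operator; the symmetrization preserves π and the
metastable structure and guarantees a real spectrum even for the
nonreversible estimator. Macrostate probabilities are χᵀπ; an empirical
frame-fraction estimate is available as `empirical_populations()`.

The CK test coarse-grains the discrete trajectories through the crisp
PCCA+ sets and compares `T(τ)^f` with the matrix estimated at lag fτ.
Error bars propagate both the estimation error at lag fτ and the error of
the base matrix raised to the power f, computed from the number of
*non-overlapping* transition windows — sliding-window counts are serially
dependent, and using raw counts would understate the error by a factor of
√lag. Crisp coarse-graining of a diffusive system retains some boundary
memory, so CK agreement is expected within a few percent absolute, not to
arbitrary statistical precision.

Representative conformations use the similarity score
$S_{ij} = e^{-d_{ij}/d_{\text{scale}}}$ with $d_{\text{scale}}$ the
standard deviation of the pairwise distances (each unordered pair counted
once). The score aggregates over the pool by the mean over $j \ne i$ —
the "highest similarity" reading leaves the aggregation open, and the mean
is the natural choice (including $j = i$ adds a constant and cannot change
the winner). Ties resolve to the lowest frame index.

# Transition path theory

`committor()` solves the discrete committor linear system;
`mfpt()` solves $(I - T_{\neg \text{target}})\,t = \tau\,\mathbf 1$ and
averages over the source set weighted by the stationary distribution
restricted to the source (the weighting is a design choice; the linear
solve itself is standard). MFPTs scale linearly in the physical lag.
Committors and MFPTs are validated against brute-force Monte-Carlo chain
simulation in the tests. On the synthetic landscape the six
inter-macrostate MFPTs reproduce the qualitative kinetic pattern of
activation: transitions into the intermediate are fast, the
intermediate→active step is the slowest exit from the intermediate
(the rate-limiting step), asserted as an ordering, never as microsecond
values.

# tICA

`fit_tica()` solves the generalized eigenproblem
$C_\tau v = \lambda (C_0 + \epsilon I)v$ with the symmetrized time-lagged
covariance. The ridge default is $\epsilon = 10^{-6}\,\mathrm{tr}(C_0)/d$,
enough to make duplicated feature columns harmless while leaving
well-conditioned problems untouched. Components are $C_0$-orthonormal;
kinetic-map scaling (multiplying components by eigenvalues) is off by
default. Dihedral features should be sin/cos-expanded
(`backbone_dihedrals()` does this) so that periodicity cannot masquerade
as slow dynamics. The tICA-space MSM reuses the MSM module verbatim.

# Operational-model pharmacology

`operational_forward()` implements both branches of the explicit
(GraphPad-style) operational model:

```
A        = 10^X
operate1 = ((1 + A) / (10^LogR * A))^n                 # reference branch
operate2 = ((1 + A/10^LogKA) / (10^LogR * A))^n        # full branch
Y        = basal + (Emax - basal) / (1 + operate)
```

with `LogR = log10(tau/K_A)` the transduction coefficient. Which curves
use which branch is a per-curve role flag (`reference` for the wild-type
receptor, `test` otherwise) — the printed model's column selector leaves
this to the analyst. Fitting is multi-start nonlinear least squares
(asymptotes from the curve extremes, n = 1, LogKA at the mid
concentration, LogR started on a −2…10 grid), polished by Nelder–Mead,
with standard errors from the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$. Flat curves are flagged
`identifiable = FALSE` — for a curve with no concentration dependence LogR
is unbounded below and any fitted number would be noise. Relative
activity is $\Delta\log(\tau/K_A) =$ mutant − reference per pathway, with
SEMs combined in quadrature, and `bias_heatmap()` arranges the results
with symmetric colour bounds ±max|Δ|.

# Pipeline and determinism

`run_pipeline()` chains simulate → landscape → MSM → TPT → tICA →
representative frames, writing plain CSV/JSON artifacts plus a summary
JSON stamped with a config hash. Every random stage is seeded from the
single config seed; rerunning a config writes byte-identical summaries.
Timescales are reported in nanoseconds under the convention one frame =
1 ns (configurable `frame_ns`), which puts the synthetic MFPTs on a
molecular-feeling scale without claiming physical time.

# Known limitations

* The crystal-structure worked examples (order parameters of the 4YAY and
  6DO1 structures) need the deposited PDB files; they are not
  redistributable here and the build environment is offline, so the
  corresponding acceptance test stays red until a user supplies the files
  under `inst/extdata/pdb/`. The packaged Ballesteros–Weinstein table for
  the human AT1 receptor was curated from generic-numbering anchor
  residues and is gated by exactly those worked examples.
* Population recovery at 10^6 steps is sampling-limited: across seeds the
  maximum absolute error is typically 0.02–0.08 against a 0.05 acceptance
  band (canonical seed 1 passes). Doubling the trajectory length brings
  every seed we examined inside the band, but the stated run length is
  kept.
* The NEB implementation is the standard (non-climbing-image) variant;
  apex energies rely on parabolic interpolation rather than a replica
  converged onto the saddle.
* MSMs here are built on 2-D projected dynamics; lag times must be read
  from the implied-timescale plateau (the pipeline default, 200 frames,
  sits on the plateau of the synthetic system).
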