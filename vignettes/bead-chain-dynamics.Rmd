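---
title: "Bead-chain dynamics in a fluidized bed: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bead-chain dynamics in a fluidized bed: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidchain)
```

## The physical system

`fluidchain` models a macroscale analog of a diffusing polymer: a chain of
centimetre-scale resin beads alternating with small metal crimp beads,
strung on thread between two fixed anchors and buffeted by the grains of an
air-fluidized bed. The crimps are radio-opaque and act as the trackable
tracers; an X-ray projection of the bed yields 2D tracks of the middle
crimps at video rate. The scientific question the toolchain addresses is
how the *shape* of the stochastic forcing — Gaussian, as for molecules in
solution, or exponential (Laplace), as measured for grains in fluidized
beds — propagates into the shape of the tracer velocity distribution,
summarized by the stretched-exponential (exponential-power) exponent
$\beta$ in $P(v) \propto \exp(-\alpha |v|^\beta)$: $\beta = 2$ is Gaussian,
$\beta = 1$ exponential.

## The discrete-element model

A chain of $N$ beads is $2N + 3$ particles: $N$ spheres of radius
$r_b = 3\,$mm (beads) alternating with $N+1$ spheres of radius
$r_t = 0.75\,$mm (crimps), starting and ending with a crimp, plus two
immobile anchors. Four force laws act:

* **Stretch bonds** between adjacent particles,
  $\mathbf{F} = -k_l\,(R - (r_b + r_t))\,\hat{\mathbf{r}}$, with
  equilibrium at contact $r_b + r_t$.
* **Bending bonds** on each consecutive triple, the exact gradient of
  $\tfrac12 k_a (\theta - \pi)^2$: end forces of magnitude
  $k_a\,|\theta - \pi| / \ell_{\text{arm}}$ perpendicular to the arms,
  central particle balancing them so the triple exerts no net force.
  $k_a$ carries units of N/rad.
* **Anchor strings**, one-sided: no force while the anchor distance is
  below the string rest length $\ell_0$, a linear restoring force
  $-k_s(\ell - \ell_0)\hat{\boldsymbol\ell}$ once taut.
* **Viscous damping** $-k_v \mathbf{v}$ on every mobile particle, the
  stand-in for all dissipative couplings to the medium.

The bed itself is not resolved. Grain buffeting enters as a **kick force**
redrawn once per timestep and held constant within it:
$\mathbf{F}_{\text{kick}} = k_r (P_x, P_y, P_z)$ with each $P_i$ an
independent draw from a standard normal (Gaussian model) or a standard
Laplace built from two uniforms, $P = \mp\log U_1$ with the sign decided
by $U_2 \le 1/2$. By default all mobile particles are kicked (both beads
and crimps are immersed in the bed); `targets = "beads_only"` restricts
kicks to the beads. There is no gravity/buoyancy term — the physical chain
is density-balanced to be neutrally buoyant (see below) — and no
excluded-volume force: the four bonded laws plus damping and kicks are the
complete force set.

## Integration and the damping regime

The central mechanism is *overdamped shape propagation*. With the
default masses (particle density $5\times10^{-3}$ kg/m³ over the sphere
volume, i.e. sub-nanogram particles) the velocity relaxation time
$m/k_v$ is five orders of magnitude shorter than the timestep, so each
particle's velocity equilibrates to $\mathbf{F}/k_v$ within a single step
and the per-component velocity distribution mirrors the kick distribution
scaled by $k_r/k_v$. This regime is far outside the stability range of an
explicit damping force, so the default integrator (`split_damping`)
replaces each velocity-Verlet half update with the exact solution of
$m\,\dot{\mathbf{v}} = \mathbf{F} - k_v\mathbf{v}$ over $dt/2$ with the
non-damping force held:
$\mathbf{v} \leftarrow \mathbf{v}\,e^{-\gamma}
 + (\mathbf{F}/k_v)(1 - e^{-\gamma})$, $\gamma = k_v\,dt/2m$.
This scheme is stable for arbitrarily strong damping, has the exact fixed
point $\mathbf{F}/k_v$ under a constant force at any timestep, and reduces
to plain velocity-Verlet as $k_v \to 0$ (the `verlet` mode, with damping
treated semi-explicitly, is provided for the lightly damped regime). The
tests verify energy conservation in the conservative limit (relative
drift $< 10^{-4}$ over $10^4$ steps), the analytic terminal velocity to
$10^{-6}$, and a two-sample Kolmogorov–Smirnov match between overdamped
single-particle velocities and the rescaled kick distribution.

### Why the default damping is 5 N·s/m

The damping coefficient is the one genuinely free parameter: physically it
is calibrated so simulated mean bead speeds match experiment (the
`damping_calibration_sweep()` procedure). Numerically it is bounded below
by stability. In the overdamped regime the position update is an explicit
map with mobility $dt/k_v$, and the stiffest mode of the chain is bending:
linearizing the angle forces about the straight chain gives an effective
transverse stiffness up to $\sim 16\,k_a/\ell_{\text{arm}}^2 \approx
1.1\times10^4$ N/m at the 3.75 mm arm length. Stability of the explicit
map requires $k_v \gtrsim 8 \cdot 16\, k_a\, dt / \ell_{\text{arm}}^2
\approx 0.6$ N·s/m; commonly quoted much smaller damping values (of order
$10^{-4}$ N·s/m) put the map four orders of magnitude outside this bound —
we verified that the chain then diverges to overflow within a few hundred
steps — and would imply a kick velocity scale $k_r/k_v = 100$ m/s, three
orders of magnitude above the few-cm/s tracer speeds actually observed.
The default $k_v = 5$ N·s/m sits comfortably inside the stability bound
(a safety factor of ~8, at which point bond-force contamination of the
velocity distribution is a few percent) while keeping $m/k_v \ll dt$, and
gives mean bead speeds of order 0.5 cm/s. With it, the full 14-bead chain
driven by Laplace kicks yields $\hat\beta \approx 1.06$ and by Gaussian
kicks $\hat\beta \approx 1.98$ (recomputed by `scripts/acceptance.R` and
asserted within 0.15 and 0.2 by the test suite).

### Study conditions

The production run integrates the 14-bead chain ($dt = 10^{-4}$ s,
$k_l = 1$ N/m, $k_a = 10^{-2}$ N/rad, $k_s = 5$ N/m, $k_r = 10^{-2}$ N,
$\ell_0 = 12$ mm, anchors 101 mm apart) for $4\times10^5$ steps,
discarding the first $10^5$ as equilibration and recording every 100th
step: 3,000 frames over a 30 s production window. The analysis pools the
recorded x/y/z velocities of the five crimps nearest the chain midpoint
(crimps 6–10 of 15), far from the constrained ends, giving 45,000
observations per fit. Kicks are drawn from R's seeded RNG in a fixed
order (step, then particle, then component), so runs are bit-reproducible
and the compiled core can be replayed exactly by the R-level
`integrate_step()` reference implementation (a test does exactly this).

```{r, eval = FALSE}
topo <- build_topology(chain_spec(), bead_spec(), force_field())
traj <- run_simulation(topo, forcing_model("laplace"), sim_config(seed = 1))
fit_exponent_beta(
  trajectory_velocity_sample(traj, select_middle_tracers(topo, 5)))
```

Two printed geometry figures deliberately coexist: the physical contact
length of the chain (126 mm via `chain_contact_length()`: 14 beads at
7.5 mm, 15 crimps at 1.4 mm) and the simulated bond-chain span (105 mm =
28 bonds at 3.75 mm), which treats crimps as spheres. The builder reports
both and does not reconcile them; the simulation uses the bond span.

## Fitting the velocity-distribution exponent

`fit_exponent_beta()` fits the exponential-power family
$f(v) = \frac{\beta}{2 a \Gamma(1/\beta)} e^{-(|v-\mu|/a)^\beta}$
by maximum likelihood with the location fixed at the sample median. The
scale has a closed-form conditional MLE,
$\hat a(\beta) = (\tfrac{\beta}{n}\sum |v_i|^\beta)^{1/\beta}$, so the fit
is a one-dimensional profile-likelihood search in $\beta \in [0.05, 20]$;
a fit landing at the search boundary is reported as non-convergence with
diagnostics rather than a value. A seeded percentile bootstrap (200
resamples by default) gives the CI on $\beta$. This is bin-free, unlike
least squares on a semi-log histogram; a Freedman–Diaconis log-histogram
fit (`fit_beta_loghist()`) is provided for visual parity with plotted
distributions but is never used for estimation. Per-sign exponential tail
rates ($\hat\lambda = 1/\overline{v}$ on each sign separately, exact zeros
assigned to neither, minimum 30 observations per sign) mirror the dashed
per-sign exponential fits customary on semi-log velocity plots. Recovery
calibration: across 50 seeded replicates at $n = 10^4$ the fitted
$\hat\beta$ falls within 0.15 of the truth for both Laplace and Gaussian
samples in at least 95% of replicates (asserted in the tests).

## Track analysis and the synthetic generator

Tracked positions (TrackMate-style CSV, calibrated millimetres at 30 fps
by default) are turned into velocities by finite differences:
`method = "central"` uses centred differences on interior frames and
one-sided differences at track ends; any frame missing a neighbour
contributes no sample — a gap never spans a difference. Central
differencing averages two consecutive displacement intervals, which
low-pass filters the velocity sequence: when the underlying velocity
decorrelates within one frame (true of the overdamped simulation, and of
any white displacement sequence) this biases $\hat\beta$ upward, toward
Gaussian. `method = "forward"` uses single-interval differences and is
shape-preserving; the end-to-end shape-recovery tests use it, and
analyses of real tracks where velocities persist across frames may prefer
`"central"` for its noise averaging. The z component simply does not
exist in 2D-projected tracks, mimicking the single-plane X-ray capture.

`generate_synthetic_tracks()` emulates this data path: per-frame,
per-component velocity draws (Laplace or Gaussian at a chosen scale)
integrated at the frame rate, plus additive Gaussian detection noise and
i.i.d. frame dropout emulating motion-blur detection failures. It is
seed-deterministic. What it does *not* emulate — spatially correlated
bubbling, velocity persistence across frames, track identity switches,
the asymmetry between the vertical (airflow) and transverse directions —
bounds what passing tests show about real recordings: they validate the
estimator pipeline, not the detector.

High-velocity single-frame outliers are *not* filtered anywhere by
default; they carry the distribution tails that distinguish $\beta = 1$
from $\beta = 2$.

## Bed design and density balancing

`ergun_minimum_fluidization()` solves the packed-bed pressure-drop
balance at minimum fluidization,
$\frac{150\,\mu U (1-\varepsilon)^2}{\varepsilon^3 (\phi_s d)^2} +
 \frac{1.75\,\rho_f U^2 (1-\varepsilon)}{\varepsilon^3 \phi_s d} =
 (\rho - \rho_f) g (1-\varepsilon)$,
as a closed-form quadratic root, with void fraction
$\varepsilon = 1 - \phi$ taken from the loose packing fraction
$\phi = 0.58$. Fluid properties are not part of the grain data, so the
defaults fix 20 °C air ($\rho_f = 1.2$ kg/m³, $\mu = 1.8\times10^{-5}$
Pa·s) and sphericity 1, all overridable. For the default poppy-seed bed
(1 mm grains, material density 983 kg/m³, bulk density 570 kg/m³) this
gives $U_f = 0.319$ m/s, and the 0.55 m/s operating point has
$U/U_f = 1.72$. Note $U_f$ *increases* with void fraction (the looser the
bed, the smaller the drag per unit velocity; in the viscous limit
$U_f \propto \varepsilon^3/(1-\varepsilon)$) — the property tests pin
this direction, and cross-check the quadratic root against a bisection
solve of the full balance.

Neutral buoyancy of the chain in the bed (effective density around
0.4 g/cm³) is achieved by hollowing the printed beads.
`effective_bead_density()` computes material volume (spherical shell +
protrusion − bore, the bore counted over the material it actually
traverses: both shell walls plus the protrusion) over the spherical
envelope; at the 0.4 mm default wall it gives 0.438 g/cm³.
`wall_thickness_for_target_density()` inverts this by root finding on
the monotone branch (wall thinner than $R - r_{\text{bore}}/\sqrt2$;
beyond that, thicker walls mostly add bore-drilled material and the map
turns over).

## Numerical choices and degenerate inputs

* Coordinates: x is the anchor axis, y vertical (airflow), z
  out-of-detector-plane; SI units internally everywhere, with mm only at
  the track-CSV boundary.
* A bond with coincident centers has no direction: zero force, with a
  warning. A perfectly straight triple needs no torque: zero bending
  force (the $\sin\theta$ guard is $10^{-12}$).
* Anchors are immobile zero-radius particles with infinite mass, exempt
  from forces; anchors farther apart than the chain plus both strings
  can span are permitted but flagged `taut`.
* Non-finite positions abort integration with the step index and force/
  velocity diagnostics rather than propagating NaNs into output.
* Recorded velocities are the integrator's instantaneous velocities;
  experiment-comparable finite-difference velocities are computed
  downstream from positions.
* Serialized trajectories: XYZ and LAMMPS-dump-style text (9 significant
  digits) and an RDS container for lossless full precision.

## Problem sizes in the test suite

The full-chain shape-propagation checks run the complete study
configuration ($4\times10^5$ steps, 31 particles) twice, about 20 s each
on one core. All other tests use reduced chains (1–3 beads), shorter runs
($10^3$–$2\times10^4$ steps), $n = 10^4$ fitting samples, and $10^6$
sampler draws — sizes chosen so each statistical assertion has at least a
3-standard-error margin while the whole suite stays around two minutes.

## Known limitations

* No excluded-volume or grain-contact forces: chain self-crossings are
  not prevented (an effect the physical chain does forbid).
* No walls, gravity, or airflow gradient: the kick field is homogeneous
  and isotropic, so the simulated vertical/transverse asymmetry of real
  beds is absent.
* The damping coefficient is a calibration stand-in for all dissipation;
  persistence-length-based calibration is not implemented (the procedure
  is underdetermined), only the mean-speed sweep.
* The exponential-power fit fixes the location at the median and assumes
  a symmetric family; strongly skewed vertical-velocity samples are
  better summarized by the per-sign exponential rates.
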