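---
title: "The soma–AIS dipole and the extracellular action potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The soma–AIS dipole and the extracellular action potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Action potentials in most vertebrate neurons start in the axon initial
segment (AIS), a short stretch of axon with a very high sodium-channel
density, tens of micrometres away from the soma.  At spike onset the AIS
draws a large axial current out of the soma through the cytoplasmic
resistance of the intervening axon: the AIS acts as an extracellular current
sink, the somatodendritic membrane as the matching source, and the pair
behaves transiently as a current dipole.  This package asks what that dipole
does to the extracellular action potential (EAP): how the far-field
amplitude decays with distance, how the peak axial current scales with the
soma–AIS distance, and how the EAP waveform changes when the AIS moves —
the biophysical basis for reading AIS plasticity out of extracellular
recordings.

`aisfield` implements the complete computational chain: a compartmental
soma–axon cable model with Hodgkin–Huxley-type channels confined to the AIS
(or, for contrast, to the soma), a line-source-approximation (LSA) forward
model for the extracellular potential, waveform and decay metrics, and the
scan experiments built from them.

## The model

### Geometry

The reduced neuron is a chain of cylinders: a soma 20 μm in diameter and
30 μm long (6 segments) centred at the origin, and an axon 1 μm × 50 μm
(10 segments) extending along the −x axis, with a 5-μm AIS placed with its
proximal edge a distance `ais_start` from the soma.  The axon is
re-segmented so the AIS edges always coincide with segment nodes, and is
extended distally if the AIS would not otherwise fit.  An optional passive
dendrite (2 μm × 400 μm, 8 segments) extends along +x; the whole cell is a
single unbranched chain, so the cable system is tridiagonal.  Membrane area
is the lateral cylinder area (the soma's is π · 20 · 30 ≈ 1885 μm²).

### Membrane and channels

The cable equation

$$C_m A_i \frac{dV_i}{dt} = -I_{ion,i} A_i + \sum_{j}
\frac{V_j - V_i}{R_{ij}} + I_{inj,i}$$

is integrated with Crank–Nicolson on the tridiagonal system
(unconditionally stable) and staggered exponential-Euler gating updates,
with `dt` = 0.005 ms by default (`dt` > 0.025 ms is rejected).  Axial
coupling resistances $R_{ij}$ are the two half-segment cytoplasmic
resistances in series, from the axial resistivity `Ra`.

Ionic currents are Hodgkin–Huxley $\bar g_{Na} m^3 h (V - E_{Na}) +
\bar g_K n^4 (V - E_K) + g_L (V - E_L)$.  The rate functions live in a
single declarative table (`default_kinetics()`); alternative
parameterisations can be loaded from YAML with `read_kinetics()` and
dropped into any simulation.  In the `ais_initiation` configuration all Na
and K channels sit on the AIS segments only; `somatic_initiation` puts them
on the soma instead, the reduced analogue of lowering the AIS sodium
density below the somatic density so the spike starts in the soma.

### Parameter choices and why

Several quantities had to be fixed by the package itself; they are all
config-overridable, and the reasoning is as follows.

* **Passive parameters**: `Ra` = 150 Ω·cm, `Cm` = 1 μF/cm², uniform leak
  0.3 pS/μm² with `E_leak` = −70 mV — textbook cortical values.
* **AIS conductances**: `gNa_bar` = 256 000 pS/μm², `gK_bar` =
  48 000 pS/μm² on the 5-μm AIS.  These are *effective* densities: a real
  AIS is 30–50 μm long at roughly 3 000–8 000 pS/μm², i.e. a few
  microsiemens of total sodium conductance.  Compressing that total into
  the model's short AIS segment (≈ 4 μS Na, 0.75 μS K) is what places spike
  initiation in the critical-resistive-coupling regime, where the AIS
  behaves as a voltage source relative to the axial resistance.  With a
  literature *density* on only 5 μm of axon (≈ 0.13 μS total) the AIS
  cannot dominate the somatic load: spikes are weak or absent and none of
  the dipole phenomenology emerges.
* **Kinetics**: the classical squid rate table shifted so rest sits at
  −70 mV, with per-gate rate factors m × 36, h × 1.2, n × 8.  Activation is
  thereby effectively instantaneous on the time scale of the cable (as in
  body-temperature AIS channels and in simplified spike-initiation models
  that treat $m$ as $m_\infty(V)$), inactivation is slow enough to survive
  the approach to threshold and sustain the AIS spike while it charges the
  soma, and the delayed rectifier is fast enough to repolarise within a
  millisecond.  The inverse-distance law for the axial current is a
  structural consequence of resistive coupling, but *observing* it requires
  the upstroke to be fast compared with the soma's charging time — with
  slower activation the soma depolarises during the upstroke and the
  apparent scaling exponent flattens from −1 towards −0.8.
* **Stimulus**: a somatic step of 1.3 nA for 1 ms (onset 5 ms,
  `t_stop` = 20 ms).  The step is strong enough that the somatic membrane
  crosses 0 mV at every AIS position in the 0–45 μm scan (one
  unambiguous AP per run) and short enough that the stimulus plateau does
  not masquerade as the somatic spike peak.
* **Somatic-initiation contrast**: the somatic configuration uses somatic
  channel densities (2 000 pS/μm² Na, 1 000 pS/μm² K) — placing AIS-grade
  densities on the large soma would give an unphysiological resting
  potassium shunt of nearly a microsiemens.

## The extracellular forward model

The medium is infinite, homogeneous, isotropic and purely resistive
(quasi-static), with conductivity σ = 0.3 S/m.  Each segment is a line
source carrying its net transmembrane current uniformly; the potential is
the analytic line integral

$$V = \frac{I}{4 \pi \sigma L} \int_0^L \frac{ds}{\lVert x_e - p(s)\rVert},$$

evaluated with the standard asinh/logarithm closed form
(`line_source_potential()`), which the test suite verifies against adaptive
numerical quadrature to better than 10⁻⁶ relative error.  An electrode on a
source segment's axis is a genuine singularity and raises an error — no
silent clamping, because a clamped electrode corrupts decay-exponent fits.
Far-field references are the point source $I/(4\pi\sigma r)$ and the dipole
$I d \cos\theta / (4\pi\sigma r^2)$, the latter valid only for $r \gg d$.

The per-segment source current is the net axial inflow
$\sum_j (V_j - V_i)/R_{ij}$, i.e. capacitive + ionic membrane current with
the injected current assigned as an extracellular sink to its target
segment.  This makes the source configuration exactly monopole-free at
every instant (the currents sum to zero at machine precision), so the
far-field decays as a dipole ($r^{-2}$), never as a monopole ($r^{-1}$).

Baseline removal follows the recording convention: per electrode, the mean
potential in the window 2 to 1 ms before the somatic AP peak is subtracted.

## Metrics

* `peak_to_peak()` — max minus min over the analysis window.
* `width_at_half_amplitude()` — the dominant extremum (largest absolute
  value) sets the reference; the threshold lies half of the peak-to-peak
  amplitude from it towards baseline; the width is the time between the two
  threshold crossings bracketing the extremum, linearly interpolated.  This
  reproduces the conventional spike half-width and is exactly covariant
  under time rescaling.  If the threshold is never crossed on one side, an
  error is raised rather than a truncated width returned.
* `detect_initial_positivity()` — true when a positive local maximum
  exceeding 5 % (configurable) of the peak-to-peak amplitude precedes the
  global trough.
* `fit_power_law()` — unweighted OLS of log₁₀ amplitude on log₁₀ distance,
  restricted to a fit range of 200–1000 μm by default.  The soma–AIS
  separation is at most ~75 μm, so 200 μm onward is far field; the fit
  range is stored in the result so alternative choices are auditable.
* `phase_plot()` / `onset_rapidity()` — the (V, dV/dt) trajectory and the
  slope of its rising limb at onset, the standard quantification of the
  somatic "kink" left by axonal initiation.

## Experiments and the study conditions

All experiments read one declarative configuration (`default_config()`,
YAML-mergeable via `load_config()`, unknown keys rejected); each writes a
results table and a named list of pass/fail checks, and is exactly
reproducible from its manifest.

* **Axial-current scan** (`exp_axial_current_scan`): AIS proximal-edge
  distances l ∈ {5, …, 45} μm; one AP per distance; the maximum over time
  of the axial current crossing the soma–axon junction; OLS slope of
  log I against log l, plus a fixed-slope fit I = c / l.  Under the default
  conditions the slope is −0.94 and c ≈ 47 nA·μm.
* **Decay exponents** (`exp_exponent_fit`): AIS at {0, 20, 45} μm; 20
  log-spaced electrodes on the horizontal line (soma–AIS axis extended
  away from the axon, 65–1000 μm from the soma centre) and on the vertical
  line through the soma centre (50–1000 μm); peak-to-peak amplitudes;
  power-law fits over 200–1000 μm.  Horizontal exponents sit within 0.15
  of −2 for every AIS position; vertical exponents are steeper (≈ −3.0
  here): along the perpendicular the angular factor of the dipole field
  adds to the radial decay.
* **Width scan** (`exp_width_scan`): l ∈ {0, 5, …, 45} μm; EAP width at
  half peak-to-peak amplitude at 30 and 100 μm perpendicular above the
  soma centre and at 30 and 100 μm along the axis opposite the axon;
  intracellular somatic half-width alongside.
* **Dipole maps** (`exp_dipole_maps`): both channel configurations with
  the passive dendrite, planar potential maps at −0.15 ms, the AIS spike
  peak, and +0.4 ms, with sink/source classification of the AIS, soma and
  dendrite regions.  The map runs use a proximal AIS (10 μm) — mirroring
  real morphologies, where the AIS begins at the axon hillock — and a 5-nA
  step to charge the dendrite-bearing cell; the initial-positivity and
  axial-current contrasts are evaluated on the dendrite-less model with
  the default stimulus, where the waveform is not dominated by the
  stimulus artefact.

## Numerical choices

Initial conditions come from a damped fixed-point solve of the steady-state
cable system with gating at steady state, so traces are flat until the
stimulus.  Halving `dt` moves the somatic AP peak by well under one sample
and its amplitude by < 0.1 mV.  Current conservation (the monopole-free
property) holds to better than 10⁻⁴ of the largest membrane current.  The
linoid rate function is evaluated through its removable singularity by a
series expansion.  All experiments are deterministic; the only randomness
in the package is the optional noise of the synthetic fixtures, which
requires an explicit seed.

## What the synthetic fixtures emulate

`make_dipole_currents()` (an ideal two-pole source with zero net current),
`make_biphasic_waveform()` (a difference-of-Gaussians trough-then-peak EAP
with closed-form peak-to-peak amplitude and half-width, and an optional
leading positivity), and `make_powerlaw_profile()` (log-spaced distances
with a planted decay exponent and seeded lognormal noise) give every metric
a ground truth that does not depend on the simulator.  They emulate
amplitudes, widths and decay laws — not the statistics of real recordings
(electrode noise, drift, spike overlap) — so passing fixture tests
validates the measurement chain, not the realism of in vivo data.

A note on the ideal-dipole calibration: along any ray through the dipole
centre the far field decays exactly as $r^{-2}$, and the pipeline recovers
k = −2 within 0.02 on such rays.  On a line perpendicular to the dipole
axis the ideal dipole has strictly zero potential (bisector) or an extra
$\cos\theta \propto 1/r$ factor (offset line, k → −3); the perpendicular
profile of the *simulated* neuron decays with k ≈ −3 for the same reason.
The calibration therefore uses rays through the centre.

## Known limitations

* The somatic spike of the axonal-initiation model is passively driven (no
  somatic sodium), as in the reduced model it emulates.  Its shape
  therefore broadens with the soma–AIS distance more than a full model
  with somatic channels would: the intracellular half-width changes by
  roughly 50 % across the 0–45 μm scan, and the extracellular width at the
  far perpendicular site shrinks again at the two most distal AIS
  positions, where the AIS sits flush against the sealed axon end and the
  sharp initiation transient inflates the half-amplitude threshold.  The
  corresponding monotonicity checks in the width experiment are reported
  honestly as failures; the axial sites and the proximal 0–35 μm range
  show the expected monotone broadening.
* With effectively instantaneous activation, both initiation modes produce
  sharp somatic onsets, so the phase-plot contrast between one and two
  dV/dt maxima is not resolved by this parameterisation; `onset_rapidity()`
  is validated on synthetic kinked vs smooth upstrokes instead.
* The detailed reconstructed-morphology phenomenology (realistic amplitude
  maps, dendritic return structure) is out of scope; the dendrite here is
  a single passive cylinder.
* Problem sizes: the default experiments integrate 16–30 compartments for
  20 ms at 5 μs steps — a few seconds per scan on one core — which is the
  scale at which all reported numbers in the README are computed.
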