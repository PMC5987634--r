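# aisfield

Action potentials usually start not in the cell body but in the axon
initial segment (AIS), a short, sodium-channel-dense stretch of axon a few
tens of micrometres from the soma. At spike onset the AIS draws a strong
axial current out of the soma, so the pair transiently forms a current
dipole whose signature is visible in extracellular recordings. `aisfield`
is an R package for studying that signature: it simulates a reduced
soma–axon neuron with Hodgkin–Huxley-type channels confined to the AIS,
maps its transmembrane currents to extracellular potentials with the
line-source approximation (LSA), and measures the resulting extracellular
action potential (EAP). It is aimed at computational neurophysiologists
interested in what EAP waveforms say about the spike initiation site — for
example, whether AIS plasticity (the activity-dependent relocation of the
AIS) could be monitored with extracellular electrodes.

## The model in brief

A chain of cylinders (soma 20 × 30 μm in 6 segments; axon 1 × 50 μm in 10
segments; optional passive dendrite) is integrated with Crank–Nicolson:

    Cm·Ai·dVi/dt = −Iion,i·Ai + Σj (Vj − Vi)/Rij + Iinj,i

with Na/K channels only on a 5-μm AIS placed 0–45 μm from the soma. Each
segment is a line source in an infinite resistive medium (σ = 0.3 S/m):

    V(x_e) = I/(4πσL) ∫ ds / |x_e − p(s)|

and the far field of the soma–AIS pair follows the dipole law
`V = I·d·cosθ/(4πσr²)`. Three quantitative laws emerge and are verified by
the test suite:

* the far-field EAP peak-to-peak amplitude decays as `r^k` with `k ≈ −2`
  along the soma–AIS axis, for every AIS position;
* decay perpendicular to the axis is steeper (`k ≤ −2`);
* the peak axial current between soma and AIS scales as `1/l` with the
  soma–AIS distance `l` (log–log slope ≈ −1), so the dipole moment `I·d` —
  and hence the far-field amplitude — is nearly independent of `l`, while
  the EAP *width* grows with `l`.

## Worked example

```r
library(aisfield)

# one action potential with the AIS 45 um from the soma
model <- build_soma_axon(ais_start = 45, ais_length = 5)
sim <- simulate_neuron(model$morphology, model$layout)
ap <- detect_ap(sim)

# extracellular waveform 30 um above the soma, baseline-subtracted
rec <- subtract_baseline(
  field_from_simulation(sim, electrode_points(x = 0, y = 30)), ap$time)
peak_to_peak(rec$V_ext[, 1])
#> [1] 9.177949
width_at_half_amplitude(rec$V_ext[, 1], rec$time)
#> [1] 0.5091965
detect_initial_positivity(rec$V_ext[, 1], rec$time)$detected
#> [1] TRUE

# far-field decay along the soma-AIS axis
r <- log_spaced(65, 1000, 20)
vpp <- apply(subtract_baseline(
  field_from_simulation(sim, electrode_points(x = r)), ap$time)$V_ext,
  2, peak_to_peak)
fit_power_law(r, vpp, fit_range = c(200, 1000))
#> power-law fit: k = -1.8584 (se 0.0083), 12 points in [200, 1000] um
```

The EAP above the soma is about 10 μV peak-to-peak, half a millisecond
wide, and carries the initial positive deflection characteristic of axonal
initiation (the somatic return current of the AIS sink); its far-field
amplitude decays almost exactly with the inverse square of distance, the
fingerprint of the soma–AIS dipole.

The full analyses live in `analysis/` as numbered drivers
(`01_axial_current_scan.R`, `02_exponent_fits.R`, `03_width_scan.R`,
`04_dipole_maps.R`); each writes its tables and a run manifest under
`results/` and prints what it found, e.g.

```sh
Rscript analysis/01_axial_current_scan.R
#> log-log slope of max axial current vs distance: -0.943 (se 0.021)
#> fixed-slope fit I_axial = c / l with c = 47.0 nA um
```

The methods vignette (`vignettes/soma-ais-dipole.Rmd`) documents the model
assumptions, parameter choices, numerical details and known limitations.

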