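# hyphadialog

Stochastic two-cell dialogue model and oscillation-trace analysis for
fungal hyphae.

Fungal hyphae fuse into networks, and before fusing, two approaching
hyphae coordinate a chemical "cell-to-cell dialogue": both cells recruit
their signaling machinery to the tip in pulses (periods of roughly
100–140 s) that run in **anti-phase** between the partners, interpreted
as taking turns sending and receiving a shared chemoattractant. The same
pulsing occurs in single hyphae with no partner nearby (the "cell
monologue"). This package implements a minimal mechanistic model of that
behavior together with the trace analysis used to quantify it.

## The model

Each cell carries an excitable activator–inhibitor circuit coupled to a
vesicle cycle and to the extracellular signal concentration at its tip
(state per cell: activator *A*, inhibitor *I*, free vesicles *X*, docked
vesicles *Y*, tip concentration *Z*). The ten-variable system evolves as

  dU = τ F(U) dt + τ Ω⁻¹ G(U) dW,

integrated by the Euler–Maruyama method (dt = 0.001, burn-in 200 time
units; one time unit = one minute). Docked-vesicle release is suppressed
while the activator is high — the refractory period that prevents a cell
from stimulating itself. The two tips exchange extracellular signal at
rate k_z·e^(−d), where *d* is the inter-cell distance: the single
coupling knob. The noise-free circuit is excitable with a stable fixed
point; the pulses are noise-driven (Ω = 1000), which is why all
oscillation claims are statistical across seeds.

The package provides:

* `simulate_dialog()` — seedable Euler–Maruyama integration (Rcpp core)
  with constant, ramped, or piecewise distance schedules;
* scenario drivers `run_single_cell()`, `run_fixed_distance()`,
  `run_distance_sweep()`, `run_approach_ramp()`, `run_media_depletion()`;
* trace analysis: `detect_peaks()` (topographic prominence),
  `interval_statistics()`, `relative_frequency_histogram()`,
  `pearson_correlation()`, `windowed_correlation()`, `phase_relation()`,
  `hilbert_phase_lag()`, `slowdown_statistic()`, `detect_episodes()`;
* a synthetic fluorescence-trace generator (`generate_pulse_trace()`,
  `generate_pair()`, `generate_entrainment_sequence()`) with ground-truth
  pulse times for recovery testing;
* Stokes–Einstein particle-size bounds (`prefactor()`,
  `radius_upper_bound()`, `traversal_time()`, `stokes_einstein_D()`);
* CSV/YAML/JSON input–output with full run provenance (`load_config()`,
  `write_trajectory_csv()`, `read_trace_csv()`).

## Worked example

```r
library(hyphadialog)

params <- default_parameters()      # the reference constants, d = 10

# Two cells in contact lock into anti-phase
dialogue <- run_fixed_distance(0, params, simulation_settings(seed = 2))
dialogue$phase
#> Phase relation: anti-phase (lag 0.501 of period, r = -0.929)

# A synthetic reporter trace with known period statistics is recovered
# by the analysis stage
g <- generate_pulse_trace(pulse_train_spec(period_mean = 104,
                                           period_sd = 28,
                                           n_pulses = 500, seed = 7,
                                           noise_sd = 5))
interval_statistics(detect_peaks(g$trace))
#> Interval statistics: mean 105.5 +/- 27.71 (SD), n = 498

# How large can the exchanged signaling particle be?
prefactor()      # kB*T/(pi*eta) at 298.15 K in water
#> [1] 1.472239e-18
```

The phase relation says the two activators are anti-correlated
(r = −0.93) with the partner's pulses falling halfway through each cycle
(lag 0.5) — the dialogue. The recovered interval statistics match the
generating 104 ± 28 s to within sampling error. The diffusion prefactor
(≈1.5×10⁻¹⁸ m² s⁻¹) feeds the upper bound on the radius of a particle
that can shuttle between two tips quickly enough to carry the dialogue;
see the vignette for a documented inconsistency between this formula and
the nanometer bound usually quoted with it.

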