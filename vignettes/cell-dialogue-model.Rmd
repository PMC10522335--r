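---
title: "The two-cell dialogue model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-cell dialogue model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyphadialog)
```

## The biological problem

Filamentous fungi fuse their hyphae into networks. Before two hyphae can
fuse they must find each other chemotropically, which poses a
self-signaling problem: both cells attract each other with what is
believed to be the same chemoattractant, so a cell must avoid stimulating
itself with its own secretions. The observed solution is oscillatory,
turn-taking signaling — the "cell-to-cell dialogue": reporters of the
signaling machinery (a fusion-scaffold protein at the plasma membrane, a
MAP kinase in nuclei, secretion cargo, actin, cytosolic calcium) pulse at
hyphal tips with periods of roughly 100–140 s, in anti-phase between two
interacting hyphae. The same pulsing is seen in single hyphae with no
partner in reach (a "monologue"), and two approaching hyphae transition
from uncoordinated monologues into the phase-locked dialogue.

`hyphadialog` implements a minimal stochastic model of this behavior,
scenario drivers that reproduce the canonical in-silico experiments, a
trace-analysis toolkit matching how oscillation periods are measured from
time-lapse microscopy, a synthetic-trace generator so that every analysis
step is testable without imaging data, and a Brownian-diffusion estimate
of how large the exchanged signaling particle can be.

## The model

Each of the two cells $c \in \{1, 2\}$ carries five variables: activator
$A_c$, inhibitor $I_c$, free vesicles $X_c$, docked vesicles $Y_c$, and
the extracellular signaling concentration at its tip, $Z_c$. The state
$U = (A_1, I_1, X_1, Y_1, Z_1, A_2, I_2, X_2, Y_2, Z_2)$ evolves as a
stochastic differential equation

$$\dot U = \tau F(U) + \tau\,\Omega^{-1} G(U)\,\xi,$$

integrated with the Euler–Maruyama method at $dt = 0.001$. The drift for
cell $c$ (partner $o$) is

$$
\begin{aligned}
\dot A_c &= a_0 - \alpha A_c + \beta A_c^2 - A_c^3 - A_c I_c + A_c Z_c\\
\dot I_c &= \varepsilon\left(i_0 + \frac{\gamma A_c^2}{A_c^2 + k} - I_c\right)\\
\dot X_c &= x_0 - k_1 A_c^2 X_c\\
\dot Y_c &= k_1 A_c^2 X_c - \frac{k_2 Y_c}{A_c^3 + 1}\\
\dot Z_c &= -k_{cext}(Z_c - C_{media}) + \frac{k_2 Y_c}{A_c^3 + 1}
            - A_c Z_c + k_z e^{-d} Z_o - k_z e^{-d} Z_c
\end{aligned}
$$

The activator is an excitable cubic circuit triggered by uptake of
extracellular signal ($+A_c Z_c$, mirrored by $-A_c Z_c$ in the $Z$
equation) and curbed by the delayed inhibitor. The activator drives
vesicle docking ($X \to Y$); release of docked vesicles back into the
extracellular pool is suppressed while the activator is high (the
$1/(A^3+1)$ factor), which creates the refractory period that prevents
self-stimulation. The two tips exchange extracellular signal at rate
$k_z e^{-d}$, where $d$ is the dimensionless inter-cell distance — the
single knob that couples the cells. The coupling terms in $\dot Z_1$ and
$\dot Z_2$ are equal and opposite, so tip-to-tip flux conserves material.

The reference parameter set is $\tau = 8.48$, $\varepsilon = 0.55$,
$\alpha = 12.4$, $\beta = 8.05$, $\gamma = 8$, $k = 6$, $a_0 = 5.6$,
$i_0 = 0.1$, $x_0 = 1.0$, $k_1 = 0.1$, $k_2 = 1.0$, $k_z = 10.0$,
$k_{cext} = 5$, $C_{media} = 1$, $\Omega = 1000$, with $d = 10$ the
canonical "long" and $d = 0$ the canonical "short" distance
(`default_parameters()`). One model time unit corresponds to one minute.
All runs start from the canonical state $A = 0.7065$, $I = 0.7145$,
$X = Y = 0$, $Z = 1$ in both cells and discard a burn-in of 200 time
units.

## Noise: interpretation and aggregation

The noise function $G$ lists, per variable, one channel per kinetic term
(6 for $A$, 3 for $I$, 2 for $X$, 2 for $Y$, 6 for $Z$; 19 per cell,
each with its own Wiener process — including separate channels for the
release term that appears in both the $Y$ and $Z$ rows). Two readings of
the noise scale are plausible, and the package implements both:

* **`"as-printed"`** (default): each channel contributes
  $g_j\,dW_j$, with overall amplitude $\tau\,\Omega^{-1}$. This is the
  literal reading of the prefactor as the fraction $1/\Omega$.
* **`"chemical-langevin"`**: each channel contributes
  $\sqrt{g_j}\,dW_j$ with amplitude $\tau\,\Omega^{-1/2}$, the standard
  chemical-Langevin convention in which $\Omega$ is a system size and
  fluctuations scale as $\Omega^{-1/2}$.

The superficially attractive third combination — raw propensities
$g_j\,dW_j$ at amplitude $\tau\,\Omega^{-1/2}$ — is numerically unstable
at the reference parameters: the per-variable noise SD near the excited
state (about $40/\sqrt{\mathrm{tu}}$ on $A$, against state magnitudes of
order 4) drives the Euler scheme to non-finite values within the
burn-in. The two supported modes are both stable; the default reproduces
all of the qualitative two-cell phenomenology below with wide margins,
while the chemical-Langevin mode oscillates faster and anti-correlates
more weakly at contact. The `simulate_dialog()` property tests pin the
$\Omega$-scaling of each mode (quadrupling $\Omega$ quarters the
quiescent fluctuation SD in as-printed mode and halves it in
chemical-Langevin mode).

Independent Gaussian increments add in variance, so the integrator draws
one aggregated normal per variable per step
(SD $\sqrt{\sum_j g_j^2}$ or $\sqrt{\sum_j g_j}$ by mode) in a fixed
variable order, which keeps trajectories reproducible from the R seed.
`per_channel = TRUE` draws all 38 increments individually for audit runs;
the two paths are distributionally identical. After every step all
variables are clamped at zero (concentrations are physical; the clamp
also prevents the $-A^3$ term from stabilizing spurious negative
excursions). The clamp is configurable off.

## Excitability, not a deterministic limit cycle

A point worth stating explicitly, because it shapes what the package
asserts in its tests: at the reference parameters the noise-free model
does **not** possess a limit cycle. The single-cell system has a unique
stable fixed point (numerically $A \approx 3.955$, $I \approx 5.882$,
$X \approx 0.639$, $Y \approx 62.85$, $Z \approx 0.670$); its Jacobian
eigenvalues all have negative real parts, with a damped oscillatory pair.
Deterministic runs — from the canonical initial state, from mid-pulse
states, and for the coupled pair at any distance probed — converge to a
fixed point, as confirmed by an independent fine-step Runge–Kutta
integration (`deSolve`). The circuit is *excitable*: at $\Omega = 1000$
the noise recurrently kicks it over threshold, producing the
large-amplitude relaxation pulses (amplitude $\approx 5$ on $A$, one
pulse per 1–3 minutes at long distance) that constitute the monologue.
All oscillation-dependent checks in this package are therefore run at the
model's stated noise level, never in the deterministic limit; the
deterministic mode serves for numerical hygiene (step-halving
convergence, oracle comparisons, reproducibility).

## Scenarios and their design choices

* **Monologue** (`run_single_cell()`): coupling forced to zero. All five
  variables pulse; the activator shows $\ge 5$ peaks per 60 time units
  across seeds (typical rate 6–9).
* **Dialogue at fixed distance** (`run_fixed_distance()`): at $d = 0$ the
  activators anti-correlate strongly (Pearson $r \approx -0.93$, negative
  in 10/10 seeds); at $d = 10$ the cells are effectively uncoupled
  ($k_z e^{-10} \approx 4.5\times10^{-4}$, $|r| < 0.1$). Correlations are
  computed on the activators.
* **Distance sweep** (`run_distance_sweep()`): over $d \in \{0,\dots,10\}$
  with 10 seeds per point the mean correlation is minimized at $d = 0$
  and rises monotonically (rank correlation with $d$ near 1).
* **Approach ramp** (`run_approach_ramp()`): the default protocol holds
  $d = 10$ for 20 time units, ramps linearly to 0 over the next 30, and
  holds at contact (`default_ramp()`); the burn-in runs at the schedule's
  starting distance and the ramp clock starts when the burn-in ends. The
  sliding-window activator correlation (window 10 tu) moves from about 0
  to below $-0.3$ in $\ge 9/10$ seeds.
* **Media depletion** (`run_media_depletion()`): single-cell runs at each
  $C_{media}$. With $C_{media} = 0$ the pulses disappear entirely; the
  trace only shows small stochastic ripples around the quiescent state
  (range $\approx 0.1$ versus pulse amplitude $\approx 5$). Peak
  detection therefore references its prominence threshold to 20% of the
  largest activator range across the compared conditions, so ripples in
  a silenced condition are not counted as oscillation. Control runs
  ($C_{media} = 1$) yield 10–14 peaks per 100 time units; depleted runs
  yield 0.

### Phase-lag estimation on relaxation waveforms

`phase_relation()` implements two lag estimators. The default follows
the classical recipe — dominant period from the mean inter-peak interval,
lag from the argmax of the circular cross-correlation within one period —
and is exact on regular waveforms (sines, jittered pulse trains). The
model's locked dialogue, however, is *event-wise* alternation: plateau
dwell times wander (the alternation is irregular in period while strict
in turn-taking), which decorrelates half-period time shifts and makes the
cross-correlation argmax unstable. The `"hilbert"` method instead takes
the circular mean of the instantaneous analytic-signal phase difference,
which is invariant to dwell-time irregularity; on the $d = 0$ dialogue it
gives a lag fraction of 0.50 with spread below 0.01 across seeds. The
scenario drivers use the Hilbert estimator; both agree on regular traces.

A similar consideration motivates `detect_episodes()`: local-maximum
counting over-counts noise riding on the excited plateau, so episode
rhythms are measured by hysteresis (Schmitt-trigger) onsets on the
quantile-normalized trace.

### Transition slowing: a limitation

Two approaching hyphae are reported to slow their oscillations
transiently while locking into the dialogue ("critical slowing down"),
and `slowdown_statistic()` implements the corresponding measure: the
pooled mean inter-peak interval in a transition window divided by the
mean of the flanking windows. On synthetic entrainment sequences built
with a slowed middle segment the statistic recovers the construction
(ratio $\approx 1.5$ for a 1.5-fold slowdown). Under the simulated ramp,
however, the signature is *not* robust: stationary runs show inter-peak
intervals that shorten monotonically with coupling (activator-peak
interval $\approx 3.2$ tu at $d = 10$ down to $\approx 1.2$ tu at
$d = 0$, with the episode interval minimized at intermediate $d \approx
2$), so there is no interval maximum between the regimes, and the
transition window exceeds both flanks in only a minority of seeds
(1–4 of 10 depending on the estimator). The package reports the
statistic honestly rather than forcing the signature; the corresponding
acceptance check is expected to fail and documents this model-level
disagreement.

## The synthetic-trace generator

`generate_pulse_trace()` emulates what the microscopy pipeline hands to
the analysis stage: a baseline with optional linear drift
(photobleaching), Gaussian-shaped pulses of width 10 s (SD) whose
inter-pulse intervals are drawn from a normal distribution truncated
below at twice the pulse width (so pulses cannot merge), additive white
measurement noise, and a 5-s sampling cadence. Defaults use a period of
104 ± 28 s, the dialogue-phase scale of the measured reporters; the
single-hypha reporters span 103–137 s means with SDs 17–37 s and are
available by overriding the spec. The generator returns its ground-truth
pulse centers, enabling recovery tests: at 500 pulses the detected
interval statistics land within ±3 s of the generating mean and SD, and
detection recovers $\ge 99\%$ of pulses at 10% noise.

`generate_pair()` builds anti-phasic pairs (shared interval realization,
train 2 bisecting train 1) and uncoordinated pairs (independent
realizations); `generate_entrainment_sequence()` concatenates
independent, slowed, and anti-phasic segments with recorded change
points. Deliberately not modeled: imaging physics (point-spread function,
shot noise, region-of-interest geometry), exponential bleaching, and any
multiplicative (coefficient-of-variation-preserving) interval
variability — the available summaries do not constrain these. Passing
recovery tests on this generator therefore demonstrates correctness of
the analysis algorithms, not robustness to every artifact of real
imaging data.

## Numerical choices

* $dt = 0.001$, burn-in 200 tu, recording every 0.1 tu (about 17 samples
  per typical cycle). Step-halving on the deterministic transient gives a
  maximum state discrepancy of $\approx 0.03$ (on variables ranging up to
  $\approx 63$); the package's tolerance for this check is 0.05 absolute,
  and the Euler trajectory agrees with a 10-fold-finer Runge–Kutta
  oracle to better than 0.1.
* Peak detection uses topographic prominence (height above the higher of
  the two separating minima) with a relative threshold of 0.2 of the
  detrended range and a minimum separation of 30 s (experimental-scale
  traces) or 0.5 tu (model traces); linear detrending is on by default.
  When two candidates conflict, the more prominent wins.
* Phase labels: in-phase for lag fractions in $[0, 0.15] \cup [0.85, 1)$
  with $r \ge 0.3$; anti-phase for $[0.35, 0.65]$ with $r \le -0.3$;
  otherwise uncoordinated. The correlation gates are sign-aware — a
  strongly anti-correlated pair can never be labelled in-phase.
* Undefined statistics (fewer than 2 peaks, zero-variance windows) are
  `NA`-marked, never silently zero.
* Histogram bins are left-closed, right-open, width 20 s, anchored at 0.
* Test and acceptance problem sizes: 10 seeds per stochastic claim,
  300-time-unit horizons for rate estimates, 500-pulse trains for
  recovery — sizes at which every Monte-Carlo margin above is stable
  across seeds.

## The particle-size bound

Brownian diffusion in three dimensions covers a mean-square distance
$L^2 = 6 D t$; with the Stokes–Einstein relation
$D = k_B T / (6 \pi \eta r)$ this gives an upper bound on the radius of
a particle that must cross the inter-hyphal gap $L$ within time $t$:

$$r \le \frac{k_B T}{\pi \eta}\,\frac{t}{L^2},$$

with prefactor $k_B T / (\pi \eta) \approx 1.5\times10^{-18}\,
\mathrm{m^2\,s^{-1}}$ at $T = 298.15$ K and $\eta = 0.89$ mPa·s
(`prefactor()`). One caveat is documented rather than resolved: at the
canonical inputs $L = 10\,\mu$m and $t = 10$ s the formula yields
$r \approx 1.5\times10^{-7}$ m, which is two orders of magnitude larger
than the $\sim$1.5 nm bound usually quoted alongside it (consistent
inputs would require, e.g., $L \approx 100\,\mu$m or $t \approx 0.1$ s).
`radius_upper_bound()` returns what the formula states; the package does
not silently reconcile the discrepancy. Note that the nanometer-scale
conclusion — ions and small proteins can shuttle between tips fast
enough, secretory vesicles cannot — survives either way, since a 1.5-nm
particle crosses 10 µm in $\approx 0.1$ s (`traversal_time()`).

## Known limitations

* Distance enters only through $k_z e^{-d}$; there is no spatial or PDE
  structure, and no parameter fitting to experimental traces.
* The transition-slowing signature of the ramp scenario is not
  reproduced (see above).
* Seeds of the original figure realizations are unknown; all two-cell
  claims here are statistical across seeds, not realization-matched.
* The Euler–Maruyama scheme is fixed-step and first-order; no
  higher-order stochastic schemes are provided.
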