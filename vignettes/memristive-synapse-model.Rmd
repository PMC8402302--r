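---
title: "A stochastic memristive synapse between FitzHugh-Nagumo neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic memristive synapse between FitzHugh-Nagumo neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsyn)
```

## The model

memsyn simulates a neuromorphic interface in which a presynaptic
FitzHugh-Nagumo (FHN) oscillator drives a postsynaptic one through a
metal-oxide memristive device acting as a synapse. The neurons are the
two-variable FHN reduction with cubic nonlinearity and a piecewise-linear
recovery term,

$$\dot u = u - u^3/3 - v, \qquad
  \dot v = \varepsilon\,(g(u) - v) - I,$$

with $g(u) = \alpha u$ for $u<0$ and $\beta u$ for $u \ge 0$. $u$ is the
membrane potential, $v$ the recovery variable, $\varepsilon \ll 1$ the
time-scale separation, and $I$ the depolarization parameter that sets the
excitation threshold. All neuron variables are dimensionless; model time is
dimensionless too, with a configurable seconds-per-model-time mapping used
only when waveforms are exported at a physical sampling rate.

The device passes a current density that mixes ohmic conduction along
conductive filaments with Poole-Frenkel emission through the remaining
insulator,

$$j = w\,\frac{u}{\rho} + (1-w)\,u\,e^{b u - E_b}, \qquad
  w(u) = \mathrm{clamp}\!\left\{A\,e^{-(E_m - \alpha_1 u)/kT}\right\}_0^1 ,$$

where the filament fraction $w$ is the internal state. Both branches are
proportional to $u$, so $j(0) = 0$ exactly in every cycle — the pinched
hysteresis fingerprint. $\alpha_1 < 0$ by default, so the filament grows
(SET, HRS→LRS) at negative applied voltage and shrinks back (RESET) at
positive voltage, matching the polarity of the device this model describes.
The one-way coupling is

$$\dot u_2 = f(u_2) - v_2 + j(u_1)\,S\,d,$$

with $S$ the filament area and $d$ the equivalent load resistance; nothing
feeds back from the postsynaptic pair to the presynaptic one. The coupling
strength is reported as $z$, the steady-state peak of $|j \cdot S \cdot d|$.

### Quasi-static versus relaxation state update

As printed, $w(u)$ is an instantaneous function of the applied voltage: a
first-order, memoryless device. That form (`mode = "quasi_static"`, the
`memristor_params()` default) cannot open an I-V loop: the up- and
down-sweeps retrace each other. The package therefore also implements
`mode = "relaxation"`, which integrates
$\dot w = (w_\infty(u) - w)/\tau_w$ with $w_\infty$ the quasi-static law.
The shipped calibration uses relaxation mode throughout: the carried state
is what separates the high- and low-resistance reads on the two negative
branches of a cycle, and in the coupled system the low-resistance state
set during the presynaptic hyperpolarization persists into the following
depolarization, which shapes the forcing the postsynaptic neuron receives.
$\tau_w$ is expressed in the time base of the simulation at hand: model
time units for coupled runs (default 8) and seconds for sampled-stimulus
I-V runs (the I-V presets use 4 ms against the 5 kHz stimulus).

### Stochasticity

Cycle-to-cycle variability enters only through the device parameters:
normally distributed multiplicative fluctuations of the ion-migration
barrier $E_m$ (relative SD 0.10), the Poole-Frenkel barrier $E_b$ (0.01)
and the ohmic resistivity $\rho$ (0.10), redrawn once per stimulus period
by default (`per_cycle`; `per_step` and `off` are available). There is no
additive Langevin forcing. Draws are truncated at $10^{-6}$ of the nominal
value so parameters stay positive; at the default dispersions the
truncation is never active in practice. Because $w$ depends on $E_m$
through an exponential, the 10% barrier fluctuation produces the
asymmetric, occasionally large excursions of device conductance that drive
the stochastic switching spread and the seed-to-seed variability of regime
classification near band edges.

## The `paper2021` calibration

The neuron and device constants behind the published regime boundaries are
not public, so the package ships a named calibration, fitted with the
sweep scripts included in the source tree, and documented here:

| quantity | value | role |
|---|---|---|
| pre: $\varepsilon_1, I_1, \alpha, \beta$ | 0.08, 0.02, 1, 2 | robust relaxation oscillator, period $T_1 = 27.7$ |
| post: $\varepsilon_2, I_2, \alpha, \beta$ | 0.0436, 0.12353, 1, 4 | period $T_2 = 28.3$ (≈2% slower), steep recovery loading |
| device: $\rho, b, E_b, E_m, \alpha_1, A, kT$ | 1, 1, 5, 2.3, −1, 1, 0.2 | SET knee near −2.3 V, HRS Poole-Frenkel floor |
| device: $S, d$, mode, $\tau_w$ | 0.02, 25, relaxation, 8 | default operating point inside the 1:1 band at gain 0.85 |
| drive | `amplitude_gain` 0.85 | device sees ±1.6 V at the default operating point |

Key calibration choices, in the order they were made:

* **Postsynaptic operating point.** The post neuron is slightly slower
  than the pre neuron (≈2%) and carries a steep recovery slope
  ($\beta = 4$). The small detuning sets the onset of 1:1 locking near
  $z = 0.02$; the steep recovery makes each forced spike load the recovery
  variable in proportion to the forcing, which destabilises the 1:1 state
  in a resonance window around $z \approx 0.05{-}0.08$ — the intermittent
  band. Without the loading term the 1:1 state is essentially
  indestructible (we observed stable 1:1 at forcing a hundred times the
  membrane scale), because the postsynaptic neuron is simply re-triggered
  once per forcing period whatever the amplitude.
* **Device knee placement.** $E_m = 2.3$ with $kT = 0.2$ puts the SET
  threshold between the −1.95 V and −2.5 V stimulus minima, so that among
  the tested stimulus peaks {1.558, 2, 2.5, 3, 3.5, 4} V the device first
  switches (majority of noisy cycles) at the 2 V peak.
* **Amplitude dial.** In the hardware, the presynaptic potentiometer
  changes the generator's operating point — its rate was tunable over
  10–150 Hz — as well as the voltage reaching the device. Scaling only the
  device input never re-selects a subharmonic: the locking ratio is set by
  the period ratio $T_2/T_1$, and stable 2:1 (3:1) states appear when
  $T_2/T_1 \approx 2$ (≈3). `sweep_amplitude()` therefore accepts a
  `potentiometer` curve mapping drive peak to presynaptic $\varepsilon_1$;
  the calibrated curve (`paper2021_potentiometer()`) carries the 1.6–2 V
  range across both subharmonics, and the 2:1 and 3:1 plateaus then emerge
  from the locking dynamics with unanimous seed votes.

The calibration reproduces: 1:1 locking on $z \in (0.024, 0.050)$ against
the reported (0.02, 0.06); an adjacent intermittent band whose upper edge
falls at $z \approx 0.06{-}0.08$ depending on seed, short of the reported
0.095 — in this model family the 1:1-destabilising resonance window cannot
be stretched to 0.095 without pushing the 1:1 edges off their own targets,
and we report that discrepancy rather than widen the detector; 2:1 and 3:1
plateaus in order across the 1.6–2 V drive range; and first switching at
the 2 V stimulus peak.

## The locking detector

`detect_spikes()` finds upward threshold crossings (threshold defaults to
the signal's min/max midpoint, refractory to half the median inter-spike
interval of a pilot pass) with linear-interpolation onsets.
`locking_ratio()` slides a window of 12 presynaptic spikes (divisible by
1–4, so small integer ratios give exact counts), labels each window with
the simplest rational $p\!:\!q$ (both ≤ 8) near the pre/post count ratio,
and reports the modal label with its occupancy as confidence. Regimes:

* **locked** — confidence ≥ 0.95 *and* the stroboscopic phase of the
  postsynaptic spikes drifts by less than half a presynaptic cycle over
  the analysed span. Count windows alone cannot tell true locking from a
  slow phase slip at small detuning; the drift bound can.
* **intermittent** — at least two labels each occupy ≥ 20% of windows,
  the mean run length of identical labels is ≥ 3 windows, and the modal
  label's epochs individually hold their phase. The last two conditions
  keep quasi-periodic drift — which alternates adjacent labels almost
  every window without any epoch holding a phase — out of this class.
* **unlocked** — everything else.

The pre:post direction (2:1 = two presynaptic spikes per postsynaptic
spike) is the default and is selectable via `direction`.

## Switching analysis

`extract_switching()` reads the high- and low-resistance states as secant
resistances $|v/i|$ at a fixed read voltage (half the smaller peak) on the
entering and returning negative branches, calls a cycle switched when
their ratio is at least 10 (partial filament growth below threshold
already yields small contrasts; 10 separates the 1.558 V minority-switch
stimulus from the 2 V majority-switch one), and localises $V_{set}$ /
$V_{reset}$ as the $|$slope$|$-weighted centroid of the steepest
log-current intervals beyond the read voltage (the log-current slope
diverges at the pinch point, so the near-origin region is excluded).
`variance_decomposition()` reruns the sweep with one noise source at a
time; it reads the resistance states deeper into the loop (0.65 of the
smaller peak) so the low-resistance attribution reflects the fully formed
filament, where the ohmic-resistivity fluctuation dominates, while the
SET-voltage spread is dominated by the ion-migration barrier.

## Numerical choices

Integration is fixed-step classical RK4 (default `dt` = 1e-3 for single
neurons, 5e-3 for the coupled presets; halving the step changes noise-off
end states by far less than 1e-4). Device parameters are held
piecewise-constant between resampling events, with all random draws taken
from R's RNG before integration, so a seed fully determines a trace.
Divergence aborts with the step index. The coupled presets integrate to
t = 2000–2500 model units (≈70–170 presynaptic periods), discard the first
half as transient, and classify on the remainder; sweeps take 5 replicate
seeds per grid point and report majority votes. These problem sizes give
stable majorities at interior grid points while keeping a full sweep under
a minute on one core; band-edge points legitimately flip with seed, which
is the stochastic-boundary behaviour the fluctuating device produces.

## What the generator does and does not emulate

The built-in stimulus reproduces the asymmetric neuron-like pulse: four
monotone-trend segments 0 → −5 V → 0 → +4 V → 0 per period, 10–150 Hz,
10–25 ms spike duration, 5 kHz sampling, with the waveform taken from a
simulated FHN cycle (or a closed-form biphasic template for fast tests)
and the two half-waves rescaled to the requested peaks. It is exactly
periodic; a real electronic generator has timing jitter, drift and
amplifier distortion that are not modelled. Likewise the device model is a
lumped first-order description: no explicit ion migration, no
self-consistent Joule heating (kT is a constant), no multi-filament or
higher-order state dynamics. Passing tests demonstrate internal
consistency of this model family and reproduction of the calibrated
regime structure — not quantitative agreement with any particular
physical device.

## Known limitations

* The intermittent band's upper edge falls short of 0.095 (see above).
* The quasi-static mode, kept as the literal first-order law, shows no
  hysteresis; all loop-opening results require relaxation mode.
* Locking ratios are represented with numerator and denominator at most 8;
  true higher-order ratios (e.g. 9:10) classify as unlocked.
* Absolute currents are in model units; converting to amperes requires an
  external scale factor that the published material does not pin down.
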