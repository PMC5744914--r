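---
title: "Modeling binaural coding in the lateral superior olive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling binaural coding in the lateral superior olive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Principal neurons of the lateral superior olive (LSO) receive phase-locked
excitatory input driven by the ipsilateral ear (via spherical bushy cells of
the AVCN) and phase-locked inhibitory input driven by the contralateral ear
(via the MNTB). By comparing the two streams they encode interaural level
differences (ILD) and, for amplitude-modulated (AM) sounds, envelope timing
differences. olivesim implements a common stochastic input stage, seven
point-neuron models of the LSO spanning a wide range of biophysical detail,
and the output measures used to calibrate all of them against the same set
of empirical firing-rate ranges. This vignette records the modeling choices
and their rationale.

## The input stage

All models are driven by 20 excitatory and 8 inhibitory input fibers,
simulated as statistically independent inhomogeneous Poisson processes.
Under AM stimulation at modulation frequency $f_m$ a fiber's intensity is

$$\lambda(t) = 2\pi\,\lambda_1(f_m)\, p_k(2\pi f_m t), \qquad
  p_k(x) = \frac{e^{k\cos x}}{2\pi I_0(k)},$$

a von Mises phase density scaled so the average rate over one modulation
cycle is $\lambda_1(f_m) = 180 - 0.03 f_m$ spikes/s. The concentration $k$
is obtained by inverting the vector-strength relation
$\mathrm{VS}(k) = I_1(k)/I_0(k)$ for the target
$\mathrm{VS}(f_m) = 0.65\,(1-e^{(f_m-2000)/500})/(1+e^{(f_m-2000)/500})$;
the inversion uses bisection on $k \in [0, 10^4]$ (the Bessel ratio is
strictly increasing), which is robust for VS near 0 and near 1 where
Newton steps misbehave. Unmodulated tones instead drive homogeneous trains
at the sigmoidal rate-level function
$\lambda(\mathrm{SPL}) = 30 + 240/(1+e^{-(\mathrm{SPL}-20)/6})$ spikes/s,
and under ipsilateral-only AM stimulation the inhibitory fibers fire
spontaneously at 30 spikes/s (no spontaneous floor is added to the
excitatory AM rate: $\lambda_1$ itself is the excitatory mean).

Trains are sampled by Lewis–Shedler thinning with the exact intensity
maximum $2\pi\lambda_1 p_k(0)$ as the envelope, so acceptance rates are
predictable and no intensity value can exceed the bound. Each fiber draws
from its own seed derived arithmetically from the master seed, with separate
offsets for the excitatory and inhibitory populations; consequently a given
`(stimulus, seed)` pair yields a bit-identical ensemble — every model is
compared on literally the same input — and enlarging one population never
perturbs the streams of existing fibers. Binaural AM phase differences are
stored in cycles (`ms` input is converted by $\Delta\phi = \Delta t\, f_m$),
with positive values meaning the inhibitory locking phase *precedes* the
excitatory one, matching the physiological sign convention for
envelope-timing experiments.

What the generator deliberately does not emulate: cochlear and
auditory-nerve filtering (inputs are parametric Poisson processes, not
responses to sound waveforms), across-fiber correlations, non-Poisson
renewal statistics, and adaptation. Passing tests therefore validate the
models' input–output behaviour under the stated statistical model of their
afferents, not under real acoustic stimulation.

## The seven models

**Coincidence counting** (event-driven): at each excitatory arrival $t$ the
count $C(t) = \#\{\text{ex in } (t-W_{ex}, t]\} - H\,\#\{\text{inh in }
(t-W_{inh}, t]\}$ is compared with the integer threshold $\theta = 8$; a
crossing emits a spike unless it falls within $T_{ref} = 1.6$ ms of the
previous one. Windows are half-open — an input exactly $W$ in the past has
left the window — which makes the rule deterministic and order-independent
for tied timestamps; evaluation at excitatory arrivals only is sufficient
because $C$ can increase nowhere else. Inhibition-as-count-subtraction is
mathematically identical to elevating the threshold by $H$ per inhibitory
spike.

**Stein models**: each input launches a decaying kernel — exponential
(peak 1 at onset, $\tau_{ex} = 0.70$ ms, $\theta = 5.5$) or alpha
(peak at $t=\tau$, $\tau_{ex} = 0.45$ ms, $\theta = 7.3$) — and the
"virtual membrane potential" is their linear sum minus $H$-scaled
inhibitory kernels. The sums are advanced by an exact per-step exponential
recursion (one state per exponential kernel population, two per alpha
population), so no spike history is stored and the subthreshold trace
equals the direct convolution to machine precision. At a spike the summed
state is cleared and held at zero for $T_{ref}$. Whether kernels started
*during* the refractory period should survive it is not determined by the
models' published description; the default here lets them persist (the
state keeps accumulating while threshold checks are suspended), and
`discard_refractory_inputs = TRUE` provides the stricter alternative. Both
behaviours are unit-tested; the calibration results are indistinguishable
because refractory periods are short relative to the kernel decay.

**Conductance-based synapses** (shared by the remaining four models):
alpha-function conductances with peak 3.5 nS / 0.16 ms (excitatory, reversal
0 mV) and 12 nS / 0.32 ms (inhibitory, reversal −75 mV; the original
Wang–Colburn model keeps its published −70 mV). On the spikeless RC
calibration membrane these produce unitary PSPs of about 2.3 mV (EPSP) and
2.7 mV (IPSP) with 5%-of-peak durations of about 3.5 and 4.1 ms — the
quantities the acceptance script recomputes.

**Passive IF**: leaky RC membrane (24 pF, 26.4 nS, rest −60 mV) with
threshold −45.3 mV, reset to −60 mV held for 1.6 ms. **Active IF** adds a
low-voltage-activated potassium (KLVA) conductance (21.6 nS) with a
first-order gate whose symmetric exponential rates give
$d_\infty(V) = 1/(1+e^{-(V+50)/8})$ and $\tau_d(V) = 1/\cosh((V+50)/16)$ ms,
and replaces the reset by an injected spike-associated current
$I_{spike}(t) = 24 e^{-t/0.15} - 12 e^{-t/0.30}$ nA. All currents are kept
in the canonical unit system (ms, mV, nS, pA, pF — so nS·mV = pA and
pF/nS = ms); the nA amplitudes are converted to pA at construction, which
eliminates unit errors inside the Euler update.

**Wang–Colburn models**: HH-type membranes with leak, KLVA ($w^4 z$), KHVA
($0.85 n^2 + 0.15 p$) and fast sodium ($m^3 h$) currents using
Rothman–Manis kinetics, all rates multiplied by
$\phi = Q_{10}^{(T_{body}-22)/10} = 3^{1.5}$ and voltages shifted by
$V_{shift}$ (0 mV original, +5 mV adjusted). There is no explicit
threshold: spikes are detected by hysteresis, armed when $V$ rises through
−30 mV and counted once $V$ subsequently falls below −45 mV. The spike
*time* is taken at the upward −30 mV crossing (the repolarization merely
confirms the event), which keeps output phase measurements aligned with
spike initiation.

## Numerical scheme

All fixed-step models integrate with explicit forward Euler at
$\Delta t = 2\ \mu s$ (configurable; the HH system warns above 2 µs because
it is stiff). Spike times are reported at the first grid point where the
detection condition holds — no sub-step interpolation, consistent with the
fixed-step scheme. Input spike times are quantized to the nearest grid
point. Gate updates use a rate-capped Euler step,
$x \mathrel{+}= \min(1, \Delta t\,\phi/\tau_x)\,(x_\infty - x)$, which can
never overshoot the target; combined with $x_\infty \in [0,1]$ this
guarantees all gating variables remain in $[0,1]$ for any input, a property
the test suite asserts on driven simulations. The six Rothman–Manis gate
functions are evaluated through a lookup table on a 0.025 mV grid with
linear interpolation (built once per run); the table agrees with direct
formula evaluation to better than $10^{-5}$ relative and removes a dozen
`exp()` calls per step from the inner loop.

Every conductance-model protocol begins from a defined state: gates are
initialized at their steady states for the starting potential and the
membrane is settled for 200 ms before the stimulus; reported traces and
spike times exclude the settle window. Initializing at the steady state
alone is not sufficient because rest is a fixed point of the *coupled*
system, not of each equation separately. Voltage clamps are realized as the
paper-style constant bias current, found by 1-D root finding on the settled
potential to $|V - V_{clamp}| < 0.01$ mV; the per-evaluation settle is
generous (1.5 s) because the KLVA inactivation gate $z$ has time constants
of several hundred ms near rest.

## Output measures and calibration conditions

The three calibration protocols use the conditions under which the
published reference rates were obtained: 40 s of stimulation per point,
modulation frequencies 50–1200 Hz in 50 Hz steps (the exact grid is not
prescribed anywhere; 50 Hz steps resolve the band-pass peak while keeping
24 points), 16 phase-difference points per cycle at 300 Hz, and
contralateral levels −10 to +50 dB in 5 dB steps at a fixed ipsilateral
+35 dB (so ILD spans −45 to +15 dB). Peak and trough are grid extrema
without interpolation, matching how single summary numbers are reported per
curve; grid-induced deviations of a few spikes/s from the reference values
are expected and covered by the stochastic tolerances. Each grid point gets
its own derived seed, so any single point can be re-run in isolation.

Scoring uses nine measures — peak, trough and depth (peak − trough) of each
curve — against targeted and accepted intervals. Closed interval
boundaries count as attained; the depth criteria are strict one-sided
bounds (e.g. depth > 110), open exactly as printed. Vector strength of the
output train at $f_m$ yields the synchrony MTF via the modulation gain
$20\log_{10}(2R)$.

Membrane characterization follows the standard protocols: impedance from
10 pA sinusoids at a −60 mV clamp, read from the last three full cycles
after a 200 ms settle under the stimulus; I–V curves from −0.5 to +1.5 nA
steps with spike mechanisms disabled (threshold detector off, $g_{Na} = 0$
for HH models), steady state read 500 ms after onset; $R_{DC}$ from a
+10 pA step. For the original Wang–Colburn model the measurement point of
its published input resistance is ambiguous (clamp vs. rest); the package
computes both and finds that the −60 mV clamp value reproduces 21.1 MΩ
(the rest-potential value is ≈17 MΩ), so `iv_curve()` reports the clamp
value as `R_DC_MOhm` and the rest measurement as `R_DC_rest_MOhm`.
Step-response classification calls a response tonic when the last spike
falls within one mean inter-spike interval of the 30 ms step offset — a
concrete operationalization of "spiking lasted until the end".

## Known limitations

* Forward Euler at a fixed 2 µs step is the reference scheme, not the most
  efficient one; adaptive or exponential integrators would be faster but
  would change spike times at the microsecond level.
* The models are single-compartment: no dendritic integration, axonal spike
  initiation, or channel gradients. The Stein and coincidence models have
  no membrane at all, so membrane protocols reject them.
* Calibration statistics are stochastic; at 40 s per point the standard
  error of a 140 spikes/s estimate is ≈1.9 spikes/s, so attained-range
  counts are reproducible but individual rates vary by a few spikes/s
  across seeds.
* The input stage is stationary; onset transients, adaptation and
  level-dependent phase locking are outside its scope.

## Reproducing the calibration numbers

```{r}
library(olivesim)

# deterministic membrane characterization
psp_metrics(unitary_psp("ex"))     # ~2.3 mV, ~3.5 ms
iv_curve("if_active")$R_DC_MOhm    # ~38 MOhm
resting_potential("wc_original")   # ~ -65 mV

# stochastic calibration battery (40 s per stimulus point)
bat <- calibration_battery("if_active", seed = 1)
glance(bat$score)                  # 9 of 9 targeted ranges
autoplot(bat$curves$ild)
```

`scripts/acceptance.R` runs exactly these computations end-to-end and
writes the results as JSON.
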