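---
title: "Voltage-sensor priming of presynaptic Cav channels: model, analyses, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-sensor priming of presynaptic Cav channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavprime)
```

## The scientific problem

Subthreshold synaptic potentials generated in the somatodendritic compartment
of cerebellar molecular layer interneurons travel passively down the axon
("analogue signaling") and depolarize presynaptic boutons by a few mV for a
few tens of ms.  Although such depolarizations do not open voltage-gated
Ca++ channels (Cav) directly, they increase the Ca++ influx evoked by an
action potential (AP) that follows within milliseconds, and thereby GABA
release.  `cavprime` implements the biophysical account of this effect — a
voltage-dependent *priming* of the Cav voltage sensors — together with the
trace analyses used to quantify the underlying somato-axonal coupling.

## The four-sensor Cav model

The channel carries four independent, identical voltage sensors and
conducts only when all four are active.  The steady open probability is a
Boltzmann sigmoid of membrane potential,

$$P_{open}(V) = \frac{1}{1 + e^{-\alpha\,(V - V_{Cav50})}},$$

so a single sensor's steady activation is $P_{s}(V) = P_{open}(V)^{1/4}$.
Each sensor relaxes toward its steady activation with an asymmetric rate,

$$\frac{dP}{dt} = v \cdot (P_s(V) - P), \qquad
v = \begin{cases} k_{on}\, P_s(V) & P_s(V) > P \\
                  k_{off}\,(1 - P_s(V)) & P_s(V) < P, \end{cases}$$

and the normalized current is $I(t) = P(t)^4\,(V(t) - E_{Ca})$ — an ohmic
driving force with unit conductance, inward negative.  With four sensors the
channel occupies five states: fully resting (a), one to three sensors active
(b–d, the "primed" closed states), and open; their occupancies are the
binomial masses over the single-sensor activation
(`state_occupancies()`).

The defaults (`cav_params()`) are the values obtained by fitting the model
to bouton Ca++ current recordings: $V_{Cav50} = -17$ mV, $\alpha = 0.2$ /mV,
$k_{on} = 0.55$ /ms, $k_{off} = 0.65$ /ms, with $E_{Ca} = +60$ mV assumed.
Because only the normalized current enters the model, only ratios and
shapes — never absolute amplitudes — are compared to data.

Priming in one sentence: at rest ($-70$ mV) a sensor's activation is only
$P_s \approx 0.07$, but a few-mV, tens-of-ms depolarization raises it two-
fold; since the open probability is the *fourth power*, the current evoked
by the next AP grows disproportionately, even though the channel never
opens during the subthreshold phase.

```{r priming}
p <- cav_params()
steady_sensor_activation(c(-70, -60), p)
aug <- epsp_augmentation(epsp_ap_spec(), p)
aug$ratio   # AP preceded by two EPSPs vs AP alone
```

## Numerical scheme

The sensor ODE is integrated by the forward Euler method (compiled core) at
`dt = 0.01` ms, with the steady target and rate branch evaluated from the
voltage of the current sample, and the activation clipped to [0, 1] after
each step.  `cav_params()` accepts `dt` in [0.005, 0.05] ms;
`euler_convergence()` re-runs any protocol against a 10-fold finer internal
reference and reports the relative error of the peak current (&lt; 1% for
all protocols shipped here at the default step).  Branch ties
($P_s = P$) take the activation branch; the drive term is zero there, so
the choice is inert.  Simulations start from the steady activation at the
first command sample unless an explicit initial condition is given.

## Stimulus construction

The original experiments drove boutons with *recorded* waveforms, available
only through summary parameters; `cavprime` synthesizes them:

* **AP** (`build_ap_waveform()`): product of a rising and a falling sigmoid
  (shape constants `rise_tau = 0.1`, `decay_tau = 0.15` ms, upstroke faster
  than downstroke as in real spikes).  The plateau separation is solved
  numerically so that the interval between the extrema of $dV/dt$ — the
  cell-attached-spike width convention — equals the stated 780 µs.  Rest
  $-70$ mV, peak $+40$ mV.
* **EPSPs** (`build_epsp_ap_waveform()`): each transient has a
  dual-exponential *rising limb* whose rise time constant is solved so the
  10–90% risetime equals the stated 5.7 ms (axonal EPSP), switching at the
  peak to an exact mono-exponential decay with τ = 20.4 ms.  The piecewise
  form is deliberate: recorded axonal EPSP decays are well fit by a single
  exponential *from the peak*, which a plain dual-exponential (whose decay
  flattens near the peak) does not honor, and the residual depolarization in
  the last ~10 ms before the AP is precisely what drives priming.  The
  second EPSP superposes linearly on the first's decay and its amplitude is
  adjusted iteratively so both stated peak potentials ($-58$, $-53$ mV) are
  honored exactly.  The peaks are taken as absolute potentials (rest is
  $-70$ mV); reading them as amplitudes relative to rest would place the
  command near AP threshold, which the experiments exclude.
* **Concatenation**: the AP segment begins — defined as the first sample
  deviating by 1% of the spike amplitude from rest — exactly 40 ms after the
  first EPSP onset, and is bit-identical between the test (EPSPs + AP) and
  control (AP alone) commands, so the pair differs only in the preceding
  potential.  A nonzero `gap` holds the command at rest for the stated
  interval immediately before the AP.
* **Pre-pulse protocols** (`build_prepulse_protocol()`): piecewise-constant
  holding → pre-pulse (default 20 ms, $-90..-40$ mV) → optional gap → test
  pulse (default $+30$ mV, 1.5 ms).

`run_sweep()` tabulates the augmentation ratio over EPSP–AP intervals,
pre-pulse voltages and durations, gaps, and $k_{on}$/$k_{off}$ scalings
(1/100- to 100-fold).

### Sensitivity of the headline augmentation

With the parameter set above, the clean reconstruction yields an
augmentation of ~1.28-fold.  That number is steeply sensitive to the
potential in the final milliseconds before the AP — which is the model's own
central claim: inserting just 1 ms of rest before the upstroke lowers it to
~1.16, 3 ms to ~1.05, and plausible alternative AP sigmoid constants span
~1.20–1.33.  Reconstructions from summary parameters therefore pin this
ratio only to within roughly ±0.06; the shape constants used here were fixed
a priori and not adjusted afterwards.

```{r gaps}
run_sweep("gap", c(0, 1, 3, 5, 10), epsp_ap_spec(), p)
```

## Fitting (inverse problems)

All nonlinear least squares use bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`) or L-BFGS-B with a three-point multi-start, since
sigmoid and exponential fits have flat directions.  Bounds:
$\alpha \in (0.01, 1)$, $V_{Cav50} \in (-60, 20)$ mV,
rate constants in (0.005, 55) /ms.

* `fit_iv()` fits $s \cdot P_{open}(V)(V - E_{Ca})$ to an I–V table with
  $E_{Ca}$ fixed; unweighted by default (per-point weights optional).  The
  free scale $s$ absorbs the unknown conductance, so uniform rescaling of
  the currents leaves $V_{Cav50}$ and $\alpha$ unchanged.
* `fit_kinetics()` fits $k_{on}$, $k_{off}$ to a step-response trace by
  simulating the model inside the objective, with an analytic amplitude
  scale.  The rising phase constrains $k_{on}$; the deactivating tail after
  repolarization constrains $k_{off}$, and a command without a tail flags
  `koff_unidentifiable` rather than returning a spurious number.
* `activation_tau()` fits $A(1 - e^{-t/\tau}) + B$ to the rising inward
  current from its onset (3× the pre-window noise SD, or 1% of plateau when
  noiseless) to the *end* of the analysis window, plateau included.  The
  early rise is quartic in the sensor activation, so truncating the fit
  before the plateau biases τ upward (to ~4–6 ms on the default step); with
  the plateau included the default $-70 \to 0$ mV step gives τ ≈ 3.0 ms,
  matching an exponential fit to an amplitude-versus-duration series.
* `isolate_autoreceptor()` scales the simulated Cav current to a recorded
  trace by least squares over the first 5 ms of the depolarization (the
  fast, Cav-dominated window) and returns the residual, isolating slow
  components such as the GABA-A autoreceptor-like current.  The isolation
  degrades if the slow current already develops within that window.
* `fit_decay()` (mono-/bi-exponential, $\tau_1 < \tau_2$) and
  `fit_length_constant()` ($CR = A e^{-d/\lambda}$) report 95% confidence
  half-widths; the λ fit leaves the prefactor free by default because
  dendro-somatic attenuation precedes the axon (a constrained $CR(0)=1$
  variant is available), and a distance-independent table is flagged
  unidentifiable instead of returning a huge λ.

## Trace analysis

`detect_epsps()` is a threshold detector operating on a 0.5-ms
boxcar-smoothed trace: one event per suprathreshold excursion, excursions
closer than `min_separation_ms` (default 5 ms) merged, onset at the last
sample below baseline + 0.2·threshold before the peak, amplitude measured
from the raw peak against the median of the 10 ms preceding the onset.  The
original study's detector parameters are unpublished; these defaults are
documented, not claimed identical.  Event kinetics are the 10–90% risetime
and a mono-exponential decay τ fitted up to 5 slow time constants but never
into the next event.

`match_events()` pairs each somatic event with the axonal peak inside a
search window after the somatic onset (default 10 ms); `coupling_ratio()`
averages the per-event axonal/somatic amplitude ratios (the per-cell CR is
the mean over events).  `cross_correlation_lag()` reports the lag
maximizing the normalized cross-correlation within ±20 ms, positive when
the bouton lags.  `ca_spike_metrics()` measures cell-attached spikes peak
to peak: the negative and positive extrema correspond to the maximal rising
and falling slopes of the intracellular AP, their separation is the spike
width and their difference its amplitude.  `dc_coupling_prediction()` is
the steady-state arithmetic (somatic step × DC coupling ratio).

## Synthetic data: what it emulates, and what it does not

`generate_paired_traces()` emulates a representative young soma/bouton pair:
Poisson EPSP times (0.58 Hz over 50 s ≈ 29 events), Gaussian somatic
amplitudes 13.1 ± 2.0 mV truncated at zero, per-event axonal scaling by the
true CR 0.6, axonal peaks lagging somatic peaks by 2.33 ms, risetimes
1.8/5.7 ms, slow decays 19.9/20.4 ms, additive Gaussian noise (0.5 mV SD).
The axonal channel is *phenomenological* — scale, shift, slower rise,
matched slow decay — not a compartmental cable solve.  Two consequences:
the lag is programmed peak-to-peak (within this kernel family the slow-rise
axonal event peaks later than the 2.33-ms cross-correlogram lag would
imply, so the kernel onset is shifted to honor the peak lag, and the
full-trace cross-correlogram of generated pairs is not exactly 2.33 ms);
and passing the recovery tests shows the *pipeline* is unbiased under this
statistical structure, not that real axons are cable-free.  Real data add
drift, non-Poisson event clustering and correlated noise that these
generators deliberately omit.

`generate_cr_distance_table()` (distances uniform on 64.5–244 µm,
$CR = A e^{-d/181\,\mu m}$, multiplicative noise), `generate_noisy_ica()`
(model current + noise + optional slow autoreceptor-like transient) and
`generate_ca_spike_train()` (biphasic spikes with exactly programmed
peak-to-peak width, Poisson times with a 1.5-ms refractory period) complete
the closed generate → analyze → recover loops.  Every generator returns its
ground truth and is reproducible from a single integer seed.

```{r loop}
g <- generate_paired_traces(pair_generator_spec(seed = 20))
ev <- detect_epsps(g$recording$soma, threshold_mV = 3, kinetics = FALSE)
pairs <- match_events(ev, g$recording$bouton, search_window_ms = 10)
coupling_ratio(pairs)$mean
```

## Problem sizes and degenerate inputs

The shipped checks use desk-scale sizes chosen to estimate each quantity
stably: 200 replicates of 25-point tables for the λ recovery, 50 noisy
replicates for the kinetics recovery, one 50-s paired recording (10 kHz)
for the CR pipeline, and 100 seeds for the I–V noise study.  Degenerate
inputs are flagged, not guessed at: all-zero I–V tables and flat CR tables
return non-converged results, a missing repolarizing tail flags
`koff_unidentifiable`, a zero-amplitude control current raises an
undefined-ratio error, and `--strict` mode in the command-line interface
turns any flagged fit into a nonzero exit.

## Known limitations

No inactivation gate (the recorded currents show little inactivation over
50 ms), no GHK rectification, no stochastic single-channel simulation, no
Ca++ diffusion/buffering and no vesicle-release model.  The AP and EPSP
shapes are stylized reconstructions from summary parameters; quantities
that depend on the last few ms of subthreshold potential before the AP
(notably the EPSP-priming augmentation) inherit a reconstruction
uncertainty of roughly ±0.06-fold that simulations with recorded waveforms
would not have.
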