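---
title: "Synaptic depression as a frequency-dependent filter: models, theory and validation"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

A chemical synapse transmits a presynaptic spike train `x(t)` into a
postsynaptic conductance `g(t)` through the release of neurotransmitter
vesicles. Each release site needs several hundred milliseconds to replace
a released vesicle, so sustained presynaptic firing depletes the pool of
release-ready vesicles — short-term synaptic depression. This package asks
how that depletion, and in particular the *randomness* of vesicle release
and recovery, shapes the synapse as a communication channel: which
frequency bands of presynaptic information survive the synapse, and at
what fidelity.

## The two models

A synapse has `n_sites` release sites, each holding at most one
release-ready vesicle; `v(t)` counts the vesicles available.

**Stochastic model.** At a presynaptic spike each available vesicle is
released independently with probability `p_release`, so the number
released is `k ~ Binomial(v, p_release)` drawn from the pre-spike
availability, with `v` updated immediately afterwards. Each empty site
then recovers after an independent exponential waiting time with mean
`tau_rec`. `simulate_stochastic()` implements this event-to-event with
exact sampling: between spikes each empty site gets a one-shot
exponential clock, so there is no time-stepping error; the uniform grid
only renders the trajectory.

**Deterministic (trial-average) model.** The classical description
replaces the random increments by their conditional expectations: `v`
becomes continuous, each spike releases the fraction `p_release` of it,
and between spikes `v` relaxes exponentially to `n_sites` with time
constant `tau_rec`. Because both update rules are linear in `v`, the
deterministic trace equals the trial average of the stochastic model for
the *same frozen* input — a property `trial_average_conductance()`
verifies directly (2000 trials on a frozen 10 s train agree with the
deterministic trace to within four pointwise standard errors at over 99%
of grid points).

The release train `z(t) = sum_j k_j delta(t - t_j)` drives the
conductance through convolution with a one-sided exponential kernel
`alpha(t) = exp(-t/tau_syn)/tau_syn` modelling AMPA channel decay.
Conductance units are rescaled so the kernel has unit area; the mean
conductance then equals the mean release rate, in vesicles per second.
After sampling on a grid the kernel is renormalized to unit discrete
area, so this identity holds exactly at any grid step.

## Closed-form theory

For homogeneous Poisson input at rate `r` the package evaluates every
spectral quantity analytically (`steady_state()`, `synaptic_gain()`,
`depression_kernel()`, `single_synapse_spectra()`, ...). The stationary
mean availability is `vbar = n_sites / (1 + p tau_rec r)` and
perturbations decay with `tau_eff = tau_rec / (1 + p tau_rec r)`. The
auto-covariance of `z` is a delta mass plus an exponential lobe with time
constant `tau_eff`, so its spectrum is a constant plus a Lorentzian and is
evaluated in that form — never by numerical transform of the covariance.
The second moment of `v` comes from the birth–death dynamics; for the
stochastic model two extra noise intensities appear, `(n - vbar)/tau_rec`
from Poissonian recovery and `p(1-p) vbar` from binomial release, and
setting both to zero recovers the deterministic model. These feed the
delta mass and lobe amplitude reported by `noise_intensities()`.

The input–conductance cross-spectrum is
`S_xg(f) = alpha_hat(f) r A(f)`, where
`A(f) = p vbar (1 - p r tau_eff / (1 + 2 pi i f tau_eff))` is the
high-pass depression kernel: `|A|` rises from `p vbar / (1 + p tau_rec r)`
at zero frequency (where `r A(0)` equals `r` times the gain) to the
isolated-spike release `p vbar` above the corner `1/(2 pi tau_eff)`.
Synaptic noise is uncorrelated with the input, so `S_xg` is *identical*
for the two models; all model differences live in the conductance power
`S_gg`. For the deterministic model the constant and Lorentzian parts of
`S_zz` are proportional to those of `r |A|^2`, so the magnitude-squared
coherence `C = |S_xg|^2 / (S_xx S_gg)` is *exactly* flat in frequency
(`vbar^2 / <v^2>`); the stochastic model adds low-frequency noise and its
coherence is high-pass, approaching zero at low frequencies in the
depleted regime `p r tau_rec >> 1`, where released vesicles are gated by
recovery events and the zero-frequency release power approaches
`n_sites / tau_rec`.

**Conventions.** Ordinary frequency `f` in Hz with transform kernel
`exp(-2 pi i f t)`; spectra are two-sided densities displayed on the
positive half-line without doubling (coherence and the information rate
are invariant to that choice when applied consistently). Coherence is
magnitude-squared — the form required by the Gaussian-channel information
bound below; the flat-vs-high-pass dichotomy is unchanged if the
magnitude is preferred.

**Populations.** For `n` statistically identical synapses whose Poisson
inputs share a fraction `c` of their spikes, the cross terms between
distinct synapses involve no synaptic self-noise and are identical across
models; `population_spectra()` assembles total-input/total-conductance
spectra by bilinearity. At `c = 0` the population coherence equals the
single-synapse coherence for every `n`; for `c > 0` the model difference
(a factor of order n in the diagonal) is swamped by the order-`n^2` cross
terms, and the stochastic/deterministic coherence ratio at 1 Hz is within
0.5% of unity by `n = 10^4` at the default operating point.

**Rate-coded signals.** A zero-mean Gaussian signal `s(t)` with a
Gaussian-shaped spectrum (bandwidth, central frequency, peak power)
modulates the intensity of each input, giving doubly stochastic Poisson
trains with `S_xx = r + S_ss(f)`. For `peak_power << r^2` the synapse is
linearized about the Poisson operating point: release fluctuations are
`A(f)` times input fluctuations plus synaptic noise with its
Poisson-input spectrum (`signal_transfer_spectra()`, which reduces
exactly to the Poisson formulas when the signal is silent). The linear
information rate `I = -integral log2(1 - C_sg(f)) df`
(`linear_information_rate()`) is the information available to a linear
decoder and a lower bound on the mutual information. The deterministic
model's signal coherence depends on frequency only through `S_ss`, so `I`
is independent of the central frequency; the stochastic model transmits
fast signals better than slow ones and always carries less linear
information than the deterministic model.

## Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `tau_rec` | 0.5 | s | vesicle recovery time typical of neocortical pyramidal–pyramidal synapses |
| `n_sites` | 10 | — | typical cortical contact count between a connected pair |
| `p_release` | 0.5 | — | typical cortical release probability |
| `rate` | 20 | Hz | puts the synapse in the depleted regime (`p r tau_rec = 5`) |
| `tau_syn` | 0.002 | s | AMPA-receptor decay; with the other defaults the population conductance power peaks near 12 Hz (low beta) although the inputs are white |
| signal bandwidth | 0.1 | Hz | narrow-band, to resolve frequency dependence of fidelity |
| signal peak power | 20 | Hz | small against `rate^2 = 400`, inside the linearization's validity |
| `correlation` | 0.1 | — | weak presynaptic noise correlation, typical of cortical pairs |

All defaults live in `inst/extdata/default_params.json` and are
overridable through `synapse_params()` / `experiment_config()`.

## Numerical choices

* Vesicle and signal traces use a 1 ms grid; conductance traces use
  0.4 ms so the kernel is resolved (`release_to_conductance()` requires
  `grid_dt <= tau_syn / 5`).
* Signal synthesis samples independent complex Gaussian Fourier
  coefficients scaled by the square root of the target spectrum, giving a
  circular trace whose expected periodogram is exact at grid resolution;
  doubly stochastic trains are generated by thinning at the maximum
  intensity with nearest-grid intensity lookup, and negative
  instantaneous rates are clipped to zero (a second-order effect for
  small signals: the mean rate stays within 1%).
* Shared spikes in correlated populations are exactly coincident — the
  delta mass in the pairwise cross-covariance requires exact synchrony —
  and the common-train construction makes marginals exactly Poisson and
  the pairwise count correlation exactly `c`.
* Welch estimation (`welch_cross()`) uses Hann windows, 50% overlap,
  per-segment mean removal, and 20 s segments by default (0.05 Hz
  resolution, resolving the depression corner at the defaults).
  Confidence bands are delete-one-segment jackknives on
  variance-stabilized scales (log for spectra, `atanh(sqrt(.))` for
  coherence). The raw coherence of independent series is biased up by
  about `1/n_segments`; the floor is reported and subtracted before
  information-rate integration, which avoids spurious positive
  information.
* The information integral runs over the positive-frequency grid (default
  up to 500 Hz; beyond, the integrand is negligible because the narrow
  signal band has passed). For narrow-band signals the quadrature grid is
  densified around the central frequency (`bandwidth/20` steps).
* Agreement between theory and simulation is summarized as the fraction
  of frequency bins whose CI covers the closed form
  (`agreement_report()`, pass at 90%); validation runs use 500 s of
  simulated time, which keeps each oracle under about a minute while the
  closed forms sit well inside the bands.

## What the generators do and do not emulate

The input generators produce homogeneous Poisson trains, exactly
coincident shared spikes, and Gaussian narrow-band rate signals. Real
presynaptic spike trains are often bursty or regular (non-Poisson), have
jittered rather than exact synchrony, and carry broad-band signals;
renewal or bursty inputs can interact with depression in qualitatively
different ways and are deliberately out of scope. Passing tests therefore
demonstrate internal consistency of the models and their spectral theory
under the stated input statistics, not a fit to any recorded data set.

## Known limitations

* The stochastic model's second moments use a diffusion approximation
  (noise intensities frozen at the stationary mean); the event-driven
  simulations in the test suite quantify how good it is at the packaged
  operating point.
* One vesicle per site, independent sites: multi-release-site contacts
  with dependent release, receptor saturation, facilitation and
  use-dependent recovery are not modelled.
* Population formulas assume homogeneous synaptic parameters.
* The linearized signal theory degrades as `peak_power` approaches
  `rate^2`; `signal_transfer_spectra()` warns when the small-signal
  condition is violated.
* Conductance is the endpoint: no postsynaptic membrane, spiking, or
  channel noise. Because the kernel cancels in the coherence, adding any
  high-frequency postsynaptic noise would make the transfer effectively
  band-pass rather than high-pass.
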