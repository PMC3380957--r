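# stpfilter

Short-term synaptic depression — the transient weakening of a synapse as
its readily releasable neurotransmitter vesicles are depleted — acts as a
frequency-dependent filter between a presynaptic spike train and the
postsynaptic conductance. `stpfilter` is an R package for computational
neuroscientists who want to compute, simulate and cross-validate that
filter for two standard models of vesicle dynamics:

* a **stochastic model**: at each presynaptic spike every available
  vesicle is released independently with probability `p_r`
  (`k ~ Binomial(v, p_r)`), and each emptied release site recovers after
  an exponential waiting time with mean `tau_rec`;
* the classical **deterministic model**, which propagates the conditional
  expectations (`v` continuous, a fraction `p_r` released per spike,
  exponential recovery) and equals the stochastic model's trial average
  for a frozen input.

For Poisson input at rate `r` the whole spectral theory is available in
closed form. With `vbar = n/(1 + p_r tau_rec r)` available vesicles and
effective time constant `tau_eff = tau_rec/(1 + p_r tau_rec r)`, the
input–conductance cross-spectrum is

    S_xg(f) = alpha_hat(f) * r * A(f),
    A(f)    = p_r vbar * (1 - p_r r tau_eff / (1 + 2 pi i f tau_eff)),

where `alpha_hat` is the (unit-area, exponential) conductance kernel's
transfer function and `A` the high-pass depression kernel. `S_xg` is the
same for both models; they differ only in the conductance power `S_gg`,
which the stochastic model inflates with recovery and release noise. The
magnitude-squared coherence `C(f) = |S_xg|^2/(S_xx S_gg)` is therefore
**exactly flat** in frequency for the deterministic model but **high-pass
and much smaller** for the stochastic one: stochastic vesicle dynamics
suppress slowly varying presynaptic information and pass quickly varying
information, a distinction that persists for correlated populations and
for rate-coded Gaussian signals, where the linear information rate
`-∫ log2(1 - C(f)) df` is frequency-independent for the deterministic
model but increasing in signal frequency for the stochastic model.

## Worked example

```r
library(stpfilter)

defs <- default_synapse_params()       # 10 sites, p_r = 0.5, tau_rec = 0.5 s,
params <- defs$params                  # 2 ms AMPA kernel, 20 Hz drive

steady_state(params, rate = 20)
#> Steady state (stochastic model): <v> = 1.667, <v^2> = 4.825, tau_eff = 0.08333 s,
#>   release rate = mean conductance = 16.67 vesicles/s

# simulate 500 s and check the closed forms
x   <- simulate_poisson(20, 500, seed = 101)
sim <- simulate_stochastic(params, x, seed = 102)
mean(sim$trajectory$v)                 # 1.676  (theory: 1.667)
sum(sim$release$marks) / 500           # 16.75  (theory: 16.67)

# coherence: flat (deterministic) vs high-pass (stochastic)
f  <- c(0.01, 0.1, 1, 10, 50)
round(single_synapse_spectra(params, 20, f, "deterministic")$coherence, 4)
#> [1] 0.7917 0.7917 0.7917 0.7917 0.7917
round(single_synapse_spectra(params, 20, f, "stochastic")$coherence, 4)
#> [1] 0.0310 0.0337 0.1962 0.4224 0.4277
```

At 20 Hz the synapse is strongly depleted (`p_r r tau_rec = 5`): only
1.7 of 10 vesicles are available on average, the deterministic coherence
is flat at 0.79, and the stochastic coherence collapses to 0.03 at low
frequencies — information encoded slowly is almost entirely lost to
vesicle noise, while frequencies above the depression corner
(`1/(2 pi tau_eff)` ≈ 1.9 Hz) pass at 0.43.

Pre-built recipes reproduce the package's figure-level analyses
(`run_experiment("single-coherence")`, `"mean-curves"`, `"param-sweep"`,
`"signal-transfer"`, `"population"`), and a thin command-line front end
lives in `inst/cli/stpfilter.R`. Welch cross-spectral estimators with
jackknife confidence bands (`welch_cross()`, `agreement_report()`)
validate every closed form against event-driven simulation.

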