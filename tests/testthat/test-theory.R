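test_that("steady-state moments match closed forms and simulation", {
  # no depletion limits
  ss0 <- steady_state(synapse_params(10, 0, 0.5), 20)
  expect_equal(ss0$v_mean, 10)
  expect_equal(ss0$release_rate, 0)
  expect_equal(steady_state(defaults$params, 0)$v_mean, 10)

  # worked closed form: n=10, p=0.5, tau=0.2, r=10 -> vbar = 5
  expect_equal(steady_state(synapse_params(10, 0.5, 0.2), 10)$v_mean, 5)

  # saturation: vbar strictly decreasing in rate, p, tau
  rates <- seq(1, 100, length.out = 25)
  vm <- vapply(rates, function(r) steady_state(defaults$params, r)$v_mean,
               numeric(1))
  expect_true(all(diff(vm) < 0))
  expect_lt(steady_state(synapse_params(10, 0.9, 0.5), 20)$v_mean,
            steady_state(synapse_params(10, 0.2, 0.5), 20)$v_mean)
  expect_lt(steady_state(synapse_params(10, 0.5, 1.0), 20)$v_mean,
            steady_state(synapse_params(10, 0.5, 0.2), 20)$v_mean)

  for (pg in param_grid) {
    ss <- steady_state(pg$params, pg$rate)
    expect_gte(ss$v_second, ss$v_mean^2)
    expect_lte(ss$tau_eff, pg$params$tau_rec)
  }

  # event-driven simulation oracle for the stationary mean
  x <- simulate_poisson(20, 150, seed = 13)
  sim <- simulate_stochastic(defaults$params, x, seed = 14, grid_dt = 0.001)
  expect_within_rel(mean(sim$trajectory$v),
                    steady_state(defaults$params, 20)$v_mean, 0.05)
})

test_that("gain is the rate derivative of the mean conductance", {
  h <- 1e-4
  for (r in c(0.5, 10, 60)) {
    fd <- (steady_state(defaults$params, r + h)$g_mean -
           steady_state(defaults$params, r - h)$g_mean) / (2 * h)
    expect_within_rel(synaptic_gain(defaults$params, r), fd, 1e-6)
  }
  expect_equal(synaptic_gain(defaults$params, 0), 0.5 * 10)
  expect_lt(synaptic_gain(defaults$params, 100),
            synaptic_gain(defaults$params, 10))
  expect_equal(synaptic_gain(synapse_params(10, 0, 0.5), c(1, 50)), c(0, 0))
})

test_that("depression kernel is high-pass with the correct limits", {
  f <- c(0.01, 0.1, 1, 5, 20, 50, 200, 1e5)
  A <- depression_kernel(defaults$params, 20, f)
  expect_true(all(diff(Mod(A)) > 0))                     # monotone high-pass
  ss <- steady_state(defaults$params, 20)
  expect_within_rel(Mod(A)[length(f)],
                    defaults$params$p_release * ss$v_mean, 1e-3)
  expect_lte(Mod(depression_kernel(defaults$params, 20, 0.01)),
             Mod(depression_kernel(defaults$params, 20, 50)))
  # zero-frequency kernel ties to the gain
  for (r in c(5, 20, 80))
    expect_within_rel(r * Re(depression_kernel(defaults$params, r, 0)),
                      r * synaptic_gain(defaults$params, r), 1e-10)
  # depleted regime: rate * A(0) -> 0
  expect_lt(400 * Mod(depression_kernel(defaults$params, 400, 0)), 0.5)
})

test_that("noise intensities vanish for the deterministic model only", {
  nid <- noise_intensities(defaults$params, 20, "deterministic")
  expect_equal(nid$D_recovery, 0)
  expect_equal(nid$D_release, 0)
  nis <- noise_intensities(defaults$params, 20, "stochastic")
  expect_gt(nis$D_recovery, 0)
  expect_gt(nis$D_release, 0)
  # deterministic release (p = 1) has no per-event binomial noise
  expect_equal(noise_intensities(synapse_params(10, 1, 0.5), 20,
                                 "stochastic")$D_release, 0)
  # depleted regime: stochastic zero-frequency release power -> n / tau_rec
  expect_within_rel(release_spectrum(defaults$params, 400, 0, "stochastic"),
                    defaults$params$n_sites / defaults$params$tau_rec, 0.05)
  expect_lt(release_spectrum(defaults$params, 400, 0, "deterministic"),
            0.01 * defaults$params$n_sites / defaults$params$tau_rec)
})

test_that("single-synapse spectra obey the model ordering and bounds", {
  f <- c(10^seq(-2, 0, length.out = 20), seq(1.5, 500, by = 0.5))
  for (pg in param_grid) {
    st <- single_synapse_spectra(pg$params, pg$rate, f, "stochastic")
    de <- single_synapse_spectra(pg$params, pg$rate, f, "deterministic")
    # cross-spectrum identical for the two models
    expect_equal(st$S_xg, de$S_xg)
    # stochastic vesicle noise only adds power
    expect_true(all(st$S_gg >= de$S_gg - 1e-12))
    # Cauchy-Schwarz / coherence bounds
    for (cur in list(st, de)) {
      expect_true(all(Mod(cur$S_xg)^2 <= cur$S_xx * cur$S_gg * (1 + 1e-12)))
      expect_true(all(cur$coherence >= 0 & cur$coherence <= 1))
    }
    expect_true(all(st$coherence <= de$coherence + 1e-12))
  }

  st <- single_synapse_spectra(defaults$params, 20, f, "stochastic")
  de <- single_synapse_spectra(defaults$params, 20, f, "deterministic")
  # deterministic coherence is exactly flat (analytic cancellation)
  expect_lt(max(de$coherence) / min(de$coherence) - 1, 1e-10)
  # stochastic coherence is high-pass and nearly zero at low frequency
  band <- st$freq >= 0.1 & st$freq <= 50
  expect_true(all(diff(st$coherence[band]) >= -1e-12))
  expect_lt(single_synapse_spectra(defaults$params, 200, 0.01,
                                   "stochastic")$coherence, 0.02)
  # kernel low-pass kills conductance power at high frequency
  expect_lt(st$S_gg[which.min(abs(f - 500))],
            0.1 * st$S_gg[which.min(abs(f - 1))])
  # |S_xg| is band-pass: interior maximum between the two corners
  ss <- steady_state(defaults$params, 20)
  f_dep <- 1 / (2 * pi * ss$tau_eff)
  f_syn <- 1 / (2 * pi * defaults$params$kernel$tau_syn)
  fstar <- f[which.max(Mod(st$S_xg))]
  expect_gt(fstar, f_dep)
  expect_lt(fstar, f_syn)
})

test_that("population spectra reduce correctly and converge across models", {
  f <- c(0.01, 0.1, 1, 5, 20, 50)
  one <- population_spectra(defaults$params, 20, 0.1, 1, f, "stochastic")
  single <- single_synapse_spectra(defaults$params, 20, f, "stochastic")
  expect_equal(one$coherence, single$coherence)
  expect_equal(one$S_gg, single$S_gg)

  # c = 0: population coherence equals the single-synapse coherence
  for (np in c(1, 10, 100)) {
    pop <- population_spectra(defaults$params, 20, 0, np, f, "stochastic")
    expect_equal(pop$coherence, single$coherence, tolerance = 1e-12)
  }

  # with correlations the models agree for large populations
  ratio_at <- function(np) {
    s <- population_spectra(defaults$params, 20, 0.1, np, 1, "stochastic")
    d <- population_spectra(defaults$params, 20, 0.1, np, 1,
                            "deterministic")
    s$coherence / d$coherence
  }
  expect_lt(abs(ratio_at(1e4) - 1), 0.05)
  expect_lt(abs(ratio_at(1e4) - 1), abs(ratio_at(10) - 1))
})

test_that("signal transfer obeys the linearized theory", {
  f <- sort(unique(c(seq(0.2, 60, by = 0.02), 10^seq(-2, 0, by = 0.1))))
  sp0 <- signal_spec(0.1, 5, 0)
  with0 <- signal_transfer_spectra(defaults$params, 20, sp0, 0.1, 10, f,
                                   "stochastic")
  base <- population_spectra(defaults$params, 20, 0.1, 10, f, "stochastic")
  expect_equal(with0$S_gg, base$S_gg)
  expect_equal(with0$coherence, base$coherence)
  expect_equal(max(with0$coherence_signal), 0)

  peak_coh <- function(f0, model) {
    sp <- signal_spec(0.1, f0, 20)
    fg <- sort(unique(c(seq(max(f0 - 1, 0.01), f0 + 1, by = 0.005),
                        seq(0.1, 60, by = 0.5))))
    max(signal_transfer_spectra(defaults$params, 20, sp, 0, 1, fg,
                                model)$coherence_signal)
  }
  # deterministic: shifting the signal leaves the amplitude unchanged
  expect_within_rel(peak_coh(45, "deterministic"),
                    peak_coh(1, "deterministic"), 1e-6)
  # stochastic: fast signals are transmitted more reliably
  expect_gt(peak_coh(45, "stochastic"), 1.5 * peak_coh(1, "stochastic"))

  expect_warning(
    signal_transfer_spectra(defaults$params, 2, signal_spec(0.1, 5, 20),
                            0, 1, f, "stochastic"),
    "linearization")
})

test_that("linear information rate integrates the coherence", {
  f <- seq(0, 10, by = 0.01)
  expect_equal(linear_information_rate(f, rep(0, length(f))), 0)
  expect_equal(linear_information_rate(f, rep(0.5, length(f))), 10,
               tolerance = 1e-12)
  expect_error(linear_information_rate(f, rep(1, length(f))), "diverges")
  # monotone in pointwise coherence
  c1 <- rep(0.3, length(f))
  expect_lt(linear_information_rate(f, c1),
            linear_information_rate(f, c1 + 0.2))
})
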