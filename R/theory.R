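#' Steady-state moments of the vesicle count and release train
#'
#' Closed-form stationary moments for a depressing synapse driven by a
#' homogeneous Poisson spike train. With `n` sites, release probability
#' `p`, recovery time `tau` and rate `r`:
#' \deqn{\bar v = n / (1 + p \tau r), \qquad
#'       \tau_{eff} = \tau / (1 + p \tau r),}
#' and the stationary mean release rate (= mean conductance in rescaled
#' units) is `p r vbar`. The first moments are identical for the stochastic
#' and deterministic models; the stationary second moment of the vesicle
#' count differs, because stochastic recovery and probabilistic release add
#' variance:
#' \deqn{\langle v^2\rangle = \frac{2 n \bar v/\tau + \sigma_r^2 +
#'       r \sigma_p^2}{2/\tau + 2 p r - p^2 r},}
#' with \eqn{\sigma_r^2 = (n - \bar v)/\tau} and
#' \eqn{\sigma_p^2 = p (1-p) \bar v} for the stochastic model and both zero
#' for the deterministic model.
#'
#' @param params A [synapse_params()].
#' @param rate Presynaptic rate (Hz), >= 0.
#' @param model `"stochastic"` or `"deterministic"`; affects only
#'   `v_second`.
#' @return A list of class `steady_state_moments`: `v_mean`, `v_second`,
#'   `tau_eff` (s), `release_rate` (vesicles/s), `g_mean` (rescaled
#'   conductance units), `model`.
#' @examples
#' steady_state(synapse_params(10, 0.5, 0.2), rate = 10)$v_mean  # 5
#' @export
steady_state <- function(params, rate,
                         model = c("stochastic", "deterministic")) {
  stopifnot(inherits(params, "synapse_params"))
  check_rate(rate)
  model <- match.arg(model)
  n <- params$n_sites; p <- params$p_release; tau <- params$tau_rec
  v_mean <- n / (1 + p * tau * rate)
  tau_eff <- tau / (1 + p * tau * rate)
  ni <- noise_coefficients(params, rate, model)
  v_second <- (2 * n * v_mean / tau + ni$sigma_r2 + rate * ni$sigma_p2) /
    (2 / tau + 2 * p * rate - p^2 * rate)
  release_rate <- p * rate * v_mean
  structure(list(v_mean = v_mean, v_second = v_second, tau_eff = tau_eff,
                 release_rate = release_rate, g_mean = release_rate,
                 model = model),
            class = "steady_state_moments")
}

#' @export
print.steady_state_moments <- function(x, ...) {
  cat(sprintf(
    "Steady state (%s model): <v> = %.4g, <v^2> = %.4g, tau_eff = %.4g s,\n  release rate = mean conductance = %.4g vesicles/s\n",
    x$model, x$v_mean, x$v_second, x$tau_eff, x$release_rate))
  invisible(x)
}

# diffusion noise intensities (internal); zero for the deterministic model
noise_coefficients <- function(params, rate, model) {
  n <- params$n_sites; p <- params$p_release; tau <- params$tau_rec
  v_mean <- n / (1 + p * tau * rate)
  if (identical(model, "stochastic"))
    list(sigma_r2 = (n - v_mean) / tau, sigma_p2 = p * (1 - p) * v_mean)
  else
    list(sigma_r2 = 0, sigma_p2 = 0)
}

#' Gain of the steady-state mean conductance
#'
#' Derivative of the stationary mean conductance with respect to the
#' presynaptic rate, in closed form:
#' `gain(r) = p n / (1 + p tau r)^2` (conductance units per Hz, kernel area
#' one). It decreases monotonically and decays to zero as the mean
#' conductance saturates at high rates. The zero-frequency input-output
#' cross-spectrum equals `rate * gain(rate)`.
#'
#' @inheritParams steady_state
#' @return Gain value(s); vectorized over `rate`.
#' @export
synaptic_gain <- function(params, rate) {
  stopifnot(inherits(params, "synapse_params"))
  if (any(rate < 0)) stop("'rate' must be >= 0")
  p <- params$p_release
  p * params$n_sites / (1 + p * params$tau_rec * rate)^2
}

#' Depression kernel (linearized synaptic filter)
#'
#' The deterministic linear kernel `A(f)` mapping presynaptic rate
#' fluctuations to release-rate fluctuations:
#' \deqn{A(f) = p \bar v \left(1 -
#'   \frac{p r \tau_{eff}}{1 + 2\pi i f \tau_{eff}}\right).}
#' `|A|` is a high-pass filter: it suppresses frequencies below the
#' depression corner `1/(2 pi tau_eff)` and plateaus at the mean number of
#' vesicles released by an isolated spike, `p * vbar`. Its zero-frequency
#' value satisfies `rate * A(0) = rate * gain(rate)`.
#'
#' @inheritParams steady_state
#' @param freq Frequency grid (Hz).
#' @return Complex vector `A(freq)`.
#' @export
depression_kernel <- function(params, rate, freq) {
  stopifnot(inherits(params, "synapse_params"))
  check_rate(rate)
  ss <- steady_state(params, rate)
  a <- params$p_release * rate * ss$tau_eff
  params$p_release * ss$v_mean *
    (1 - a / (1 + 2i * pi * freq * ss$tau_eff))
}

#' Transfer function of the conductance kernel
#'
#' Fourier transform of the unit-area exponential activation kernel,
#' `1 / (1 + 2 pi i f tau_syn)`: a low-pass filter with corner
#' `1/(2 pi tau_syn)`.
#'
#' @param kernel A [kernel_spec()] or [synapse_params()].
#' @param freq Frequency grid (Hz).
#' @return Complex vector.
#' @export
kernel_transfer <- function(kernel, freq) {
  if (inherits(kernel, "synapse_params")) kernel <- kernel$kernel
  stopifnot(inherits(kernel, "kernel_spec"))
  1 / (1 + 2i * pi * freq * kernel$tau_syn)
}

#' Noise intensities of the diffusion approximation
#'
#' The diffusion approximation of the stochastic model adds two white-noise
#' sources to the deterministic vesicle dynamics: a Wiener term for
#' stochastic recovery with intensity `sigma_r^2 = (n - vbar)/tau_rec`, and
#' a per-spike release-noise term with intensity
#' `sigma_p^2 = p (1 - p) vbar` (the binomial release variance at the
#' stationary mean availability). Both are zero for the deterministic
#' model. Also returned are the covariance coefficients of the release
#' train: the delta mass `r <k^2>` at lag zero and the amplitude of the
#' exponential lobe with time constant `tau_eff` (negative in the depressed
#' regime: a release transiently suppresses further releases).
#'
#' @inheritParams steady_state
#' @param model `"stochastic"` or `"deterministic"`.
#' @return A list of class `noise_intensities`: `D_input` (constant part of
#'   the release-train power in excess of `r |A|^2` shared by both models),
#'   `D_recovery` (`sigma_r^2`), `D_release` (`sigma_p^2`), and
#'   `covariance_coeffs = c(delta_mass, exp_amplitude)`.
#' @export
noise_intensities <- function(params, rate,
                              model = c("stochastic", "deterministic")) {
  stopifnot(inherits(params, "synapse_params"))
  check_rate(rate)
  model <- match.arg(model)
  p <- params$p_release
  ni <- noise_coefficients(params, rate, model)
  ss <- steady_state(params, rate, model)
  ss_det <- steady_state(params, rate, "deterministic")
  delta_mass <- rate * (p^2 * ss$v_second + ni$sigma_p2)
  exp_amplitude <- p * rate^2 *
    (p * (1 - p) * ss$v_second - ni$sigma_p2 - p * ss$v_mean^2)
  structure(list(
    D_input = rate * p^2 * (ss_det$v_second - ss_det$v_mean^2),
    D_recovery = ni$sigma_r2,
    D_release = ni$sigma_p2,
    covariance_coeffs = c(delta_mass = delta_mass,
                          exp_amplitude = exp_amplitude)),
    class = "noise_intensities")
}

# release-train power spectrum S_zz(f) = delta mass + Lorentzian lobe
release_spectrum_values <- function(params, rate, freq, model) {
  ni <- noise_intensities(params, rate, model)
  te <- steady_state(params, rate)$tau_eff
  g0 <- ni$covariance_coeffs[["delta_mass"]]
  g1 <- ni$covariance_coeffs[["exp_amplitude"]]
  g0 + g1 * 2 * te / (1 + (2 * pi * freq * te)^2)
}

#' Power spectrum of the vesicle release train
#'
#' Closed form `S_zz(f)` for either model: the auto-covariance of the
#' marked release train is a delta mass plus a two-sided exponential lobe
#' with time constant `tau_eff`, so the spectrum is a constant plus a
#' Lorentzian, evaluated analytically. In the depleted regime the
#' stochastic model's zero-frequency power approaches
#' `n_sites / tau_rec` (recovery events at each site form a Poisson stream
#' and set the long-window release-count variance), while the deterministic
#' model's approaches zero.
#'
#' @inheritParams noise_intensities
#' @param freq Frequency grid (Hz).
#' @return Numeric vector `S_zz(freq)` (two-sided spectral density).
#' @export
release_spectrum <- function(params, rate, freq,
                             model = c("stochastic", "deterministic")) {
  model <- match.arg(model)
  release_spectrum_values(params, rate, freq, model)
}

new_spectral_curves <- function(freq, ...) {
  structure(c(list(freq = freq), list(...)), class = "spectral_curves")
}

#' @export
print.spectral_curves <- function(x, ...) {
  cat(sprintf("Spectral curves on %d frequencies in [%.4g, %.4g] Hz\n",
              length(x$freq), min(x$freq), max(x$freq)))
  cat("  fields:", paste(setdiff(names(x), "freq"), collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form spectra of a single synapse driven by Poisson input
#'
#' Evaluates the theoretical input power spectrum `S_xx = rate`, the
#' input-conductance cross-spectrum
#' `S_xg(f) = alpha_hat(f) * rate * A(f)` (identical for the two models:
#' synaptic noise is uncorrelated with the input), the conductance power
#' spectrum `S_gg = |alpha_hat|^2 S_zz`, and the magnitude-squared
#' coherence `C = |S_xg|^2 / (S_xx S_gg)`. For the deterministic model the
#' kernel factors cancel exactly and the coherence is flat in frequency;
#' the stochastic model's extra low-frequency noise makes its coherence
#' high-pass and everywhere smaller.
#'
#' @inheritParams noise_intensities
#' @param freq Frequency grid (Hz), > 0 recommended.
#' @return A `spectral_curves` object with fields `freq`, `S_xx`, `S_xg`
#'   (complex), `S_gg`, `coherence`, `A`, `alpha_hat`, `model`.
#' @export
single_synapse_spectra <- function(params, rate, freq,
                                   model = c("stochastic", "deterministic")) {
  stopifnot(inherits(params, "synapse_params"))
  if (rate <= 0) stop("'rate' must be > 0")
  model <- match.arg(model)
  A <- depression_kernel(params, rate, freq)
  ah <- kernel_transfer(params, freq)
  S_zz <- release_spectrum_values(params, rate, freq, model)
  S_xx <- rep(rate, length(freq))
  S_xg <- ah * rate * A
  S_gg <- Mod(ah)^2 * S_zz
  new_spectral_curves(freq, S_xx = S_xx, S_xg = S_xg, S_gg = S_gg,
                      coherence = Mod(S_xg)^2 / (S_xx * S_gg),
                      A = A, alpha_hat = ah, model = model)
}

# cross-moment of the vesicle counts at two synapses sharing a fraction c
# of their input spikes (identical for both models: no self-noise terms)
cross_second_moment <- function(params, rate, correlation) {
  n <- params$n_sites; p <- params$p_release; tau <- params$tau_rec
  v_mean <- n / (1 + p * tau * rate)
  2 * n * v_mean /
    (tau * (2 * (1 / tau + p * rate) - correlation * p^2 * rate))
}

# cross-spectrum S_{z_i z_j}(f) between release trains of two synapses with
# shared-spike input correlation c (delta mass + symmetric exponential)
release_cross_spectrum <- function(params, rate, correlation, freq) {
  p <- params$p_release
  te <- steady_state(params, rate)$tau_eff
  v_mean <- steady_state(params, rate)$v_mean
  m <- cross_second_moment(params, rate, correlation)
  g0 <- correlation * rate * p^2 * m
  g1 <- p^2 * rate^2 * ((1 - correlation * p) * m - v_mean^2)
  g0 + g1 * 2 * te / (1 + (2 * pi * freq * te)^2)
}

#' Closed-form spectra for a population of correlated inputs
#'
#' Total-input/total-conductance spectra for `n` statistically identical
#' synapses whose Poisson input trains share a fraction `correlation` of
#' their spikes. Cross terms between distinct synapses are identical for
#' the stochastic and deterministic models (synaptic noise is independent
#' across synapses), so the model difference enters only through the `n`
#' diagonal terms and washes out as correlated cross terms dominate. At
#' `correlation = 0` the population coherence equals the single-synapse
#' coherence for every `n`.
#'
#' @inheritParams single_synapse_spectra
#' @param correlation Pairwise shared-spike fraction in `[0, 1]`.
#' @param n Population size (number of presynaptic trains), >= 1.
#' @return A `spectral_curves` object with the population fields `S_xx`
#'   (total input), `S_xg`, `S_gg`, `coherence`, plus `A` and `alpha_hat`.
#' @export
population_spectra <- function(params, rate, correlation, n, freq,
                               model = c("stochastic", "deterministic")) {
  stopifnot(inherits(params, "synapse_params"))
  if (rate <= 0) stop("'rate' must be > 0")
  if (correlation < 0 || correlation > 1)
    stop("'correlation' must be in [0, 1]")
  if (n < 1 || n != round(n)) stop("'n' must be an integer >= 1")
  model <- match.arg(model)
  A <- depression_kernel(params, rate, freq)
  ah <- kernel_transfer(params, freq)
  S_zz <- release_spectrum_values(params, rate, freq, model)
  S_zizj <- release_cross_spectrum(params, rate, correlation, freq)
  S_XX <- rep(n * rate * (1 + (n - 1) * correlation), length(freq))
  S_XZ <- n * rate * (1 + (n - 1) * correlation) * A
  S_ZZ <- n * S_zz + n * (n - 1) * S_zizj
  S_xg <- ah * S_XZ
  S_gg <- Mod(ah)^2 * S_ZZ
  new_spectral_curves(freq, S_xx = S_XX, S_xg = S_xg, S_gg = S_gg,
                      coherence = Mod(S_xg)^2 / (S_XX * S_gg),
                      A = A, alpha_hat = ah, model = model, n = n,
                      correlation = correlation)
}

#' Linearized spectra with a rate-coded signal
#'
#' Spectra for `n` doubly stochastic Poisson inputs whose common intensity
#' is `rate + s(t)`, where `s` has the Gaussian-shaped spectrum of a
#' [signal_spec()], with additional shared-spike noise correlation. The
#' synapse is linearized around the Poisson operating point (valid for
#' `peak_power << rate^2`): release fluctuations are `A(f)` times input
#' fluctuations plus synaptic noise with the Poisson-input spectrum. With
#' `peak_power = 0` the result reduces exactly to [population_spectra()].
#' The signal-conductance coherence of the deterministic model depends on
#' frequency only through `S_ss(f)`, so moving the signal's central
#' frequency shifts the coherence bump without changing its amplitude; the
#' stochastic model transmits signals concentrated at higher frequencies
#' with larger coherence.
#'
#' @inheritParams population_spectra
#' @param spec A [signal_spec()].
#' @return A `spectral_curves` object with fields `S_ss`, `S_sg` (complex
#'   signal-conductance cross-spectrum), `coherence_signal`, and the
#'   population fields `S_xx`, `S_xg`, `S_gg`, `coherence`.
#' @export
signal_transfer_spectra <- function(params, rate, spec, correlation = 0,
                                    n = 1, freq,
                                    model = c("stochastic", "deterministic")) {
  stopifnot(inherits(params, "synapse_params"), inherits(spec, "signal_spec"))
  model <- match.arg(model)
  if (spec$peak_power > 0.1 * rate^2)
    warning("linearization may be inaccurate: peak_power is not small ",
            "relative to rate^2")
  base <- population_spectra(params, rate, correlation, n, freq, model)
  S_ss <- signal_spectrum(spec, freq)
  A <- base$A; ah <- base$alpha_hat
  S_xx <- base$S_xx + n^2 * S_ss
  S_xg <- base$S_xg + ah * A * n^2 * S_ss
  S_gg <- base$S_gg + Mod(ah)^2 * Mod(A)^2 * n^2 * S_ss
  S_sg <- ah * A * n * S_ss
  # |S_sg|^2 / (S_ss S_gg) with the S_ss factor cancelled analytically,
  # so silent bands (S_ss = 0) have zero, not indeterminate, coherence
  coh_sig <- Mod(ah * A)^2 * n^2 * S_ss / Re(S_gg)
  new_spectral_curves(freq,
                      S_xx = S_xx, S_xg = S_xg, S_gg = S_gg,
                      coherence = Mod(S_xg)^2 / (S_xx * S_gg),
                      S_ss = S_ss, S_sg = S_sg,
                      coherence_signal = coh_sig,
                      A = A, alpha_hat = ah, model = model, n = n,
                      correlation = correlation)
}

#' Linear information rate from a coherence curve
#'
#' Coherence-based lower bound on the mutual information per unit time
#' available to a linear decoder:
#' \deqn{I = -\int_0^{f_{max}} \log_2(1 - C(f))\, df \quad [bits/s],}
#' integrated by the trapezoidal rule over the (possibly nonuniform)
#' positive-frequency grid.
#'
#' @param freq Frequency grid (Hz), increasing, >= 0.
#' @param coherence Coherence values in `[0, 1)` on the grid.
#' @return Information rate (bits/s), nonnegative.
#' @examples
#' f <- seq(0, 10, by = 0.01)
#' linear_information_rate(f, rep(0.5, length(f)))  # 10 bits/s
#' @export
linear_information_rate <- function(freq, coherence) {
  if (length(freq) != length(coherence))
    stop("'freq' and 'coherence' must have equal length")
  if (is.unsorted(freq)) stop("'freq' must be increasing")
  if (any(coherence < 0)) stop("coherence must be >= 0")
  if (any(coherence >= 1))
    stop("coherence reaches 1: the information integral diverges")
  y <- -log2(1 - coherence)
  sum(diff(freq) * (y[-1] + y[-length(y)]) / 2)
}
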