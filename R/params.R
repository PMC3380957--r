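#' Synaptic parameter set
#'
#' Bundles the parameters of a depressing synapse: the number of release
#' sites, the per-site release probability, the mean vesicle recovery time
#' and the postsynaptic conductance kernel. Conductance units are rescaled
#' so that the activation kernel has unit area; the mean conductance then
#' equals the mean vesicle release rate (vesicles/s).
#'
#' @param n_sites Integer number of release sites (functional contacts); each
#'   site holds at most one release-ready vesicle.
#' @param p_release Probability that an available vesicle is released by a
#'   presynaptic spike, in `[0, 1]`.
#' @param tau_rec Mean of the exponential vesicle recovery time (s).
#' @param tau_syn Decay time constant of the one-sided exponential
#'   conductance kernel (s), modelling AMPA-receptor channel dynamics.
#' @return An object of class `synapse_params`.
#' @examples
#' synapse_params(n_sites = 10, p_release = 0.5, tau_rec = 0.5)
#' @seealso [default_synapse_params()] for the packaged default values.
#' @export
synapse_params <- function(n_sites = 10L, p_release = 0.5, tau_rec = 0.5,
                           tau_syn = 0.002) {
  if (length(n_sites) != 1L || !is.finite(n_sites) ||
      n_sites < 1 || n_sites != round(n_sites))
    stop("'n_sites' must be a single integer >= 1")
  if (length(p_release) != 1L || !is.finite(p_release) ||
      p_release < 0 || p_release > 1)
    stop("'p_release' must be in [0, 1]")
  if (length(tau_rec) != 1L || !is.finite(tau_rec) || tau_rec <= 0)
    stop("'tau_rec' must be > 0")
  structure(
    list(n_sites = as.integer(n_sites), p_release = p_release,
         tau_rec = tau_rec, kernel = kernel_spec(tau_syn)),
    class = "synapse_params"
  )
}

#' Conductance kernel specification
#'
#' One-sided exponential activation kernel
#' `alpha(t) = step(t) * exp(-t / tau_syn) / tau_syn`, normalized to unit
#' area so that one released vesicle contributes unit time-integrated
#' conductance.
#'
#' @param tau_syn Decay time constant (s); must be positive.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(tau_syn = 0.002) {
  if (length(tau_syn) != 1L || !is.finite(tau_syn) || tau_syn <= 0)
    stop("'tau_syn' must be > 0")
  structure(list(tau_syn = tau_syn, shape = "exponential"),
            class = "kernel_spec")
}

#' Rate-coded signal specification
#'
#' Describes a stationary Gaussian signal `s(t)` (zero mean) with a
#' Gaussian-shaped power spectrum
#' `S_ss(f) = peak_power * (exp(-(f - f0)^2 / (2 bw^2)) +
#'            exp(-(f + f0)^2 / (2 bw^2)))`
#' centred at `f0 = central_frequency`. The signal modulates a presynaptic
#' firing rate, so its values and its spectral peak are in Hz.
#'
#' @param bandwidth Spectral width of the Gaussian bump (Hz), > 0.
#' @param central_frequency Location of the spectral peak (Hz), >= 0.
#' @param peak_power Height of the spectral peak (Hz); 0 gives a silent
#'   signal.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(bandwidth = 0.1, central_frequency = 5,
                        peak_power = 20) {
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("'bandwidth' must be > 0")
  if (!is.finite(central_frequency) || central_frequency < 0)
    stop("'central_frequency' must be >= 0")
  if (!is.finite(peak_power) || peak_power < 0)
    stop("'peak_power' must be >= 0")
  structure(list(bandwidth = bandwidth,
                 central_frequency = central_frequency,
                 peak_power = peak_power, mean = 0),
            class = "signal_spec")
}

#' Power spectrum of a rate-coded signal
#'
#' Evaluates the two-sided spectral density of the Gaussian-spectrum signal
#' described by a [signal_spec()] on a frequency grid. The density is
#' symmetric in `f`; it may be evaluated on either sign of `f`.
#'
#' @param spec A [signal_spec()].
#' @param freq Frequency grid (Hz).
#' @return Numeric vector of spectral densities (Hz).
#' @export
signal_spectrum <- function(spec, freq) {
  stopifnot(inherits(spec, "signal_spec"))
  b <- spec$bandwidth; f0 <- spec$central_frequency
  spec$peak_power * (exp(-(freq - f0)^2 / (2 * b^2)) +
                     exp(-(freq + f0)^2 / (2 * b^2)))
}

#' Default synapse and input parameters
#'
#' Loads the packaged defaults (a plain JSON file under `extdata/`) used by
#' all experiment recipes unless overridden: a 10-site synapse with release
#' probability 0.5, 0.5 s recovery, 2 ms AMPA kernel, driven at 20 Hz with
#' pairwise input correlation 0.1, and a rate-coded signal of bandwidth
#' 0.1 Hz and peak power 20 Hz.
#'
#' @return A list with components `params` (a [synapse_params()]), `rate`
#'   (Hz), `correlation`, and `signal` (a [signal_spec()]).
#' @export
default_synapse_params <- function() {
  path <- system.file("extdata", "default_params.json",
                      package = "stpfilter", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    params = synapse_params(cfg$n_sites, cfg$p_release, cfg$tau_rec,
                            cfg$tau_syn),
    rate = cfg$rate,
    correlation = cfg$correlation,
    signal = signal_spec(cfg$signal$bandwidth, cfg$signal$central_frequency,
                         cfg$signal$peak_power)
  )
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("Depressing synapse parameters\n")
  cat(sprintf("  release sites      : %d\n", x$n_sites))
  cat(sprintf("  release probability: %.3g\n", x$p_release))
  cat(sprintf("  recovery tau (s)   : %.3g\n", x$tau_rec))
  cat(sprintf("  kernel tau_syn (s) : %.3g (unit-area exponential)\n",
              x$kernel$tau_syn))
  invisible(x)
}

#' @export
print.signal_spec <- function(x, ...) {
  cat(sprintf(
    "Gaussian-spectrum rate signal: peak %.3g Hz at %.3g Hz, bandwidth %.3g Hz\n",
    x$peak_power, x$central_frequency, x$bandwidth))
  invisible(x)
}

# shared validation helper
check_rate <- function(rate) {
  if (length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("'rate' must be a single nonnegative number (Hz)")
  rate
}
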