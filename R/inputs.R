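#' Presynaptic spike train
#'
#' A realization of a point process: strictly increasing event times on
#' `[0, duration)`.
#'
#' @param times Numeric vector of event times (s), sorted, in
#'   `[0, duration)`.
#' @param duration Total observation time T (s).
#' @return An object of class `spike_train` with fields `times` and
#'   `duration`.
#' @export
spike_train <- function(times, duration) {
  if (!is.finite(duration) || duration <= 0)
    stop("'duration' must be > 0")
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop("spike times must be finite")
  if (is.unsorted(times, strictly = FALSE))
    stop("spike times must be sorted")
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration))
    stop("spike times must lie in [0, duration)")
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d events over %.4g s (rate %.4g Hz)\n",
              length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Simulate a homogeneous Poisson spike train
#'
#' @param rate Firing rate (Hz), >= 0.
#' @param duration Simulated time (s), > 0.
#' @param seed Optional integer seed; the same seed reproduces the train
#'   bit-for-bit.
#' @return A [spike_train()].
#' @examples
#' x <- simulate_poisson(20, 10, seed = 1)
#' @export
simulate_poisson <- function(rate, duration, seed = NULL) {
  check_rate(rate)
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, rate * duration)
  spike_train(sort(stats::runif(n, 0, duration)), duration)
}

#' Simulate a population of correlated Poisson spike trains
#'
#' Generates `n` spike trains, each marginally Poisson with the given rate,
#' in which every pair shares a proportion `correlation` of its spikes.
#' The construction superimposes a common Poisson train of rate
#' `correlation * rate`, copied into every member, with an independent
#' private train of rate `(1 - correlation) * rate` per member. Shared
#' spikes are exactly coincident (no jitter), so the pairwise
#' cross-spectrum is flat at `correlation * rate` and the long-window
#' spike-count correlation equals `correlation`.
#'
#' @param rate Common firing rate (Hz).
#' @param correlation Pairwise shared-spike fraction `c` in `[0, 1]`.
#' @param n Number of trains, >= 1.
#' @param duration Simulated time (s).
#' @param seed Optional integer seed.
#' @return An object of class `population_input`: a list with `trains` (a
#'   list of [spike_train()]), `rate` and `correlation`.
#' @export
simulate_correlated_population <- function(rate, correlation, n, duration,
                                           seed = NULL) {
  check_rate(rate)
  if (!is.finite(correlation) || correlation < 0 || correlation > 1)
    stop("'correlation' must be in [0, 1]")
  if (!is.finite(n) || n < 1 || n != round(n)) stop("'n' must be an integer >= 1")
  if (!is.null(seed)) set.seed(seed)
  common <- simulate_poisson(correlation * rate, duration)
  trains <- lapply(seq_len(n), function(i) {
    private <- simulate_poisson((1 - correlation) * rate, duration)
    spike_train(sort(c(common$times, private$times)), duration)
  })
  structure(list(trains = trains, rate = rate, correlation = correlation),
            class = "population_input")
}

#' @export
print.population_input <- function(x, ...) {
  cat(sprintf(
    "Population input: %d Poisson trains at %.4g Hz, pairwise correlation %.3g\n",
    length(x$trains), x$rate, x$correlation))
  invisible(x)
}

#' Signal trace on a uniform grid
#'
#' @param values Signal samples (Hz, since the signal modulates a firing
#'   rate).
#' @param dt Grid step (s).
#' @param duration Total duration (s); `length(values)` must equal
#'   `round(duration / dt)`.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(values, dt, duration) {
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (length(values) != round(duration / dt))
    stop("length(values) must equal round(duration / dt)")
  structure(list(values = as.numeric(values), dt = dt, duration = duration),
            class = "signal_trace")
}

#' Synthesize a Gaussian-spectrum signal
#'
#' Draws a stationary Gaussian trace whose power spectrum equals the
#' Gaussian-shaped target of the [signal_spec()] at the grid resolution.
#' Synthesis is by frequency-domain sampling: independent complex Gaussian
#' Fourier coefficients are scaled by the square root of the target
#' spectrum and inverse-transformed, giving a circularly stationary
#' (periodic) trace whose expected periodogram matches the target exactly
#' and whose variance equals the integral of the spectrum over frequency.
#'
#' @param spec A [signal_spec()].
#' @param duration Trace duration (s); should be much longer than
#'   `1 / bandwidth` for spectral accuracy.
#' @param dt Grid step (s); the central frequency must be below the Nyquist
#'   frequency `1 / (2 dt)`.
#' @param seed Optional integer seed.
#' @return A [signal_trace()].
#' @export
synthesize_signal <- function(spec, duration, dt = 0.001, seed = NULL) {
  stopifnot(inherits(spec, "signal_spec"))
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (spec$central_frequency >= 1 / (2 * dt))
    stop("grid too coarse: central_frequency exceeds the Nyquist frequency")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  if (n < 2) stop("'duration' must cover at least two grid steps")
  if (spec$peak_power == 0)
    return(signal_trace(numeric(n), dt, duration))
  freq <- seq_len(floor(n / 2)) / (n * dt)
  dens <- signal_spectrum(spec, freq)
  x <- complex(length.out = n)
  half <- floor((n - 1) / 2)              # bins with a distinct conjugate
  sd_half <- sqrt(dens[seq_len(half)] * n / (2 * dt))
  re <- stats::rnorm(half, sd = sd_half)
  im <- stats::rnorm(half, sd = sd_half)
  x[1 + seq_len(half)] <- complex(real = re, imaginary = im)
  x[n + 1 - seq_len(half)] <- complex(real = re, imaginary = -im)
  if (n %% 2 == 0)                        # real Nyquist bin
    x[n / 2 + 1] <- stats::rnorm(1, sd = sqrt(dens[n / 2] * n / dt))
  s <- Re(stats::fft(x, inverse = TRUE)) / n
  signal_trace(s, dt, duration)
}

#' Simulate a doubly stochastic (Cox) Poisson spike train
#'
#' Generates a Poisson process whose conditional intensity is
#' `max(rate + s(t), 0)` for a given signal trace `s`, i.e. negative
#' instantaneous rates are clipped to zero. Simulation is by thinning a
#' homogeneous Poisson train at the maximum intensity, with the signal read
#' by nearest-grid lookup, so the construction is exact up to the grid
#' resolution.
#'
#' @param rate Baseline firing rate (Hz), > 0.
#' @param signal A [signal_trace()] modulating the rate.
#' @param seed Optional integer seed.
#' @param duration Optional duration (s); defaults to the signal duration
#'   and must not exceed it.
#' @return A [spike_train()].
#' @export
simulate_doubly_stochastic <- function(rate, signal, seed = NULL,
                                       duration = NULL) {
  if (!is.finite(rate) || rate <= 0) stop("'rate' must be > 0")
  stopifnot(inherits(signal, "signal_trace"))
  if (is.null(duration)) duration <- signal$duration
  if (duration > signal$duration + 1e-12)
    stop("signal grid shorter than requested duration")
  if (!is.null(seed)) set.seed(seed)
  r_max <- rate + max(signal$values, 0)
  if (r_max <= 0) return(spike_train(numeric(0), duration))
  n_cand <- stats::rpois(1L, r_max * duration)
  tt <- sort(stats::runif(n_cand, 0, duration))
  idx <- pmin(pmax(round(tt / signal$dt) + 1L, 1L), length(signal$values))
  intensity <- pmax(rate + signal$values[idx], 0)
  keep <- stats::runif(n_cand) < intensity / r_max
  spike_train(tt[keep], duration)
}
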