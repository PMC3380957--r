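#' Marked vesicle release train
#'
#' The effective synaptic input `z(t) = sum_j k_j delta(t - t_j)`: release
#' events located at presynaptic spike times, each carrying the number of
#' vesicles released (`k_j`). Marks are integers for the stochastic model
#' and nonnegative reals for the deterministic (trial-average) model.
#'
#' @param times Event times (s), sorted.
#' @param marks Vesicles released per event, same length as `times`.
#' @param duration Total time (s).
#' @param n_sites Release-site count used to validate mark bounds
#'   (optional).
#' @return An object of class `release_train`.
#' @export
release_train <- function(times, marks, duration, n_sites = NULL) {
  if (length(times) != length(marks))
    stop("'times' and 'marks' must have equal length")
  if (is.unsorted(times)) stop("'times' must be sorted")
  if (any(marks < 0)) stop("marks must be nonnegative")
  if (!is.null(n_sites) && any(marks > n_sites))
    stop("marks cannot exceed 'n_sites'")
  structure(list(times = as.numeric(times), marks = as.numeric(marks),
                 duration = duration),
            class = "release_train")
}

#' @export
print.release_train <- function(x, ...) {
  cat(sprintf(
    "Release train: %d events over %.4g s, %.4g vesicles released (%.4g /s)\n",
    length(x$times), x$duration, sum(x$marks), sum(x$marks) / x$duration))
  invisible(x)
}

#' Vesicle-count trajectory on a uniform grid
#'
#' @param t Time grid (s).
#' @param v Available vesicle counts at the grid points (integer-valued
#'   step function for the stochastic model, real for the deterministic
#'   model).
#' @return An object of class `vesicle_trajectory`.
#' @export
vesicle_trajectory <- function(t, v) {
  stopifnot(length(t) == length(v))
  structure(list(t = t, v = v), class = "vesicle_trajectory")
}

#' Conductance trace on a uniform grid
#'
#' Conductance is in rescaled units in which the activation kernel has unit
#' area, so the time average of `g` equals the mean vesicle release rate.
#'
#' @param t Time grid (s).
#' @param g Conductance values (>= 0).
#' @param dt Grid step (s).
#' @return An object of class `conductance_trace`.
#' @export
conductance_trace <- function(t, g, dt) {
  stopifnot(length(t) == length(g))
  structure(list(t = t, g = g, dt = dt), class = "conductance_trace")
}

# Event-driven marks for the stochastic model: between consecutive spikes
# each empty site recovers independently with probability 1 - exp(-dt/tau),
# and at a spike each full site releases independently with probability p.
# Returns marks plus (optionally) the exact recovery event times needed to
# render a grid trajectory.
stochastic_events <- function(params, input, keep_recovery_times = TRUE) {
  n <- params$n_sites; p <- params$p_release; tau <- params$tau_rec
  st <- input$times
  v <- n
  marks <- numeric(length(st))
  rec_times <- if (keep_recovery_times) vector("list", length(st) + 1L)
  t_prev <- 0
  for (j in seq_along(st)) {
    gap <- st[j] - t_prev
    empty <- n - v
    if (empty > 0L && gap > 0) {
      if (keep_recovery_times) {
        w <- stats::rexp(empty, rate = 1 / tau)
        rec <- w[w < gap]
        if (length(rec)) {
          rec_times[[j]] <- t_prev + sort(rec)
          v <- v + length(rec)
        }
      } else {
        v <- v + stats::rbinom(1L, empty, 1 - exp(-gap / tau))
      }
    }
    k <- stats::rbinom(1L, v, p)
    marks[j] <- k
    v <- v - k
    t_prev <- st[j]
  }
  # recoveries after the last spike (trajectory only)
  if (keep_recovery_times) {
    empty <- n - v
    gap <- input$duration - t_prev
    if (empty > 0L && gap > 0) {
      w <- stats::rexp(empty, rate = 1 / tau)
      rec <- w[w < gap]
      if (length(rec)) rec_times[[length(st) + 1L]] <- t_prev + sort(rec)
    }
  }
  list(marks = marks, rec_times = rec_times)
}

#' Simulate the stochastic model of vesicle dynamics
#'
#' Event-driven, exact simulation: at each presynaptic spike the number of
#' vesicles released is binomial with the pre-spike availability and
#' per-site probability `p_release` (the availability is updated
#' immediately after the spike); between spikes every empty site recovers
#' after an independent exponential waiting time with mean `tau_rec`. No
#' time-stepping error is incurred; the grid only renders the trajectory.
#'
#' @param params A [synapse_params()].
#' @param input A [spike_train()].
#' @param seed Optional integer seed.
#' @param grid_dt Grid step (s) for the returned trajectory.
#' @param trajectory If `FALSE`, skip the vesicle trajectory (faster; exact
#'   recovery counts are then drawn from their binomial law directly).
#' @return A list with `release` (a [release_train()]) and `trajectory` (a
#'   [vesicle_trajectory()], or `NULL`).
#' @export
simulate_stochastic <- function(params, input, seed = NULL, grid_dt = 0.001,
                                trajectory = TRUE) {
  stopifnot(inherits(params, "synapse_params"), inherits(input, "spike_train"))
  if (!is.null(seed)) set.seed(seed)
  ev <- stochastic_events(params, input, keep_recovery_times = trajectory)
  rel <- release_train(input$times, ev$marks, input$duration, params$n_sites)
  traj <- NULL
  if (trajectory) {
    rec <- unlist(ev$rec_times, use.names = FALSE)
    if (is.null(rec)) rec <- numeric(0)
    ev_t <- c(input$times, rec)
    ev_dv <- c(-ev$marks, rep(1, length(rec)))
    o <- order(ev_t)
    ev_t <- ev_t[o]; ev_dv <- ev_dv[o]
    grid <- seq(0, input$duration, by = grid_dt)
    vstep <- params$n_sites + cumsum(ev_dv)
    idx <- findInterval(grid, ev_t)
    vg <- ifelse(idx == 0L, params$n_sites, vstep[pmax(idx, 1L)])
    traj <- vesicle_trajectory(grid, vg)
  }
  list(release = rel, trajectory = traj)
}

#' Simulate the deterministic (trial-average) model of vesicle dynamics
#'
#' Treats the vesicle count as a continuous variable: each presynaptic
#' spike releases the fraction `p_release` of the currently available
#' vesicles, and between spikes the availability relaxes exponentially back
#' to `n_sites` with time constant `tau_rec`. The recursion is evaluated in
#' closed form at the spike times, so the result is exact and fully
#' reproducible. For a frozen input this model equals the trial average of
#' the stochastic model.
#'
#' @param params A [synapse_params()].
#' @param input A [spike_train()].
#' @param grid_dt Grid step (s) for the returned trajectory; `NULL` skips
#'   the trajectory.
#' @return A list with `release` (real-marked [release_train()]) and
#'   `trajectory` (a [vesicle_trajectory()], or `NULL`).
#' @export
simulate_deterministic <- function(params, input, grid_dt = 0.001) {
  stopifnot(inherits(params, "synapse_params"), inherits(input, "spike_train"))
  n <- params$n_sites; p <- params$p_release; tau <- params$tau_rec
  st <- input$times
  m <- length(st)
  marks <- numeric(m)
  v_post <- numeric(m)                 # availability just after each spike
  v <- n
  t_prev <- 0
  for (j in seq_len(m)) {
    v <- n + (v - n) * exp(-(st[j] - t_prev) / tau)
    marks[j] <- p * v
    v <- (1 - p) * v
    v_post[j] <- v
    t_prev <- st[j]
  }
  rel <- release_train(st, marks, input$duration, n)
  traj <- NULL
  if (!is.null(grid_dt)) {
    grid <- seq(0, input$duration, by = grid_dt)
    idx <- findInterval(grid, st)
    v0 <- c(n, v_post)[idx + 1L]
    t0 <- c(0, st)[idx + 1L]
    traj <- vesicle_trajectory(grid, n + (v0 - n) * exp(-(grid - t0) / tau))
  }
  list(release = rel, trajectory = traj)
}

#' Convolve a release train with the conductance kernel
#'
#' Renders `g(t) = sum_j k_j alpha(t - t_j)` on a uniform grid, with
#' `alpha(t) = step(t) exp(-t / tau_syn) / tau_syn`. Marks are binned to
#' the nearest grid point and convolved with the sampled kernel by FFT with
#' zero padding (no circular wrap-around). The sampled kernel is
#' renormalized to unit area so that the time average of `g` equals the
#' mean release rate regardless of the grid step.
#'
#' @param release A [release_train()].
#' @param kernel A [kernel_spec()] (or a [synapse_params()], whose kernel
#'   is used).
#' @param grid_dt Grid step (s); must satisfy `grid_dt <= tau_syn / 5` to
#'   resolve the kernel.
#' @return A [conductance_trace()].
#' @export
release_to_conductance <- function(release, kernel, grid_dt = 0.0004) {
  stopifnot(inherits(release, "release_train"))
  if (inherits(kernel, "synapse_params")) kernel <- kernel$kernel
  stopifnot(inherits(kernel, "kernel_spec"))
  tau <- kernel$tau_syn
  if (grid_dt > tau / 5 + 1e-12)
    stop("grid too coarse: 'grid_dt' must be <= tau_syn / 5")
  nbins <- round(release$duration / grid_dt)
  grid <- (seq_len(nbins) - 1L) * grid_dt
  mass <- numeric(nbins)
  if (length(release$times)) {
    bins <- pmin(pmax(round(release$times / grid_dt) + 1L, 1L), nbins)
    agg <- rowsum(release$marks, bins)
    mass[as.integer(rownames(agg))] <- agg[, 1L]
  }
  klen <- min(nbins, ceiling(12 * tau / grid_dt))
  kern <- exp(-(seq_len(klen) - 1L) * grid_dt / tau) / tau
  kern <- kern / (sum(kern) * grid_dt)   # enforce unit area after sampling
  g <- fft_convolve(mass, kern)[seq_len(nbins)]
  conductance_trace(grid, pmax(g, 0), grid_dt)
}

# linear (zero-padded) convolution via FFT
fft_convolve <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nfft <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                stats::fft(c(y, numeric(nfft - length(y)))),
                inverse = TRUE))[seq_len(n)] / nfft
}

#' Trial-averaged conductance for a frozen input
#'
#' Presents the identical presynaptic spike train to `n_trials`
#' independent realizations of the stochastic model and averages the
#' resulting conductances pointwise. As the number of trials grows the
#' average converges to the deterministic model's trace, whose vesicle
#' update rule is exactly the conditional expectation of the stochastic
#' one.
#'
#' @param params A [synapse_params()].
#' @param frozen_input A [spike_train()] presented on every trial.
#' @param n_trials Number of independent stochastic trials, >= 1.
#' @param seed Optional integer seed.
#' @param grid_dt Conductance grid step (s).
#' @return A [conductance_trace()] whose `g` is the trial mean, with extra
#'   fields `se` (pointwise standard error of the mean) and `n_trials`.
#' @export
trial_average_conductance <- function(params, frozen_input, n_trials,
                                      seed = NULL, grid_dt = 0.0004) {
  stopifnot(inherits(params, "synapse_params"),
            inherits(frozen_input, "spike_train"))
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  acc <- acc2 <- NULL
  tgrid <- NULL
  for (i in seq_len(n_trials)) {
    sim <- simulate_stochastic(params, frozen_input, grid_dt = grid_dt,
                               trajectory = FALSE)
    tr <- release_to_conductance(sim$release, params$kernel, grid_dt)
    if (is.null(acc)) {
      acc <- tr$g; acc2 <- tr$g^2; tgrid <- tr$t
    } else {
      acc <- acc + tr$g; acc2 <- acc2 + tr$g^2
    }
  }
  mean_g <- acc / n_trials
  out <- conductance_trace(tgrid, mean_g, grid_dt)
  if (n_trials > 1) {
    var_g <- pmax(acc2 / n_trials - mean_g^2, 0) * n_trials / (n_trials - 1)
    out$se <- sqrt(var_g / n_trials)
  } else {
    out$se <- rep(NA_real_, length(mean_g))
  }
  out$n_trials <- n_trials
  out
}
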