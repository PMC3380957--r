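#' Bin a spike train onto a uniform grid
#'
#' Counts events per bin with the assignment `floor(t / dt)` (bin `b`
#' covers `[b dt, (b+1) dt)`). Dividing the counts by `dt` gives the
#' intensity series used for spectral estimation.
#'
#' @param train A [spike_train()] or [release_train()]; for a release
#'   train the marks are summed per bin instead of the event count.
#' @param dt Bin width (s), > 0.
#' @return Numeric vector of counts (or summed marks), with attribute
#'   `dt`.
#' @export
bin_train <- function(train, dt) {
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  stopifnot(inherits(train, "spike_train") || inherits(train, "release_train"))
  nbins <- round(train$duration / dt)
  counts <- numeric(nbins)
  if (length(train$times)) {
    bins <- pmin(floor(train$times / dt) + 1L, nbins)
    w <- if (inherits(train, "release_train")) train$marks
         else rep(1, length(train$times))
    agg <- rowsum(w, bins)
    counts[as.integer(rownames(agg))] <- agg[, 1L]
  }
  attr(counts, "dt") <- dt
  counts
}

#' Welch cross-spectral estimate
#'
#' Averaged cross- and auto-spectra of two series on a shared uniform
#' grid, using Hann-windowed overlapping segments with per-segment mean
#' removal (the spectra estimated are those of the fluctuations).
#' Densities follow the two-sided convention displayed on positive
#' frequencies: a binned Poisson train divided by `dt` has a flat spectrum
#' at its rate. Pointwise standard errors of `S_xx`, `S_gg`, `|S_xg|` and
#' the coherence are computed by deleting one segment at a time
#' (jackknife); the raw magnitude-squared coherence carries a positive
#' bias of about `1 / n_segments`, reported as `bias_floor`.
#'
#' @param x,y Numeric series of equal length (e.g. binned counts / `dt`
#'   and a conductance trace).
#' @param dt Sample step (s).
#' @param segment_s Segment length (s); sets the resolution
#'   `1 / segment_s`.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @param ci_level Confidence level for the reported bands.
#' @return An object of class `spectral_estimate` with fields `freq`,
#'   `S_xx`, `S_gg`, `S_xg` (complex), `coherence`, standard errors
#'   (`se_S_xx`, `se_S_gg`, `se_S_xg_mod`, `se_coherence`), `n_segments`,
#'   `bias_floor`, `ci_level`, `z` (the normal quantile used for bands).
#' @export
welch_cross <- function(x, y = x, dt, segment_s = 20, overlap = 0.5,
                        ci_level = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  L <- round(segment_s / dt)
  if (L < 8) stop("segment too short for the sample step")
  if (L > length(x)) stop("series shorter than one segment")
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  nseg <- length(starts)
  if (nseg < 8)
    warning("fewer than 8 segments: confidence bands are unreliable")
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))     # periodic Hann
  norm <- dt / sum(w^2)
  nf <- floor(L / 2)
  freq <- (1:nf) / (L * dt)
  Pxx <- Pyy <- matrix(0, nf, nseg)
  Pxy <- matrix(0i, nf, nseg)
  for (s in seq_len(nseg)) {
    xs <- x[starts[s]:(starts[s] + L - 1L)]
    ys <- y[starts[s]:(starts[s] + L - 1L)]
    X <- stats::fft(w * (xs - mean(xs)))[2:(nf + 1L)]
    Y <- stats::fft(w * (ys - mean(ys)))[2:(nf + 1L)]
    Pxx[, s] <- norm * Mod(X)^2
    Pyy[, s] <- norm * Mod(Y)^2
    Pxy[, s] <- norm * Conj(X) * Y
  }
  sxx <- rowMeans(Pxx); syy <- rowMeans(Pyy); sxy <- rowMeans(Pxy)
  coh <- Mod(sxy)^2 / (sxx * syy)
  # delete-one-segment jackknife
  jk <- function(leave_one) {
    dev <- sweep(leave_one, 1L, rowMeans(leave_one))
    sqrt((nseg - 1) / nseg * rowSums(dev^2))
  }
  lx <- (rowSums(Pxx) - Pxx) / (nseg - 1)
  ly <- (rowSums(Pyy) - Pyy) / (nseg - 1)
  lxy <- (rowSums(Pxy) - Pxy) / (nseg - 1)
  lcoh <- Mod(lxy)^2 / (lx * ly)
  # variance-stabilized scales: log for spectra, atanh(sqrt) for coherence
  atanh_c <- function(v) atanh(sqrt(pmin(pmax(v, 0), 1 - 1e-12)))
  out <- structure(list(
    freq = freq, S_xx = sxx, S_gg = syy, S_xg = sxy, coherence = coh,
    se_S_xx = jk(lx), se_S_gg = jk(ly),
    se_S_xg_mod = jk(Mod(lxy)), se_coherence = jk(lcoh),
    se_log_S_xx = jk(log(pmax(lx, 1e-300))),
    se_log_S_gg = jk(log(pmax(ly, 1e-300))),
    se_log_S_xg_mod = jk(log(pmax(Mod(lxy), 1e-300))),
    se_atanh_coherence = jk(atanh_c(lcoh)),
    n_segments = nseg, bias_floor = 1 / nseg, ci_level = ci_level,
    z = stats::qnorm(1 - (1 - ci_level) / 2)),
    class = "spectral_estimate")
  out
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "Welch estimate: %d frequencies up to %.4g Hz, %d segments (coherence bias floor %.3g)\n",
    length(x$freq), max(x$freq), x$n_segments, x$bias_floor))
  invisible(x)
}

#' Variance rate of windowed release counts
#'
#' Variance of the number of vesicles released in disjoint windows,
#' divided by the window length: an estimator of the release-train power
#' spectrum at zero frequency. In the depleted regime this approaches
#' `n_sites / tau_rec` for the stochastic model (release is gated by the
#' Poisson stream of recovery events) and zero for the deterministic
#' model.
#'
#' @param release A [release_train()].
#' @param window_s Window length (s); the duration should be at least 50
#'   windows.
#' @return Estimated variance per unit time (units of a spectral density).
#' @export
count_variance_rate <- function(release, window_s) {
  stopifnot(inherits(release, "release_train"))
  if (!is.finite(window_s) || window_s <= 0) stop("'window_s' must be > 0")
  nwin <- floor(release$duration / window_s)
  if (nwin < 2) stop("duration too short for two windows")
  if (nwin < 50)
    warning("fewer than 50 windows: variance estimate is unreliable")
  if (!length(release$times)) return(0)
  counts <- numeric(nwin)
  keep <- release$times < nwin * window_s
  bins <- floor(release$times[keep] / window_s) + 1L
  agg <- rowsum(release$marks[keep], bins)
  counts[as.integer(rownames(agg))] <- agg[, 1L]
  stats::var(counts) / window_s
}

#' Information rate from an estimated coherence
#'
#' Applies the linear-information integral to a Welch coherence estimate
#' over a frequency band, after subtracting the `1 / n_segments` estimator
#' bias floor and clipping at zero (raw coherence estimates of
#' independent series sit at the floor, which would otherwise contribute
#' spurious information).
#'
#' @param estimate A [welch_cross()] result.
#' @param band Length-2 frequency interval (Hz) within the estimate's
#'   range.
#' @return Information rate (bits/s).
#' @export
empirical_information_rate <- function(estimate, band = range(estimate$freq)) {
  stopifnot(inherits(estimate, "spectral_estimate"))
  if (length(band) != 2 || band[1] >= band[2]) stop("invalid 'band'")
  if (band[2] > max(estimate$freq) + 1e-9)
    stop("'band' exceeds the Nyquist frequency of the estimate")
  sel <- estimate$freq >= band[1] & estimate$freq <= band[2]
  coh <- pmax(estimate$coherence[sel] - estimate$bias_floor, 0)
  coh <- pmin(coh, 1 - 1e-12)
  linear_information_rate(estimate$freq[sel], coh)
}
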