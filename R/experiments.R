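#' Experiment configuration
#'
#' Bundles everything a pre-built experiment needs: synapse parameters,
#' input statistics, optional rate-coded signal, which model(s) to run,
#' durations, grid steps, estimator settings, seed and output directory.
#' Fully serializable to JSON so any run can be reproduced bit-for-bit
#' from its recorded configuration and seed.
#'
#' @param params A [synapse_params()].
#' @param rate Presynaptic rate (Hz).
#' @param correlation Pairwise input correlation.
#' @param n_population Number of presynaptic trains.
#' @param signal A [signal_spec()] or `NULL`.
#' @param model `"stochastic"`, `"deterministic"` or `"both"`.
#' @param duration Simulated time (s).
#' @param dt Trace grid step (s) for vesicle/signal traces.
#' @param conductance_dt Conductance grid step (s); must resolve the
#'   kernel (`<= tau_syn / 5`).
#' @param seed Integer seed.
#' @param segment_s,overlap Welch estimator settings.
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(params = default_synapse_params()$params,
                              rate = 20, correlation = 0.1,
                              n_population = 1, signal = NULL,
                              model = c("both", "stochastic", "deterministic"),
                              duration = 500, dt = 0.001,
                              conductance_dt = 0.0004, seed = 1L,
                              segment_s = 20, overlap = 0.5,
                              outdir = NULL) {
  model <- match.arg(model)
  structure(list(params = params, rate = rate, correlation = correlation,
                 n_population = n_population, signal = signal, model = model,
                 duration = duration, dt = dt,
                 conductance_dt = conductance_dt, seed = as.integer(seed),
                 segment_s = segment_s, overlap = overlap, outdir = outdir),
            class = "experiment_config")
}

#' Read / write an experiment configuration (JSON)
#'
#' @param config An [experiment_config()].
#' @param path JSON file path.
#' @return `read_experiment_config` returns an [experiment_config()];
#'   `write_experiment_config` returns `path` invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x$params <- list(n_sites = config$params$n_sites,
                   p_release = config$params$p_release,
                   tau_rec = config$params$tau_rec,
                   tau_syn = config$params$kernel$tau_syn)
  if (!is.null(config$signal))
    x$signal <- list(bandwidth = config$signal$bandwidth,
                     central_frequency = config$signal$central_frequency,
                     peak_power = config$signal$peak_power)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- synapse_params(x$params$n_sites, x$params$p_release,
                           x$params$tau_rec, x$params$tau_syn)
  signal <- if (!is.null(x$signal))
    signal_spec(x$signal$bandwidth, x$signal$central_frequency,
                x$signal$peak_power)
  experiment_config(params = params, rate = x$rate,
                    correlation = x$correlation,
                    n_population = x$n_population, signal = signal,
                    model = x$model, duration = x$duration, dt = x$dt,
                    conductance_dt = x$conductance_dt, seed = x$seed,
                    segment_s = x$segment_s, overlap = x$overlap,
                    outdir = x$outdir)
}

#' Agreement between a theory curve and a Welch estimate
#'
#' Fraction of frequency bins in a band where the theoretical value lies
#' inside the estimate's pointwise confidence interval. An agreement
#' fraction of at least `pass_fraction` counts as a pass. The theory curve
#' is interpolated onto the estimate's frequency grid.
#'
#' @param theory_freq,theory_values Theoretical curve (real values:
#'   e.g. `S_gg`, `|S_xg|` or coherence).
#' @param estimate A [welch_cross()] result.
#' @param field Which estimated quantity to compare: `"S_xx"`, `"S_gg"`,
#'   `"S_xg_mod"` or `"coherence"`.
#' @param band Frequency band (Hz) over which to compare.
#' @param pass_fraction Passing threshold on the agreement fraction.
#' @return A list of class `agreement_report`: `fraction`, `pass`,
#'   `n_bins`, `field`, `band`.
#' @export
agreement_report <- function(theory_freq, theory_values, estimate,
                             field = c("coherence", "S_xx", "S_gg",
                                       "S_xg_mod"),
                             band = range(estimate$freq),
                             pass_fraction = 0.9) {
  stopifnot(inherits(estimate, "spectral_estimate"))
  field <- match.arg(field)
  if (!length(theory_freq)) stop("empty frequency grid")
  if (length(theory_freq) != length(theory_values))
    stop("theory grid/value length mismatch")
  sel <- estimate$freq >= band[1] & estimate$freq <= band[2]
  if (!any(sel)) stop("no estimate bins inside 'band'")
  f <- estimate$freq[sel]
  th <- stats::approx(theory_freq, theory_values, xout = f, rule = 2)$y
  est <- switch(field,
                coherence = estimate$coherence[sel],
                S_xx = estimate$S_xx[sel],
                S_gg = estimate$S_gg[sel],
                S_xg_mod = Mod(estimate$S_xg)[sel])
  # compare on a variance-stabilized scale: log for (positive) spectral
  # densities, atanh(sqrt(.)) for coherence; linear fallback where the
  # theory value is nonpositive
  if (field == "coherence") {
    se <- estimate$se_atanh_coherence[sel]
    tr <- function(v) atanh(sqrt(pmin(pmax(v, 0), 1 - 1e-12)))
    inside <- abs(tr(est) - tr(th)) <= estimate$z * se
  } else {
    se_log <- switch(field,
                     S_xx = estimate$se_log_S_xx[sel],
                     S_gg = estimate$se_log_S_gg[sel],
                     S_xg_mod = estimate$se_log_S_xg_mod[sel])
    se_lin <- switch(field,
                     S_xx = estimate$se_S_xx[sel],
                     S_gg = estimate$se_S_gg[sel],
                     S_xg_mod = estimate$se_S_xg_mod[sel])
    ok_pos <- th > 0 & est > 0
    inside <- ifelse(ok_pos,
                     abs(log(pmax(est, 1e-300)) - log(pmax(th, 1e-300))) <=
                       estimate$z * se_log,
                     abs(est - th) <= estimate$z * se_lin)
  }
  frac <- mean(inside)
  structure(list(fraction = frac, pass = frac >= pass_fraction,
                 n_bins = sum(sel), field = field, band = band),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement (%s, %.3g-%.3g Hz): %.1f%% of %d bins inside CI [%s]\n",
              x$field, x$band[1], x$band[2], 100 * x$fraction, x$n_bins,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

# simulate a single synapse end to end and estimate its spectra
simulate_and_estimate <- function(config, model, input = NULL) {
  cfg <- config
  if (is.null(input))
    input <- simulate_poisson(cfg$rate, cfg$duration)
  sim <- if (model == "stochastic")
    simulate_stochastic(cfg$params, input, grid_dt = cfg$dt,
                        trajectory = FALSE)
  else simulate_deterministic(cfg$params, input, grid_dt = NULL)
  g <- release_to_conductance(sim$release, cfg$params$kernel,
                              cfg$conductance_dt)
  xs <- bin_train(input, cfg$conductance_dt) / cfg$conductance_dt
  est <- welch_cross(xs, g$g, cfg$conductance_dt, cfg$segment_s, cfg$overlap)
  list(input = input, release = sim$release, conductance = g, estimate = est)
}

#' Run a pre-built experiment recipe
#'
#' Reproduces the package's figure-level analyses at desk scale: closed
#' form curves overlaid with simulation estimates and machine-readable
#' agreement reports.
#'
#' Recipes:
#' \describe{
#'   \item{`mean-curves`}{Steady-state mean conductance and gain versus
#'     presynaptic rate; simulated means at a few rates.}
#'   \item{`single-coherence`}{Theory and Welch spectra/coherence for one
#'     synapse, both models, with agreement reports and the flatness
#'     statistic (max/min) of the deterministic coherence.}
#'   \item{`param-sweep`}{Population coherence across population sizes at
#'     fixed correlation (including the `c = 0` identity).}
#'   \item{`signal-transfer`}{Signal-conductance coherence and linear
#'     information rate versus the signal's central frequency, both
#'     models.}
#'   \item{`population`}{Population spectra at the default operating
#'     point; reports the interior peak frequency of the total
#'     conductance power spectrum.}
#' }
#'
#' @param name Recipe name (see Details).
#' @param config An [experiment_config()].
#' @return A list of result tables (and agreement reports where
#'   applicable); written as CSV + JSON to `config$outdir` when set.
#' @export
run_experiment <- function(name = c("mean-curves", "single-coherence",
                                    "param-sweep", "signal-transfer",
                                    "population"),
                           config = experiment_config()) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown experiment name: ", name[1]))
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$outdir) &&
      !dir.exists(config$outdir) &&
      !dir.create(config$outdir, recursive = TRUE))
    stop("cannot create output directory ", config$outdir)
  set.seed(config$seed)
  res <- switch(name,
                "mean-curves" = exp_mean_curves(config),
                "single-coherence" = exp_single_coherence(config),
                "param-sweep" = exp_param_sweep(config),
                "signal-transfer" = exp_signal_transfer(config),
                "population" = exp_population(config))
  if (!is.null(config$outdir)) {
    for (nm in names(res$tables))
      utils::write.csv(res$tables[[nm]],
                       file.path(config$outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
    meta <- list(experiment = name, seed = config$seed,
                 duration = config$duration, rate = config$rate,
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(meta, file.path(config$outdir, "run.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}

exp_mean_curves <- function(cfg) {
  rates <- seq(1, 100, by = 1)
  theory <- data.frame(
    rate = rates,
    g_mean = vapply(rates, function(r) steady_state(cfg$params, r)$g_mean,
                    numeric(1)),
    gain = synaptic_gain(cfg$params, rates))
  sim_rates <- c(5, 20, 80)
  sim <- data.frame(rate = sim_rates, g_mean = NA_real_)
  for (i in seq_along(sim_rates)) {
    inp <- simulate_poisson(sim_rates[i], min(cfg$duration, 200))
    s <- simulate_stochastic(cfg$params, inp, trajectory = FALSE)
    g <- release_to_conductance(s$release, cfg$params$kernel,
                                cfg$conductance_dt)
    sim$g_mean[i] <- mean(g$g)
  }
  list(tables = list(mean_curves_theory = theory, mean_curves_sim = sim))
}

exp_single_coherence <- function(cfg) {
  models <- if (cfg$model == "both") c("stochastic", "deterministic")
            else cfg$model
  input <- simulate_poisson(cfg$rate, cfg$duration)
  tables <- list(); reports <- list()
  for (m in models) {
    run <- simulate_and_estimate(cfg, m, input)
    th <- single_synapse_spectra(cfg$params, cfg$rate, run$estimate$freq, m)
    tables[[paste0("coherence_", m)]] <- data.frame(
      f = run$estimate$freq, coherence_theory = th$coherence,
      coherence_est = run$estimate$coherence,
      Sgg_theory = th$S_gg, Sgg_est = run$estimate$S_gg)
    for (fld in c("coherence", "S_gg", "S_xg_mod")) {
      tv <- switch(fld, coherence = th$coherence, S_gg = th$S_gg,
                   S_xg_mod = Mod(th$S_xg))
      reports[[paste(m, fld, sep = "_")]] <-
        agreement_report(th$freq, tv, run$estimate, fld, band = c(0.1, 50))
    }
  }
  fgrid <- seq(0.1, 50, by = 0.05)
  det <- single_synapse_spectra(cfg$params, cfg$rate, fgrid, "deterministic")
  flatness <- max(det$coherence) / min(det$coherence)
  list(tables = tables, reports = reports, flatness = flatness)
}

exp_param_sweep <- function(cfg) {
  fgrid <- c(10^seq(-2, 0, length.out = 30), seq(1.5, 100, by = 0.5))
  sizes <- c(1, 10, 100, 1000, 10000)
  out <- list()
  for (m in c("stochastic", "deterministic"))
    for (np in sizes) {
      sp <- population_spectra(cfg$params, cfg$rate, cfg$correlation, np,
                               fgrid, m)
      out[[length(out) + 1L]] <- data.frame(
        model = m, n = np, f = fgrid, coherence = sp$coherence)
    }
  sweep <- do.call(rbind, out)
  # c = 0 identity: population coherence equals the single-synapse curve
  c0 <- vapply(sizes, function(np) {
    sp <- population_spectra(cfg$params, cfg$rate, 0, np, fgrid,
                             "stochastic")
    s1 <- single_synapse_spectra(cfg$params, cfg$rate, fgrid, "stochastic")
    max(abs(sp$coherence - s1$coherence))
  }, numeric(1))
  list(tables = list(population_sweep = sweep,
                     c0_identity = data.frame(n = sizes, max_dev = c0)))
}

exp_signal_transfer <- function(cfg) {
  sig <- if (is.null(cfg$signal)) default_synapse_params()$signal
         else cfg$signal
  fs_grid <- seq(1, 50, by = 1)
  rows <- list()
  for (m in c("stochastic", "deterministic")) {
    info <- vapply(fs_grid, function(f0) {
      sp <- signal_spec(sig$bandwidth, f0, sig$peak_power)
      fg <- signal_band_grid(f0, sig$bandwidth)
      cur <- signal_transfer_spectra(cfg$params, cfg$rate, sp,
                                     cfg$correlation, cfg$n_population,
                                     fg, m)
      linear_information_rate(fg, cur$coherence_signal)
    }, numeric(1))
    rows[[m]] <- data.frame(model = m, central_frequency = fs_grid,
                            info_rate = info)
  }
  list(tables = list(information_rate = do.call(rbind, rows)))
}

# frequency grid resolving a narrow signal bump at f0 plus broadband tails
signal_band_grid <- function(f0, bandwidth) {
  lo <- max(f0 - 8 * bandwidth, 1e-3)
  sort(unique(c(seq(lo, f0 + 8 * bandwidth, by = bandwidth / 20),
                10^seq(-3, log10(500), length.out = 200))))
}

exp_population <- function(cfg) {
  np <- max(cfg$n_population, 100)
  fgrid <- seq(0.1, 200, by = 0.1)
  tabs <- list()
  peaks <- numeric(0)
  for (m in c("stochastic", "deterministic")) {
    sp <- population_spectra(cfg$params, cfg$rate, cfg$correlation, np,
                             fgrid, m)
    tabs[[paste0("population_", m)]] <- data.frame(
      f = fgrid, Sxx = sp$S_xx, Sxg_mod = Mod(sp$S_xg), Sgg = sp$S_gg,
      coherence = sp$coherence)
    peaks[m] <- fgrid[which.max(sp$S_gg)]
  }
  list(tables = tabs, peak_frequency = peaks)
}

#' Generate small deterministic fixture files
#'
#' Writes a set of small plain-text datasets (a Poisson train, a
#' stochastic release train, a signal trace and a theory curve) used by
#' the test suite and examples. Regeneration with the same seed is
#' byte-identical.
#'
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
make_fixtures <- function(seed = 42L, outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create ", outdir)
  set.seed(seed)
  defs <- default_synapse_params()
  train <- simulate_poisson(defs$rate, 5)
  sim <- simulate_stochastic(defs$params, train, trajectory = FALSE)
  sig <- synthesize_signal(defs$signal, 10, 0.001)
  fgrid <- seq(0.1, 100, by = 0.5)
  th <- single_synapse_spectra(defs$params, defs$rate, fgrid, "stochastic")
  paths <- c(
    train = file.path(outdir, "poisson_train.csv"),
    release = file.path(outdir, "release_train.csv"),
    signal = file.path(outdir, "signal_trace.csv"),
    theory = file.path(outdir, "theory_curves.csv"))
  write_spike_train(train, paths["train"], list(seed = seed, rate = defs$rate))
  write_release_train(sim$release, paths["release"], list(seed = seed))
  utils::write.csv(data.frame(t = (seq_along(sig$values) - 1) * sig$dt,
                              s = sig$values),
                   paths["signal"], row.names = FALSE)
  write_spectra(th, paths["theory"], list(seed = seed))
  invisible(paths)
}
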