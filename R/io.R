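#' Write and read spike trains as plain text
#'
#' Spike trains are stored as a two-column CSV (`train_id`, `time_s`); a
#' JSON sidecar (`<path>.json`) records the duration, rate and seed so a
#' run is reproducible from its outputs.
#'
#' @param x A [spike_train()] or [`population_input`][simulate_correlated_population].
#' @param path Output CSV path.
#' @param metadata Named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(x, path, metadata = list()) {
  if (inherits(x, "spike_train")) x <- list(trains = list(x))
  df <- do.call(rbind, lapply(seq_along(x$trains), function(i)
    data.frame(train_id = i, time_s = x$trains[[i]]$times)))
  if (is.null(df)) df <- data.frame(train_id = integer(), time_s = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(list(duration = x$trains[[1]]$duration,
                 n_trains = length(x$trains)), metadata)
  write_metadata(path, meta)
  invisible(path)
}

#' @rdname write_spike_train
#' @param duration Duration (s) when the sidecar is absent.
#' @export
read_spike_train <- function(path, duration = NULL) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  if (is.null(duration) && file.exists(meta_path))
    duration <- jsonlite::read_json(meta_path)$duration
  if (is.null(duration)) stop("'duration' is required (no JSON sidecar found)")
  trains <- lapply(split(df$time_s, df$train_id),
                   function(tt) spike_train(sort(tt), duration))
  names(trains) <- NULL
  if (length(trains) == 1L) trains[[1]] else trains
}

#' Write a release train as CSV
#'
#' Columns `time_s`, `mark`; JSON sidecar as for [write_spike_train()].
#' @param x A [release_train()].
#' @inheritParams write_spike_train
#' @export
write_release_train <- function(x, path, metadata = list()) {
  stopifnot(inherits(x, "release_train"))
  utils::write.csv(data.frame(time_s = x$times, mark = x$marks), path,
                   row.names = FALSE)
  write_metadata(path, c(list(duration = x$duration), metadata))
  invisible(path)
}

#' Write spectral curves or estimates as CSV
#'
#' Theory curves use columns `f, Sxx, ReSxg, ImSxg, Sgg, coherence`;
#' estimates add `n_segments` and lower/upper confidence bands.
#' @param x A `spectral_curves` or `spectral_estimate` object.
#' @inheritParams write_spike_train
#' @export
write_spectra <- function(x, path, metadata = list()) {
  df <- data.frame(f = x$freq, Sxx = Re(x$S_xx),
                   ReSxg = Re(x$S_xg), ImSxg = Im(x$S_xg),
                   Sgg = Re(x$S_gg), coherence = x$coherence)
  if (inherits(x, "spectral_estimate")) {
    df$coherence_lo <- pmax(x$coherence - x$z * x$se_coherence, 0)
    df$coherence_hi <- pmin(x$coherence + x$z * x$se_coherence, 1)
    df$n_segments <- x$n_segments
  }
  utils::write.csv(df, path, row.names = FALSE)
  write_metadata(path, metadata)
  invisible(path)
}

write_metadata <- function(path, meta) {
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(NULL)
}
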