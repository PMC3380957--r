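test_that("homogeneous Poisson trains have Poisson count statistics", {
  expect_length(simulate_poisson(0, 10, seed = 1)$times, 0)
  expect_error(simulate_poisson(-1, 10), "rate")
  expect_error(simulate_poisson(10, -1), "duration")

  # same seed reproduces the train bit-for-bit
  expect_identical(simulate_poisson(20, 10, seed = 7)$times,
                   simulate_poisson(20, 10, seed = 7)$times)

  set.seed(101)
  counts <- replicate(200, length(simulate_poisson(20, 100)$times))
  expect_lt(abs(mean(counts) - 2000), 15)          # ~3 SE of the mean
  fano <- var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 0.25)

  # inter-event intervals are exponential: KS against the fitted rate
  x <- simulate_poisson(20, 500, seed = 3)
  iei <- diff(x$times)
  ks <- suppressWarnings(ks.test(iei, "pexp", rate = 1 / mean(iei)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a binned Poisson train has a flat spectrum at its rate", {
  x <- simulate_poisson(20, 200, seed = 11)
  xs <- bin_train(x, 0.001) / 0.001
  est <- welch_cross(xs, xs, 0.001, segment_s = 10)
  band <- est$freq >= 0.5 & est$freq <= 100
  expect_within_rel(mean(est$S_xx[band]), 20, 0.05)
  # no trend: low and high halves of the band agree
  lo <- est$freq >= 0.5 & est$freq <= 20
  hi <- est$freq >= 50 & est$freq <= 100
  expect_within_rel(mean(est$S_xx[lo]), mean(est$S_xx[hi]), 0.1)
})

test_that("shared-spike populations have the requested pairwise correlation", {
  expect_error(simulate_correlated_population(20, 1.5, 2, 10), "correlation")

  # c = 1: all trains share every spike
  pop1 <- simulate_correlated_population(20, 1, 3, 50, seed = 5)
  expect_identical(pop1$trains[[1]]$times, pop1$trains[[2]]$times)
  expect_identical(pop1$trains[[1]]$times, pop1$trains[[3]]$times)

  count_corr <- function(pop, win = 1) {
    cts <- sapply(pop$trains, function(tr)
      bin_train(tr, win))
    cor(cts)[upper.tri(cor(cts))]
  }

  # c = 0: independent trains
  set.seed(21)
  cc0 <- mean(replicate(5, count_corr(
    simulate_correlated_population(20, 0, 2, 200))))
  expect_lt(abs(cc0), 0.03)

  # c = 0.1: long-window count correlation matches (60 seeds x 500 s)
  set.seed(22)
  cc <- replicate(60, count_corr(
    simulate_correlated_population(20, 0.1, 2, 500)))
  expect_lt(abs(mean(cc) - 0.1), 0.02)

  # marginals stay Poisson at the nominal rate
  rates <- sapply(pop1$trains, function(tr) length(tr$times) / tr$duration)
  expect_true(all(abs(rates - 20) / 20 < 0.15))

  # shared-spike symmetry: every pair correlates equally
  set.seed(23)
  cc3 <- count_corr(simulate_correlated_population(20, 0.3, 3, 500))
  expect_lt(max(cc3) - min(cc3), 0.05)
})

test_that("synthesized signals match the Gaussian-spectrum target", {
  sp <- signal_spec(bandwidth = 0.1, central_frequency = 5, peak_power = 20)

  expect_identical(
    synthesize_signal(signal_spec(0.1, 5, 0), 10, 0.001, seed = 1)$values,
    numeric(10000))
  expect_error(synthesize_signal(signal_spec(0.1, 600, 20), 10, 0.001),
               "Nyquist")

  # variance equals the integrated spectrum (trapezoid oracle, 50 seeds)
  fg <- seq(-10, 10, by = 0.001)
  dens <- signal_spectrum(sp, fg)
  target_var <- sum(diff(fg) * (dens[-1] + dens[-length(dens)]) / 2)
  set.seed(31)
  vv <- replicate(50, var(synthesize_signal(sp, 100, 0.001)$values))
  expect_within_rel(mean(vv), target_var, 0.05)

  # Welch spectrum peaks at the central frequency with a Gaussian bump
  s <- synthesize_signal(sp, 400, 0.001, seed = 32)
  est <- welch_cross(s$values, s$values, 0.001, segment_s = 40)
  expect_lt(abs(est$freq[which.max(est$S_xx)] - 5), 0.2)
  bump <- est$freq > 4.5 & est$freq < 5.5
  floorband <- est$freq > 8 & est$freq < 20
  expect_gt(mean(est$S_xx[bump]), 20 * mean(est$S_xx[floorband]))
})

test_that("doubly stochastic trains obey the rectified-intensity model", {
  # zero signal degenerates to homogeneous Poisson
  zero <- signal_trace(numeric(10000), 0.001, 10)
  set.seed(41)
  counts <- replicate(100, length(simulate_doubly_stochastic(20, zero)$times))
  expect_lt(abs(mean(counts) - 200), 5)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.4)

  # fully rectified: large negative signal silences the train
  neg <- signal_trace(rep(-30, 10000), 0.001, 10)
  expect_length(simulate_doubly_stochastic(20, neg, seed = 2)$times, 0)

  # requesting more time than the signal covers is an error
  expect_error(simulate_doubly_stochastic(20, zero, duration = 11),
               "shorter")

  # rectification bias is second order: mean rate within 1%
  sp <- signal_spec(0.1, 5, 20)
  set.seed(43)
  tot <- 0; dur <- 0
  for (i in 1:40) {
    s <- synthesize_signal(sp, 200, 0.001)
    tot <- tot + length(simulate_doubly_stochastic(20, s)$times)
    dur <- dur + 200
  }
  expect_within_rel(tot / dur, 20, 0.01)
})
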