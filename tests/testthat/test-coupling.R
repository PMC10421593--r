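test_that("EPSP detector finds all programmed events and nothing in noise", {
  set.seed(31)
  dt <- 0.1
  flat <- voltage_trace(-70 + rnorm(2e4, 0, 0.5), dt)
  expect_equal(nrow(detect_epsps(flat, 3, kinetics = FALSE)), 0)
  # 29 events of 13.1 mV over 50 s at threshold 3 mV
  tr <- synthetic_epsp_train(n_events = 29, amp = 13.1, noise_sd = 0.5,
                             seed = 7)
  ev <- detect_epsps(tr$trace, 3, kinetics = FALSE)
  expect_equal(nrow(ev), 29)
  expect_equal(median(ev$amplitude_mV), 13.1, tolerance = 0.1)
  expect_equal(ev$onset_ms, tr$onsets, tolerance = 2 / min(tr$onsets))
})

test_that("events closer than the separation rule are merged", {
  dt <- 0.1
  tau_r <- cavprime:::solve_rise_tau(1.8, 19.9)
  kt <- seq(0, 150, by = dt)
  k <- cavprime:::epsp_kernel(kt, tau_r, 19.9)
  x <- rep(0, 5000)
  for (on in c(200, 210)) {            # onsets 1 ms apart
    i0 <- on / dt + 1
    idx <- i0:min(5000, i0 + length(k) - 1)
    x[idx] <- x[idx] + 10 * k[seq_along(idx)]
  }
  ev <- detect_epsps(voltage_trace(-70 + x, dt), 3, min_separation_ms = 5,
                     kinetics = FALSE)
  expect_equal(nrow(ev), 1)
})

test_that("event kinetics reflect the generating rise and decay", {
  tr <- synthetic_epsp_train(n_events = 10, amp = 13.1, noise_sd = 0,
                             rise = 1.8, decay = 19.9)
  ev <- detect_epsps(tr$trace, 3)
  expect_equal(median(ev$rise_10_90_ms, na.rm = TRUE), 1.8, tolerance = 0.3)
  expect_equal(median(ev$decay_tau_ms, na.rm = TRUE), 19.9, tolerance = 0.5)
})

test_that("matching pairs somatic events with axonal peaks", {
  # identical traces: every event matches itself with zero lag and CR 1
  tr <- synthetic_epsp_train(n_events = 10, amp = 10, noise_sd = 0)
  ev <- detect_epsps(tr$trace, 3, kinetics = FALSE)
  pairs <- match_events(ev, tr$trace, 10)
  expect_equal(nrow(pairs), nrow(ev))
  expect_true(all(abs(pairs$lag_ms) <= 0.1 + 1e-9))
  cr <- coupling_ratio(pairs)
  expect_equal(cr$mean, 1, tolerance = 0.01)
  # flat axonal trace: nothing matches
  flat <- voltage_trace(rep(-70, length(tr$trace$V)), tr$trace$dt)
  pairs0 <- match_events(ev, flat, 10)
  expect_equal(nrow(pairs0), 0)
  expect_equal(attr(pairs0, "n_unmatched"), nrow(ev))
})

test_that("coupling ratio matches amplitude arithmetic and gain invariance", {
  # programmed axonal/somatic amplitudes 7.8 / 13.1 give CR ~ 0.60
  g <- generate_paired_traces(pair_generator_spec(seed = 3, noise_sd_mV = 0))
  ev <- detect_epsps(g$recording$soma, 3, kinetics = FALSE)
  pairs <- match_events(ev, g$recording$bouton, 10)
  cr <- coupling_ratio(pairs)
  expect_equal(cr$mean, 0.6, tolerance = 0.001)
  expect_equal(median(pairs$lag_ms), 2.33, tolerance = 0.11)
  # multiplying both channels by a common gain leaves CR unchanged,
  # and adding a common offset leaves CR and lag unchanged
  gain <- function(v, a, b) voltage_trace(a * (v$V + 70) - 70 + b, v$dt)
  soma2 <- gain(g$recording$soma, 2, 5)
  bout2 <- gain(g$recording$bouton, 2, 5)
  ev2 <- detect_epsps(soma2, 3 * 2, kinetics = FALSE)
  pairs2 <- match_events(ev2, bout2, 10)
  expect_equal(coupling_ratio(pairs2)$mean, cr$mean, tolerance = 1e-6)
  expect_equal(median(pairs2$lag_ms), median(pairs$lag_ms), tolerance = 1e-9)
})

test_that("DC coupling arithmetic scales a somatic step by the ratio", {
  expect_identical(dc_coupling_prediction(20, 0.7), 14)
  expect_equal(dc_coupling_prediction(c(10, 20), 0.6), c(6, 12))
  expect_error(dc_coupling_prediction(20, 1.6),
               class = "cavprime_invalid_input")
})

test_that("cross-correlation lag recovers a programmed shift antisymmetrically", {
  tr <- synthetic_epsp_train(n_events = 8, amp = 10, noise_sd = 0.2,
                             seed = 12)
  x <- tr$trace
  shift <- round(2.33 / x$dt)
  y <- voltage_trace(c(rep(-70, shift), x$V[1:(length(x$V) - shift)]), x$dt)
  expect_equal(cross_correlation_lag(x, x), 0)
  expect_equal(cross_correlation_lag(x, y), 2.33, tolerance = x$dt / 2.33)
  expect_equal(cross_correlation_lag(y, x), -cross_correlation_lag(x, y))
  flat <- voltage_trace(rep(-70, length(x$V)), x$dt)
  expect_error(cross_correlation_lag(x, flat),
               class = "cavprime_undefined_ratio")
})

test_that("cell-attached spike metrics read width and amplitude peak to peak", {
  g <- generate_ca_spike_train(width_us = 620, rate_Hz = 100,
                               duration_s = 0.3, noise_sd = 0, seed = 2)
  sp <- ca_spike_metrics(g$trace)
  expect_equal(nrow(sp), nrow(g$truth))
  expect_true(all(sp$width_us == 620))
  # mature-like spikes at 45% of the immature width
  g2 <- generate_ca_spike_train(width_us = 280, rate_Hz = 100,
                                duration_s = 0.3, noise_sd = 0, seed = 2)
  sp2 <- ca_spike_metrics(g2$trace)
  expect_true(all(sp2$width_us == 280))
  # amplitude is invariant under a baseline offset
  off <- current_trace(g$trace$I + 3, g$trace$dt)
  sp3 <- ca_spike_metrics(off)
  expect_equal(sp3$amplitude, sp$amplitude, tolerance = 1e-9)
  expect_equal(sp3$width_us, sp$width_us)
})

test_that("detection and matching recover programmed events at SNR >= 5", {
  # axonal amplitude ~7.8 mV over 1.5 mV noise (SNR ~5 on the weaker channel)
  g <- generate_paired_traces(pair_generator_spec(seed = 9,
                                                  noise_sd_mV = 1.5))
  ev <- detect_epsps(g$recording$soma, 3, kinetics = FALSE)
  pairs <- match_events(ev, g$recording$bouton, 10)
  expect_gte(nrow(pairs), ceiling(0.95 * nrow(g$truth)))
  # the cable physics encoded by the generator survives the pipeline:
  # axonal events are smaller than somatic ones
  expect_lt(coupling_ratio(pairs)$mean, 1)
})

test_that("axonal events rise more slowly than somatic ones on filtered pairs", {
  g <- generate_paired_traces(pair_generator_spec(seed = 21,
                                                  noise_sd_mV = 0.3))
  ev_s <- detect_epsps(g$recording$soma, 3)
  ev_a <- detect_epsps(g$recording$bouton, 3)
  expect_gt(median(ev_a$rise_10_90_ms, na.rm = TRUE),
            median(ev_s$rise_10_90_ms, na.rm = TRUE))
  expect_lt(median(ev_a$amplitude_mV), median(ev_s$amplitude_mV))
})
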