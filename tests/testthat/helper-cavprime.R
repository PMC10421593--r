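# shared fixtures: everything is generated in code at test time

default_params <- function() cav_params()

# a current trace that is exactly A*(1 - exp(-t/tau)) inward on a step,
# for exercising the tau fitter against a known closed form
synthetic_rise_trace <- function(tau, A = 5, dt = 0.01, pre = 5, dur = 25) {
  t_pre <- rep(0, round(pre / dt))
  t <- seq(0, dur, by = dt)
  I <- c(t_pre, -A * (1 - exp(-t / tau)))
  current_trace(I, dt)
}

# deterministic train of identical EPSP-like events on a flat baseline
synthetic_epsp_train <- function(n_events = 29, amp = 13.1, duration_ms = 5e4,
                                 dt = 0.1, rise = 1.8, decay = 19.9,
                                 v_rest = -70, noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- round(duration_ms / dt)
  onsets <- seq(200, duration_ms - 200, length.out = n_events)
  tau_r <- cavprime:::solve_rise_tau(rise, decay)
  kt <- (seq_len(round(8 * decay / dt)) - 1) * dt
  k <- cavprime:::epsp_kernel(kt, tau_r, decay)
  x <- rep(0, n)
  for (on in onsets) {
    i0 <- round(on / dt) + 1L
    idx <- i0:min(n, i0 + length(k) - 1L)
    x[idx] <- x[idx] + amp * k[seq_along(idx)]
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  list(trace = voltage_trace(v_rest + x, dt), onsets = onsets,
       peak_offset = cavprime:::kernel_peak_time(tau_r, decay))
}
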