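# Seeded generators for every input class the analyses consume.  Each
# generator returns its ground truth so that every pipeline stage has a
# closed generate -> analyze -> compare loop.

#' Noise specification
#'
#' @param kind `"gaussian-additive"` (level = SD in trace units) or
#'   `"multiplicative-CV"` (level = coefficient of variation).
#' @param level Noise level (>= 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian-additive", "multiplicative-CV"),
                       level = 0) {
  kind <- match.arg(kind)
  if (level < 0) cp_stop("`level` must be >= 0.")
  structure(list(kind = kind, level = level), class = "noise_spec")
}

#' Paired-trace generator specification
#'
#' Defaults mirror a representative young-interneuron soma/bouton pair:
#' spontaneous EPSPs at ~0.58 Hz over 50 s (29 events expected), somatic
#' amplitudes 13.1 +/- 2.0 mV, true per-event coupling ratio 0.6, axonal
#' peak lagging the somatic peak by 2.33 ms, somatic/axonal 10-90% risetimes
#' 1.8/5.7 ms, slow decay taus 19.9/20.4 ms, additive noise SD 0.5 mV.
#'
#' @param duration_s Recording duration (s).
#' @param event_rate_Hz Poisson event rate (Hz).
#' @param somatic_amp_mean,somatic_amp_sd Somatic amplitude distribution
#'   (mV, Gaussian truncated at 0).
#' @param cr_true True per-event axonal/somatic amplitude ratio.
#' @param lag_ms Axonal peak lag behind the somatic peak (ms).
#' @param somatic_rise,axonal_rise 10-90% risetimes (ms).
#' @param somatic_decay,axonal_decay Slow decay taus (ms).
#' @param noise_sd_mV Additive Gaussian noise SD (mV).
#' @param distance_um Soma-bouton path distance (um).
#' @param v_rest Resting potential of both channels (mV).
#' @param dt_ms Sample interval (ms).
#' @param seed Integer seed.
#' @return An object of class `pair_generator_spec`.
#' @export
pair_generator_spec <- function(duration_s = 50, event_rate_Hz = 0.58,
                                somatic_amp_mean = 13.1,
                                somatic_amp_sd = 2.0,
                                cr_true = 0.6, lag_ms = 2.33,
                                somatic_rise = 1.8, somatic_decay = 19.9,
                                axonal_rise = 5.7, axonal_decay = 20.4,
                                noise_sd_mV = 0.5, distance_um = 111.75,
                                v_rest = -70, dt_ms = 0.1, seed = 1L) {
  if (cr_true <= 0 || cr_true > 1) cp_stop("`cr_true` must lie in (0, 1].")
  if (any(c(somatic_rise, somatic_decay, axonal_rise, axonal_decay) <= 0)) {
    cp_stop("all kinetic constants must be > 0.")
  }
  structure(as.list(environment()), class = "pair_generator_spec")
}

#' Generate a synthetic paired soma/bouton recording
#'
#' Poisson event times; somatic events are dual-exponential transients with
#' Gaussian (truncated at 0) amplitudes; the axonal channel carries the same
#' events scaled by `cr_true`, with a slower rise, the matched slow decay,
#' and peaks shifted so that the axonal peak lags the somatic one by
#' `lag_ms`.  Additive Gaussian noise on both channels.  The axonal
#' filtering is phenomenological (scale + shift + slower rise), not a cable
#' solve.
#'
#' @param spec A [pair_generator_spec()].
#' @return A list with `recording` (a [paired_recording()]) and `truth`
#'   (data frame of event onsets, somatic peak times/amplitudes and the
#'   programmed axonal amplitudes).
#' @export
generate_paired_traces <- function(spec = pair_generator_spec()) {
  stopifnot(inherits(spec, "pair_generator_spec"))
  set.seed(spec$seed)
  dt <- spec$dt_ms
  dur_ms <- spec$duration_s * 1000
  n <- round(dur_ms / dt)
  margin <- 150                                  # ms kept free at both ends
  lambda <- spec$event_rate_Hz * spec$duration_s
  n_ev <- rpois(1, lambda)
  if (lambda < 1) cp_warn("expected event count below 1.")
  onsets <- sort(runif(n_ev, margin, dur_ms - margin))
  amps <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    repeat {
      a <- rnorm(1, spec$somatic_amp_mean, spec$somatic_amp_sd)
      if (a > 0) break
    }
    amps[i] <- a
  }

  tau_rs <- solve_rise_tau(spec$somatic_rise, spec$somatic_decay)
  tau_ra <- solve_rise_tau(spec$axonal_rise, spec$axonal_decay)
  klen <- round(8 * max(spec$somatic_decay, spec$axonal_decay) / dt)
  kt <- (seq_len(klen) - 1) * dt
  ks <- epsp_kernel(kt, tau_rs, spec$somatic_decay)
  ka <- epsp_kernel(kt, tau_ra, spec$axonal_decay)
  tp_s <- kernel_peak_time(tau_rs, spec$somatic_decay)
  tp_a <- kernel_peak_time(tau_ra, spec$axonal_decay)
  # place the axonal kernel so its *peak* lags the somatic peak by lag_ms
  ax_shift <- spec$lag_ms + tp_s - tp_a

  soma <- rep(0, n)
  bout <- rep(0, n)
  add_kernel <- function(sig, onset_ms, kernel, amp) {
    i0 <- round(onset_ms / dt) + 1L
    i1 <- min(n, i0 + klen - 1L)
    if (i0 < 1L) return(sig)
    idx <- i0:i1
    sig[idx] <- sig[idx] + amp * kernel[seq_along(idx)]
    sig
  }
  for (i in seq_len(n_ev)) {
    soma <- add_kernel(soma, onsets[i], ks, amps[i])
    bout <- add_kernel(bout, onsets[i] + ax_shift, ka,
                       amps[i] * spec$cr_true)
  }
  soma <- spec$v_rest + soma + rnorm(n, 0, spec$noise_sd_mV)
  bout <- spec$v_rest + bout + rnorm(n, 0, spec$noise_sd_mV)
  truth <- data.frame(onset_ms = onsets,
                      soma_peak_ms = onsets + tp_s,
                      soma_amp_mV = amps,
                      ax_amp_mV = amps * spec$cr_true,
                      lag_ms = rep(spec$lag_ms, n_ev))
  list(recording = paired_recording(voltage_trace(soma, dt),
                                    voltage_trace(bout, dt),
                                    spec$distance_um),
       truth = truth)
}

#' Generate a coupling-ratio versus distance table
#'
#' Distances uniform over `d_range_um`; coupling ratios follow
#' `A * exp(-d / lambda_um)` with optional noise.
#'
#' @param lambda_um True length constant (um).
#' @param A Prefactor (CR extrapolated to distance 0).
#' @param n_cells Number of cells (rows).
#' @param d_range_um `(min, max)` recording distances (um).
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return A data frame of class `distance_cr_table` with columns
#'   `distance_um`, `cr`, `cell`, and the generating parameters attached as
#'   attribute `"truth"`.
#' @export
generate_cr_distance_table <- function(lambda_um = 181, A = 1, n_cells = 25,
                                       d_range_um = c(64.5, 244),
                                       noise = noise_spec("multiplicative-CV",
                                                          0.15),
                                       seed = 1L) {
  if (n_cells < 2) cp_stop("`n_cells` must be >= 2.")
  set.seed(seed)
  d <- sort(runif(n_cells, d_range_um[1], d_range_um[2]))
  cr <- A * exp(-d / lambda_um)
  cr <- apply_noise(cr, noise)
  cr <- pmax(cr, 1e-6)
  out <- data.frame(distance_um = d, cr = cr, cell = seq_len(n_cells))
  class(out) <- c("distance_cr_table", "data.frame")
  attr(out, "truth") <- list(lambda_um = lambda_um, A = A)
  out
}

apply_noise <- function(x, noise) {
  if (noise$level == 0) return(x)
  switch(noise$kind,
         "gaussian-additive" = x + rnorm(length(x), 0, noise$level),
         "multiplicative-CV" = x * (1 + rnorm(length(x), 0, noise$level)))
}

#' Generate a noisy synthetic Ca++ current
#'
#' Simulates the four-sensor model under `stim`, adds noise, and optionally
#' injects a slow transient emulating the GABA-A autoreceptor-like current
#' that rides on recorded bouton Ca++ currents (for testing
#' [isolate_autoreceptor()]).
#'
#' @param params A [cav_params()] object.
#' @param stim A [voltage_trace()] at `params$dt`.
#' @param noise A [noise_spec()]; additive levels are in normalized current
#'   units.
#' @param autoreceptor Optional list with `amplitude` (signed, normalized
#'   units), `onset_ms`, `tau_rise`, `tau_decay` (ms).
#' @param seed Integer seed.
#' @return A list with `trace` (noisy [current_trace()]) and `truth`
#'   (`clean` trace and the injected `autoreceptor` component).
#' @export
generate_noisy_ica <- function(params = cav_params(), stim,
                               noise = noise_spec("gaussian-additive", 0),
                               autoreceptor = NULL, seed = 1L) {
  set.seed(seed)
  sim <- simulate_current(stim, params)
  I <- trace_values(sim$current)
  auto <- rep(0, length(I))
  if (!is.null(autoreceptor)) {
    a <- autoreceptor
    tt <- trace_time(stim) - a$onset_ms
    auto <- a$amplitude * dualexp_kernel(tt, a$tau_rise, a$tau_decay)
  }
  noisy <- apply_noise(I + auto, noise)
  list(trace = current_trace(noisy, stim$dt, t0 = stim$t0),
       truth = list(clean = sim$current,
                    autoreceptor = current_trace(auto + 0, stim$dt,
                                                 t0 = stim$t0)))
}

#' Generate a cell-attached spike train
#'
#' Biphasic extracellular spikes (negative then positive Gaussian lobes)
#' whose extrema are exactly `width_us` apart, at Poisson-like times with an
#' absolute refractory period, plus additive Gaussian noise.
#'
#' @param width_us Peak-to-peak spike width (us); must exceed twice the
#'   sample interval.
#' @param amplitude Peak-to-peak spike amplitude (trace units).
#' @param rate_Hz Mean firing rate (Hz).
#' @param duration_s Trace duration (s).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param dt_ms Sample interval (ms).
#' @param refractory_ms Minimum inter-spike interval (ms).
#' @return A list with `trace` (a [current_trace()]) and `truth` (data frame
#'   of spike times and programmed widths).
#' @export
generate_ca_spike_train <- function(width_us = 620, amplitude = 1,
                                    rate_Hz = 350, duration_s = 0.3,
                                    noise_sd = 0, seed = 1L, dt_ms = 0.02,
                                    refractory_ms = 1.5) {
  if (width_us <= 2 * dt_ms * 1000) {
    cp_stop("`width_us` must exceed twice the sample interval.")
  }
  set.seed(seed)
  dur_ms <- duration_s * 1000
  w_ms <- width_us / 1000
  mean_isi <- 1000 / rate_Hz
  if (mean_isi <= refractory_ms) {
    cp_stop("rate too high for the refractory period.")
  }
  times <- numeric(0)
  t <- 10                                       # ms lead-in
  repeat {
    t <- t + refractory_ms + rexp(1, 1 / (mean_isi - refractory_ms))
    if (t > dur_ms - 10) break
    times <- c(times, t)
  }
  n <- round(dur_ms / dt_ms)
  x <- rep(0, n)
  sig <- w_ms / 4                               # lobes well separated
  half <- round(4 * sig / dt_ms)
  for (tm in times) {
    i_neg <- round(tm / dt_ms) + 1L
    i_pos <- i_neg + round(w_ms / dt_ms)
    for (s in list(c(i_neg, -1), c(i_pos, 1))) {
      i0 <- max(1L, s[1] - half); i1 <- min(n, s[1] + half)
      idx <- i0:i1
      x[idx] <- x[idx] + s[2] * (amplitude / 2) *
        exp(-((idx - s[1]) * dt_ms)^2 / (2 * sig^2))
    }
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  truth <- data.frame(neg_peak_ms = times,
                      width_us = rep(width_us, length(times)))
  list(trace = current_trace(x, dt_ms), truth = truth)
}
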