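#' Steady-state opening and sensor-activation probabilities
#'
#' The steady open probability of the channel is a Boltzmann sigmoid of
#' membrane potential,
#' \deqn{P_{open}(V) = \frac{1}{1 + e^{-\alpha (V - V_{Cav50})}},}
#' and, because the channel conducts only when all four independent voltage
#' sensors are simultaneously active, the steady activation probability of a
#' single sensor is its 1/4th power.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param params A [cav_params()] object.
#' @return Probabilities in (0, 1), same length as `V`.
#' @examples
#' p <- cav_params()
#' steady_open_probability(c(-37, -17, 60), p)
#' steady_sensor_activation(-17, p)^4  # equals steady_open_probability(-17, p)
#' @export
steady_open_probability <- function(V, params = cav_params()) {
  if (!is.numeric(V) || length(V) == 0 || anyNA(V) || any(!is.finite(V))) {
    cp_stop("`V` must be finite membrane potential(s) in mV.")
  }
  1 / (1 + exp(-params$alpha * (V - params$V_Cav50)))
}

#' @rdname steady_open_probability
#' @export
steady_sensor_activation <- function(V, params = cav_params()) {
  steady_open_probability(V, params)^0.25
}

#' Velocity of the sensor state change
#'
#' The relaxation rate of a single voltage sensor towards its steady
#' activation.  The rate is asymmetric: activation proceeds at
#' `k_on * P_steady` when the steady target exceeds the current activation,
#' deactivation at `k_off * (1 - P_steady)` otherwise.  At the tie the
#' activation branch is returned (the drive term is zero there, so the choice
#' has no effect on the dynamics).
#'
#' @param P_act Current single-sensor activation probability.
#' @param P_steady Steady-state activation probability at the present voltage.
#' @param params A [cav_params()] object.
#' @return Rate (per ms), vectorized over the inputs.
#' @export
sensor_velocity <- function(P_act, P_steady, params = cav_params()) {
  check_prob(P_act, "P_act")
  check_prob(P_steady, "P_steady")
  ifelse(P_steady >= P_act,
         params$k_on * P_steady,
         params$k_off * (1 - P_steady))
}

#' One forward-Euler step of the sensor ODE
#'
#' Advances the single-sensor activation probability by one time step `dt`
#' under the voltage of the current sample:
#' `P' = P + dt * v * (P_steady(V) - P)`, clipped to \[0, 1\].
#'
#' @inheritParams sensor_velocity
#' @param V Membrane potential at the current sample (mV).
#' @return Updated activation probability.
#' @export
step_sensor <- function(P_act, V, params = cav_params()) {
  check_prob(P_act, "P_act")
  pss <- steady_sensor_activation(V, params)
  v <- sensor_velocity(P_act, pss, params)
  pmin(1, pmax(0, P_act + params$dt * v * (pss - P_act)))
}

#' Channel state occupancies from the single-sensor activation
#'
#' With four independent, identical sensors the channel occupies one of five
#' states: all sensors resting (a), 1-3 sensors active (b-d, the "primed"
#' closed states), or all four active (open).  The occupancies are the
#' binomial masses for 0..4 active sensors and sum to one.
#'
#' @param P_act Single-sensor activation probability; vectorized.
#' @return For scalar input a named length-5 vector `(P_a, P_b, P_c, P_d,
#'   P_open)`; for vector input a matrix with one row per element.
#' @examples
#' state_occupancies(0.5)
#' @export
state_occupancies <- function(P_act) {
  check_prob(P_act, "P_act")
  p <- P_act
  q <- 1 - p
  m <- cbind(P_a = q^4,
             P_b = 4 * p * q^3,
             P_c = 6 * p^2 * q^2,
             P_d = 4 * p^3 * q,
             P_open = p^4)
  if (length(p) == 1L) m[1L, ] else m
}

# internal: sensor trajectory for a voltage sample vector (no dt validation)
sensor_path <- function(V, params, P_init = "steady") {
  p0 <- if (identical(P_init, "steady")) {
    steady_sensor_activation(V[1L], params)
  } else {
    check_prob(P_init, "P_init")
    as.numeric(P_init)
  }
  cav_sensor_path(V, params$dt, params$V_Cav50, params$alpha,
                  params$k_on, params$k_off, p0)
}

#' Simulate the normalized Ca++ current under a voltage command
#'
#' Integrates the single-sensor ODE along the command with the forward Euler
#' method and applies the instantaneous current equation
#' `I(t) = P_act(t)^4 * (V(t) - E_Ca)` (unit normalized conductance, inward
#' negative, ohmic driving force).
#'
#' @param stim A [voltage_trace()]; its `dt` must equal `params$dt`.
#' @param params A [cav_params()] object.
#' @param P_init Initial single-sensor activation, or `"steady"` to start at
#'   the steady activation for the first command sample.
#' @return A list of class `cav_simulation` with elements `current`
#'   (a [current_trace()]), `P_act` (sensor trajectory) and `occupancy`
#'   (n x 5 state-occupancy matrix).
#' @examples
#' prm <- cav_params()
#' stim <- step_protocol(prm)            # -70 -> 0 mV, 20 ms
#' sim <- simulate_current(stim, prm)
#' min(trace_values(sim$current))        # peak inward current
#' @export
simulate_current <- function(stim, params = cav_params(), P_init = "steady") {
  stopifnot(inherits(stim, "voltage_trace"))
  if (abs(stim$dt - params$dt) > 1e-9 * params$dt) {
    cp_stop("`stim$dt` must equal `params$dt`.", "cavprime_config_error")
  }
  p <- sensor_path(stim$V, params, P_init)
  I <- p^4 * (stim$V - params$E_Ca)
  structure(
    list(current = current_trace(I, stim$dt, t0 = stim$t0),
         P_act = p,
         occupancy = state_occupancies(p)),
    class = "cav_simulation"
  )
}

#' @export
print.cav_simulation <- function(x, ...) {
  cat("Cav model simulation\n")
  print(x$current)
  cat(sprintf("  final P_act = %.4f, peak inward I = %g\n",
              tail(x$P_act, 1), min(trace_values(x$current))))
  invisible(x)
}

#' Steady-state current-voltage relationship
#'
#' Pointwise evaluation of the steady current
#' `I(V) = P_open(V) * (V - E_Ca)` over a voltage grid.
#'
#' @param V_grid Voltages (mV); sorted internally.
#' @param params A [cav_params()] object.
#' @return An `iv_dataset`: a data frame with columns `V` and `I`.
#' @export
steady_iv_curve <- function(V_grid, params = cav_params()) {
  if (length(V_grid) == 0) cp_stop("`V_grid` must not be empty.")
  V <- sort(unique(as.numeric(V_grid)))
  I <- steady_open_probability(V, params) * (V - params$E_Ca)
  iv_dataset(V, I)
}

#' Current-voltage dataset
#'
#' @param V Voltages (mV), strictly increasing.
#' @param I Normalized currents.
#' @param spread Optional per-point spread (e.g. SD across cells).
#' @return A data frame of class `iv_dataset`.
#' @export
iv_dataset <- function(V, I, spread = NULL) {
  if (length(V) != length(I)) cp_stop("`V` and `I` must have equal length.")
  if (is.unsorted(V, strictly = TRUE)) {
    cp_stop("`V` must be strictly increasing.")
  }
  df <- data.frame(V = as.numeric(V), I = as.numeric(I))
  if (!is.null(spread)) df$spread <- as.numeric(spread)
  class(df) <- c("iv_dataset", "data.frame")
  df
}

#' Peak inward amplitude of a current trace
#'
#' Baseline-subtracted peak inward amplitude within an analysis window.  The
#' baseline is the mean current over `baseline_window`, by default the 5 ms
#' immediately preceding the window; the amplitude is
#' `|min(I in window) - baseline|`.
#'
#' @param trace A [current_trace()].
#' @param window `(from, to)` in ms.
#' @param baseline_window Optional `(from, to)` in ms for the baseline mean.
#' @return Peak amplitude (>= 0, normalized units).
#' @export
peak_inward_amplitude <- function(trace, window, baseline_window = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(baseline_window)) {
    baseline_window <- c(window[1] - 5, window[1])
  }
  bidx <- window_index(trace, baseline_window)
  baseline <- mean(trace$I[bidx])
  idx <- window_index(trace, window)
  abs(min(trace$I[idx]) - baseline)
}

#' Augmentation ratio of a test over a control current
#'
#' Ratio of the baseline-subtracted peak inward amplitudes of two simulated
#' (or recorded) Ca++ currents within the same analysis window.  Used to
#' quantify the priming effect of a preceding subthreshold depolarization on
#' the AP-evoked current.
#'
#' @param test,control [current_trace()] objects with equal sampling.
#' @param window `(from, to)` ms window covering the evoked transient.
#' @param baseline_window Optional baseline window (ms); default is the 5 ms
#'   preceding `window`.
#' @return The amplitude ratio test/control (> 0).
#' @export
augmentation_ratio <- function(test, control, window, baseline_window = NULL) {
  stopifnot(inherits(test, "current_trace"),
            inherits(control, "current_trace"))
  if (abs(test$dt - control$dt) > 1e-9 * test$dt) {
    cp_stop("test and control traces must share `dt`.",
            "cavprime_config_error")
  }
  a_test <- peak_inward_amplitude(test, window, baseline_window)
  a_ctrl <- peak_inward_amplitude(control, window, baseline_window)
  if (a_ctrl <= 0 || !is.finite(a_ctrl)) {
    cp_stop("control trace has zero peak amplitude; ratio undefined.",
            "cavprime_undefined_ratio")
  }
  a_test / a_ctrl
}

#' Euler convergence check
#'
#' Re-runs a simulation with the voltage command resampled to a finer step
#' and reports the relative difference of the peak inward current.  The fine
#' reference uses an internal parameter copy whose `dt` may lie below the
#' user-facing range.
#'
#' @param stim A [voltage_trace()] at `params$dt`.
#' @param params A [cav_params()] object.
#' @param refine Integer step-refinement factor (default 10).
#' @param P_init Initial condition, as in [simulate_current()].
#' @return A list with `rel_error` (|peak - peak_ref| / |peak_ref|), `peak`
#'   and `peak_ref`.
#' @export
euler_convergence <- function(stim, params = cav_params(), refine = 10,
                              P_init = "steady") {
  coarse <- simulate_current(stim, params, P_init)
  dtf <- params$dt / refine
  fine_params <- params_replace(params, dt = dtf)
  fine_stim <- resample_trace(stim, dtf)
  fine <- simulate_current(fine_stim, fine_params, P_init)
  pk <- min(trace_values(coarse$current))
  pkr <- min(trace_values(fine$current))
  list(rel_error = abs(pk - pkr) / abs(pkr), peak = pk, peak_ref = pkr)
}
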