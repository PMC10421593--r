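#' Uniformly sampled voltage and current traces
#'
#' Containers for membrane potential commands/recordings (mV) and normalized
#' Ca++ currents (dimensionless conductance times driving force, inward
#' negative).  Both carry a start time `t0` and a sample interval `dt` in ms.
#'
#' @param V,I Numeric sample vector (length >= 2, finite).
#' @param dt Sample interval (ms).
#' @param t0 Time of the first sample (ms).
#' @return An object of class `voltage_trace` or `current_trace`.
#' @examples
#' v <- voltage_trace(rep(-70, 100), dt = 0.01)
#' trace_time(v)[1:3]
#' @export
voltage_trace <- function(V, dt, t0 = 0) {
  new_trace(V, dt, t0, "voltage_trace", "V")
}

#' @rdname voltage_trace
#' @export
current_trace <- function(I, dt, t0 = 0) {
  new_trace(I, dt, t0, "current_trace", "I")
}

new_trace <- function(x, dt, t0, class, field) {
  if (!is.numeric(x) || length(x) < 2L) {
    cp_stop("trace samples must be a numeric vector of length >= 2.")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    cp_stop("trace samples must be finite.")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    cp_stop("`dt` must be a single positive number (ms).")
  }
  out <- list(t0 = as.numeric(t0), dt = as.numeric(dt))
  out[[field]] <- as.numeric(x)
  structure(out, class = c(class, "ephys_trace"))
}

#' Time axis, samples and duration of a trace
#'
#' @param x A `voltage_trace` or `current_trace`.
#' @return `trace_time()` the time of every sample (ms); `trace_values()` the
#'   sample vector; `trace_duration()` the span from first to last sample (ms).
#' @export
trace_time <- function(x) {
  stopifnot(inherits(x, "ephys_trace"))
  x$t0 + x$dt * (seq_along(trace_values(x)) - 1L)
}

#' @rdname trace_time
#' @export
trace_values <- function(x) {
  if (inherits(x, "voltage_trace")) x$V else x$I
}

#' @rdname trace_time
#' @export
trace_duration <- function(x) {
  (length(trace_values(x)) - 1L) * x$dt
}

#' @export
print.ephys_trace <- function(x, ...) {
  kind <- if (inherits(x, "voltage_trace")) "Voltage" else "Current"
  unit <- if (inherits(x, "voltage_trace")) "mV" else "normalized"
  v <- trace_values(x)
  cat(sprintf("%s trace: %d samples, dt = %g ms, t = [%g, %g] ms\n",
              kind, length(v), x$dt, x$t0, x$t0 + (length(v) - 1) * x$dt))
  cat(sprintf("  range [%g, %g] %s\n", min(v), max(v), unit))
  invisible(x)
}

#' @export
as.data.frame.ephys_trace <- function(x, ...) {
  data.frame(time_ms = trace_time(x), value = trace_values(x))
}

# internal: check two traces share sampling (dt, length, t0)
check_same_sampling <- function(a, b, strict_t0 = FALSE) {
  if (abs(a$dt - b$dt) > 1e-9 * a$dt) {
    cp_stop("traces have different sample intervals.", "cavprime_config_error")
  }
  if (length(trace_values(a)) != length(trace_values(b))) {
    cp_stop("traces have different lengths.", "cavprime_config_error")
  }
  if (strict_t0 && abs(a$t0 - b$t0) > 1e-9) {
    cp_stop("traces are not aligned in time.", "cavprime_config_error")
  }
  invisible(TRUE)
}

# internal: index range of a [from, to] ms window (closed on the left)
window_index <- function(x, window) {
  tt <- trace_time(x)
  idx <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  if (length(idx) == 0) {
    cp_stop("analysis window contains no samples.", "cavprime_config_error")
  }
  idx
}

#' Resample a trace onto a new sample interval
#'
#' Linear interpolation onto a uniform grid with step `dt_new`, spanning the
#' same time interval.  Used mainly to build fine-step reference commands for
#' Euler convergence checks.
#'
#' @param x A trace.
#' @param dt_new New sample interval (ms).
#' @return A trace of the same class.
#' @export
resample_trace <- function(x, dt_new) {
  tt <- trace_time(x)
  tnew <- seq(tt[1], tt[length(tt)], by = dt_new)
  vnew <- approx(tt, trace_values(x), xout = tnew)$y
  if (inherits(x, "voltage_trace")) {
    voltage_trace(vnew, dt_new, t0 = x$t0)
  } else {
    current_trace(vnew, dt_new, t0 = x$t0)
  }
}

#' Paired somatic/axonal recording
#'
#' A simultaneous somatic and presynaptic-bouton voltage recording plus the
#' axonal path distance between the two sites.
#'
#' @param soma,bouton `voltage_trace` objects with identical sampling.
#' @param distance_um Soma-center to varicosity path length (micrometers).
#' @return An object of class `paired_recording`.
#' @export
paired_recording <- function(soma, bouton, distance_um) {
  stopifnot(inherits(soma, "voltage_trace"), inherits(bouton, "voltage_trace"))
  check_same_sampling(soma, bouton, strict_t0 = TRUE)
  if (!is.numeric(distance_um) || length(distance_um) != 1L ||
      !is.finite(distance_um) || distance_um <= 0) {
    cp_stop("`distance_um` must be a single positive number.")
  }
  structure(list(soma = soma, bouton = bouton,
                 distance_um = as.numeric(distance_um)),
            class = "paired_recording")
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("Paired soma/bouton recording, distance %g um\n", x$distance_um))
  cat(sprintf("  %d samples at dt = %g ms (%.3f s)\n",
              length(x$soma$V), x$soma$dt,
              trace_duration(x$soma) / 1000))
  invisible(x)
}
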