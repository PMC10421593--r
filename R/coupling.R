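# Analysis of paired somatic/axonal current-clamp traces: threshold EPSP
# detection, soma-bouton event matching, coupling ratios, cross-correlation
# lag, and cell-attached spike metrics.

# centered boxcar smoothing; edges keep the raw samples
smooth_boxcar <- function(x, width_samples) {
  w <- max(1L, as.integer(width_samples))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  bad <- is.na(sm)
  sm[bad] <- x[bad]
  sm
}

#' Detect EPSP-like events in a current-clamp trace
#'
#' Threshold detector: the trace is boxcar-smoothed (0.5 ms), candidate
#' peaks are local maxima exceeding the resting baseline (trace median) by
#' at least `threshold_mV`, peaks closer than `min_separation_ms` are merged
#' (largest kept), and each event's onset is the last sample below
#' `baseline + 0.2 * threshold` before the peak.  Per-event amplitude is the
#' raw peak minus the median of the 10 ms preceding the onset; events whose
#' amplitude falls below threshold after local-baseline subtraction are
#' dropped.
#'
#' @param trace A [voltage_trace()] in mV.
#' @param threshold_mV Detection threshold (mV above baseline).
#' @param min_separation_ms Minimum separation between events (ms).
#' @param smooth_ms Boxcar width used for detection (ms).
#' @param kinetics Also compute the 10-90% risetime and a mono-exponential
#'   decay tau per event.
#' @return A data frame of class `epsp_events` with columns `onset_ms`,
#'   `peak_ms`, `amplitude_mV`, and (with `kinetics`) `rise_10_90_ms`,
#'   `decay_tau_ms`.  Zero rows when nothing crosses threshold.
#' @export
detect_epsps <- function(trace, threshold_mV = 3, min_separation_ms = 5,
                         smooth_ms = 0.5, kinetics = TRUE) {
  stopifnot(inherits(trace, "voltage_trace"))
  dt <- trace$dt
  x <- trace$V
  xs <- smooth_boxcar(x, round(smooth_ms / dt))
  base0 <- median(xs)
  above <- xs >= base0 + threshold_mV

  empty <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      amplitude_mV = numeric(0))
  if (kinetics) {
    empty$rise_10_90_ms <- numeric(0)
    empty$decay_tau_ms <- numeric(0)
  }
  class(empty) <- c("epsp_events", "data.frame")
  if (!any(above)) return(empty)

  # suprathreshold runs; runs separated by less than min_separation belong
  # to the same event (noise briefly dipping below threshold on a decay
  # must not split an event, and genuinely overlapping events merge)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  rs <- starts[runs]
  re <- ends[runs]
  min_sep <- min_separation_ms / dt
  grp <- cumsum(c(1, (rs[-1] - re[-length(re)]) >= min_sep))
  peaks <- vapply(split(seq_along(runs), grp), function(g) {
    i <- rs[g[1]]:re[g[length(g)]]
    i[which.max(xs[i])]
  }, integer(1))

  onset_level <- base0 + 0.2 * threshold_mV
  nb10 <- round(10 / dt)
  rows <- lapply(peaks, function(pk) {
    lo <- max(1L, pk - round(50 / dt))
    below <- which(xs[lo:pk] <= onset_level)
    onset <- if (length(below)) lo + below[length(below)] - 1L else lo
    b0 <- max(1L, onset - nb10)
    baseline <- median(x[b0:onset])
    # raw peak near the smoothed peak
    w1 <- max(1L, pk - round(1 / dt)); w2 <- min(length(x), pk + round(1 / dt))
    praw <- w1 + which.max(x[w1:w2]) - 1L
    amp <- x[praw] - baseline
    if (amp < threshold_mV) return(NULL)
    data.frame(onset_ms = (onset - 1) * dt + trace$t0,
               peak_ms = (praw - 1) * dt + trace$t0,
               amplitude_mV = amp,
               peak_idx = pk, onset_idx = onset, baseline_mV = baseline)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)

  if (kinetics) {
    n_ev <- nrow(out)
    out$rise_10_90_ms <- NA_real_
    out$decay_tau_ms <- NA_real_
    for (i in seq_len(n_ev)) {
      pk <- out$peak_idx[i]; onset <- out$onset_idx[i]
      lev <- out$baseline_mV[i] +
        c(0.1, 0.9) * (xs[pk] - out$baseline_mV[i])
      seg <- xs[onset:pk]
      i90 <- which(seg >= lev[2])[1]
      if (!is.na(i90)) {
        pre <- which(seg[seq_len(i90)] < lev[1])
        i10 <- if (length(pre)) pre[length(pre)] else 1L
        out$rise_10_90_ms[i] <- (i90 - i10) * dt
      }
      # decay window: up to 5 slow time constants, but never into the
      # next event
      dend <- min(length(x), pk + round(100 / dt))
      if (i < n_ev) {
        dend <- min(dend, out$onset_idx[i + 1] - round(2 / dt))
      }
      if (dend - pk > round(5 / dt)) {
        dfit <- suppressWarnings(fit_decay(x[pk:dend], n_exp = 1, dt = dt))
        if (dfit$converged && dfit$estimates[["tau"]] < 500) {
          out$decay_tau_ms[i] <- dfit$estimates[["tau"]]
        }
      }
    }
  }
  out$peak_idx <- out$onset_idx <- out$baseline_mV <- NULL
  class(out) <- c("epsp_events", "data.frame")
  out
}

#' Match somatic events to axonal peaks
#'
#' For each somatic event, finds the axonal peak within
#' `[onset, onset + search_window_ms]` of the (smoothed) bouton trace.  The
#' axonal amplitude is measured against the median of the 10 ms preceding
#' the somatic onset; events whose axonal amplitude falls below
#' `min_amplitude_mV` are dropped and counted as unmatched.
#'
#' @param soma_events An `epsp_events` table from [detect_epsps()].
#' @param bouton_trace The axonal [voltage_trace()].
#' @param search_window_ms Search window after the somatic onset (ms).
#' @param min_amplitude_mV Smallest axonal amplitude accepted as a match.
#' @param smooth_ms Boxcar width for the axonal peak search (ms).
#' @return A data frame of class `matched_pairs` with per-pair somatic and
#'   axonal amplitudes, peak times and `lag_ms` (axonal minus somatic peak
#'   time); the number of unmatched somatic events is attached as attribute
#'   `"n_unmatched"`.
#' @export
match_events <- function(soma_events, bouton_trace, search_window_ms = 10,
                         min_amplitude_mV = 1, smooth_ms = 0.5) {
  stopifnot(inherits(bouton_trace, "voltage_trace"))
  dt <- bouton_trace$dt
  y <- bouton_trace$V
  ys <- smooth_boxcar(y, round(smooth_ms / dt))
  nb10 <- round(10 / dt)
  n_unmatched <- 0L
  rows <- lapply(seq_len(nrow(soma_events)), function(i) {
    ev <- soma_events[i, ]
    i_on <- round((ev$onset_ms - bouton_trace$t0) / dt) + 1L
    i_hi <- min(length(y), i_on + round(search_window_ms / dt))
    if (i_on < 1L || i_on >= i_hi) return(NULL)
    seg <- ys[i_on:i_hi]
    pk <- i_on + which.max(seg) - 1L
    # refine on the raw trace, as detect_epsps does for the somatic peak,
    # so both amplitudes carry the same peak-measurement convention
    w1 <- max(1L, pk - round(1 / dt)); w2 <- min(length(y), pk + round(1 / dt))
    pk <- w1 + which.max(y[w1:w2]) - 1L
    b0 <- max(1L, i_on - nb10)
    baseline <- median(y[b0:i_on])
    amp <- y[pk] - baseline
    if (amp < min_amplitude_mV || pk >= i_hi) return(NULL)
    data.frame(soma_onset_ms = ev$onset_ms, soma_peak_ms = ev$peak_ms,
               soma_amp_mV = ev$amplitude_mV,
               ax_peak_ms = (pk - 1) * dt + bouton_trace$t0,
               ax_amp_mV = amp,
               lag_ms = (pk - 1) * dt + bouton_trace$t0 - ev$peak_ms)
  })
  ok <- !vapply(rows, is.null, logical(1))
  n_unmatched <- sum(!ok)
  rows <- rows[ok]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(soma_onset_ms = numeric(0), soma_peak_ms = numeric(0),
               soma_amp_mV = numeric(0), ax_peak_ms = numeric(0),
               ax_amp_mV = numeric(0), lag_ms = numeric(0))
  class(out) <- c("matched_pairs", "data.frame")
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Soma-to-bouton coupling ratio
#'
#' Per-event coupling ratio (axonal over somatic peak depolarization) with
#' its mean and SD across events.  Events with zero somatic amplitude are
#' excluded with a warning.
#'
#' @param pairs A `matched_pairs` table from [match_events()].
#' @return A list with `cr` (per-event ratios), `mean` and `sd`.
#' @export
coupling_ratio <- function(pairs) {
  if (nrow(pairs) < 1) cp_stop("need at least one matched pair.")
  ok <- pairs$soma_amp_mV != 0
  if (any(!ok)) {
    cp_warn("excluded event(s) with zero somatic amplitude.")
  }
  cr <- pairs$ax_amp_mV[ok] / pairs$soma_amp_mV[ok]
  list(cr = cr, mean = mean(cr), sd = if (length(cr) > 1) sd(cr) else NA_real_)
}

#' Predicted bouton depolarization under DC coupling
#'
#' Arithmetic of steady-state (DC) attenuation: a somatic voltage step of
#' `delta_vm_mV` scaled by the DC coupling ratio.
#'
#' @param delta_vm_mV Somatic depolarization (mV).
#' @param cr DC coupling ratio in (0, 1.5).
#' @return Predicted bouton depolarization (mV).
#' @examples
#' dc_coupling_prediction(20, 0.7)   # 14 mV
#' @export
dc_coupling_prediction <- function(delta_vm_mV, cr) {
  if (!is.numeric(cr) || any(cr <= 0) || any(cr >= 1.5)) {
    cp_stop("`cr` must lie in (0, 1.5).")
  }
  delta_vm_mV * cr
}

#' Cross-correlation lag between somatic and axonal traces
#'
#' Lag maximizing the normalized cross-correlation of the mean-subtracted
#' traces within +/- `max_lag_ms`.  Positive lags mean the bouton lags the
#' soma.
#'
#' @param soma,bouton [voltage_trace()] objects with identical sampling.
#' @param max_lag_ms Maximum |lag| scanned (ms).
#' @return The lag (ms).
#' @export
cross_correlation_lag <- function(soma, bouton, max_lag_ms = 20) {
  check_same_sampling(soma, bouton)
  x <- soma$V - mean(soma$V)
  y <- bouton$V - mean(bouton$V)
  if (var(x) == 0 || var(y) == 0) {
    cp_stop("constant trace: cross-correlation undefined.",
            "cavprime_undefined_ratio")
  }
  dt <- soma$dt
  L <- round(max_lag_ms / dt)
  n <- length(x)
  lags <- -L:L
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      xi <- x[1:(n - k)]; yi <- y[(1 + k):n]
    } else {
      xi <- x[(1 - k):n]; yi <- y[1:(n + k)]
    }
    sum(xi * yi) / sqrt(sum(xi^2) * sum(yi^2))
  }, numeric(1))
  lags[which.max(r)] * dt
}

#' Cell-attached spike metrics
#'
#' Detects biphasic extracellular spikes in a cell-attached current trace by
#' thresholding the negative excursion, then pairing each negative peak with
#' the following positive peak.  The spike width is the time between the two
#' extrema (which correspond to the maximal rising and falling slopes of the
#' intracellular AP) and the amplitude is their difference.
#'
#' @param trace A [current_trace()] from a cell-attached recording.
#' @param threshold Detection threshold on the negative excursion (same
#'   units as the trace); `NULL` picks `max(5 * MAD, 30% of the largest
#'   excursion)` automatically.
#' @param min_separation_ms Minimum separation between spikes (ms).
#' @param pos_window_ms How far after the negative peak to search for the
#'   positive peak (ms).
#' @return A data frame of class `ca_spikes` with columns `neg_peak_ms`,
#'   `pos_peak_ms`, `width_us`, `amplitude`.
#' @export
ca_spike_metrics <- function(trace, threshold = NULL, min_separation_ms = 1,
                             pos_window_ms = 3) {
  stopifnot(inherits(trace, "current_trace"))
  dt <- trace$dt
  x <- trace$I
  baseline <- median(x)
  dev <- x - baseline
  if (is.null(threshold)) {
    # noise SD from first differences (robust to the spikes themselves);
    # floor at a third of the largest negative excursion
    sigma <- mad(diff(x)) / sqrt(2)
    threshold <- max(4 * sigma, 0.35 * max(-dev))
  }
  below <- dev <= -threshold
  empty <- data.frame(neg_peak_ms = numeric(0), pos_peak_ms = numeric(0),
                      width_us = numeric(0), amplitude = numeric(0))
  class(empty) <- c("ca_spikes", "data.frame")
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  negs <- vapply(runs, function(k) {
    i <- starts[k]:ends[k]
    i[which.min(x[i])]
  }, integer(1))
  # enforce min separation (keep deeper trough)
  if (length(negs) > 1) {
    ord <- order(x[negs])
    keep <- logical(length(negs))
    taken <- numeric(0)
    min_sep <- min_separation_ms / dt
    for (j in ord) {
      if (all(abs(negs[j] - taken) >= min_sep)) {
        keep[j] <- TRUE
        taken <- c(taken, negs[j])
      }
    }
    negs <- sort(negs[keep])
  }
  rows <- lapply(negs, function(ng) {
    hi <- min(length(x), ng + round(pos_window_ms / dt))
    if (hi <= ng + 1L) return(NULL)
    ps <- ng + which.max(x[(ng + 1L):hi])
    data.frame(neg_peak_ms = (ng - 1) * dt + trace$t0,
               pos_peak_ms = (ps - 1) * dt + trace$t0,
               width_us = (ps - ng) * dt * 1000,
               amplitude = x[ps] - x[ng])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("ca_spikes", "data.frame")
  out
}
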