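# Inverse problems: recovering model parameters from (possibly noisy)
# current data.  All nonlinear least squares go through bounded
# Levenberg-Marquardt (minpack.lm) or L-BFGS-B with a small multi-start to
# avoid the flat directions of sigmoid/exponential fits.

#' Fit-result container
#'
#' @param estimates Named numeric vector of parameter estimates.
#' @param half_width Optional named 95% confidence half-widths.
#' @param residual_norm Residual sum of squares at the optimum.
#' @param converged Logical convergence flag.
#' @param flags Character vector of quality flags (e.g.
#'   `"koff_unidentifiable"`, `"degenerate_second_component"`).
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(estimates, half_width = NULL,
                       residual_norm = NA_real_, converged = FALSE,
                       flags = character()) {
  structure(list(estimates = estimates, half_width = half_width,
                 residual_norm = residual_norm, converged = converged,
                 flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result (%s)\n",
              if (x$converged) "converged" else "NOT converged"))
  for (nm in names(x$estimates)) {
    hw <- if (!is.null(x$half_width) && nm %in% names(x$half_width)) {
      sprintf(" +/- %.4g", x$half_width[[nm]])
    } else ""
    cat(sprintf("  %-10s %.6g%s\n", nm, x$estimates[[nm]], hw))
  }
  if (is.finite(x$residual_norm)) {
    cat(sprintf("  residual SS: %.4g\n", x$residual_norm))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

nls_half_width <- function(fit) {
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  if (is.null(se)) NULL else 1.96 * se
}

#' Fit the steady-state I--V relationship
#'
#' Least-squares fit of `I = scale * P_open(V) * (V - E_Ca)` (Boltzmann
#' open probability, ohmic driving force) to an I--V dataset with `E_Ca`
#' fixed.  Three starting points guard against the sigmoid's flat
#' directions; bounds are `alpha` in (0.01, 1), `V_Cav50` in (-60, 20).
#'
#' @param data An [iv_dataset()] (or data frame with columns `V`, `I`).
#' @param E_Ca Fixed Ca++ equilibrium potential (mV).
#' @param weights Optional per-point weights.
#' @return A [fit_result()] with estimates `V_Cav50`, `alpha`, `scale`.
#' @examples
#' iv <- steady_iv_curve(seq(-60, 50, by = 10), cav_params())
#' fit_iv(iv)$estimates
#' @export
fit_iv <- function(data, E_Ca = 60, weights = NULL) {
  if (nrow(data) < 4) cp_stop("an I-V dataset needs at least 4 points.")
  V <- data$V
  I <- data$I
  if (all(I == 0)) {
    return(fit_result(c(V_Cav50 = NA_real_, alpha = NA_real_,
                        scale = NA_real_),
                      converged = FALSE, flags = "degenerate_input"))
  }
  w <- if (is.null(weights)) rep(1, length(V)) else weights
  starts <- list(c(v50 = -30, alpha = 0.1), c(v50 = -17, alpha = 0.2),
                 c(v50 = 0, alpha = 0.4))
  best <- NULL
  for (st in starts) {
    pred0 <- plogis(st[["alpha"]] * (V - st[["v50"]])) * (V - E_Ca)
    s0 <- max(abs(I)) / max(abs(pred0))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        I ~ s * plogis(alpha * (V - v50)) * (V - E_Ca),
        start = list(v50 = st[["v50"]], alpha = st[["alpha"]], s = s0),
        lower = c(v50 = -60, alpha = 0.01, s = 1e-9),
        upper = c(v50 = 20, alpha = 1, s = Inf),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(w * residuals(fit)^2)
      if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
    }
  }
  if (is.null(best)) {
    return(fit_result(c(V_Cav50 = NA_real_, alpha = NA_real_,
                        scale = NA_real_),
                      converged = FALSE, flags = "nonconvergence"))
  }
  cf <- coef(best$fit)
  hw <- nls_half_width(best$fit)
  if (!is.null(hw)) names(hw) <- c("V_Cav50", "alpha", "scale")
  fit_result(c(V_Cav50 = cf[["v50"]], alpha = cf[["alpha"]],
               scale = cf[["s"]]),
             half_width = hw, residual_norm = best$ss, converged = TRUE)
}

#' Fit the sensor rate constants to a current time course
#'
#' Fits `k_on` and `k_off` of the four-sensor model by least squares between
#' a recorded/synthetic current trace and the simulated current under the
#' same step command, with `(V_Cav50, alpha, E_Ca)` fixed and an analytic
#' free amplitude scale.  The rising phase of the current constrains `k_on`,
#' the deactivating tail constrains `k_off`; if the command never
#' repolarizes the tail is absent and `k_off` is flagged unidentifiable.
#'
#' @param trace A [current_trace()].
#' @param stim The [voltage_trace()] command (same sampling as `trace`).
#' @param fixed Named list with `V_Cav50`, `alpha`, `E_Ca`.
#' @return A [fit_result()] with estimates `k_on`, `k_off`, `scale`.
#' @export
fit_kinetics <- function(trace, stim,
                         fixed = list(V_Cav50 = -17, alpha = 0.2,
                                      E_Ca = 60)) {
  stopifnot(inherits(trace, "current_trace"), inherits(stim, "voltage_trace"))
  check_same_sampling(trace, stim)
  V <- stim$V
  I_obs <- trace$I
  dep <- V > min(V) + 0.5 * diff(range(V))
  has_tail <- any(dep) && max(which(dep)) < length(V)

  base <- params_replace(cav_params(), V_Cav50 = fixed$V_Cav50,
                         alpha = fixed$alpha, E_Ca = fixed$E_Ca,
                         dt = stim$dt)
  sim_I <- function(kon, koff) {
    p <- sensor_path(V, params_replace(base, k_on = kon, k_off = koff))
    p^4 * (V - base$E_Ca)
  }
  obj <- function(logk) {
    kon <- exp(logk[1])
    koff <- if (has_tail) exp(logk[2]) else base$k_off
    Is <- sim_I(kon, koff)
    s <- sum(Is * I_obs) / sum(Is * Is)
    sum((I_obs - s * Is)^2)
  }
  np <- if (has_tail) 2L else 1L
  starts <- list(log(c(0.5, 0.5))[seq_len(np)],
                 log(c(0.05, 0.05))[seq_len(np)],
                 log(c(5, 5))[seq_len(np)])
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      optim(st, obj, method = "L-BFGS-B",
            lower = rep(log(0.005), np), upper = rep(log(55), np),
            control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(fit_result(c(k_on = NA_real_, k_off = NA_real_,
                        scale = NA_real_),
                      converged = FALSE, flags = "nonconvergence"))
  }
  kon <- exp(best$par[1])
  koff <- if (has_tail) exp(best$par[2]) else NA_real_
  Is <- sim_I(kon, if (has_tail) koff else base$k_off)
  s <- sum(Is * I_obs) / sum(Is * Is)
  flags <- if (has_tail) character() else "koff_unidentifiable"
  fit_result(c(k_on = kon, k_off = koff, scale = s),
             residual_norm = best$value,
             converged = best$convergence == 0, flags = flags)
}

#' Activation time constant of a rising inward current
#'
#' Fits `A * (1 - exp(-t/tau)) + B` to the rising (inward-growing) phase of
#' the current within `window`.  The fit region runs from the onset (first
#' sample exceeding 3x the pre-window noise SD, or 1% of the plateau when
#' there is no noise) to the end of the window, which should include the
#' approach to the plateau: the current's early rise is quartic in the
#' sensor activation, so truncating the fit before the plateau biases the
#' single-exponential tau upward.
#'
#' @param trace A [current_trace()].
#' @param window `(from, to)` ms covering the rise and its plateau.
#' @return The fitted tau (ms), with the underlying [fit_result()] attached
#'   as attribute `"fit"`.
#' @export
activation_tau <- function(trace, window) {
  idx <- window_index(trace, window)
  dt <- trace$dt
  tt <- trace_time(trace)[idx]
  I <- trace$I[idx]
  nb <- max(1L, round(0.2 / dt))
  baseline <- mean(I[seq_len(nb)])
  m <- -(I - baseline)            # inward magnitude, >= 0 along the rise
  plateau <- mean(tail(m, max(1L, round(0.05 * length(m)))))
  pre_idx <- which(trace_time(trace) < window[1] - 1e-9)
  noise <- if (length(pre_idx) >= 10) sd(trace$I[pre_idx]) else 0
  thr <- max(3 * noise, 0.01 * plateau)
  i_on <- which(m > thr)[1]
  if (is.na(i_on) || plateau <= 0) {
    cp_warn("no rising inward current found in the window.",
            "cavprime_fit_warning")
    return(structure(NA_real_, fit = fit_result(c(tau = NA_real_),
                                                converged = FALSE)))
  }
  i_end <- length(m)
  seg <- m[i_on:i_end]
  i95 <- i_on + which(m[i_on:length(m)] >= 0.95 * plateau)[1] - 1L
  rise_part <- m[i_on:ifelse(is.na(i95), length(m), i95)]
  if (mean(diff(rise_part) < 0) > 0.25) {
    cp_warn("rise is not monotonic in the fit window; tau may be unreliable.",
            "cavprime_fit_warning")
  }
  tloc <- (seq_along(seg) - 1) * dt
  A0 <- plateau - seg[1]
  i63 <- which(seg - seg[1] >= 0.632 * A0)[1]
  tau0 <- max(dt, tloc[ifelse(is.na(i63), length(seg), i63)])
  fit <- tryCatch(
    minpack.lm::nlsLM(seg ~ A * (1 - exp(-tloc / tau)) + B,
                      start = list(A = A0, tau = tau0, B = seg[1]),
                      lower = c(A = 0, tau = dt / 10, B = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(NA_real_, fit = fit_result(c(tau = NA_real_),
                                                converged = FALSE)))
  }
  cf <- coef(fit)
  fr <- fit_result(c(tau = cf[["tau"]], A = cf[["A"]], B = cf[["B"]]),
                   half_width = nls_half_width(fit),
                   residual_norm = sum(residuals(fit)^2), converged = TRUE)
  structure(unname(cf[["tau"]]), fit = fr)
}

#' Isolate a slow residual current by model subtraction
#'
#' Scales the simulated Cav current to the recorded one over the first 5 ms
#' of the depolarization (the fast, Cav-dominated window) by least squares
#' and returns the pointwise residual `recorded - scale * simulated`.  Both
#' traces are baseline-subtracted over the pre-onset samples first.  The
#' residual isolates slow components such as the GABA-A autoreceptor-like
#' current that rides on recorded bouton Ca++ currents.
#'
#' @param recorded,simulated [current_trace()] objects with identical
#'   sampling and alignment.
#' @return A [current_trace()] residual with attribute `"scale"`.
#' @export
isolate_autoreceptor <- function(recorded, simulated) {
  stopifnot(inherits(recorded, "current_trace"),
            inherits(simulated, "current_trace"))
  check_same_sampling(recorded, simulated, strict_t0 = TRUE)
  dt <- recorded$dt
  Is <- simulated$I
  rng <- diff(range(Is))
  i_on <- which(abs(Is - Is[1]) > 0.01 * rng)[1]
  if (is.na(i_on)) i_on <- 1L
  pre <- seq_len(max(1L, i_on - 1L))
  br <- mean(recorded$I[pre])
  bs <- mean(Is[pre])
  y <- recorded$I - br
  x <- Is - bs
  wi <- i_on:min(length(x), i_on + round(5 / dt))
  s <- sum(x[wi] * y[wi]) / sum(x[wi]^2)
  res <- current_trace(y - s * x, dt, t0 = recorded$t0)
  attr(res, "scale") <- s
  res
}

#' Mono- or bi-exponential decay fit
#'
#' Fits `C + A * exp(-t/tau)` (or the two-component sum, with `tau1 < tau2`
#' by convention) to a trace segment that starts at an event peak.
#'
#' @param segment A trace (voltage or current) whose first sample is the
#'   event peak, or a numeric vector with `dt` supplied.
#' @param n_exp 1 or 2 exponential components.
#' @param dt Sample interval (ms), required when `segment` is numeric.
#' @return A [fit_result()] with `tau` (and `tau2`), amplitudes and offset.
#'   A second component carrying under 2% of the amplitude, or separated
#'   from the first by less than a factor 2, is flagged degenerate.
#' @export
fit_decay <- function(segment, n_exp = 1, dt = NULL) {
  if (inherits(segment, "ephys_trace")) {
    y <- trace_values(segment)
    dt <- segment$dt
  } else {
    y <- as.numeric(segment)
    if (is.null(dt)) cp_stop("`dt` required for numeric segments.")
  }
  if (!n_exp %in% c(1, 2)) cp_stop("`n_exp` must be 1 or 2.")
  t <- (seq_along(y) - 1) * dt
  C0 <- mean(tail(y, max(1L, round(0.05 * length(y)))))
  A0 <- y[1] - C0
  if (A0 <= 0 || y[length(y)] > y[1]) {
    cp_warn("segment does not decay; fit may be meaningless.",
            "cavprime_fit_warning")
  }
  iefold <- which(y - C0 <= A0 / exp(1))[1]
  tau0 <- max(dt, t[ifelse(is.na(iefold), length(y), iefold)])

  if (n_exp == 1) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ C + A * exp(-t / tau),
                        start = list(C = C0, A = A0, tau = tau0),
                        lower = c(C = -Inf, A = -Inf, tau = dt / 10),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(fit_result(c(tau = NA_real_), converged = FALSE,
                        flags = "nonconvergence"))
    }
    cf <- coef(fit)
    return(fit_result(c(tau = cf[["tau"]], A = cf[["A"]], C = cf[["C"]]),
                      half_width = nls_half_width(fit),
                      residual_norm = sum(residuals(fit)^2),
                      converged = TRUE))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ C + A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
      start = list(C = C0, A1 = A0 / 2, tau1 = tau0 / 4,
                   A2 = A0 / 2, tau2 = tau0 * 1.5),
      lower = c(C = -Inf, A1 = -Inf, tau1 = dt / 10, A2 = -Inf,
                tau2 = dt / 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(fit_result(c(tau = NA_real_, tau2 = NA_real_),
                      converged = FALSE, flags = "nonconvergence"))
  }
  cf <- coef(fit)
  tau1 <- cf[["tau1"]]; tau2 <- cf[["tau2"]]
  A1 <- cf[["A1"]]; A2 <- cf[["A2"]]
  if (tau1 > tau2) {                       # enforce tau1 < tau2
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- A1; A1 <- A2; A2 <- tmp
  }
  flags <- character()
  wmin <- min(abs(A1), abs(A2)) / (abs(A1) + abs(A2))
  if (tau2 / tau1 < 2 || wmin < 0.02) flags <- "degenerate_second_component"
  fit_result(c(tau = tau1, tau2 = tau2, A1 = A1, A2 = A2, C = cf[["C"]]),
             residual_norm = sum(residuals(fit)^2),
             converged = TRUE, flags = flags)
}

#' Fit the axonal length constant of the coupling ratio
#'
#' Least-squares fit of `CR(d) = A * exp(-d / lambda)` to a table of
#' (distance, coupling ratio) points.  The prefactor `A` is free by default
#' (dendro-somatic attenuation precedes the axon); `constrain_A = TRUE`
#' forces `CR(0) = 1`.
#'
#' @param table A data frame with columns `distance_um` and `cr` (e.g. from
#'   [generate_cr_distance_table()]).
#' @param constrain_A Force the prefactor to 1.
#' @return A [fit_result()] with estimates `lambda_um` and `A`; a table with
#'   no distance-dependent decline is flagged unidentifiable.
#' @export
fit_length_constant <- function(table, constrain_A = FALSE) {
  d <- table$distance_um
  cr <- table$cr
  if (length(d) < 3) cp_stop("need at least 3 (distance, CR) points.")
  pos <- cr > 0
  if (sum(pos) < 3) {
    return(fit_result(c(lambda_um = NA_real_, A = NA_real_),
                      converged = FALSE, flags = "degenerate_input"))
  }
  lf <- stats::lm(log(cr[pos]) ~ d[pos])
  slope <- coef(lf)[[2]]
  if (!is.finite(slope) || slope >= -1e-10) {
    return(fit_result(c(lambda_um = Inf, A = mean(cr)),
                      converged = FALSE, flags = "unidentifiable"))
  }
  lam0 <- -1 / slope
  A0 <- exp(coef(lf)[[1]])
  fit <- tryCatch(
    if (constrain_A) {
      minpack.lm::nlsLM(cr ~ exp(-d / lambda),
                        start = list(lambda = lam0),
                        lower = c(lambda = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      minpack.lm::nlsLM(cr ~ A * exp(-d / lambda),
                        start = list(A = A0, lambda = lam0),
                        lower = c(A = 1e-9, lambda = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    },
    error = function(e) NULL)
  if (is.null(fit)) {
    return(fit_result(c(lambda_um = NA_real_, A = NA_real_),
                      converged = FALSE, flags = "nonconvergence"))
  }
  cf <- coef(fit)
  A_hat <- if (constrain_A) 1 else cf[["A"]]
  hw <- nls_half_width(fit)
  if (!is.null(hw)) {
    names(hw) <- sub("^lambda$", "lambda_um", names(hw))
  }
  fit_result(c(lambda_um = cf[["lambda"]], A = A_hat),
             half_width = hw, residual_norm = sum(residuals(fit)^2),
             converged = TRUE)
}
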