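#' Parameter set of the four-voltage-sensor Cav model
#'
#' Bundles the five biophysical constants of the channel model together with
#' the Euler integration step.  Defaults are the values obtained by fitting
#' the model to presynaptic bouton Ca++ current recordings (I--V curve and
#' step-response time course) in cerebellar molecular layer interneurons.
#'
#' @param V_Cav50 Membrane potential of half-maximal channel opening (mV).
#' @param alpha Steepness of the voltage-dependent activation (per mV).
#' @param k_on Maximal sensor activation rate constant (per ms).
#' @param k_off Maximal sensor deactivation rate constant (per ms).
#' @param E_Ca Ca++ equilibrium potential (mV); must exceed `V_Cav50`.
#' @param dt Euler time step (ms), restricted to \[0.005, 0.05\].
#'
#' @return An object of class `cav_params`.
#' @examples
#' p <- cav_params()
#' steady_open_probability(-17, p)  # 0.5 by definition of V_Cav50
#' @export
cav_params <- function(V_Cav50 = -17, alpha = 0.2, k_on = 0.55, k_off = 0.65,
                       E_Ca = 60, dt = 0.01) {
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      cp_stop(sprintf("`%s` must be a single finite number.", name))
    }
    as.numeric(x)
  }
  V_Cav50 <- num1(V_Cav50, "V_Cav50")
  alpha <- num1(alpha, "alpha")
  k_on <- num1(k_on, "k_on")
  k_off <- num1(k_off, "k_off")
  E_Ca <- num1(E_Ca, "E_Ca")
  dt <- num1(dt, "dt")
  if (alpha <= 0) cp_stop("`alpha` must be > 0.")
  if (k_on <= 0) cp_stop("`k_on` must be > 0.")
  if (k_off <= 0) cp_stop("`k_off` must be > 0.")
  if (dt < 0.005 || dt > 0.05) cp_stop("`dt` must lie in [0.005, 0.05] ms.")
  if (E_Ca <= V_Cav50) cp_stop("`E_Ca` must exceed `V_Cav50`.")
  structure(
    list(V_Cav50 = V_Cav50, alpha = alpha, k_on = k_on, k_off = k_off,
         E_Ca = E_Ca, dt = dt),
    class = "cav_params"
  )
}

#' @export
print.cav_params <- function(x, ...) {
  cat("Cav channel model parameters (four independent voltage sensors)\n")
  cat(sprintf("  V_Cav50 : %8.3f mV\n", x$V_Cav50))
  cat(sprintf("  alpha   : %8.3f /mV\n", x$alpha))
  cat(sprintf("  k_on    : %8.3f /ms\n", x$k_on))
  cat(sprintf("  k_off   : %8.3f /ms\n", x$k_off))
  cat(sprintf("  E_Ca    : %8.3f mV\n", x$E_Ca))
  cat(sprintf("  dt      : %8.4f ms (Euler)\n", x$dt))
  invisible(x)
}

# internal: copy with fields replaced, *without* revalidating dt bounds.
# Used only by the convergence utility, which needs a finer reference step
# than the user-facing range admits.
params_replace <- function(params, ...) {
  out <- unclass(params)
  repl <- list(...)
  out[names(repl)] <- repl
  class(out) <- "cav_params"
  out
}
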