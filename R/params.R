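#' Lumped equivalent-circuit parameters of the membrane
#'
#' The membrane is modelled as three parallel branches: (i) a viscoelastic
#' branch, a series resistance `r` feeding the nonlinear capacitance
#' `C1 = (1 - kappa) * C0 * (1 + beta * Utilde^2)`, whose voltage `Utilde`
#' (proportional to the electric displacement) lags the command voltage; (ii)
#' a purely elastic branch of capacitance `kappa * C0` (its own nonlinearity
#' is negligible for solvent-free material and is fixed at zero); and (iii) an
#' ionic branch with current `g * U + gamma * U^9`.
#'
#' All values are in SI units. The polarization lag time is
#' `tau = (1 - kappa) * r * C0`; `tau` is stored and the series resistance is
#' derived (see [implied_series_resistance()]).
#'
#' @param C0 Zero-voltage capacitance of the whole membrane, farads (> 0).
#' @param beta Capacitance nonlinearity of the viscoelastic part, 1/V^2 (>= 0).
#' @param kappa Elastic fraction of the membrane, in `[0, 1]`.
#' @param tau Polarization lag time, seconds (>= 0). Must be 0 when
#'   `kappa = 1` (no viscoelastic branch).
#' @param g Linear ionic conductance, siemens (>= 0).
#' @param gamma Ninth-order ionic conductance coefficient, S/V^8 (>= 0).
#'
#' @return An object of class `memcap_params` (a named list).
#' @examples
#' membrane_params(C0 = 897e-12, beta = 13.75, kappa = 0.2, tau = 0.019,
#'                 g = 0.05e-9, gamma = 5e-4)
#' @export
membrane_params <- function(C0, beta = 0, kappa = 0, tau = 0, g = 0, gamma = 0) {
  vals <- c(C0 = C0, beta = beta, kappa = kappa, tau = tau, g = g, gamma = gamma)
  stopifnot(all(vapply(vals, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), TRUE)))
  if (C0 <= 0) stop("`C0` must be > 0")
  if (beta < 0 || tau < 0 || g < 0 || gamma < 0)
    stop("`beta`, `tau`, `g` and `gamma` must be >= 0")
  if (kappa < 0 || kappa > 1) stop("`kappa` must lie in [0, 1]")
  if (kappa == 1 && tau > 0)
    stop("`kappa = 1` leaves no viscoelastic branch; `tau` must then be 0")
  structure(as.list(vals), class = "memcap_params")
}

#' @export
print.memcap_params <- function(x, ...) {
  cat(sprintf(
    "<memcap_params> C0 = %g pF, beta = %g 1/V^2, kappa = %g, tau = %g ms, g = %g nS, gamma = %g S/V^8\n",
    1e12 * x$C0, x$beta, x$kappa, 1e3 * x$tau, 1e9 * x$g, x$gamma))
  invisible(x)
}

#' Series resistance implied by the polarization lag time
#'
#' The viscoelastic branch stores `tau = (1 - kappa) * r * C0`; this returns
#' `r = tau / ((1 - kappa) * C0)`, or `Inf` when `kappa = 1` with `tau > 0`
#' (impossible by construction) and `0` when `tau = 0`.
#'
#' @param params A [membrane_params()].
#' @return Resistance in ohms.
#' @export
implied_series_resistance <- function(params) {
  stopifnot(inherits(params, "memcap_params"))
  if (params$tau == 0) return(0)
  params$tau / ((1 - params$kappa) * params$C0)
}

#' Voltage-clamp amplifier feedback parameters
#'
#' The measured output current is the membrane current filtered by the
#' amplifier feedback loop, a first-order lag with time constant
#' `tau_out = Rout * Cout` where `Rout` is the feedback resistance and `Cout`
#' its parasitic capacitance.
#'
#' @param Rout Feedback resistance in ohms (> 0).
#' @param tau_out Feedback time constant in seconds (>= 0).
#' @return An object of class `memcap_amp`.
#' @examples
#' amplifier_params(Rout = 100e6, tau_out = 0.8e-3)
#' @export
amplifier_params <- function(Rout, tau_out) {
  stopifnot(is.numeric(Rout), length(Rout) == 1, is.finite(Rout), Rout > 0,
            is.numeric(tau_out), length(tau_out) == 1, is.finite(tau_out),
            tau_out >= 0)
  structure(list(Rout = as.numeric(Rout), tau_out = as.numeric(tau_out)),
            class = "memcap_amp")
}

#' @export
print.memcap_amp <- function(x, ...) {
  cat(sprintf("<memcap_amp> Rout = %g MOhm, tau_out = %g ms (Cout = %g pF)\n",
              1e-6 * x$Rout, 1e3 * x$tau_out, 1e12 * x$tau_out / x$Rout))
  invisible(x)
}

#' Ionic branch current
#'
#' Odd ninth-order current-voltage law of the ionic branch,
#' `i3(U) = g * U + gamma * U^9`.
#'
#' @param U Membrane voltage(s), volts.
#' @param params A [membrane_params()].
#' @return Current in amperes, same length as `U`.
#' @examples
#' p <- membrane_params(C0 = 1e-9, g = 5e-11)
#' ionic_current(0.1, p) # 5e-12 A
#' @export
ionic_current <- function(U, params) {
  stopifnot(inherits(params, "memcap_params"), is.numeric(U))
  if (any(!is.finite(U))) stop("`U` must be finite")
  params$g * U + params$gamma * U^9
}

#' Quantities derived from a parameter set and a drive
#'
#' Collects the combinations that control the memcapacitive response:
#' * `beta_exp = beta * (1 - kappa)`, the effective nonlinearity seen in the
#'   paired-ramp capacitance curve;
#' * `C_exp0 = C0 * (1 + 5 * beta_exp * (k * tau)^2)`, the apparent
#'   zero-voltage capacitance;
#' * `g_star = 4 * beta_exp * k^2 * C0 * tau`, the insertion conductance
#'   magnitude (the ionic conductance at which the hysteresis loop closes);
#' * `g_app = g - g_star`, the apparent conductance (negative in the
#'   memcapacitive regime when `gamma = 0`);
#' * `A_up = 2 * k * tau`, `A_down = -2 * k * tau`, the branch-voltage
#'   transient amplitudes fixed by periodic steady-state matching.
#'
#' `g_app + g_star = g` holds exactly.
#'
#' @param params A [membrane_params()].
#' @param drive A [drive_spec()].
#' @return A one-row tibble with columns `beta_exp`, `C_exp0`, `g_app`,
#'   `g_star`, `A_up`, `A_down`.
#' @examples
#' derived_params(membrane_params(C0 = 1120e-12, beta = 18.75, kappa = 0.2,
#'                                tau = 0.01), drive_spec(0.2, 2))
#' @export
derived_params <- function(params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  k <- drive$k
  beta_exp <- params$beta * (1 - params$kappa)
  g_star <- 4 * beta_exp * k^2 * params$C0 * params$tau
  tibble::tibble(
    beta_exp = beta_exp,
    C_exp0 = params$C0 * (1 + 5 * beta_exp * (k * params$tau)^2),
    g_app = params$g - g_star,
    g_star = g_star,
    A_up = 2 * k * params$tau,
    A_down = -2 * k * params$tau
  )
}

# warn when the half-period is not long compared to the lag time; the
# closed-form response assumes the corner transient has decayed well before
# the next slope reversal
check_transient_decay <- function(params, drive) {
  if (params$tau > 0 && drive$T / 2 < 5 * params$tau)
    warning(sprintf(
      "half-period T/2 = %g s is below 5 * tau = %g s; the steady-ramp forms degrade",
      drive$T / 2, 5 * params$tau), call. = FALSE)
  invisible(NULL)
}
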