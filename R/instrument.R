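#' First-order amplifier feedback filter
#'
#' The voltage-clamp amplifier reports the membrane current through its
#' feedback loop, a first-order low-pass with time constant `tau_out`.
#' The discrete update is the exact exponential (zero-order-hold) recursion
#' `y[n] = a * y[n-1] + (1 - a) * x[n]`, `a = exp(-dt / tau_out)`, which is
#' far more accurate than a forward-Euler step when `tau_out` is comparable
#' to the sample interval. `tau_out = 0` returns the input unchanged; the DC
#' gain is exactly 1 and the filter is linear sample-wise.
#'
#' @param i Current samples, amperes (numeric vector).
#' @param amp An [amplifier_params()].
#' @param dt Sample interval, seconds.
#' @param init Initial output value; defaults to the first input sample
#'   (filter already settled when recording starts).
#' @return Filtered current, amperes, same length as `i`.
#' @export
filter_current <- function(i, amp, dt, init = i[[1]]) {
  stopifnot(inherits(amp, "memcap_amp"), is.numeric(i),
            is.numeric(dt), length(dt) == 1, dt > 0)
  if (amp$tau_out == 0) return(i)
  a <- exp(-dt / amp$tau_out)
  y <- stats::filter((1 - a) * i, filter = a, method = "recursive",
                     init = init)
  as.numeric(y)
}

#' Closed-form amplifier output after a slope reversal
#'
#' Output current (output voltage over the feedback resistance) during the
#' rising half-period, for the linear membrane limit (`beta = 0`,
#' `gamma = 0`, `g = 0`), where the membrane current is
#' `k*C0 - 2*(1-kappa)*k*C0*exp(-t/tau)`. Passing that through the feedback
#' lag gives a two-exponential transient riding on the steady plateau
#' `k*C0`: a slow membrane exponential of amplitude
#' `2*(1-kappa)*k*C0 / (1 - tau_out/tau)` and a fast amplifier exponential
#' carrying the remainder, so the output starts exactly at `-k*C0` and
#' settles at `+k*C0`. The confluent limit `tau_out -> tau` is handled, and
#' `tau_out = 0` returns the unfiltered membrane current.
#'
#' @param t Time since the slope reversal, seconds (in `[0, T/2]`).
#' @param params A [membrane_params()].
#' @param drive A [drive_spec()].
#' @param amp An [amplifier_params()].
#' @return Current in amperes.
#' @export
analytic_output_transient <- function(t, params, drive, amp) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"),
            inherits(amp, "memcap_amp"))
  k <- drive$k; C0 <- params$C0; fr <- 1 - params$kappa
  tau <- params$tau; tau_out <- amp$tau_out
  if (any(t < -1e-12 | t > drive$T / 2 + 1e-12))
    stop("`t` must lie within a half-period [0, T/2]")
  if (tau == 0) {
    # purely elastic input k*C0*(1 - 2*exp(-t/tau)) degenerates to a step
    if (tau_out == 0) return(rep(k * C0, length(t)))
    return(k * C0 * (1 - 2 * exp(-t / tau_out)))
  }
  if (tau_out == 0) return(k * C0 * (1 - 2 * fr * exp(-t / tau)))
  ratio <- tau_out / tau
  if (abs(1 - ratio) < 1e-8) {
    # confluent limit: (exp(-t/tau) - exp(-t/tau_out)) / (1 - ratio) ->
    # (t / tau_out) * exp(-t/tau)
    mid <- (t / tau_out) * exp(-t / tau)
  } else {
    mid <- (exp(-t / tau) - exp(-t / tau_out)) / (1 - ratio)
  }
  k * C0 - 2 * fr * k * C0 * mid - 2 * k * C0 * exp(-t / tau_out)
}

#' Amplitudes of the two transient exponentials
#'
#' In the regime `tau_out << tau` the post-reversal transient of the
#' measured current is the sum of a slow membrane exponential of amplitude
#' `2 * (1 - kappa) * k * C0` and a fast amplifier exponential of amplitude
#' `2 * kappa * k * C0`; the amplitudes add to the full jump `2 * k * C0`.
#' The split of the jump between the two time scales is what identifies the
#' elastic fraction `kappa` from a recording.
#'
#' @param params A [membrane_params()].
#' @param drive A [drive_spec()].
#' @return Named numeric vector `c(a_slow =, a_fast =)`, amperes.
#' @export
two_exponential_amplitudes <- function(params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  kC0 <- drive$k * params$C0
  c(a_slow = 2 * (1 - params$kappa) * kC0, a_fast = 2 * params$kappa * kC0)
}
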