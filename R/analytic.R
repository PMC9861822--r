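#' First-order branch voltage on the rising half-period
#'
#' Closed-form steady-periodic voltage across the viscoelastic capacitance
#' during the rising ramp, to first order in the nonlinearity `beta`:
#' a lagged copy of the command voltage (`U(t) - k * tau` plus the decaying
#' corner transient `2 * k * tau * exp(-t / tau)`) with the first-order
#' polynomial correction. With `tau = 0` the branch voltage equals the
#' command voltage exactly.
#'
#' @param t Time since the start of the rising half-period, seconds, in
#'   `[0, T/2]`.
#' @param params A [membrane_params()].
#' @param drive A [drive_spec()].
#' @return Branch voltage in volts.
#' @export
utilde_up <- function(t, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  k <- drive$k; tau <- params$tau; beta <- params$beta; Umax <- drive$Umax
  if (any(t < -1e-12 | t > drive$T / 2 + 1e-12))
    stop("`t` must lie within the rising half-period [0, T/2]")
  if (tau == 0) return(-Umax + k * t)
  check_transient_decay(params, drive)
  kt <- k * t
  -Umax - k * tau + kt + 2 * k * tau * exp(-t / tau) -
    beta * k * tau * (Umax^2 + 4 * Umax * k * tau + 5 * (k * tau)^2) +
    2 * beta * k * tau * (Umax + 2 * k * tau) * kt -
    beta * k * tau * kt^2
}

#' @rdname utilde_up
#' @param t_down Time since the start of the falling half-period, seconds.
#' @export
utilde_down <- function(t_down, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  k <- drive$k; tau <- params$tau; beta <- params$beta; Umax <- drive$Umax
  if (any(t_down < -1e-12 | t_down > drive$T / 2 + 1e-12))
    stop("`t_down` must lie within the falling half-period [0, T/2]")
  if (tau == 0) return(Umax - k * t_down)
  check_transient_decay(params, drive)
  kt <- k * t_down
  Umax + k * tau - kt - 2 * k * tau * exp(-t_down / tau) +
    beta * k * tau * (Umax^2 + 4 * Umax * k * tau + 5 * (k * tau)^2) -
    2 * beta * k * tau * (Umax + 2 * k * tau) * kt +
    beta * k * tau * kt^2
}

#' First-order viscoelastic branch current
#'
#' Current through the lagged nonlinear capacitance branch during the rising
#' (`branch_current_viscoelastic_up`) or falling
#' (`branch_current_viscoelastic_down`) half-period, to first order in
#' `beta`. Away from the corner transient and with `beta = 0` the rising-half
#' current settles at the linear charging value `(1 - kappa) * k * C0`.
#'
#' @inheritParams utilde_up
#' @return Current in amperes.
#' @export
branch_current_viscoelastic_up <- function(t, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  k <- drive$k; tau <- params$tau; beta <- params$beta; Umax <- drive$Umax
  C0 <- params$C0; fr <- 1 - params$kappa
  if (any(t < -1e-12 | t > drive$T / 2 + 1e-12))
    stop("`t` must lie within the rising half-period [0, T/2]")
  if (tau == 0) return(rep(fr * k * C0, length(t)))
  kt <- k * t
  fr * k * C0 * (1 + beta * (Umax^2 + 4 * Umax * k * tau + 5 * (k * tau)^2)) -
    2 * beta * k * C0 * fr * (Umax + 2 * k * tau) * kt +
    beta * k * C0 * fr * kt^2 -
    2 * k * C0 * fr * exp(-t / tau)
}

#' @rdname branch_current_viscoelastic_up
#' @export
branch_current_viscoelastic_down <- function(t_down, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  k <- drive$k; tau <- params$tau; beta <- params$beta; Umax <- drive$Umax
  C0 <- params$C0; fr <- 1 - params$kappa
  if (any(t_down < -1e-12 | t_down > drive$T / 2 + 1e-12))
    stop("`t_down` must lie within the falling half-period [0, T/2]")
  if (tau == 0) return(rep(-fr * k * C0, length(t_down)))
  kt <- k * t_down
  -fr * k * C0 * (1 + beta * (Umax^2 + 4 * Umax * k * tau + 5 * (k * tau)^2)) +
    2 * beta * k * C0 * fr * (Umax + 2 * k * tau) * kt -
    beta * k * C0 * fr * kt^2 +
    2 * k * C0 * fr * exp(-t_down / tau)
}

# exponential corner-transient factor; identically 0 when tau = 0 (the
# no-lag limit has no transient), otherwise exp(-x / (k tau))
transient_exp <- function(x, k, tau) {
  if (tau == 0) return(rep(0, length(x)))
  exp(-x / (k * tau))
}

check_U_range <- function(U, drive) {
  if (any(!is.finite(U))) stop("`U` must be finite")
  if (any(abs(U) > drive$Umax * (1 + 1e-9)))
    stop("`U` outside the ramp range [-Umax, Umax]")
}

#' Total membrane current versus voltage on the ramps
#'
#' First-order total current response (viscoelastic + elastic + ionic
#' branches) expressed as a function of the command voltage `U`.
#' `total_current_up()` is the rising-ramp response; `total_current_down_inv()`
#' is the falling-ramp response after time inversion, so both live on the same
#' ascending voltage axis and together form the hysteresis loop.
#'
#' @param U Command voltage(s), volts, within `[-Umax, Umax]`.
#' @param params A [membrane_params()].
#' @param drive A [drive_spec()].
#' @return Current in amperes.
#' @examples
#' p <- membrane_params(C0 = 897e-12, beta = 13.75, kappa = 0.2, tau = 0.019,
#'                      g = 0.05e-9, gamma = 5e-4)
#' total_current_up(0, p, drive_spec(0.2, 1))
#' @export
total_current_up <- function(U, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  check_U_range(U, drive)
  k <- drive$k; tau <- params$tau; C0 <- params$C0; fr <- 1 - params$kappa
  be <- params$beta * fr
  k * C0 * (1 + be * (U^2 + 5 * (k * tau)^2)) +
    (params$g + params$gamma * U^8 - 4 * be * k^2 * C0 * tau) * U -
    2 * k * C0 * fr * transient_exp(U + drive$Umax, k, tau)
}

#' @rdname total_current_up
#' @export
total_current_down_inv <- function(U, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  check_U_range(U, drive)
  k <- drive$k; tau <- params$tau; C0 <- params$C0; fr <- 1 - params$kappa
  be <- params$beta * fr
  -k * C0 * (1 + be * (U^2 + 5 * (k * tau)^2)) +
    (params$g + params$gamma * U^8 - 4 * be * k^2 * C0 * tau) * U +
    2 * k * C0 * fr * transient_exp(drive$Umax - U, k, tau)
}

#' Paired-ramp half-difference and half-sum of the current response
#'
#' The half-difference `(I_up - I_down_inv) / 2` isolates the capacitive part
#' of the response (even in `U`, a parabola `k * C0 * (1 + beta_exp * U^2)`
#' plus the lag correction), while the half-sum `(I_up + I_down_inv) / 2`
#' isolates the conductive part, whose slope at low voltage is the apparent
#' conductance `g_app = g - 4 * beta_exp * k^2 * C0 * tau`. The identities
#' `half_difference + half_sum = I_up` and
#' `half_difference - half_sum = -I_down_inv` are algebraic.
#'
#' @inheritParams total_current_up
#' @return Current in amperes.
#' @export
half_difference <- function(U, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  check_U_range(U, drive)
  k <- drive$k; tau <- params$tau; C0 <- params$C0; fr <- 1 - params$kappa
  be <- params$beta * fr
  k * C0 * (1 + be * (U^2 + 5 * (k * tau)^2)) -
    k * C0 * fr * (transient_exp(U + drive$Umax, k, tau) +
                   transient_exp(drive$Umax - U, k, tau))
}

#' @rdname half_difference
#' @export
half_sum <- function(U, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  check_U_range(U, drive)
  k <- drive$k; tau <- params$tau; C0 <- params$C0; fr <- 1 - params$kappa
  be <- params$beta * fr
  (params$g + params$gamma * U^8 - 4 * be * k^2 * C0 * tau) * U -
    k * C0 * fr * (transient_exp(U + drive$Umax, k, tau) -
                   transient_exp(drive$Umax - U, k, tau))
}

#' Apparent and zero-hysteresis conductance
#'
#' `apparent_conductance()` returns `g_app = g - 4 * beta_exp * k^2 * C0 *
#' tau`, the coefficient of the term linear in voltage in the total current —
#' the only conductance an experiment can read off directly. Its second
#' component is the negative insertion conductance created jointly by
#' capacitance nonlinearity and polarization lag. `zero_hysteresis_conductance()`
#' returns that insertion magnitude `g_star = 4 * beta_exp * k^2 * C0 * tau`,
#' the ionic conductance at which the loop width vanishes. With `gamma = 0`,
#' `g_app < 0` is the memcapacitive regime.
#'
#' @inheritParams total_current_up
#' @return Conductance in siemens.
#' @examples
#' p <- membrane_params(C0 = 1120e-12, beta = 18.75, kappa = 0.2, tau = 0.01)
#' zero_hysteresis_conductance(p, drive_spec(0.2, 2)) # 1.72e-9 S
#' @export
apparent_conductance <- function(params, drive) {
  params$g - zero_hysteresis_conductance(params, drive)
}

#' @rdname apparent_conductance
#' @export
zero_hysteresis_conductance <- function(params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  4 * params$beta * (1 - params$kappa) * drive$k^2 * params$C0 * params$tau
}

#' Capacitance-voltage hysteresis loop (closed form)
#'
#' Evaluates the two dynamic-capacitance branches `C_up = I_up / k` and
#' `C_down = I_down_inv / (-k)` on a voltage grid. In the memcapacitive
#' regime (`g_app < 0`, `gamma = 0`) the branches cross at `U = 0` with
#' `C_up` below `C_down` on the positive side: the pinched loop.
#'
#' @param params A [membrane_params()].
#' @param drive A [drive_spec()].
#' @param U_grid Ascending voltage grid in `[-Umax, Umax]`; defaults to `n`
#'   equally spaced points.
#' @param n Grid size used when `U_grid` is `NULL`.
#' @return A `memcap_curves` tibble with columns `U_V`, `I_up_A`,
#'   `I_down_inv_A`, `C_up_F`, `C_down_F`.
#' @examples
#' p <- membrane_params(C0 = 1120e-12, beta = 18.75, kappa = 0.2, tau = 0.01)
#' loops <- capacitance_loops(p, drive_spec(0.2, 2))
#' @export
capacitance_loops <- function(params, drive, U_grid = NULL, n = 201) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  if (is.null(U_grid))
    U_grid <- seq(-drive$Umax, drive$Umax, length.out = n)
  check_U_range(U_grid, drive)
  iu <- total_current_up(U_grid, params, drive)
  idi <- total_current_down_inv(U_grid, params, drive)
  new_curves(tibble::tibble(
    U_V = U_grid, I_up_A = iu, I_down_inv_A = idi,
    C_up_F = iu / drive$k, C_down_F = idi / (-drive$k)
  ), drive = drive, source = "analytic")
}

new_curves <- function(tbl, drive, source) {
  structure(tbl, drive = drive, source = source,
            class = c("memcap_curves", class(tbl)))
}

#' Width of the hysteresis loop
#'
#' Exact branch difference `C_up(U) - C_down(U) = 2 * half_sum(U) / k`. With
#' `gamma = 0` and the corner transients negligible this is
#' `(2 / k) * g_app * U`: a straight line through the pinch point at the
#' origin whose slope carries the sign of the apparent conductance. A
#' commonly quoted relative-width approximation drops the factor 2 and the
#' transient terms; this function keeps both.
#'
#' @inheritParams total_current_up
#' @return Capacitance difference in farads.
#' @export
loop_width <- function(U, params, drive) {
  2 * half_sum(U, params, drive) / drive$k
}

#' Work done by the voltage source per steady period
#'
#' Integrating current times voltage over one period of the steady nonlinear
#' response (corner transients excluded, `gamma = 0`) gives
#' `W = (T / 3) * Umax^2 * g_app`. Negative work (`g < g_star`) means the
#' membrane returns net energy to the source over a cycle through the
#' insertion conductance: the active memcapacitive regime. The dissipation of
#' the lag resistance driven by the corner transients is accounted
#' separately by [lag_dissipation_per_period()].
#'
#' @inheritParams apparent_conductance
#' @return Energy in joules.
#' @export
work_per_period <- function(params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  (drive$T / 3) * drive$Umax^2 * apparent_conductance(params, drive)
}

#' Energy dissipated by the polarization lag per period
#'
#' The corner-transient terms of the current response, multiplied by the
#' command voltage and integrated over a steady period, account for the
#' ohmic dissipation of the series (lag) resistance:
#' `W_lag = 4 * k * C0 * (1 - kappa) * tau * (Umax - k * tau)` at zeroth
#' order in `beta`. It is non-negative, vanishes with `tau` or with
#' `kappa = 1`, and is excluded from the steady-response work of
#' [work_per_period()].
#'
#' @inheritParams apparent_conductance
#' @return Energy in joules (>= 0).
#' @export
lag_dissipation_per_period <- function(params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  k <- drive$k; tau <- params$tau
  4 * k * params$C0 * (1 - params$kappa) * tau * (drive$Umax - k * tau)
}

#' Rising-ramp current of the ferroelectric counter-example
#'
#' The same perturbation treatment applied to a capacitor with the inverse
#' charge-voltage law (voltage growing as the cube of charge, as in a
#' ferroelectric, instead of charge growing as the cube of voltage as in the
#' membrane) yields
#' `I_up = k*C0*(1 - beta_exp*(U^2 + 5*(k*tau)^2)) +
#'   (g + gamma*U^8 + 4*beta_exp*k^2*C0*tau)*U - 2*k*C0*(1-kappa)*exp(...)`:
#' the capacitive parabola is inverted (capacitance decreases with voltage)
#' and the insertion conductance is positive, so the loop is not pinched and
#' the device is passive.
#'
#' @inheritParams total_current_up
#' @return Current in amperes.
#' @export
ferro_current_up <- function(U, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  check_U_range(U, drive)
  k <- drive$k; tau <- params$tau; C0 <- params$C0; fr <- 1 - params$kappa
  be <- params$beta * fr
  k * C0 * (1 - be * (U^2 + 5 * (k * tau)^2)) +
    (params$g + params$gamma * U^8 + 4 * be * k^2 * C0 * tau) * U -
    2 * k * C0 * fr * transient_exp(U + drive$Umax, k, tau)
}

#' @rdname ferro_current_up
#' @export
ferro_current_down_inv <- function(U, params, drive) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  check_U_range(U, drive)
  k <- drive$k; tau <- params$tau; C0 <- params$C0; fr <- 1 - params$kappa
  be <- params$beta * fr
  -k * C0 * (1 - be * (U^2 + 5 * (k * tau)^2)) +
    (params$g + params$gamma * U^8 + 4 * be * k^2 * C0 * tau) * U +
    2 * k * C0 * fr * transient_exp(drive$Umax - U, k, tau)
}

#' Classify the hysteresis regime
#'
#' Trichotomy on the sign of the apparent conductance (`gamma = 0` picture):
#' `g < g_star` gives a pinched loop with the rising-ramp current minimum
#' shifted to positive voltage (active memcapacitor); `g = g_star` closes the
#' loop; `g > g_star` opens it with the ordinary passive orientation.
#'
#' @inheritParams apparent_conductance
#' @param tol Relative tolerance on `g_app` against the `k * C0` current
#'   scale for calling the regime "zero-hysteresis".
#' @return One of `"memcapacitive"`, `"zero-hysteresis"`, `"passive"`.
#' @export
classify_regime <- function(params, drive, tol = 1e-3) {
  g_app <- apparent_conductance(params, drive)
  scale <- drive$k * params$C0 / drive$Umax
  if (abs(g_app) <= tol * scale) "zero-hysteresis"
  else if (g_app < 0) "memcapacitive"
  else "passive"
}
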