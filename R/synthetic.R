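#' Generate a synthetic voltage-clamp recording
#'
#' Emulates the recording protocol used for solvent-containing planar
#' bilayers: a periodic triangular command voltage, currents sampled at
#' `fs` (1 kHz by default) for 20-30 periods, optional first-order amplifier
#' filtering, and additive white Gaussian current noise. The membrane current
#' is the exact ODE solution of the equivalent circuit started from
#' equilibrium at `-Umax` (branch voltage equal to the command voltage at
#' `t = 0`), so the first cycles carry the physical startup transient that an
#' analysis pipeline is expected to discard.
#'
#' @param params A [membrane_params()].
#' @param drive A [drive_spec()].
#' @param amp Optional [amplifier_params()]; `NULL` for an ideal amplifier.
#' @param fs Sampling rate, Hz.
#' @param n_periods Number of drive periods recorded (>= 2).
#' @param noise_sd Standard deviation of the additive current noise, amperes.
#' @param seed Optional integer; when given, the noise is drawn under this
#'   seed without touching the session RNG state, so traces are reproducible
#'   bit for bit.
#' @param rel_tol,abs_tol Solver tolerances passed to the integrator.
#' @return A `memcap_trace` tibble with columns `time_s`, `voltage_V`,
#'   `current_A` and attributes `drive`, `fs` (and `params`, `amp`,
#'   `noise_sd` as generation provenance).
#' @examples
#' ref <- reference_parameter_sets()$azolectin
#' tr <- generate_trace(ref$params, ref$drive, n_periods = 3, noise_sd = 0)
#' @export
generate_trace <- function(params, drive, amp = NULL, fs = 1000,
                           n_periods = 25L, noise_sd = 5e-12, seed = NULL,
                           rel_tol = 1e-9, abs_tol = 1e-12) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  if (!is.null(amp)) stopifnot(inherits(amp, "memcap_amp"))
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  n_periods <- as.integer(n_periods)
  if (is.na(n_periods) || n_periods < 2L) stop("`n_periods` must be >= 2")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number")
  taus <- c(params$tau, if (!is.null(amp)) amp$tau_out)
  taus <- taus[taus > 0]
  if (length(taus) && fs * min(taus) < 2)
    warning("sampling rate under-resolves the fastest time constant", call. = FALSE)

  dt <- 1 / fs
  n <- round(n_periods * drive$T * fs)
  tt <- (seq_len(n) - 1L) * dt
  U <- command_voltage(tt, drive)

  i_mem <- simulate_current(params, drive, tt, rel_tol, abs_tol)
  i_out <- if (is.null(amp)) i_mem else filter_current(i_mem, amp, dt)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(n, 0, noise_sd)
             else withr::with_seed(as.integer(seed), stats::rnorm(n, 0, noise_sd))
    i_out <- i_out + noise
  }

  structure(
    tibble::tibble(time_s = tt, voltage_V = U, current_A = i_out),
    drive = drive, fs = fs, params = params, amp = amp, noise_sd = noise_sd,
    class = c("memcap_trace", class(tibble::tibble()))
  )
}

# exact membrane current at the sample times, integrating the branch-voltage
# ODE piecewise between slope reversals, started from Utilde(0) = U(0)
simulate_current <- function(params, drive, tt, rel_tol = 1e-9,
                             abs_tol = 1e-12) {
  Tp <- drive$T
  n <- length(tt)
  U <- command_voltage(tt, drive)
  if (params$tau == 0) {
    slope <- command_slope(tt, drive)
    i1 <- (1 - params$kappa) * params$C0 * (1 + params$beta * U^2) * slope
    if (params$kappa == 1) i1 <- rep(0, n)
    return(i1 + params$kappa * params$C0 * slope + ionic_current(U, params))
  }
  n_half <- ceiling(max(tt) / (Tp / 2) + 1e-9)
  ut <- numeric(n)
  y <- U[1L]  # membrane equilibrated at -Umax before the sweep starts
  for (h in seq_len(n_half)) {
    t0 <- (h - 1L) * Tp / 2
    t1 <- h * Tp / 2
    idx <- which(tt >= t0 - 1e-12 & tt < t1 - 1e-12)
    rising <- (h %% 2L) == 1L
    U0 <- if (rising) -drive$Umax else drive$Umax
    slope <- if (rising) drive$k else -drive$k
    deriv <- function(t, y, parms) {
      list((U0 + slope * t - y) / (params$tau * (1 + params$beta * y^2)))
    }
    loc <- c(tt[idx] - t0, Tp / 2)
    out <- deSolve::lsoda(y = c(y = y), times = c(0, loc), func = deriv,
                          rtol = rel_tol, atol = abs_tol)
    vals <- out[-1L, "y"]
    ut[idx] <- vals[seq_along(idx)]
    y <- unname(vals[length(vals)])
  }
  i1 <- (1 - params$kappa) * params$C0 * (U - ut) / params$tau
  if (params$kappa == 1) i1 <- rep(0, n)
  i2 <- params$kappa * params$C0 * command_slope(tt, drive)
  i1 + i2 + ionic_current(U, params)
}

#' Reference equivalent-circuit parameter sets
#'
#' Named parameter/drive pairs used throughout the package:
#' * `azolectin`: an azolectin membrane in 0.1 M KCl under a 200 mV,
#'   1 Hz triangular drive; `C0 = 897` pF, effective nonlinearity
#'   `beta_exp = 11` 1/V^2 (intrinsic `beta = beta_exp / (1 - kappa) =
#'   13.75` 1/V^2), `kappa = 0.2`, `tau = 19` ms, `g = 0.05` nS and the
#'   ninth-order conductance coefficient `gamma = 0.5e-18 nS/mV^8 = 5e-4
#'   S/V^8`.
#' * `regime_negative`, `regime_zero`, `regime_positive`: the regime-trichotomy sets (`C0 = 1120`
#'   pF, `tau = 10` ms, effective `beta_exp = 15` 1/V^2, 200 mV at 2 Hz,
#'   `gamma = 0`) with `g = 0`, `1.72` nS (the zero-hysteresis value) and
#'   `8` nS. The quoted nonlinearity is interpreted as the effective
#'   coefficient `beta * (1 - kappa)` with `kappa = 0.2`: that convention
#'   reproduces the reference zero-hysteresis conductance of 1.72 nS exactly.
#'
#' @return A named list; each element has `$params` ([membrane_params()]) and
#'   `$drive` ([drive_spec()]).
#' @export
reference_parameter_sets <- function() {
  regime_set <- function(g) list(
    params = membrane_params(C0 = 1120e-12, beta = 15 / 0.8, kappa = 0.2,
                             tau = 0.010, g = g, gamma = 0),
    drive = drive_spec(Umax = 0.2, f = 2)
  )
  list(
    azolectin = list(
      params = membrane_params(C0 = 897e-12, beta = 11 / 0.8, kappa = 0.2,
                               tau = 0.019, g = 0.05e-9, gamma = 5e-4),
      drive = drive_spec(Umax = 0.2, f = 1)
    ),
    regime_negative = regime_set(0),
    regime_zero = regime_set(1.72e-9),
    regime_positive = regime_set(8e-9)
  )
}
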