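#' Integrate the full nonlinear circuit to its periodic steady state
#'
#' Exact reference for the closed-form response: integrates the branch-voltage
#' state equation
#' `dUtilde/dt = (U(t) - Utilde) / (tau * (1 + beta * Utilde^2))`
#' (membrane law) or, for the ferroelectric counter-example, the charge-law
#' analogue `dv/dt = (U(t) - v - beta * v^3 / 3) / tau`, over whole periods of
#' the triangular drive until the Poincare map of the state at the period
#' start reaches a fixed point. Integration restarts at every slope reversal
#' so the adaptive stepper never crosses a corner of the drive.
#'
#' @param params A [membrane_params()].
#' @param drive A [drive_spec()].
#' @param rel_tol,abs_tol Solver tolerances (state in volts).
#' @param max_periods Give up (with an error reporting the residual) after
#'   this many periods without convergence.
#' @param n_out Output samples per period of the returned steady cycle.
#' @param law `"membrane"` (charge grows superlinearly with voltage) or
#'   `"ferroelectric"` (inverse law).
#' @param conv_tol Poincare fixed-point tolerance on the state, volts.
#' @return A `memcap_oracle` object: a tibble with columns `t_s`, `utilde_V`,
#'   `i1_A`, `i2_A`, `i3_A`, `I0_A` over one steady period, with attributes
#'   `n_periods_to_converge`, `params`, `drive`, `law`.
#' @examples
#' p <- membrane_params(C0 = 1e-9, beta = 4, kappa = 0.2, tau = 0.019)
#' sol <- integrate_to_steady_state(p, drive_spec(0.1, 1))
#' attr(sol, "n_periods_to_converge")
#' @export
integrate_to_steady_state <- function(params, drive,
                                      rel_tol = 1e-9, abs_tol = 1e-12,
                                      max_periods = 50L, n_out = 1000L,
                                      law = c("membrane", "ferroelectric"),
                                      conv_tol = 1e-10) {
  stopifnot(inherits(params, "memcap_params"), inherits(drive, "memcap_drive"))
  law <- match.arg(law)
  Tp <- drive$T
  half_n <- max(2L, ceiling(n_out / 2))

  if (params$tau == 0) {
    # algebraic limit: the branch voltage tracks the command voltage exactly
    tt <- seq(0, Tp, length.out = 2L * half_n + 1L)
    U <- command_voltage(tt, drive)
    sol <- oracle_assemble(tt, U, U, params, drive, law)
    attr(sol, "n_periods_to_converge") <- 0L
    return(sol)
  }

  # state y = Utilde (membrane) or v = q / C1 (ferroelectric); start from the
  # quasi-steady lag at the foot of the rising ramp
  y <- -drive$Umax + drive$k * params$tau
  half_times <- seq(0, Tp / 2, length.out = half_n + 1L)

  integrate_half <- function(y0, rising) {
    U0 <- if (rising) -drive$Umax else drive$Umax
    slope <- if (rising) drive$k else -drive$k
    deriv <- if (law == "membrane") {
      function(t, y, parms) {
        U <- U0 + slope * t
        list((U - y) / (params$tau * (1 + params$beta * y^2)))
      }
    } else {
      function(t, y, parms) {
        U <- U0 + slope * t
        list((U - y - params$beta * y^3 / 3) / params$tau)
      }
    }
    out <- deSolve::lsoda(y = c(y = y0), times = half_times, func = deriv,
                          rtol = rel_tol, atol = abs_tol)
    out[, "y"]
  }

  n_per <- 0L
  repeat {
    y_start <- y
    up <- integrate_half(y_start, rising = TRUE)
    dn <- integrate_half(up[half_n + 1L], rising = FALSE)
    y <- dn[half_n + 1L]
    n_per <- n_per + 1L
    resid <- abs(y - y_start)
    if (resid < conv_tol) break
    if (n_per >= max_periods)
      stop(sprintf(
        "no periodic steady state after %d periods (residual %.3e V)",
        n_per, resid))
  }

  tt <- c(half_times, Tp / 2 + half_times[-1L])
  ut <- c(up, dn[-1L])
  U <- command_voltage(pmin(tt, Tp * (1 - 1e-12)), drive)
  U[length(U)] <- -drive$Umax  # wrap: t = T is the start of the next period
  sol <- oracle_assemble(tt, U, ut, params, drive, law)
  attr(sol, "n_periods_to_converge") <- n_per
  sol
}

# branch currents and total current from the state trajectory
oracle_assemble <- function(tt, U, state, params, drive, law) {
  fr <- 1 - params$kappa
  if (params$tau == 0) {
    # i1 is the direct charging current of the (non-lagged) branch
    slope <- command_slope(tt, drive)
    i1 <- if (law == "membrane") {
      fr * params$C0 * (1 + params$beta * U^2) * slope
    } else {
      # dv/dt from U = v + beta v^3 / 3 differentiated implicitly
      fr * params$C0 * slope / (1 + params$beta * U^2)
    }
  } else {
    i1 <- if (law == "membrane") {
      fr * params$C0 * (U - state) / params$tau
    } else {
      fr * params$C0 * (U - state - params$beta * state^3 / 3) / params$tau
    }
  }
  if (params$kappa == 1) i1 <- rep(0, length(tt))
  i2 <- params$kappa * params$C0 * command_slope(tt, drive)
  i3 <- ionic_current(U, params)
  tbl <- tibble::tibble(t_s = tt, utilde_V = state, i1_A = i1, i2_A = i2,
                        i3_A = i3, I0_A = i1 + i2 + i3)
  structure(tbl, params = params, drive = drive, law = law,
            class = c("memcap_oracle", class(tbl)))
}

#' Fold a steady oracle period into current-versus-voltage branches
#'
#' Splits one steady period into the rising-half current and the
#' time-inverted falling-half current and interpolates both onto a common
#' ascending voltage grid, mirroring how recorded paired-ramp data are
#' presented.
#'
#' @param sol A `memcap_oracle` from [integrate_to_steady_state()].
#' @param U_grid Optional ascending voltage grid; defaults to the rising-half
#'   sample voltages.
#' @return A `memcap_curves` tibble (`U_V`, `I_up_A`, `I_down_inv_A`,
#'   `C_up_F`, `C_down_F`) with `source = "oracle"`.
#' @export
steady_current_vs_voltage <- function(sol, U_grid = NULL) {
  stopifnot(inherits(sol, "memcap_oracle"))
  drive <- attr(sol, "drive")
  params <- attr(sol, "params")
  Tp <- drive$T
  # recompute the elastic-branch current per half so the shared corner samples
  # (t = T/2 belongs to both halves) get the slope sign of their own half
  i_other <- sol$i1_A + sol$i3_A
  up <- sol$t_s <= Tp / 2 + 1e-15
  dn <- sol$t_s >= Tp / 2 - 1e-15
  t_up <- sol$t_s[up]
  U_up <- -drive$Umax + drive$k * t_up
  I_up <- i_other[up] + params$kappa * params$C0 * drive$k
  t_dn <- sol$t_s[dn] - Tp / 2
  # time inversion: sample at t' maps to t = T/2 - t', i.e. voltage
  # -Umax + k (T/2 - t')
  U_dn <- -drive$Umax + drive$k * (Tp / 2 - t_dn)
  I_dn <- i_other[dn] - params$kappa * params$C0 * drive$k
  ord <- order(U_dn)
  if (is.null(U_grid)) U_grid <- U_up
  I_up_g <- stats::approx(U_up, I_up, xout = U_grid, rule = 2)$y
  I_dn_g <- stats::approx(U_dn[ord], I_dn[ord], xout = U_grid, rule = 2)$y
  new_curves(tibble::tibble(
    U_V = U_grid, I_up_A = I_up_g, I_down_inv_A = I_dn_g,
    C_up_F = I_up_g / drive$k, C_down_F = I_dn_g / (-drive$k)
  ), drive = drive, source = "oracle")
}

#' Numerical work integral over one steady period
#'
#' Trapezoidal quadrature of current times command voltage over the steady
#' cycle of an oracle solution. `which` selects the total current or the
#' ionic branch only; their difference is the net energy taken by the
#' reactive branches (dissipated in the lag resistance).
#'
#' @param sol A `memcap_oracle`.
#' @param which `"total"` or `"ionic"`.
#' @return Energy in joules.
#' @export
oracle_work_per_period <- function(sol, which = c("total", "ionic")) {
  stopifnot(inherits(sol, "memcap_oracle"))
  which <- match.arg(which)
  drive <- attr(sol, "drive")
  U <- command_voltage(pmin(sol$t_s, drive$T * (1 - 1e-12)), drive)
  i <- if (which == "total") sol$I0_A else sol$i3_A
  trapz(sol$t_s, i * U)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
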