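#' Periodic triangular command voltage
#'
#' A drive specification describes the symmetric triangular command voltage
#' applied to the membrane in voltage-clamp mode: amplitude `Umax` (the sweep
#' spans `-Umax` to `+Umax`) and frequency `f`. The derived quantities are the
#' period `T = 1/f` and the sweep rate `k = 4 * Umax * f`, the absolute slope
#' of the ramps. By convention each period starts at `U = -Umax` on the rising
#' ramp, so the rising half covers `t` in `[0, T/2]` and the falling half
#' `[T/2, T]`.
#'
#' @param Umax Voltage amplitude in volts (> 0).
#' @param f Frequency in Hz (> 0).
#'
#' @return An object of class `memcap_drive`: a list with fields `Umax`, `f`,
#'   `T` (period, s) and `k` (sweep rate, V/s).
#' @examples
#' dr <- drive_spec(Umax = 0.2, f = 1)
#' dr$k # 0.8 V/s
#' @export
drive_spec <- function(Umax, f) {
  stopifnot(is.numeric(Umax), length(Umax) == 1, is.finite(Umax), Umax > 0,
            is.numeric(f), length(f) == 1, is.finite(f), f > 0)
  structure(
    list(Umax = as.numeric(Umax), f = as.numeric(f),
         T = 1 / as.numeric(f), k = 4 * as.numeric(Umax) * as.numeric(f)),
    class = "memcap_drive"
  )
}

#' @export
print.memcap_drive <- function(x, ...) {
  cat(sprintf("<memcap_drive> Umax = %g mV, f = %g Hz (T = %g s, k = %g V/s)\n",
              1e3 * x$Umax, x$f, x$T, x$k))
  invisible(x)
}

#' Sweep rate of a triangular drive
#'
#' @param drive A [drive_spec()].
#' @return The sweep rate `4 * Umax * f` in V/s.
#' @examples
#' sweep_rate(drive_spec(0.2, 1)) # 0.8
#' @export
sweep_rate <- function(drive) {
  stopifnot(inherits(drive, "memcap_drive"))
  drive$k
}

#' Evaluate the triangular command voltage
#'
#' The waveform is `T`-periodic and piecewise linear: `U = -Umax + k * t` on
#' the rising half-period and `U = Umax - k * (t - T/2)` on the falling one.
#' Times are reduced modulo the period, so any real `t` is accepted.
#'
#' @param t Time(s) in seconds (numeric vector).
#' @param drive A [drive_spec()].
#' @return The command voltage in volts, same length as `t`.
#' @examples
#' dr <- drive_spec(0.2, 1)
#' command_voltage(c(0, 0.25, 0.5), dr) # -0.2, 0, 0.2
#' @export
command_voltage <- function(t, drive) {
  stopifnot(inherits(drive, "memcap_drive"), is.numeric(t))
  if (any(!is.finite(t))) stop("`t` must be finite")
  tm <- t %% drive$T
  up <- tm <= drive$T / 2
  ifelse(up,
         -drive$Umax + drive$k * tm,
         drive$Umax - drive$k * (tm - drive$T / 2))
}

# slope of the command voltage (+k on the rising half, -k on the falling),
# sampled half-open so the corner at t = T/2 belongs to the falling half
command_slope <- function(t, drive) {
  tm <- t %% drive$T
  ifelse(tm < drive$T / 2, drive$k, -drive$k)
}
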