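#' Segment a recording and fold it over the drive cycle
#'
#' Implements the paired-ramp preprocessing applied to voltage-clamp
#' recordings: align the trace to the drive phase (each period starts at
#' `-Umax` on the rising ramp), discard the first cycles (startup
#' transient), average the remaining cycles pointwise, split the averaged
#' period into the rising-half current and the time-inverted falling-half
#' current, and optionally smooth with a centered moving average. The two
#' branches are also averaged into common voltage bins so they share one
#' ascending voltage grid.
#'
#' Phase alignment searches integer sample offsets of the recorded voltage
#' against the command waveform, so a trace that starts mid-cycle folds
#' identically to one that starts at a corner. If no voltage column is
#' present the trace is assumed to start at `U = -Umax`.
#'
#' @param trace A `memcap_trace` (or any data frame with `time_s`,
#'   `current_A` and optionally `voltage_V`).
#' @param drive A [drive_spec()]; defaults to the trace attribute.
#' @param discard_cycles Number of leading cycles dropped before averaging.
#' @param smooth_window Width of the centered moving-average smoother in
#'   seconds (30 ms by default, truncated at segment edges); 0 disables.
#'   Smoothing is applied to the binned curves; the time-domain branches are
#'   kept raw for transient analysis.
#' @param bin_width Voltage bin width in volts for the common grid.
#' @return A `memcap_fold` object: a list with
#'   * `curves`: tibble `U_V`, `I_up_A`, `I_down_inv_A` on the binned grid,
#'   * `up`, `down_inv`: full-resolution averaged branches (`t_s` measured
#'     from the rising-corner, `U_V`, `i_A`),
#'   * `n_cycles_used`, `smooth_window`, `phase_offset` (samples), `drive`,
#'     `fs`.
#' @export
segment_and_fold <- function(trace, drive = NULL, discard_cycles = 2L,
                             smooth_window = 0.03, bin_width = 0.002) {
  drive <- drive %||% attr(trace, "drive")
  if (is.null(drive)) stop("no drive specification: pass `drive`")
  stopifnot(inherits(drive, "memcap_drive"),
            all(c("time_s", "current_A") %in% names(trace)))
  fs <- attr(trace, "fs") %||% (1 / stats::median(diff(trace$time_s)))
  n <- nrow(trace)
  Np <- round(drive$T * fs)
  if (abs(Np - drive$T * fs) > 0.01 * Np)
    stop("drive period is not close to an integer number of samples")
  if (Np %% 2L != 0L)
    stop("drive period must span an even number of samples")
  Nh <- Np %/% 2L
  if (n < Np * (discard_cycles + 1L))
    stop("trace shorter than discard_cycles + 1 drive periods")

  offset <- 0L
  if ("voltage_V" %in% names(trace)) {
    tmpl <- command_voltage((seq_len(Np) - 1L) / fs, drive)
    v <- trace$current_A * 0 + trace$voltage_V  # force numeric
    n_cmp <- min(n - Np, Np)
    score <- vapply(seq_len(Np) - 1L, function(s) {
      sum((v[s + seq_len(n_cmp)] - tmpl[seq_len(n_cmp)])^2)
    }, numeric(1))
    offset <- which.min(score) - 1L
    if (sqrt(min(score) / n_cmp) > 0.05 * drive$Umax)
      stop("recorded voltage does not match the drive specification ",
           "(period or amplitude mismatch)")
  }

  n_cyc <- (n - offset) %/% Np
  if (n_cyc <= discard_cycles)
    stop("not enough complete cycles after discarding")
  use <- seq.int(discard_cycles + 1L, n_cyc)
  idx0 <- offset + (use - 1L) * Np
  # pointwise cycle average at full sample resolution
  per <- rowMeans(vapply(idx0, function(i0) trace$current_A[i0 + seq_len(Np)],
                         numeric(Np)))

  t_up <- (seq_len(Nh) - 1L) / fs
  up <- tibble::tibble(t_s = t_up, U_V = -drive$Umax + drive$k * t_up,
                       i_A = per[seq_len(Nh)])
  t_dn <- (seq_len(Nh) - 1L) / fs
  # time inversion: falling-half sample at t' plotted at t = T/2 - t'
  dn_inv <- tibble::tibble(t_s = drive$T / 2 - t_dn,
                           U_V = -drive$Umax + drive$k * (drive$T / 2 - t_dn),
                           i_A = per[Nh + seq_len(Nh)])
  dn_inv <- dn_inv[order(dn_inv$t_s), ]

  w <- max(1L, round(smooth_window * fs))
  i_up_s <- moving_average(up$i_A, w)
  i_dn_s <- moving_average(dn_inv$i_A, w)

  brk <- seq(-drive$Umax - bin_width / 2, drive$Umax + bin_width / 2,
             by = bin_width)
  bin_curve <- function(U, i) {
    cut_i <- findInterval(U, brk)
    tibble::tibble(bin = cut_i, U = U, i = i) |>
      dplyr::summarise(U_V = mean(.data$U), i_A = mean(.data$i),
                       n = dplyr::n(), .by = "bin")
  }
  bu <- bin_curve(up$U_V, i_up_s)
  bd <- bin_curve(dn_inv$U_V, i_dn_s)
  curves <- dplyr::inner_join(
    dplyr::rename(bu, I_up_A = "i_A", n_up = "n", U_up = "U_V"),
    dplyr::rename(bd, I_down_inv_A = "i_A", n_down = "n", U_down = "U_V"),
    by = "bin")
  curves <- tibble::tibble(
    U_V = (curves$U_up * curves$n_up + curves$U_down * curves$n_down) /
      (curves$n_up + curves$n_down),
    I_up_A = curves$I_up_A, I_down_inv_A = curves$I_down_inv_A,
    n_up = curves$n_up, n_down = curves$n_down)
  curves <- curves[order(curves$U_V), ]

  structure(
    list(curves = curves, up = up, down_inv = dn_inv,
         n_cycles_used = length(use), smooth_window = smooth_window,
         phase_offset = offset, drive = drive, fs = fs),
    class = "memcap_fold")
}

#' @export
print.memcap_fold <- function(x, ...) {
  cat(sprintf(
    "<memcap_fold> %d cycles averaged, %d voltage bins, smoothing %g ms, phase offset %d samples\n",
    x$n_cycles_used, nrow(x$curves), 1e3 * x$smooth_window, x$phase_offset))
  invisible(x)
}

# centered moving average, window truncated at the edges
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Half-sum / half-difference decomposition of a folded response
#'
#' Exact pointwise arithmetic on the folded branches: the half-difference
#' `(I_up - I_down_inv) / 2` is the capacitive (even) component and the
#' half-sum `(I_up + I_down_inv) / 2` the conductive (odd) component of the
#' paired-ramp response.
#'
#' @param folded A `memcap_fold` from [segment_and_fold()].
#' @return A tibble `U_V`, `I_up_A`, `I_down_inv_A`, `half_diff_A`,
#'   `half_sum_A`.
#' @export
paired_ramp_decompose <- function(folded) {
  stopifnot(inherits(folded, "memcap_fold"))
  cv <- folded$curves
  tibble::tibble(
    U_V = cv$U_V, I_up_A = cv$I_up_A, I_down_inv_A = cv$I_down_inv_A,
    half_diff_A = (cv$I_up_A - cv$I_down_inv_A) / 2,
    half_sum_A = (cv$I_up_A + cv$I_down_inv_A) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
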