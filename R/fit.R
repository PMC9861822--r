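#' Parabolic fit of the paired-ramp capacitance curve
#'
#' Least-squares fit of `half_diff / k = a + b * U^2` over the low-voltage
#' window, where the corner-transient exponentials are negligible. The
#' constant is the apparent zero-voltage capacitance
#' `C_exp0 = C0 * (1 + 5 * beta_exp * (k * tau)^2)` and the curvature is
#' `b = C0 * beta_exp`, so once the lag time is known the bare capacitance
#' follows as `C0 = a - 5 * b * (k * tau)^2` and the effective nonlinearity
#' as `beta_exp = b / C0`.
#'
#' @param decomp Output of [paired_ramp_decompose()].
#' @param drive A [drive_spec()].
#' @param fit_window Half-width of the voltage window as a fraction of
#'   `Umax`.
#' @param guard Additional guard band in volts excluded at both ends of the
#'   sweep (a band of `3 * k * tau` after each ramp start keeps the corner
#'   exponentials below `exp(-3)` of their initial size inside the window).
#' @return A list with `C_exp0_hat` (F), `quad_coef` (F/V^2), `n`, `rms` (F).
#' @export
fit_capacitance <- function(decomp, drive, fit_window = 0.6, guard = 0) {
  stopifnot(inherits(drive, "memcap_drive"))
  w <- abs(decomp$U_V) <= pmin(fit_window * drive$Umax, drive$Umax - guard)
  if (sum(w) < 5) stop("fewer than 5 grid points in the capacitance window")
  U <- decomp$U_V[w]
  y <- decomp$half_diff_A[w] / drive$k
  fit <- stats::lm(y ~ I(U^2))
  list(C_exp0_hat = unname(coef(fit)[1]), quad_coef = unname(coef(fit)[2]),
       n = sum(w), rms = sqrt(mean(stats::residuals(fit)^2)),
       fit_window = fit_window)
}

#' Linear fit of the apparent conductance
#'
#' Slope of the least-squares line through the origin fitted to the
#' half-sum over the low-voltage window (where both the corner transients
#' and the ninth-order ionic term are negligible). The slope is the apparent
#' conductance `g_app = g - 4 * beta_exp * k^2 * C0 * tau`; a negative value
#' is the signature of the insertion conductance outweighing the ionic one.
#'
#' @param decomp Output of [paired_ramp_decompose()].
#' @param drive A [drive_spec()].
#' @param fit_window Half-width of the window as a fraction of `Umax`.
#' @param guard Guard band in volts excluded at both sweep ends (see
#'   [fit_capacitance()]).
#' @return A list with `g_app_hat` (S), `n`, `rms` (A).
#' @export
fit_apparent_conductance <- function(decomp, drive, fit_window = 0.5,
                                     guard = 0) {
  stopifnot(inherits(drive, "memcap_drive"))
  w <- abs(decomp$U_V) <= pmin(fit_window * drive$Umax, drive$Umax - guard)
  if (sum(w) < 5) stop("fewer than 5 grid points in the conductance window")
  U <- decomp$U_V[w]
  y <- decomp$half_sum_A[w]
  g_app <- sum(U * y) / sum(U^2)
  list(g_app_hat = g_app, n = sum(w),
       rms = sqrt(mean((y - g_app * U)^2)), fit_window = fit_window)
}

#' Ninth-order conductance trend from the half-sum tails
#'
#' Least-squares coefficient of `U^9` in the residual half-sum after
#' removing the apparent-conductance line, over the high-voltage tails
#' `|U| > tail_from * Umax`. This mirrors how the steep current growth near
#' the rails is summarised: a trend, not a precise parameter, since the
#' tails also hold the corner transients.
#'
#' @param decomp Output of [paired_ramp_decompose()].
#' @param drive A [drive_spec()].
#' @param g_app_hat Apparent conductance from [fit_apparent_conductance()].
#' @param tail_from Lower edge of the tail window as a fraction of `Umax`.
#' @return `gamma_hat` in S/V^8 (clamped at 0).
#' @export
fit_gamma_trend <- function(decomp, drive, g_app_hat, tail_from = 0.75) {
  w <- abs(decomp$U_V) > tail_from * drive$Umax
  if (sum(w) < 4) return(0)
  U <- decomp$U_V[w]
  r <- decomp$half_sum_A[w] - g_app_hat * U
  max(0, sum(r * U^9) / sum(U^18))
}

#' Transient fit of the folded post-reversal current
#'
#' Fits the early-time current after the rising-corner of the folded
#' record. Without an amplifier model the current is a smooth polynomial
#' background minus the slow viscoelastic exponential
#' `a_slow * exp(-t / tau)`; with an amplifier a fast feedback exponential
#' `a_fast * exp(-t / tau_out)` is added. Amplitudes enter linearly, so the
#' time constants are profiled: for each candidate (`tau`, `tau_out`) the
#' amplitudes and background solve a linear least-squares problem, and the
#' profile residual is minimised.
#'
#' The elastic fraction is recovered from the amplitude relations. At
#' finite nonlinearity the slow amplitude is inflated to
#' `2 * (1 - kappa) * k * C0 * (1 + beta * Umax^2)`, i.e.
#' `a_slow / (2 k C0) = (1 - kappa) + beta_exp * Umax^2`, which the
#' estimator inverts when `beta_exp_ref` is supplied. Without an amplifier
#' the fast (elastic) amplitude is not smeared over a feedback time
#' constant: it appears as the instantaneous corner jump `2 * kappa * k *
#' C0` between the last falling-half sample and the first rising-half
#' sample, which gives a direct, nonlinearity-insensitive `kappa` estimate
#' (`kappa_jump`); that value is reported as `kappa_hat` in this case.
#'
#' @param folded A `memcap_fold`.
#' @param drive A [drive_spec()].
#' @param amp Optional [amplifier_params()]; when present a two-exponential
#'   model is fitted.
#' @param kC0_ref Reference steady capacitive current `k * C0` in amperes
#'   (from the capacitance fit) used to normalise amplitudes.
#' @param beta_exp_ref Effective nonlinearity used for the amplitude
#'   correction; 0 disables it.
#' @param window Fit window in seconds after the corner; default `5 *
#'   tau_guess` with `tau_guess` from a coarse profile search.
#' @return A list with `kappa_hat`, `tau_hat` (s), `tau_out_hat` (s or NA),
#'   `kappa_jump` (NA with an amplifier), `kappa_amp`, `a_slow`, `a_fast`
#'   (A), `reliable` (FALSE when the two time constants are within 20% of
#'   each other), `window` (s), `rms` (A).
#' @export
fit_transient <- function(folded, drive = NULL, amp = NULL, kC0_ref,
                          beta_exp_ref = 0, window = NULL) {
  stopifnot(inherits(folded, "memcap_fold"))
  drive <- drive %||% folded$drive
  Umax <- drive$Umax
  two_exp <- !is.null(amp) && amp$tau_out > 0

  # the transient is fitted on the time-domain half-difference, where the
  # ionic terms of the two branches cancel exactly (same voltage, same odd
  # current) and only the capacitive parabola plus the rising-corner
  # exponentials remain; the falling-corner exponential of the inverted
  # branch lives at the far end of the window and is negligible there
  t <- folded$up$t_s
  i_dn <- stats::approx(folded$down_inv$t_s, folded$down_inv$i_A,
                        xout = t, rule = 2)$y
  y <- (folded$up$i_A - i_dn) / 2

  # linear-profile residual for fixed time constants
  design <- function(sel, taus) {
    X <- cbind(1, t[sel], t[sel]^2,
               exp(-t[sel] / taus[1]),
               if (length(taus) > 1) exp(-t[sel] / taus[2]))
    ls <- stats::lsfit(X, y[sel], intercept = FALSE)
    list(coef = ls$coefficients, rss = sum(ls$residuals^2),
         rms = sqrt(mean(ls$residuals^2)))
  }

  # coarse time-constant search, then profile refinement on a 5 tau window
  coarse_tau <- exp(seq(log(2e-4), log(drive$T / 10), length.out = 30))
  sel0 <- t <= drive$T / 4
  if (!two_exp) {
    rss0 <- vapply(coarse_tau, function(tt) design(sel0, tt)$rss, numeric(1))
    tau_g <- coarse_tau[which.min(rss0)]
    if (is.null(window)) window <- 5 * tau_g
    sel <- t <= window
    if (sum(sel) < 8) stop("transient window holds fewer than 8 samples")
    opt <- stats::optimize(function(tt) design(sel, tt)$rss,
                           interval = c(tau_g / 5, min(5 * tau_g, drive$T / 4)),
                           tol = 1e-10)
    tau_hat <- opt$minimum
    fin <- design(sel, tau_hat)
    a_slow <- -fin$coef[4]
    a_fast <- NA_real_
    tau_out_hat <- NA_real_
    reliable <- TRUE
  } else {
    grid <- expand.grid(tau = coarse_tau, tau_out = coarse_tau)
    grid <- grid[grid$tau_out < grid$tau, ]
    rss0 <- mapply(function(a, b) design(sel0, c(a, b))$rss,
                   grid$tau, grid$tau_out)
    st <- grid[which.min(rss0), ]
    if (is.null(window)) window <- 5 * st$tau
    sel <- t <= window
    if (sum(sel) < 10) stop("transient window holds fewer than 10 samples")
    opt <- stats::optim(log(c(st$tau, st$tau_out)), function(lt) {
      design(sel, exp(lt))$rss
    }, method = "Nelder-Mead", control = list(reltol = 1e-12, maxit = 400))
    taus <- exp(opt$par)
    tau_hat <- max(taus); tau_out_hat <- min(taus)
    fin <- design(sel, c(tau_hat, tau_out_hat))
    a_slow <- -fin$coef[4]
    a_fast <- -fin$coef[5]
    reliable <- abs(tau_hat - tau_out_hat) > 0.2 * tau_hat
    if (!reliable)
      warning("slow and fast time constants are within 20%: ",
              "the elastic fraction is not identifiable", call. = FALSE)
  }

  # amplitude relations -> elastic fraction (half-difference amplitudes are
  # half the raw-current jump amplitudes)
  if (two_exp) {
    one_minus_kappa <- a_slow * (1 - tau_out_hat / tau_hat) / kC0_ref -
      beta_exp_ref * Umax^2
    kappa_amp <- 1 - one_minus_kappa
    kappa_jump <- NA_real_
    kappa_hat <- kappa_amp
  } else {
    one_minus_kappa <- a_slow / kC0_ref - beta_exp_ref * Umax^2
    kappa_amp <- 1 - one_minus_kappa
    # elastic corner jump: last falling sample to first rising sample of the
    # raw folded branches (the tau_out -> 0 limit of the fast exponential)
    i_before <- folded$down_inv$i_A[which.min(folded$down_inv$t_s)]
    kappa_jump <- (folded$up$i_A[1] - i_before) / (2 * kC0_ref)
    kappa_hat <- kappa_jump
  }
  kappa_hat <- min(1, max(0, kappa_hat))

  list(kappa_hat = kappa_hat, tau_hat = tau_hat, tau_out_hat = tau_out_hat,
       kappa_jump = kappa_jump, kappa_amp = kappa_amp,
       a_slow = unname(a_slow), a_fast = unname(a_fast),
       reliable = reliable, window = window, rms = fin$rms)
}

# steady-state branch voltage at requested within-half times, for the exact
# forward model used in refinement
steady_branch_voltages <- function(params, drive, t_up, t_down,
                                   rel_tol = 1e-8, abs_tol = 1e-11) {
  Tp <- drive$T
  if (params$tau == 0) {
    return(list(up = -drive$Umax + drive$k * t_up,
                dn = drive$Umax - drive$k * t_down))
  }
  half <- function(y0, rising, times) {
    U0 <- if (rising) -drive$Umax else drive$Umax
    slope <- if (rising) drive$k else -drive$k
    deriv <- function(t, y, parms)
      list((U0 + slope * t - y) / (params$tau * (1 + params$beta * y^2)))
    tt <- sort(unique(c(0, times, Tp / 2)))
    out <- suppressWarnings(
      deSolve::lsoda(c(y = y0), tt, deriv, rtol = rel_tol, atol = abs_tol))
    if (nrow(out) < length(tt) || anyNA(out[, "y"]))
      stop("integration failed", call. = FALSE)
    list(at = unname(out[match(times, tt), "y"]),
         end = unname(out[nrow(out), "y"]))
  }
  y <- -drive$Umax + drive$k * params$tau
  # Poincare iteration to the periodic state
  for (p in seq_len(25L)) {
    y0 <- y
    e_up <- half(y, TRUE, numeric(0))$end
    y <- half(e_up, FALSE, numeric(0))$end
    if (abs(y - y0) < 1e-10) break
  }
  up <- half(y, TRUE, t_up)
  dn <- half(up$end, FALSE, t_down)
  list(up = up$at, dn = dn$at)
}

# steady periodic response of the amplifier filter to a one-period input:
# run the exponential-hold recursion over repeated copies until the cycle
# start value settles
filter_periodic <- function(x, amp, dt) {
  if (is.null(amp) || amp$tau_out == 0) return(x)
  y_prev <- x[1]
  for (rep in 1:8) {
    y <- filter_current(x, amp, dt, init = y_prev)
    if (abs(y[length(y)] - y_prev) < 1e-12 * max(abs(x), 1e-300)) break
    y_prev <- y[length(y)]
  }
  y
}

# exact-model refinement of (kappa, tau): the folded rising and
# (time-inverted) falling branches are matched against the steady-state
# circuit response, with C0 and beta tied to the measured parabola
# (C0 = a - 5 b (k tau)^2, beta = b / (C0 (1 - kappa))) and the ionic
# parameters (g, gamma) profiled linearly at each candidate point. When the
# recording went through the amplifier feedback filter, the model (base
# response and ionic regressors alike) is passed through the same filter in
# period order, so data and model see identical instrumentation.
refine_kappa_tau <- function(folded, drive, cap, kappa0, tau0, amp = NULL,
                             control = list(reltol = 1e-10, maxit = 200)) {
  t_up <- folded$up$t_s
  U_up <- folded$up$U_V
  t_dn <- drive$T / 2 - folded$down_inv$t_s   # back to falling-half time
  U_dn <- folded$down_inv$U_V
  y <- c(folded$up$i_A, folded$down_inv$i_A)
  Uall <- c(U_up, U_dn)
  k <- drive$k
  a <- cap$C_exp0_hat; b <- cap$quad_coef
  i_scale <- k * a  # residuals are scaled to the capacitive current so the
                    # optimizer tolerances are meaningful in relative terms

  # period ordering (rising half by time, falling half by its own time) and
  # the inverse map back to the c(up, down_inv) data layout
  n_up <- length(t_up)
  ord_dn <- order(t_dn)
  period_order <- c(seq_len(n_up), n_up + ord_dn)
  inv_order <- order(period_order)
  dt <- 1 / folded$fs
  apply_amp <- function(v) {
    if (is.null(amp) || amp$tau_out == 0) return(v)
    filter_periodic(v[period_order], amp, dt)[inv_order]
  }
  X <- cbind(apply_amp(Uall), apply_amp(Uall^9)) / i_scale

  eval_rss <- function(theta) {
    tau <- exp(theta[1])
    kappa <- stats::plogis(theta[2])
    C0 <- a - 5 * b * (k * tau)^2
    if (C0 <= 0) return(list(rss = Inf))
    beta <- b / (C0 * (1 - kappa))
    if (!is.finite(beta) || beta < 0) return(list(rss = Inf))
    p <- membrane_params(C0 = C0, beta = beta, kappa = kappa, tau = tau)
    ut <- tryCatch(steady_branch_voltages(p, drive, t_up, t_dn),
                   error = function(e) NULL)
    if (is.null(ut)) return(list(rss = Inf))
    i1_up <- (1 - kappa) * C0 * (U_up - ut$up) / tau
    i1_dn <- (1 - kappa) * C0 * (U_dn - ut$dn) / tau
    base <- apply_amp(c(i1_up + kappa * C0 * k, i1_dn - kappa * C0 * k))
    ls <- stats::lsfit(X, (y - base) / i_scale, intercept = FALSE)
    list(rss = sum(ls$residuals^2), g = ls$coefficients[1],
         gamma = ls$coefficients[2],
         rms = i_scale * sqrt(mean(ls$residuals^2)),
         params = p)
  }

  start <- c(log(tau0), stats::qlogis(min(0.95, max(0.05, kappa0))))
  opt <- stats::optim(start, function(th) eval_rss(th)$rss,
                      method = "Nelder-Mead", control = control)
  fin <- eval_rss(opt$par)
  list(tau_hat = exp(opt$par[1]), kappa_hat = stats::plogis(opt$par[2]),
       g_direct = unname(fin$g), gamma_direct = unname(max(0, fin$gamma)),
       rms = fin$rms, convergence = opt$convergence)
}

#' Assemble the full parameter estimate
#'
#' Combines the component fits into the final equivalent-circuit estimate:
#' `C0_hat = C_exp0_hat - 5 * quad_coef * (k * tau_hat)^2` (the apparent
#' capacitance corrected for the lag), `beta_exp_hat = quad_coef / C0_hat`,
#' and `g_hat = g_app_hat + 4 * beta_exp_hat * k^2 * C0_hat * tau_hat` (the
#' insertion term added back), with the ninth-order conductance reported as
#' a trend.
#'
#' @param cap Output of [fit_capacitance()].
#' @param cond Output of [fit_apparent_conductance()].
#' @param transient Output of [fit_transient()].
#' @param drive A [drive_spec()].
#' @param decomp Output of [paired_ramp_decompose()] (for the gamma trend).
#' @param refined Optional output of the exact-model refinement; when
#'   present its `kappa`/`tau` supersede the transient-fit values.
#' @param folded Optional `memcap_fold` carried for diagnostics/plotting.
#' @return A `memcap_fit` object; see [estimate_membrane()].
#' @export
assemble_parameters <- function(cap, cond, transient, drive, decomp = NULL,
                                refined = NULL, folded = NULL) {
  k <- drive$k
  tau_hat <- refined$tau_hat %||% transient$tau_hat
  kappa_hat <- refined$kappa_hat %||% transient$kappa_hat
  C0_hat <- cap$C_exp0_hat - 5 * cap$quad_coef * (k * tau_hat)^2
  beta_exp_hat <- cap$quad_coef / C0_hat
  g_star_hat <- 4 * beta_exp_hat * k^2 * C0_hat * tau_hat
  g_hat <- cond$g_app_hat + g_star_hat
  gamma_hat <- if (!is.null(decomp))
    fit_gamma_trend(decomp, drive, cond$g_app_hat) else NA_real_

  est <- tibble::tibble(
    term = c("C0", "beta_exp", "kappa", "tau", "g_app", "g", "gamma",
             "C_exp0", "g_star"),
    estimate = c(C0_hat, beta_exp_hat, kappa_hat, tau_hat, cond$g_app_hat,
                 g_hat, gamma_hat, cap$C_exp0_hat, g_star_hat),
    unit = c("F", "1/V^2", "", "s", "S", "S", "S/V^8", "F", "S"))

  structure(
    list(estimates = est, drive = drive,
         fits = list(capacitance = cap, conductance = cond,
                     transient = transient, refined = refined),
         decomp = decomp, folded = folded),
    class = "memcap_fit")
}

#' Estimate equivalent-circuit parameters from a voltage-clamp trace
#'
#' The full paired-ramp analysis pipeline: fold the recording over the
#' drive cycle ([segment_and_fold()]), decompose into half-sum and
#' half-difference ([paired_ramp_decompose()]), fit the capacitance
#' parabola and the apparent-conductance line, fit the post-reversal
#' transient for the elastic fraction and lag time, optionally refine
#' `kappa` and `tau` by matching the folded record against the exact
#' circuit ODE (with the ionic parameters profiled), and assemble the
#' final parameter set.
#'
#' @param trace A `memcap_trace` or data frame (`time_s`, `current_A`,
#'   optionally `voltage_V`).
#' @param drive A [drive_spec()]; defaults to the trace attribute.
#' @param amp Optional [amplifier_params()] describing the recording
#'   amplifier (enables the two-exponential transient model).
#' @param discard_cycles,smooth_window,bin_width Passed to
#'   [segment_and_fold()].
#' @param cap_window,cond_window Fit windows (fractions of `Umax`).
#' @param refine Refine `kappa`/`tau` against the exact model (recommended;
#'   disable for speed on linear membranes).
#' @return A `memcap_fit`; use [tidy()] for the parameter table, [glance()]
#'   for one-row diagnostics, `autoplot()` for data-versus-fit curves.
#' @examples
#' ref <- reference_parameter_sets()$azolectin
#' tr <- generate_trace(ref$params, ref$drive, n_periods = 5, noise_sd = 0)
#' fit <- estimate_membrane(tr)
#' tidy(fit)
#' @export
estimate_membrane <- function(trace, drive = NULL, amp = NULL,
                              discard_cycles = 2L, smooth_window = 0.03,
                              bin_width = 0.002, cap_window = 0.6,
                              cond_window = 0.5, refine = TRUE) {
  drive <- drive %||% attr(trace, "drive")
  folded <- segment_and_fold(trace, drive, discard_cycles = discard_cycles,
                             smooth_window = smooth_window,
                             bin_width = bin_width)
  decomp <- paired_ramp_decompose(folded)
  cap <- fit_capacitance(decomp, drive, fit_window = cap_window)
  cond <- fit_apparent_conductance(decomp, drive, fit_window = cond_window)
  kC0_ref <- drive$k * cap$C_exp0_hat
  beta_exp_ref <- cap$quad_coef / cap$C_exp0_hat
  transient <- fit_transient(folded, drive, amp = amp, kC0_ref = kC0_ref,
                             beta_exp_ref = beta_exp_ref)
  # second pass: once the lag time is known, exclude a 3*k*tau guard band
  # after each ramp start so the corner exponentials cannot bias the
  # low-voltage fits
  guard <- 3 * drive$k * transient$tau_hat
  if (guard > 0.02 * drive$Umax) {
    cap <- tryCatch(
      fit_capacitance(decomp, drive, fit_window = cap_window, guard = guard),
      error = function(e) cap)
    cond <- tryCatch(
      fit_apparent_conductance(decomp, drive, fit_window = cond_window,
                               guard = guard),
      error = function(e) cond)
  }
  refined <- NULL
  if (refine) {
    refined <- refine_kappa_tau(folded, drive, cap,
                                kappa0 = transient$kappa_hat,
                                tau0 = transient$tau_hat, amp = amp)
  }
  assemble_parameters(cap, cond, transient, drive, decomp = decomp,
                      refined = refined, folded = folded)
}

#' @export
print.memcap_fit <- function(x, ...) {
  e <- x$estimates
  pick <- function(term) e$estimate[e$term == term]
  cat("<memcap_fit> paired-ramp equivalent-circuit estimate\n")
  cat(sprintf("  C0 = %.1f pF   beta_exp = %.2f 1/V^2   kappa = %.3f\n",
              1e12 * pick("C0"), pick("beta_exp"), pick("kappa")))
  cat(sprintf("  tau = %.2f ms   g_app = %.3f nS   g = %.3f nS\n",
              1e3 * pick("tau"), 1e9 * pick("g_app"), 1e9 * pick("g")))
  invisible(x)
}
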