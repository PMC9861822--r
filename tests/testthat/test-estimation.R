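test_that("folding a linear membrane reproduces the closed-form branches", {
  p <- linear_params(g = 0, tau = 0.019, C0 = 1e-9)
  dr <- drive_spec(0.15, 1)
  tr <- generate_trace(p, dr, n_periods = 5, noise_sd = 0)
  fold <- segment_and_fold(tr, smooth_window = 0)
  closed <- dr$k * p$C0 *
    (1 - 2 * (1 - p$kappa) * exp(-(fold$up$U_V + dr$Umax) / (dr$k * p$tau)))
  expect_equal(fold$up$i_A, closed, tolerance = 1e-5)
  # folding is idempotent over extra cycles for a noiseless periodic record
  tr2 <- generate_trace(p, dr, n_periods = 8, noise_sd = 0)
  fold2 <- segment_and_fold(tr2, smooth_window = 0)
  expect_equal(fold2$up$i_A, fold$up$i_A, tolerance = 1e-9)
  # antisymmetry of the lossless membrane: I_down_inv(U) = -I_up(-U)
  i_up_rev <- approx(fold$up$U_V, fold$up$i_A,
                     xout = -fold$down_inv$U_V)$y
  ok <- !is.na(i_up_rev)
  expect_equal(fold$down_inv$i_A[ok], -i_up_rev[ok], tolerance = 1e-4)
})

test_that("folding realigns an arbitrary integer-sample phase offset", {
  p <- linear_params(g = 1e-9)
  dr <- drive_spec(0.1, 2)
  tr <- generate_trace(p, dr, n_periods = 6, noise_sd = 0)
  # rotate the steady part of the record by a third of a period
  shift <- 167L
  n <- nrow(tr)
  idx <- c((shift + 1L):n, 1:shift)
  tr_shift <- tibble::tibble(time_s = tr$time_s,
                             voltage_V = tr$voltage_V[idx],
                             current_A = tr$current_A[idx])
  attr(tr_shift, "fs") <- 1000
  f0 <- segment_and_fold(tr, dr, discard_cycles = 3, smooth_window = 0)
  f1 <- segment_and_fold(tr_shift, dr, discard_cycles = 3, smooth_window = 0)
  expect_equal(f1$phase_offset, (1000 / 2 - shift) %% 500)
  expect_equal(f1$up$i_A, f0$up$i_A, tolerance = 1e-3)
})

test_that("folding rejects traces that do not match the drive", {
  p <- linear_params()
  tr <- generate_trace(p, drive_spec(0.1, 1), n_periods = 3, noise_sd = 0)
  expect_error(segment_and_fold(tr, drive_spec(0.1, 1.4)),
               "does not match|integer")
  expect_error(segment_and_fold(tr[1:1500, ], drive_spec(0.1, 1)),
               "shorter|cycles")
  expect_error(segment_and_fold(tibble::tibble(time_s = 1, current_A = 1)),
               "drive")
})

test_that("decomposition is exact pointwise arithmetic", {
  fold <- segment_and_fold(azolectin_trace())
  d <- paired_ramp_decompose(fold)
  expect_equal(d$half_diff_A + d$half_sum_A, d$I_up_A, tolerance = 1e-15)
  expect_equal(d$half_diff_A - d$half_sum_A, -d$I_down_inv_A,
               tolerance = 1e-15)
})

test_that("capacitance and conductance fits read the closed forms back", {
  # fit on curves built from the closed-form response: pure regression check
  p <- refs$azolectin$params
  dr <- refs$azolectin$drive
  U <- seq(-0.2, 0.2, by = 0.002)
  d <- tibble::tibble(
    U_V = U,
    half_diff_A = half_difference(U, p, dr),
    half_sum_A = half_sum(U, p, dr))
  cap <- fit_capacitance(d, dr)
  expect_equal(cap$C_exp0_hat, derived_params(p, dr)$C_exp0, tolerance = 1e-5)
  expect_equal(cap$quad_coef, p$C0 * 11, tolerance = 1e-3)
  cond <- fit_apparent_conductance(d, dr)
  expect_equal(cond$g_app_hat, apparent_conductance(p, dr), tolerance = 5e-3)
  # windows that leave too few points are rejected
  expect_error(fit_capacitance(d[abs(d$U_V) < 0.003, ], dr), "fewer than")
  expect_error(fit_apparent_conductance(d[1:3, ], dr), "fewer than")
  # a membrane without nonlinearity fits a flat parabola (short lag so the
  # corner exponentials are fully decayed inside the window)
  p0 <- linear_params(g = 1e-9, tau = 0.005)
  d0 <- tibble::tibble(U_V = U, half_diff_A = half_difference(U, p0, dr),
                       half_sum_A = half_sum(U, p0, dr))
  cap0 <- fit_capacitance(d0, dr)
  expect_lt(abs(cap0$quad_coef / cap0$C_exp0_hat) * dr$Umax^2, 1e-3)
  expect_equal(fit_apparent_conductance(d0, dr)$g_app_hat, 1e-9,
               tolerance = 1e-3)
})

test_that("transient fit identifies the lag and the elastic fraction", {
  fold <- segment_and_fold(azolectin_trace())
  dr <- refs$azolectin$drive
  p <- refs$azolectin$params
  d <- paired_ramp_decompose(fold)
  cap <- fit_capacitance(d, dr)
  tf <- fit_transient(fold, dr, kC0_ref = dr$k * cap$C_exp0_hat,
                      beta_exp_ref = cap$quad_coef / cap$C_exp0_hat)
  # the corner jump isolates the elastic branch
  expect_equal(tf$kappa_jump, 0.2, tolerance = 0.1)
  # single-exponential lag estimate lands near tau (rate-variation bias
  # at this nonlinearity is removed later by the exact-model refinement)
  expect_equal(tf$tau_hat, p$tau, tolerance = 0.35)
  expect_true(is.na(tf$tau_out_hat))
})

test_that("full pipeline recovers the generating parameters (noiseless grid)", {
  cases <- list(
    list(C0 = 0.5e-9, be = 2, kap = 0.1, tau = 0.005, g = 0,
         Umax = 0.1, f = 2),
    list(C0 = 2e-9, be = 8, kap = 0.3, tau = 0.030, g = 2e-9,
         Umax = 0.1, f = 0.5),
    list(C0 = 1e-9, be = 20, kap = 0.2, tau = 0.010, g = 0.5e-9,
         Umax = 0.15, f = 1)
  )
  for (cs in cases) {
    p <- membrane_params(C0 = cs$C0, beta = cs$be / (1 - cs$kap),
                         kappa = cs$kap, tau = cs$tau, g = cs$g)
    dr <- drive_spec(cs$Umax, cs$f)
    tr <- generate_trace(p, dr, n_periods = 5, noise_sd = 0)
    fit <- estimate_membrane(tr)
    expect_equal(estimate_pick(fit, "C0"), cs$C0, tolerance = 0.03)
    expect_equal(estimate_pick(fit, "beta_exp"), cs$be, tolerance = 0.10)
    expect_lt(abs(estimate_pick(fit, "kappa") - cs$kap), 0.05)
    expect_equal(estimate_pick(fit, "tau"), cs$tau, tolerance = 0.10)
    expect_lt(abs(estimate_pick(fit, "g") - cs$g), 1e-10)
    # the assembled conductance honours the insertion identity exactly
    expect_equal(estimate_pick(fit, "g"),
                 estimate_pick(fit, "g_app") +
                   4 * estimate_pick(fit, "beta_exp") * dr$k^2 *
                   estimate_pick(fit, "C0") * estimate_pick(fit, "tau"),
                 tolerance = 1e-12)
  }
})

test_that("a linear membrane needs no corrections", {
  p <- linear_params(g = 1e-9, tau = 0.005, C0 = 1e-9)
  dr <- drive_spec(0.1, 1)
  tr <- generate_trace(p, dr, n_periods = 5, noise_sd = 0)
  fit <- estimate_membrane(tr, refine = FALSE)
  expect_equal(estimate_pick(fit, "C0"), 1e-9, tolerance = 5e-3)
  expect_lt(abs(estimate_pick(fit, "beta_exp")) * dr$Umax^2, 1e-3)
  expect_equal(estimate_pick(fit, "g_app"), 1e-9, tolerance = 0.01)
  expect_equal(estimate_pick(fit, "g"), 1e-9, tolerance = 0.02)
})

test_that("estimates are robust to noise and to the 30 ms smoother", {
  p <- refs$azolectin$params
  dr <- refs$azolectin$drive
  noisy <- generate_trace(p, dr, n_periods = 25, noise_sd = 5e-12, seed = 3)
  fit_n <- estimate_membrane(noisy)
  expect_equal(estimate_pick(fit_n, "C0"), 897e-12, tolerance = 0.03)
  expect_equal(estimate_pick(fit_n, "beta_exp"), 11, tolerance = 0.12)
  # the 30 ms smoother barely moves noiseless capacitance estimates: the
  # apparent capacitance is untouched (a moving average preserves a parabola
  # in the window interior) and the curvature shifts only through the
  # smeared corner-transient tail
  tr <- azolectin_trace()
  f_sm <- estimate_membrane(tr, smooth_window = 0.03, refine = FALSE)
  f_raw <- estimate_membrane(tr, smooth_window = 0, refine = FALSE)
  expect_equal(estimate_pick(f_sm, "C_exp0"), estimate_pick(f_raw, "C_exp0"),
               tolerance = 0.01)
  expect_equal(estimate_pick(f_sm, "beta_exp"),
               estimate_pick(f_raw, "beta_exp"), tolerance = 0.02)
})

test_that("amplifier-filtered recordings are analysed with the filter in the loop", {
  p <- refs$azolectin$params
  dr <- refs$azolectin$drive
  amp <- amplifier_params(100e6, 0.8e-3)
  tr <- generate_trace(p, dr, amp = amp, fs = 10000, n_periods = 4,
                       noise_sd = 0)
  fit <- estimate_membrane(tr, amp = amp)
  expect_lt(abs(estimate_pick(fit, "kappa") - 0.2), 0.05)
  expect_equal(estimate_pick(fit, "tau"), 0.019, tolerance = 0.1)
  expect_equal(estimate_pick(fit, "C0"), 897e-12, tolerance = 0.03)
  tf <- fit$fits$transient
  expect_equal(tf$tau_out_hat, amp$tau_out, tolerance = 0.25)
})

test_that("tidy, glance and augment expose the fit in broom shape", {
  fit <- azolectin_fit()
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("C0", "beta_exp", "kappa", "tau", "g_app", "g",
                    "gamma") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$refine_converged)
  expect_gt(gl$n_cycles_used, 0)
  au <- augment(fit)
  expect_true(all(c(".fitted_I_up_A", ".fitted_I_down_inv_A") %in% names(au)))
  # fitted branches track the folded data
  expect_equal(au$.fitted_I_up_A, au$I_up_A,
               tolerance = 0.05)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(fit$folded), "ggplot")
})
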