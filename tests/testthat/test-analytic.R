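test_that("branch voltage reduces to the lagged command voltage at beta = 0", {
  dr <- drive_spec(0.2, 1)
  p <- linear_params()
  kt <- dr$k * p$tau
  # transient decayed by T/4: pure lag U(t) - k*tau
  expect_equal(utilde_up(dr$T / 4, p, dr), -kt, tolerance = 1e-5)
  # periodic matching at the corner: previous half ends at -Umax + k*tau
  expect_equal(utilde_up(0, p, dr), -dr$Umax + kt)
  expect_equal(utilde_down(0, p, dr), dr$Umax - kt)
  # tau = 0 degenerates to the command voltage, not a division error
  p0 <- membrane_params(C0 = 1e-9, beta = 4)
  t <- seq(0, dr$T / 2, by = 0.01)
  expect_equal(utilde_up(t, p0, dr), -dr$Umax + dr$k * t)
  expect_error(utilde_up(dr$T, p, dr), "half-period")
})

test_that("branch voltage warns when the half-period is short against tau", {
  dr <- drive_spec(0.2, 10)   # T/2 = 50 ms
  p <- linear_params(tau = 0.019)
  expect_warning(utilde_up(0.01, p, dr), "5 \\* tau")
})

test_that("viscoelastic branch current matches its Kirchhoff restatement", {
  dr <- drive_spec(0.2, 1)
  t <- seq(0, dr$T / 2, length.out = 81)
  # beta = 0: the polynomial form is exact, i1 = (1-kappa) C0 (U - Utilde)/tau
  p <- linear_params()
  i_poly <- branch_current_viscoelastic_up(t, p, dr)
  i_kirch <- (1 - p$kappa) * p$C0 *
    (command_voltage(t, dr) - utilde_up(t, p, dr)) / p$tau
  expect_equal(i_poly, i_kirch, tolerance = 1e-12)
  expect_equal(i_poly[length(t)], (1 - p$kappa) * dr$k * p$C0,
               tolerance = 1e-6)
  expect_equal(i_poly[1], -(1 - p$kappa) * dr$k * p$C0)
  # the Kirchhoff restatement holds algebraically at any beta: the closed-form
  # polynomial current is (U - Utilde)/r with the first-order branch voltage
  pb <- membrane_params(1e-9, beta = 4, kappa = 0.2, tau = 0.019)
  expect_equal(branch_current_viscoelastic_up(t, pb, dr),
               (1 - pb$kappa) * pb$C0 *
                 (command_voltage(t, dr) - utilde_up(t, pb, dr)) / pb$tau,
               tolerance = 1e-12)
  # kappa = 1: no viscoelastic branch
  p1 <- membrane_params(1e-9, kappa = 1)
  expect_equal(branch_current_viscoelastic_up(t, p1, dr), rep(0, length(t)))
  expect_equal(branch_current_viscoelastic_down(t, p1, dr), rep(0, length(t)))
})

test_that("total current matches its time-domain construction", {
  # substituting k*t = U + Umax into branch + elastic + ionic currents
  # reproduces the voltage-domain forms exactly
  dr <- drive_spec(0.2, 1)
  p <- refs$azolectin$params
  t <- seq(0, dr$T / 2, length.out = 41)
  U <- -dr$Umax + dr$k * t
  lhs <- total_current_up(U, p, dr)
  rhs <- branch_current_viscoelastic_up(t, p, dr) +
    p$kappa * p$C0 * dr$k + ionic_current(U, p)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  lhs_d <- total_current_down_inv(U, p, dr)
  rhs_d <- branch_current_viscoelastic_down(dr$T / 2 - t, p, dr) -
    p$kappa * p$C0 * dr$k + ionic_current(U, p)
  expect_equal(lhs_d, rhs_d, tolerance = 1e-12)
  expect_error(total_current_up(0.3, p, dr), "outside")
})

test_that("rising-ramp current at zero voltage carries the lag correction", {
  p <- refs$azolectin$params
  dr <- refs$azolectin$drive
  kt <- dr$k * p$tau
  expected <- dr$k * p$C0 * (1 + 5 * 11 * kt^2)  # exp terms ~ 2e-15 A here
  expect_equal(total_current_up(0, p, dr), expected, tolerance = 1e-4)
  expect_equal(expected, 7.267e-10, tolerance = 1e-3)
  # capacitive parts opposite, ionic parts cancel in the branch difference
  expect_equal(total_current_up(0, p, dr) - total_current_down_inv(0, p, dr),
               2 * expected, tolerance = 1e-4)
  # linear capacitor limit away from the ramp start
  p0 <- membrane_params(1e-9, kappa = 0.2, tau = 0.019)
  expect_equal(total_current_up(0.15, p0, dr), dr$k * p0$C0,
               tolerance = 1e-6)
})

test_that("half-sum and half-difference reconstruct both branches exactly", {
  dr <- drive_spec(0.2, 1)
  U <- seq(-0.2, 0.2, by = 0.005)
  for (p in list(refs$azolectin$params, refs$regime_zero$params,
                 linear_params(g = 1e-9))) {
    hd <- half_difference(U, p, dr)
    hs <- half_sum(U, p, dr)
    expect_equal(hd + hs, total_current_up(U, p, dr), tolerance = 1e-14)
    expect_equal(hd - hs, -total_current_down_inv(U, p, dr),
                 tolerance = 1e-14)
    # parity: capacitive component even, conductive component odd
    expect_equal(hd, half_difference(-U, p, dr), tolerance = 1e-14)
    expect_equal(hs, -half_sum(-U, p, dr), tolerance = 1e-14)
  }
  # half-difference at U = 0 reads off k * C_exp0
  p <- refs$azolectin$params
  expect_equal(half_difference(0, p, dr),
               dr$k * derived_params(p, dr)$C_exp0, tolerance = 1e-9)
  # at g = g_star (gamma = 0) the conductive component vanishes identically
  dr8 <- refs$regime_zero$drive
  pb <- refs$regime_zero$params
  g_star <- zero_hysteresis_conductance(pb, dr8)
  p_bal <- membrane_params(pb$C0, pb$beta, pb$kappa, pb$tau, g = g_star)
  Uin <- seq(-0.08, 0.08, by = 0.01)   # clear of the corner transients
  expect_lt(max(abs(half_sum(Uin, p_bal, dr8))), 1e-3 * dr8$k * pb$C0)
})

test_that("zero-hysteresis conductance evaluates to the reference 1.72 nS and scales as k^2", {
  pb <- refs$regime_zero$params
  dr <- refs$regime_zero$drive
  g_star <- zero_hysteresis_conductance(pb, dr)
  expect_equal(g_star, 1.72032e-9)
  expect_equal(round(1e9 * g_star, 2), 1.72)
  expect_equal(apparent_conductance(pb, dr), pb$g - g_star)
  expect_lt(abs(apparent_conductance(pb, dr)), 2e-3 * g_star)
  expect_equal(apparent_conductance(refs$regime_negative$params, dr), -g_star)
  # no insertion term without nonlinearity
  expect_equal(zero_hysteresis_conductance(linear_params(g = 1e-9), dr), 0)
  expect_equal(apparent_conductance(linear_params(g = 1e-9), dr), 1e-9)
  # g_star is proportional to k^2: doubling the amplitude quadruples it
  dr2 <- drive_spec(2 * dr$Umax, dr$f)
  expect_equal(zero_hysteresis_conductance(pb, dr2), 4 * g_star)
})

test_that("capacitance loops pinch, close, or open with the apparent conductance", {
  dr <- refs$regime_negative$drive
  # linear capacitor: both branches sit at C0 away from the corners
  p0 <- membrane_params(1.12e-9, kappa = 0.2, tau = 0.01)
  lc <- capacitance_loops(p0, dr, U_grid = seq(-0.1, 0.1, by = 0.005))
  expect_equal(lc$C_up_F, rep(p0$C0, nrow(lc)), tolerance = 1e-4)
  expect_equal(lc$C_down_F, rep(p0$C0, nrow(lc)), tolerance = 1e-4)

  # memcapacitive set: branch difference is a negative-slope line
  pa <- refs$regime_negative$params
  U <- seq(-0.1, 0.1, by = 0.005)
  la <- capacitance_loops(pa, dr, U_grid = U)
  width <- la$C_up_F - la$C_down_F
  expect_equal(width, loop_width(U, pa, dr), tolerance = 1e-12)
  g_app <- apparent_conductance(pa, dr)
  expect_equal(width, (2 / dr$k) * g_app * U, tolerance = 2e-2)
  expect_equal(loop_width(0.1, pa, dr), (2 / dr$k) * g_app * 0.1,
               tolerance = 2e-2)
  expect_equal((2 / dr$k) * g_app * 0.1, -2.1504e-10)
  expect_identical(loop_width(0, pa, dr), 0)

  # balanced set: loop closes away from the corner-transient bands
  pb <- refs$regime_zero$params
  Ui <- seq(-dr$Umax + 6 * dr$k * pb$tau, dr$Umax - 6 * dr$k * pb$tau,
            by = 0.005)
  expect_lt(max(abs(loop_width(Ui, pb, dr))), 0.01 * pb$C0)

  # each of kappa = 1, tau = 0, beta = 0 collapses the loop (gamma = g = 0)
  for (p in list(membrane_params(1e-9, beta = 10, kappa = 1, tau = 0),
                 membrane_params(1e-9, beta = 10, kappa = 0.2, tau = 0),
                 membrane_params(1e-9, beta = 0, kappa = 0.2, tau = 0.01)))
    expect_equal(max(abs(loop_width(Ui, p, dr))), 0)
})

test_that("work per period is (T/3) Umax^2 g_app and flips sign at g = g_star", {
  dr <- refs$regime_negative$drive
  pa <- refs$regime_negative$params
  expect_equal(work_per_period(pa, dr), (0.5 / 3) * 0.04 * (-1.72032e-9))
  expect_equal(work_per_period(pa, dr), -1.146880e-11)
  g_star <- zero_hysteresis_conductance(pa, dr)
  p_bal <- membrane_params(pa$C0, pa$beta, pa$kappa, pa$tau, g = g_star)
  expect_equal(work_per_period(p_bal, dr), 0)
  p2 <- membrane_params(pa$C0, pa$beta, pa$kappa, pa$tau, g = 2 * g_star)
  expect_equal(work_per_period(p2, dr), +1.146880e-11, tolerance = 1e-9)
  expect_equal(classify_regime(pa, dr), "memcapacitive")
  expect_equal(classify_regime(p_bal, dr), "zero-hysteresis")
  expect_equal(classify_regime(refs$regime_positive$params, dr), "passive")
})

test_that("lag dissipation is non-negative and vanishes without a lag", {
  dr <- refs$regime_negative$drive
  expect_gt(lag_dissipation_per_period(refs$regime_negative$params, dr), 0)
  expect_equal(lag_dissipation_per_period(
    membrane_params(1e-9, kappa = 1), dr), 0)
  expect_equal(lag_dissipation_per_period(
    membrane_params(1e-9, kappa = 0.2, tau = 0), dr), 0)
})

test_that("ferroelectric counter-example inverts the parabola and the insertion sign", {
  dr <- drive_spec(0.2, 1)
  U <- seq(-0.2, 0.2, by = 0.01)
  # the two charge-voltage laws coincide at beta = 0
  p0 <- linear_params(g = 5e-11)
  expect_equal(ferro_current_up(U, p0, dr), total_current_up(U, p0, dr))
  p <- membrane_params(897e-12, beta = 13.75, kappa = 0.2, tau = 0.019)
  # capacitive part decreases with |U| ...
  hd <- (ferro_current_up(U, p, dr) - ferro_current_down_inv(U, p, dr)) / 2
  expect_lt(hd[which.min(abs(U - 0.15))], hd[which.min(abs(U))])
  # ... and the insertion conductance is positive: loop orientation reversed
  hs <- (ferro_current_up(U, p, dr) + ferro_current_down_inv(U, p, dr)) / 2
  inner <- abs(U) <= 0.1 & U != 0
  expect_true(all(sign(hs[inner]) == sign(U[inner])))
  expect_equal(sum(U * hs) / sum(U^2),
               4 * p$beta * (1 - p$kappa) * dr$k^2 * p$C0 * p$tau,
               tolerance = 0.05)
})
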