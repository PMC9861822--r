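#' Tidy a fitted membrane estimate
#'
#' @param x A `memcap_fit` from [estimate_membrane()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit` covering the
#'   recovered circuit parameters (`C0`, `beta_exp`, `kappa`, `tau`, `g_app`,
#'   `g`, `gamma`) and the derived quantities (`C_exp0`, `g_star`), all in
#'   SI units.
#' @export
tidy.memcap_fit <- function(x, ...) {
  x$estimates
}

#' One-row diagnostics of a fitted membrane estimate
#'
#' @param x A `memcap_fit`.
#' @param ... Unused.
#' @return A one-row tibble: cycles averaged, fit windows, rms residual per
#'   stage, the transient-stage `kappa`/`tau`, and the refinement
#'   convergence flag.
#' @export
glance.memcap_fit <- function(x, ...) {
  f <- x$fits
  tibble::tibble(
    n_cycles_used = x$folded$n_cycles_used %||% NA_integer_,
    cap_window = f$capacitance$fit_window,
    cond_window = f$conductance$fit_window,
    rms_capacitance_F = f$capacitance$rms,
    rms_conductance_A = f$conductance$rms,
    rms_transient_A = f$transient$rms,
    rms_refine_A = f$refined$rms %||% NA_real_,
    kappa_transient = f$transient$kappa_hat,
    tau_transient_s = f$transient$tau_hat,
    refined = !is.null(f$refined),
    refine_converged = if (is.null(f$refined)) NA else
      f$refined$convergence == 0
  )
}

#' Augment the folded curves with fitted values
#'
#' @param x A `memcap_fit`.
#' @param ... Unused.
#' @return The decomposition tibble (`U_V`, branch currents, half-sum and
#'   half-difference) with the closed-form fitted branches
#'   (`.fitted_I_up_A`, `.fitted_I_down_inv_A`) evaluated at the recovered
#'   parameters.
#' @export
augment.memcap_fit <- function(x, ...) {
  e <- x$estimates
  pick <- function(term) e$estimate[e$term == term]
  p <- membrane_params(
    C0 = pick("C0"), beta = pick("beta_exp") / (1 - pick("kappa")),
    kappa = pick("kappa"), tau = pick("tau"),
    g = max(0, pick("g")), gamma = max(0, pick("gamma")))
  d <- x$decomp
  d$.fitted_I_up_A <- total_current_up(d$U_V, p, x$drive)
  d$.fitted_I_down_inv_A <- total_current_down_inv(d$U_V, p, x$drive)
  d
}

#' @export
generics::augment
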