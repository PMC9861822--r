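#' Read and write parameter sets, drives and amplifiers as JSON
#'
#' On disk every quantity carries its unit in the key name, while the package
#' works in SI internally. Membrane parameters use `C0_pF`, `beta_per_V2`,
#' `kappa`, `tau_ms`, `g_nS`, `gamma_nS_per_mV8` (note `1 nS/mV^8 = 1e15
#' S/V^8`); drives use `Umax_mV`, `f_Hz`; amplifiers use `Rout_MOhm`,
#' `tau_out_ms`. Unknown keys are rejected so a config typo cannot silently
#' drop a parameter.
#'
#' @param x The object to serialize.
#' @param path File path.
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name params_io
NULL

GAMMA_SI_PER_DISPLAY <- 1e15  # S/V^8 per nS/mV^8

check_keys <- function(obj, allowed, what) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra))
    stop(sprintf("unknown %s key(s): %s", what,
                 paste(extra, collapse = ", ")))
  miss <- setdiff(allowed, names(obj))
  if (length(miss))
    stop(sprintf("missing %s key(s): %s", what,
                 paste(miss, collapse = ", ")))
}

#' @rdname params_io
#' @export
write_membrane_params <- function(x, path) {
  stopifnot(inherits(x, "memcap_params"))
  jsonlite::write_json(list(
    C0_pF = 1e12 * x$C0, beta_per_V2 = x$beta, kappa = x$kappa,
    tau_ms = 1e3 * x$tau, g_nS = 1e9 * x$g,
    gamma_nS_per_mV8 = x$gamma / GAMMA_SI_PER_DISPLAY
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_io
#' @export
read_membrane_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_membrane_params(obj)
}

parse_membrane_params <- function(obj) {
  check_keys(obj, c("C0_pF", "beta_per_V2", "kappa", "tau_ms", "g_nS",
                    "gamma_nS_per_mV8"), "membrane parameter")
  membrane_params(C0 = 1e-12 * obj$C0_pF, beta = obj$beta_per_V2,
                  kappa = obj$kappa, tau = 1e-3 * obj$tau_ms,
                  g = 1e-9 * obj$g_nS,
                  gamma = obj$gamma_nS_per_mV8 * GAMMA_SI_PER_DISPLAY)
}

#' @rdname params_io
#' @export
write_drive <- function(x, path) {
  stopifnot(inherits(x, "memcap_drive"))
  jsonlite::write_json(list(Umax_mV = 1e3 * x$Umax, f_Hz = x$f), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_io
#' @export
read_drive <- function(path) {
  parse_drive(jsonlite::read_json(path, simplifyVector = TRUE))
}

parse_drive <- function(obj) {
  check_keys(obj, c("Umax_mV", "f_Hz"), "drive")
  drive_spec(Umax = 1e-3 * obj$Umax_mV, f = obj$f_Hz)
}

#' @rdname params_io
#' @export
write_amplifier <- function(x, path) {
  stopifnot(inherits(x, "memcap_amp"))
  jsonlite::write_json(list(Rout_MOhm = 1e-6 * x$Rout,
                            tau_out_ms = 1e3 * x$tau_out), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_io
#' @export
read_amplifier <- function(path) {
  parse_amplifier(jsonlite::read_json(path, simplifyVector = TRUE))
}

parse_amplifier <- function(obj) {
  check_keys(obj, c("Rout_MOhm", "tau_out_ms"), "amplifier")
  amplifier_params(Rout = 1e6 * obj$Rout_MOhm,
                   tau_out = 1e-3 * obj$tau_out_ms)
}

#' Read and write recorded traces as CSV
#'
#' Traces travel as plain CSV with a header row and columns `time_s`,
#' `voltage_V`, `current_A` (full double precision, lossless round trip).
#' A JSON sidecar (same path with extension `.json`) stores the drive, the
#' sampling rate and — for synthetic traces — the generating parameters;
#' `write_trace(meta = FALSE)` omits it to emulate blind experimental data.
#'
#' @param trace A `memcap_trace` (or data frame with the trace columns).
#' @param path CSV file path.
#' @param meta Write the JSON sidecar?
#' @param drive Optional [drive_spec()] for `read_trace()` when no sidecar
#'   exists.
#' @return `read_trace()` returns a `memcap_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path, meta = TRUE) {
  stopifnot(all(c("time_s", "current_A") %in% names(trace)))
  tbl <- tibble::as_tibble(trace)[, intersect(
    c("time_s", "voltage_V", "current_A"), names(trace))]
  # 17 significant digits guarantee a bit-exact double round trip
  tbl[] <- lapply(tbl, function(col) sprintf("%.17g", col))
  readr::write_csv(tbl, path)
  if (meta) {
    drive <- attr(trace, "drive")
    params <- attr(trace, "params")
    amp <- attr(trace, "amp")
    m <- list(fs_Hz = attr(trace, "fs"))
    if (!is.null(drive))
      m$drive <- list(Umax_mV = 1e3 * drive$Umax, f_Hz = drive$f)
    if (!is.null(params))
      m$params <- list(C0_pF = 1e12 * params$C0, beta_per_V2 = params$beta,
                       kappa = params$kappa, tau_ms = 1e3 * params$tau,
                       g_nS = 1e9 * params$g,
                       gamma_nS_per_mV8 = params$gamma / GAMMA_SI_PER_DISPLAY)
    if (!is.null(amp))
      m$amp <- list(Rout_MOhm = 1e-6 * amp$Rout,
                    tau_out_ms = 1e3 * amp$tau_out)
    if (!is.null(attr(trace, "noise_sd")))
      m$noise_sd_pA <- 1e12 * attr(trace, "noise_sd")
    jsonlite::write_json(m, meta_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, drive = NULL) {
  # base read.csv parses doubles with correct rounding, so a trace written
  # at 17 significant digits round-trips bit-exactly
  tbl <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("time_s", "current_A") %in% names(tbl)))
  fs <- 1 / stats::median(diff(tbl$time_s))
  params <- NULL; amp <- NULL
  mp <- meta_path(path)
  if (is.null(drive) && file.exists(mp)) {
    m <- jsonlite::read_json(mp, simplifyVector = TRUE)
    if (!is.null(m$drive)) drive <- parse_drive(m$drive)
    if (!is.null(m$fs_Hz)) fs <- m$fs_Hz
    if (!is.null(m$params)) params <- parse_membrane_params(m$params)
    if (!is.null(m$amp)) amp <- parse_amplifier(m$amp)
  }
  structure(tbl, drive = drive, fs = fs, params = params, amp = amp,
            class = c("memcap_trace", class(tbl)))
}

meta_path <- function(path) paste0(sub("\\.[Cc][Ss][Vv]$", "", path), ".json")

#' Write response curves or an oracle solution as CSV
#'
#' @param x A `memcap_curves` or `memcap_oracle` tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Write an estimation result as JSON
#'
#' Estimates are written with unit-suffixed keys (`C0_pF`,
#' `beta_exp_per_V2`, `kappa`, `tau_ms`, `g_app_nS`, `g_nS`,
#' `gamma_nS_per_mV8`, `C_exp0_pF`, `g_star_nS`) together with fit
#' diagnostics (windows, cycles used, rms residual per fit stage).
#'
#' @param fit A `memcap_fit` from [estimate_membrane()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(fit, path) {
  stopifnot(inherits(fit, "memcap_fit"))
  e <- fit$estimates
  pick <- function(term) e$estimate[e$term == term]
  out <- list(
    C0_pF = 1e12 * pick("C0"),
    beta_exp_per_V2 = pick("beta_exp"),
    kappa = pick("kappa"),
    tau_ms = 1e3 * pick("tau"),
    g_app_nS = 1e9 * pick("g_app"),
    g_nS = 1e9 * pick("g"),
    gamma_nS_per_mV8 = pick("gamma") / GAMMA_SI_PER_DISPLAY,
    C_exp0_pF = 1e12 * pick("C_exp0"),
    g_star_nS = 1e9 * pick("g_star"),
    diagnostics = as.list(glance(fit))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
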