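# shared fixtures: reference parameter sets and lazily built synthetic traces
refs <- reference_parameter_sets()

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# short noiseless azolectin recording (3 analysable cycles) used by most
# estimation tests; the acceptance suite builds its own 25-period version
azolectin_trace <- function() cached("azolectin_trace", function() {
  generate_trace(refs$azolectin$params, refs$azolectin$drive,
                 n_periods = 5, noise_sd = 0)
})

azolectin_fit <- function() cached("azolectin_fit", function() {
  estimate_membrane(azolectin_trace())
})

estimate_pick <- function(fit, term) {
  e <- fit$estimates
  e$estimate[e$term == term]
}

# membrane with a plain linear-lag viscoelastic branch (beta = 0)
linear_params <- function(g = 0, kappa = 0.2, tau = 0.019, C0 = 1e-9)
  membrane_params(C0 = C0, beta = 0, kappa = kappa, tau = tau, g = g)
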