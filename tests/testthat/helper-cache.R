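# memoised fixtures: the expensive cable simulations and relaxations are
# computed once per test run and shared across test files
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_env, inherits = FALSE))
    assign(name, force(expr), .fixture_env)
  get(name, .fixture_env, inherits = FALSE)
}

control_dims <- c(nsv_length = 638, nsv_width = 309,
                  connector_length = 486, connector_width = 136)

control_traces <- function(mode = "periodic") {
  cached(paste0("control_", mode), {
    geo <- build_geometry(638, 309, 486, 136)
    simulate_ap(geo, ephys_params(), place_channels(geo, mode))
  })
}

cylinder_traces <- function(mode = "uniform", diameter = 300) {
  cached(paste0("cyl_", mode, "_", diameter), {
    geo <- build_geometry(cylinder_diameter = diameter)
    simulate_ap(geo, ephys_params(), place_channels(geo, mode))
  })
}

relaxed_control <- function() {
  cached("relaxed_control", {
    p <- membrane_params(kappa_kbt = 50, sigma = 0.02, c_ext_mosm = 300)
    lam <- fastest_growing_wavelength(85, p)
    relax_shape(cylinder_state(85, lam, n = 128, perturb = 0.1), p,
                tol = 1e-4, max_iter = 40000)
  })
}

# pearled-synthetic cohort measured end to end, reused by several files
measured_cohort <- function(n_axons = 20, noise_sd = 0, smoothing = 15,
                            seed = 11) {
  key <- paste("cohort", n_axons, noise_sd, smoothing, seed, sep = "_")
  cached(key, {
    pop <- gen_population(c(600, 311, 552, 127), c(50, 30, 50, 10),
                          n_axons = n_axons, synaptic_fraction = 0,
                          seed = seed, n_periods = 5, noise_sd = noise_sd)
    recs <- lapply(pop$profiles, function(p)
      measure_segments(segment_profile(p, smoothing), p$annotations))
    list(pop = pop, records = recs,
         summary = summarize_morphometry(recs))
  })
}
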