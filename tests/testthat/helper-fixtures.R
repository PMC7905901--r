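# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

make_scene <- function(t_ref = 298.15, t_env = 298.15, rho = 0.99,
                       sigma = SIGMA_SB, ...) {
  scene_conditions(t_ref = t_ref, t_env = t_env, rho = rho, sigma = sigma,
                   ...)
}

# Randomised (epsilon, T_obj, T_ref, T_env, rho) tuples over the ranges the
# round-trip and equivalence properties quantify over.
random_tuples <- function(n, seed = 101) {
  set.seed(seed)
  data.frame(
    epsilon = runif(n, -0.2, 1.2),
    t_obj = runif(n, 290, 330),
    t_ref = runif(n, 285, 305),
    t_env = runif(n, 290, 305),
    rho = sample(c(0.9, 0.99, 1), n, replace = TRUE))
}

# Minimal raw thermocouple table (canonical headers) with controllable
# reflected temperatures.
toy_thermocouple_table <- function(t_obj_k, t_ref_k, epsilon = 0.98,
                                   t_env = 298.15, rho = 0.99) {
  n <- length(t_obj_k)
  if (!n)
    return(data.frame(measurement = character(0), individual = integer(0),
                      species = character(0),
                      measurement_location = character(0),
                      tobj_k = numeric(0), tref_k = numeric(0),
                      tapp_k = numeric(0), stringsAsFactors = FALSE))
  t_app <- vapply(seq_len(n), function(i) {
    sc <- make_scene(t_ref = t_ref_k[i], t_env = t_env, rho = rho)
    radiance_to_apparent(total_radiance(t_obj_k[i], epsilon, sc))
  }, numeric(1))
  data.frame(measurement = sprintf("m%02d", seq_len(n)),
             individual = seq_len(n),
             species = "Testflower",
             measurement_location = rep(c("A: repro struc", "B: petal base",
                                          "C: petal edge"), length.out = n),
             tobj_k = t_obj_k, tref_k = t_ref_k, tapp_k = t_app,
             stringsAsFactors = FALSE)
}

noiseless_config <- function(epsilon = 0.98, n_individuals = 5, seed = 11,
                             ...) {
  synthetic_config(
    species_profiles = list(Testflower = epsilon),
    n_individuals = n_individuals,
    camera_noise_sd = 0, thermocouple_noise_sd = 0,
    thermometer_noise_sd = 0, seed = seed, ...)
}
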