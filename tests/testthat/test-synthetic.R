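test_that("noise helper is Gaussian with the documented default magnitudes", {
  expect_equal(default_camera_noise_sd(), 2 / 1.96)
  # thermocouple spec: max(2.2 C, 0.75% of the Celsius reading) / 1.96
  expect_equal(default_thermocouple_noise_sd(310),
               max(2.2, 0.0075 * (310 - 273.15)) / 1.96)
  expect_equal(default_thermocouple_noise_sd(273.15 + 400), # % term dominates
               0.0075 * 400 / 1.96)
  set.seed(1)
  expect_equal(apply_measurement_noise(300, 0), 300) # sd 0 is identity
  expect_error(apply_measurement_noise(300, -1), "non-negative")
})

test_that("same seed and config give identical tables; different seeds differ", {
  cfg <- synthetic_config(species_profiles = list(A = 0.98, B = 0.97),
                          n_individuals = 3, seed = 99)
  t1 <- generate_dataset("thermocouple", cfg)
  t2 <- generate_dataset("thermocouple", cfg)
  expect_identical(t1, t2)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(generate_dataset("thermocouple", cfg2)$tapp_k,
                         t1$tapp_k))
  w1 <- generate_dataset("water_bath", cfg)
  w2 <- generate_dataset("water_bath", cfg)
  expect_identical(w1, w2)
})

test_that("subsetting the species roster leaves other rows untouched", {
  cfg <- synthetic_config(species_profiles = list(A = 0.98, B = 0.95),
                          n_individuals = 4, seed = 12)
  full <- generate_dataset("thermocouple", cfg)
  cfgB <- synthetic_config(species_profiles = list(B = 0.95),
                           n_individuals = 4, seed = 12)
  onlyB <- generate_dataset("thermocouple", cfgB)
  fullB <- full[full$species == "B",
                setdiff(names(full), c("individual", "measurement"))]
  rownames(fullB) <- NULL
  onlyB <- onlyB[, setdiff(names(onlyB), c("individual", "measurement"))]
  expect_equal(fullB, onlyB)
})

test_that("noiseless generation is exactly identifiable end to end", {
  profiles <- list(
    A = c(reproductive_structures = 0.93, petal_base = 0.99,
          petal_edge = 1.02),
    B = c(reproductive_structures = 0.97, petal_base = 0.96,
          petal_edge = 0.95))
  cfg <- synthetic_config(species_profiles = profiles, n_individuals = 3,
                          camera_noise_sd = 0, thermocouple_noise_sd = 0,
                          thermometer_noise_sd = 0, seed = 77)
  for (protocol in c("thermocouple", "water_bath")) {
    fit <- estimate_emissivity(generate_dataset(protocol, cfg), protocol)
    est <- fit$estimates
    truth <- vapply(seq_len(nrow(est)), function(i)
      profiles[[est$species[i]]][[est$location[i]]], numeric(1))
    expect_lt(max(abs(est$epsilon_solver - truth)), 1e-8)
    expect_lt(max(abs(est$epsilon_calc - truth)), 1e-8)
  }
})

test_that("unknown protocol is rejected and zero individuals give an empty table", {
  expect_error(generate_dataset("microbolometer", synthetic_config()),
               "arg")
  cfg0 <- synthetic_config(species_profiles = list(A = 0.98),
                           n_individuals = 0, seed = 1)
  t0 <- generate_dataset("thermocouple", cfg0)
  expect_equal(nrow(t0), 0L)
})

test_that("config validation rejects bad noise, emissivity and bath inputs", {
  expect_error(synthetic_config(camera_noise_sd = -0.5), "non-negative")
  expect_error(synthetic_config(species_profiles = list(A = Inf)), "finite")
  expect_error(synthetic_config(bath_set_temps_c = c(35, 50)))
  expect_error(synthetic_config(
    species_profiles = list(A = c(petal_base = 0.98))), "all locations")
})

test_that("contact bias on petals inflates petal estimates above reproductive ones", {
  cfg <- synthetic_config(species_profiles = list(A = 0.98),
                          n_individuals = 167, contact_bias = 1, seed = 1)
  fit <- estimate_emissivity(generate_dataset("thermocouple", cfg),
                             "thermocouple")
  est <- fit$estimates[!fit$estimates$degenerate, ]
  petal <- mean(est$epsilon_solver[est$location != "reproductive_structures"])
  repro <- mean(est$epsilon_solver[est$location == "reproductive_structures"])
  expect_gt(petal, repro)
  expect_gt(petal, 1)
})

test_that("elevation and submersion biases push water-bath estimates in opposite directions", {
  # structures above the waterline cool below bath temperature: estimates drop
  cfg_el <- synthetic_config(species_profiles = list(A = 0.98),
                             n_individuals = 42, elevation_bias = 1,
                             submerged_species = character(0), seed = 1)
  fit_el <- estimate_emissivity(generate_dataset("water_bath", cfg_el),
                                "water_bath")
  e <- fit_el$estimates[!fit_el$estimates$degenerate, ]
  expect_lt(mean(e$epsilon_solver[e$location == "reproductive_structures"]),
            mean(e$epsilon_solver[e$location != "reproductive_structures"]))
  # submerged structures run warmer than the surface: estimates rise
  cfg_su <- synthetic_config(species_profiles = list(A = 0.98),
                             n_individuals = 42, submersion_bias = 1,
                             submerged_species = "A", seed = 1)
  fit_su <- estimate_emissivity(generate_dataset("water_bath", cfg_su),
                                "water_bath")
  e2 <- fit_su$estimates[!fit_su$estimates$degenerate, ]
  expect_gt(mean(e2$epsilon_solver[e2$location == "reproductive_structures"]),
            mean(e2$epsilon_solver[e2$location != "reproductive_structures"]))
})

test_that("generated values respect the protocol envelopes", {
  cfg <- synthetic_config(species_profiles = list(A = 0.98),
                          n_individuals = 40, seed = 3)
  tc <- generate_dataset("thermocouple", cfg)
  truth <- attr(tc, "truth")
  expect_true(all(truth$t_obj_true >= 296.9 & truth$t_obj_true <= 309.2))
  expect_true(all(tc$tref_k >= 287.0 & tc$tref_k <= 300.5))
  expect_true(all(tc$tref_k < truth$t_obj_true))
  wb <- generate_dataset("water_bath", cfg)
  expect_true(all(wb$tref_k >= 299.5 & wb$tref_k <= 301.6))
  expect_true(all(wb$bath_set %in% c("35C", "45C")))
  expect_true(all(abs(wb$thermometer_c -
                        as.numeric(sub("C", "", wb$bath_set))) < 1))
})

test_that("default rosters mirror the study replication", {
  tc <- default_species_profiles("thermocouple")
  wb <- default_species_profiles("water_bath")
  expect_length(tc, 10L)
  expect_length(wb, 6L)
  expect_true(all(vapply(wb, attr, numeric(1), "n_individuals") == 12))
  expect_equal(sort(unique(unlist(lapply(tc, names)))), sort(LOCATIONS))
})
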