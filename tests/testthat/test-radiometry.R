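test_that("temperature unit conversion round-trips and rejects sub-absolute-zero", {
  expect_equal(celsius_to_kelvin(0), 273.15)
  expect_equal(celsius_to_kelvin(25), 298.15)
  # published work often rounds 25 C to 298.2 K; within rounding of ours
  expect_lt(abs(celsius_to_kelvin(25) - 298.2), 0.051)
  expect_equal(kelvin_to_celsius(celsius_to_kelvin(36.0)), 36.0)
  expect_error(celsius_to_kelvin(-274), "absolute zero")
  expect_error(kelvin_to_celsius(-1), "positive")
})

test_that("total_radiance reproduces the grey-body decomposition", {
  # single surviving emitted term: sigma * 300^4, hand-evaluated
  sc <- make_scene(t_ref = 290, t_env = 295, rho = 1)
  expect_equal(total_radiance(300, 1, sc), 459.300327939, tolerance = 1e-9)
  # epsilon = 0 and rho = 1: pure reflection
  expect_equal(total_radiance(320, 0, sc), SIGMA_SB * 290^4)
  # all temperatures equal: terms collapse to sigma * T^4 for any eps, rho
  for (rho in c(0.9, 0.99, 1)) for (eps in c(-0.1, 0.5, 1.1)) {
    scT <- make_scene(t_ref = 305, t_env = 305, rho = rho)
    expect_equal(total_radiance(305, eps, scT), SIGMA_SB * 305^4,
                 tolerance = 1e-12)
  }
  expect_error(total_radiance(NaN, 1, sc), "finite")
  expect_error(total_radiance(300, Inf, sc), "finite")
})

test_that("apparent radiance and its inverse round-trip", {
  expect_equal(apparent_radiance(300), 459.300327939, tolerance = 1e-9)
  expect_equal(radiance_to_apparent(459.300327939), 300, tolerance = 1e-5)
  for (t in c(250.5, 298.15, 310, 399)) {
    expect_equal(radiance_to_apparent(apparent_radiance(t)), t,
                 tolerance = 1e-12)
  }
  expect_error(radiance_to_apparent(0), "degenerate")
  expect_error(radiance_to_apparent(-5), "degenerate")
})

test_that("closed-form emissivity inverts the forward model (round trip to 1e-9)", {
  tup <- random_tuples(500, seed = 42)
  for (i in seq_len(nrow(tup))) {
    sc <- make_scene(t_ref = tup$t_ref[i], t_env = tup$t_env[i],
                     rho = tup$rho[i])
    w <- total_radiance(tup$t_obj[i], tup$epsilon[i], sc)
    e <- emissivity_calc(w, tup$t_obj[i], sc)
    if (tup$t_obj[i] > tup$t_ref[i] + 1e-3) {
      expect_equal(as.numeric(e), tup$epsilon[i], tolerance = 1e-9)
    }
  }
})

test_that("closed-form boundary cases: T_app = T_obj gives 1, T_app = T_ref gives 0", {
  sc <- make_scene(t_ref = 295, t_env = 298.15, rho = 1)
  expect_equal(as.numeric(emissivity_calc(apparent_radiance(310), 310, sc)),
               1, tolerance = 1e-12)
  expect_equal(as.numeric(emissivity_calc(apparent_radiance(295), 310, sc)),
               0, tolerance = 1e-12)
  # algebraic round trip at protocol-like values
  sc2 <- make_scene(t_ref = 298.15, t_env = 298.15, rho = 0.99)
  w <- total_radiance(308.15, 0.95, sc2)
  expect_equal(as.numeric(emissivity_calc(w, 308.15, sc2)), 0.95,
               tolerance = 1e-9)
})

test_that("emissivity estimates are invariant to the Stefan-Boltzmann value", {
  tup <- random_tuples(200, seed = 7)
  tup <- tup[tup$t_obj > tup$t_ref + 0.5, ]
  t_app <- tup$t_obj + 1 # arbitrary apparent temperature
  # pipeline estimates are computed in T^4 space: bit-identical for any sigma
  pts <- data.frame(species = "X", individual = "1",
                    location = "petal_base", t_obj = tup$t_obj,
                    t_app = t_app, t_ref = tup$t_ref, flag = "",
                    stringsAsFactors = FALSE)
  batch <- lapply(c(5.7e-8, 5.670374419e-8), function(sig) {
    sc <- scene_conditions(rho = 0.99, sigma = sig)
    est <- solve_emissivity_batch(pts, scene = sc)
    list(calc = est$epsilon_calc, solver = est$epsilon_solver)
  })
  expect_identical(batch[[1]]$calc, batch[[2]]$calc)
  expect_identical(batch[[1]]$solver, batch[[2]]$solver)
  # the radiance interface divides sigma back out; agreement is to
  # floating-point round-off of the sigma*T^4 product
  est <- lapply(c(5.7e-8, 5.670374419e-8), function(sig) {
    sc <- scene_conditions(t_ref = tup$t_ref, t_env = tup$t_env, rho = 0.99,
                           sigma = sig)
    as.numeric(emissivity_calc(sig * t_app^4, tup$t_obj, sc))
  })
  expect_equal(est[[1]], est[[2]], tolerance = 1e-12)
})

test_that("closed form is unclipped but an optional clamp exists", {
  sc <- make_scene(t_ref = 290, rho = 0.99)
  w <- total_radiance(310, 1.05, sc)
  expect_equal(as.numeric(emissivity_calc(w, 310, sc)), 1.05,
               tolerance = 1e-9)
  expect_equal(as.numeric(emissivity_calc(w, 310, sc, clamp = TRUE)), 1)
})

test_that("degenerate denominator (T_ref >= T_obj) is flagged, not computed", {
  sc_eq <- make_scene(t_ref = 300)
  e <- emissivity_calc(apparent_radiance(305), 300, sc_eq)
  expect_true(is.na(as.numeric(e)))
  expect_true(attr(e, "degenerate"))
  sc_gt <- make_scene(t_ref = 310)
  e2 <- emissivity_calc(apparent_radiance(305), 300, sc_gt)
  expect_true(attr(e2, "degenerate"))
})

test_that("closed form decreases as t_obj rises past t_ref (fixed W_obs)", {
  sc <- make_scene(t_ref = 295)
  w <- total_radiance(305, 0.98, sc)
  tt <- seq(297, 320, by = 0.5)
  ee <- vapply(tt, function(t) as.numeric(emissivity_calc(w, t, sc)),
               numeric(1))
  expect_true(all(diff(ee) < 0))
})

test_that("temperature retrieval at an assumed emissivity inverts the forward model", {
  tup <- random_tuples(200, seed = 13)
  tup$epsilon <- runif(nrow(tup), 0.5, 1.2) # retrieval needs eps > 0
  for (i in seq_len(nrow(tup))) {
    sc <- make_scene(t_ref = tup$t_ref[i], t_env = tup$t_env[i],
                     rho = tup$rho[i])
    w <- total_radiance(tup$t_obj[i], tup$epsilon[i], sc)
    expect_equal(as.numeric(object_temp_at_emissivity(w, tup$epsilon[i], sc)),
                 tup$t_obj[i], tolerance = 1e-6)
  }
  # eps = 1, rho = 1 reduces to the plain fourth-root inverse
  sc1 <- make_scene(t_ref = 290, rho = 1)
  w <- apparent_radiance(312)
  expect_equal(as.numeric(object_temp_at_emissivity(w, 1, sc1)), 312,
               tolerance = 1e-9)
})

test_that("under-assumed emissivity inflates retrieved temperature when target is warm", {
  # truth eps = 1.00 at 318.15 K, surroundings 300.65 K; retrieved at 0.98
  # the independent algebraic oracle gives ((318.15^4 - 0.02*300.65^4)/0.98)^(1/4)
  sc <- make_scene(t_ref = 300.65, t_env = 298.15, rho = 0.99)
  w <- total_radiance(318.15, 1.00, sc)
  t098 <- as.numeric(object_temp_at_emissivity(w, 0.98, sc))
  expect_equal(t098, 318.478233036, tolerance = 1e-6)
  expect_gt(t098, 318.15)
  # non-positive bracketed quantity flags
  sc_hot <- make_scene(t_ref = 399, rho = 0.99)
  wlow <- apparent_radiance(251)
  r <- object_temp_at_emissivity(wlow, 0.02, sc_hot)
  expect_true(is.na(as.numeric(r)))
  expect_true(attr(r, "degenerate"))
})

test_that("scene conditions validate their inputs", {
  expect_error(scene_conditions(rho = 0), "rho")
  expect_error(scene_conditions(rho = 1.2), "rho")
  expect_error(scene_conditions(t_ref = 200), "t_ref")
  expect_error(scene_conditions(t_env = 500), "t_env")
  expect_error(scene_conditions(sigma = -1), "sigma")
  expect_s3_class(scene_conditions(), "scene_conditions")
})
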