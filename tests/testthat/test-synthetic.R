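test_that("zero noise reproduces the exact simulation samples", {
  sc <- fit_scenario(0.10, 10, wheat)
  ds <- generate_timecourse(sc, table1, noise_model(sigma = 0))
  sim <- simulate_scenario(sc, table1, sampling_interval = 6)
  tc <- sim$timecourse
  expect_equal(ds$observations$glucose_g_per_kg,
               tc$glucose_g_per_kg[match(ds$observations$time_h, tc$time_h)])
  expect_equal(ds$observations$time_h, seq(0, 96, by = 6))
})

test_that("generation is deterministic for a fixed seed", {
  sc <- fit_scenario(0.10, 10, wheat)
  a <- generate_timecourse(sc, table1, noise_model(sigma = 0.05, seed = 77))
  b <- generate_timecourse(sc, table1, noise_model(sigma = 0.05, seed = 77))
  c <- generate_timecourse(sc, table1, noise_model(sigma = 0.05, seed = 78))
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$observations, c$observations))
})

test_that("relative noise has the configured empirical magnitude", {
  sc <- fit_scenario(0.10, 10, wheat)
  truth <- generate_timecourse(sc, table1, noise_model(sigma = 0),
                               sampling_interval = 0.1)
  noisy <- generate_timecourse(sc, table1,
                               noise_model(sigma = 0.05, seed = 5),
                               sampling_interval = 0.1)
  keep <- truth$observations$glucose_g_per_kg > 5
  rel <- (noisy$observations$glucose_g_per_kg[keep] -
            truth$observations$glucose_g_per_kg[keep]) /
    truth$observations$glucose_g_per_kg[keep]
  expect_gt(length(rel), 500)
  expect_equal(sd(rel), 0.05, tolerance = 0.1)
})

test_that("per-observable noise levels are honoured", {
  sc <- fit_scenario(0.10, 10, wheat)
  nm <- noise_model(sigma = c(glucose_g_per_kg = 0.05), seed = 2)
  ds <- generate_timecourse(sc, table1, nm)
  clean <- generate_timecourse(sc, table1, noise_model(sigma = 0))
  expect_false(identical(ds$observations$glucose_g_per_kg,
                         clean$observations$glucose_g_per_kg))
  expect_identical(ds$observations$wis_pct, clean$observations$wis_pct)
})

test_that("time-course files round-trip losslessly at working precision", {
  sc <- fit_scenario(0.10, 10, wheat)
  ds <- generate_timecourse(sc, table1, noise_model(sigma = 0.02, seed = 4))
  path <- tempfile(fileext = ".csv")
  write_timecourse(ds$observations, path)
  back <- read_timecourse(path)
  expect_equal(back, ds$observations, tolerance = 1e-12)
})

test_that("packaged fixtures carry the published values exactly", {
  expect_equal(unname(fx$params[c("k_ad", "k", "K_G", "gamma")]),
               c(0.27, 0.016, 6.13, 0.028))
  expect_equal(unname(fx$params[c("K_iEtOH", "q_G", "K", "Y_EtOH",
                                  "alpha", "beta")]),
               c(16.6, 1.6, 0.01, 0.42, 0.026, 0.0037))
  expect_equal(fx$lab_composition$glucan_frac, 0.479)
  expect_equal(fx$lab_composition$xylan_frac, 0.023)
  expect_equal(unname(fx$lab_composition$liquid_sugars[c("glucose", "xylose")]),
               c(6.8, 12.8))
  expect_equal(fx$demo_composition$glucan_frac, 0.424)
  expect_equal(fx$demo_composition$xylan_frac, 0.026)
  expect_equal(unname(fx$demo_composition$liquid_sugars[c("glucose", "xylose")]),
               c(2.4, 18.3))
  expect_equal(fx$lab_schedule$solids_added_at_h, c(0, 4, 12, 24, 48, 72, 96))
  expect_equal(fx$lab_schedule$cells_added_at_h, c(0, 24, 48, 72, 96))
  expect_equal(fx$lab_schedule$total_weight_g, 1252)
  expect_equal(fx$lab_schedule$wis_loading_pct, 22.2)
  expect_equal(fx$param_ci["K_G", ], c(lower = 2.7, upper = 13.8))
})

test_that("schedule reconstruction matches the recorded totals", {
  rec <- reconstruct_schedule(fx$lab_schedule$solids_added_at_h, table1,
                              wheat, final_mass = 1252)
  expect_equal(rec$sim$state$total_mass * 1252 / rec$sim$state$total_mass,
               1252)
  total <- rec$initial_mass +
    sum(vapply(rec$events, `[[`, 0, "solid_wet_mass"))
  expect_equal(total, 1252, tolerance = 1e-6)
  expect_true(all(vapply(rec$events, `[[`, 0, "time") %in%
                    fx$lab_schedule$solids_added_at_h))
})
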