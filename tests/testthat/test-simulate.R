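test_that("derivatives vanish without enzyme and at exhausted substrate", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 0)
  d <- sscf_derivatives(s, table1, "hydrolysis_only")
  expect_equal(unname(d[c("cellulose_mass", "glucose", "xylose")]),
               c(0, 0, 0))
  # at process start nothing is adsorbed yet, so no hydrolysis either
  s10 <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  d10 <- sscf_derivatives(s10, table1, "hydrolysis_only")
  expect_equal(unname(d10["glucose"]), 0)
  expect_gt(unname(d10["e_ad"]), 0)
})

test_that("SSCF derivatives reduce to hydrolysis-only at zero cells and ethanol", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  s$e_ad <- 4; s$glucose <- 20
  expect_equal(sscf_derivatives(s, table1, "sscf"),
               sscf_derivatives(s, table1, "hydrolysis_only"))
})

test_that("simulation without enzyme leaves the state unchanged", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 0)
  sim <- sscf_simulate(s, table1, 48, "hydrolysis_only")
  for (f in c("wis_mass", "cellulose_mass", "glucose", "xylose"))
    expect_equal(sim$state[[f]], s[[f]], tolerance = 1e-10)
  expect_equal(sim$state$time, 48)
})

test_that("batch hydrolysis is monotone and non-negative", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  sim <- sscf_simulate(s, table1, 96, "hydrolysis_only")
  tc <- sim$timecourse
  expect_true(all(diff(tc$glucose_g_per_kg) > 0))
  expect_true(all(diff(tc$cellulose_g) < 0))
  expect_true(all(as.matrix(tc) >= 0))
})

test_that("adsorbed enzyme rises monotonically and never exceeds its capacity", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  sim <- sscf_simulate(s, table1, 96, "hydrolysis_only",
                       sampling_interval = 0.5)
  tc <- sim$timecourse
  expect_true(all(diff(tc$e_ad_fpu_per_g) >= -1e-9))
  e_eq <- 10 * 100 / (tc$wis_pct / 100 * 1000)
  expect_true(all(tc$e_ad_fpu_per_g <= e_eq * (1 + 1e-6)))
})

test_that("sugar release and ethanol production satisfy mass conservation", {
  # hydrolysis: glucose released equals 1.111 x cellulose consumed
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  sim <- sscf_simulate(s, table1, 96, "hydrolysis_only")
  d_glu <- (sim$state$glucose - s$glucose) * s$total_mass / 1000
  d_cel <- s$cellulose_mass - sim$state$cellulose_mass
  expect_equal(d_glu, 1.111 * d_cel, tolerance = 1e-6)
  d_xyl <- (sim$state$xylose - s$xylose) * s$total_mass / 1000
  expect_equal(d_xyl, 1.136 * (s$xylan_mass - sim$state$xylan_mass),
               tolerance = 1e-6)

  # SSCF: ethanol = yield x glucose consumed; released = 1.111 x consumed cellulose
  s2 <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10,
                      cell_dosage = 0.02)
  sim2 <- sscf_simulate(s2, table1, 96, "sscf")
  consumed <- (sim2$state$ethanol / table1[["Y_EtOH"]]) * s2$total_mass / 1000
  released <- 1.111 * (s2$cellulose_mass - sim2$state$cellulose_mass)
  d_glu2 <- (sim2$state$glucose - s2$glucose) * s2$total_mass / 1000
  expect_equal(d_glu2 + consumed, released, tolerance = 1e-6)
})

test_that("SSCF at zero cells and ethanol reproduces the hydrolysis trajectory", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  a <- sscf_simulate(s, table1, 96, "hydrolysis_only")
  b <- sscf_simulate(s, table1, 96, "sscf")
  expect_equal(a$timecourse, b$timecourse, tolerance = 1e-8)
})

test_that("with hydrolysis disabled and constant ethanol cells decay exponentially", {
  s <- reactor_state(total_mass = 1000, wis_mass = 10, cellulose_mass = 5,
                     ethanol = 30, viable_cells = 2, enzyme_total = 0)
  sim <- sscf_simulate(s, table1, 24, "sscf")
  expect_equal(sim$state$ethanol, 30, tolerance = 1e-10)
  lambda <- table1[["alpha"]] * exp(table1[["beta"]] * 30)
  expect_equal(sim$state$viable_cells, 2 * exp(-lambda * 24),
               tolerance = 1e-6)
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle to 0.1 %", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  sim <- sscf_simulate(s, table1, 96, "hydrolysis_only")
  oracle <- rk4_final(s, table1, 96, "hydrolysis_only", h = 0.001)
  for (f in c("wis_mass", "cellulose_mass", "xylan_mass", "e_ad",
              "glucose", "xylose"))
    expect_equal(sim$state[[f]], unname(oracle[f]), tolerance = 1e-3)

  s2 <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10,
                      cell_dosage = 0.02)
  sim2 <- sscf_simulate(s2, table1, 96, "sscf")
  oracle2 <- rk4_final(s2, table1, 96, "sscf", h = 0.001)
  for (f in c("cellulose_mass", "glucose", "ethanol", "viable_cells"))
    expect_equal(sim2$state[[f]], unname(oracle2[f]), tolerance = 1e-3)
})

test_that("feed events inside a simulated span conserve dissolved amounts", {
  s <- initial_state(1000, 0.07, wheat, enzyme_dosage = 10)
  ev <- feed_event(24, solid_wet_mass = 150)
  sim <- sscf_simulate(s, table1, 48, "hydrolysis_only", events = list(ev),
                       composition = wheat)
  tc <- sim$timecourse
  at24 <- which(tc$time_h == 24)
  expect_length(at24, 2)                    # pre- and post-feed samples
  pre <- tc[at24[1], ]; post <- tc[at24[2], ]
  carried <- 150 - 150 * 0.40
  expect_equal(post$glucose_g_per_kg * post$total_mass_g,
               pre$glucose_g_per_kg * pre$total_mass_g + 6.8 * carried,
               tolerance = 1e-9)
  expect_equal(post$total_mass_g, 1150)
})

test_that("explicit sample times are honoured", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  sim <- sscf_simulate(s, table1, 96, "hydrolysis_only",
                       sample_times = c(13, 31.5, 77))
  expect_true(all(c(13, 31.5, 77) %in% sim$timecourse$time_h))
})

test_that("malformed simulations fail loudly", {
  s <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
  expect_error(sscf_simulate(s, table1, -5, "hydrolysis_only"))
  ev <- feed_event(200, liquid_mass = 10)
  expect_error(sscf_simulate(s, table1, 96, events = list(ev)), "span")
})
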