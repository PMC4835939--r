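lab_cfg <- function(...) {
  design_config(cumulative_wis_target = 0.22, ...)
}

test_that("design configurations are validated before any simulation", {
  expect_error(design_config(wis_ub = 0.45, wis_solids = 0.40), "wis_ub")
  expect_error(design_config(phi = 0), "phi")
  expect_error(design_config(initial_wis = 0.20, wis_ub = 0.13),
               "infeasible")
  expect_error(design_config(check_interval = 0), "check_interval")
})

test_that("an unreachable trigger yields a schedule with no solid feeds", {
  d <- design_feeds(lab_cfg(phi = 1, horizon = 48, cell_mode = "all_initial"),
                    table1, wheat)
  expect_equal(sum(vapply(d$schedule, `[[`, 0, "solid_wet_mass") > 0), 0)
})

test_that("a zero horizon returns only the initial sample", {
  d <- design_feeds(lab_cfg(horizon = 0), table1, wheat)
  expect_equal(length(d$schedule), 0)
  expect_equal(nrow(d$timecourse), 1)
})

test_that("the designed lab process exceeds 20 % cumulative WIS loading under the 13 % ceiling", {
  d <- design_feeds(lab_cfg(), table1, wheat)
  expect_gt(d$cumulative_wis_loading_pct, 20)
  expect_lte(d$max_wis_pct, 13 + 1e-7)
  # every positive solid feed tops the broth up to the ceiling exactly
  tc <- d$timecourse
  post_feed <- tc$wis_pct[abs(tc$wis_pct - 13) < 1e-6]
  expect_gte(length(post_feed), 3)
  expect_equal(cumulative_wis_loading(d), d$cumulative_wis_loading_pct)
})

test_that("lowering the conversion trigger never reduces the number of feeds", {
  counts <- vapply(c(0.3, 0.5, 0.6, 0.8), function(phi) {
    d <- design_feeds(design_config(phi = phi, horizon = 120), table1, wheat)
    sum(vapply(d$schedule, `[[`, 0, "solid_wet_mass") > 0)
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[4])
})

test_that("feed intervals stretch out as hydrolysis slows", {
  d <- design_feeds(design_config(mode = "hydrolysis_only", cell_dosage = 0,
                                  cell_mode = "all_initial", horizon = 120),
                    table1, wheat)
  tt <- vapply(Filter(function(e) e$solid_wet_mass > 0, d$schedule),
               `[[`, 0, "time")
  expect_gte(length(tt), 2)
  expect_true(all(diff(diff(tt)) >= 0))
})

test_that("the design loop is deterministic", {
  d1 <- design_feeds(lab_cfg(), table1, wheat)
  d2 <- design_feeds(lab_cfg(), table1, wheat)
  expect_identical(d1$schedule, d2$schedule)
  expect_identical(d1$timecourse, d2$timecourse)
})

test_that("SSCF designs schedule solid feeds earlier than hydrolysis-only designs", {
  # with the yeast consuming glucose, product inhibition of the enzymes is
  # weaker, conversion is faster and the trigger fires sooner
  dh <- design_feeds(design_config(mode = "hydrolysis_only",
                                   cell_dosage = 0,
                                   cell_mode = "all_initial",
                                   horizon = 120), table1, wheat)
  ds <- design_feeds(design_config(mode = "sscf",
                                   cell_mode = "all_initial",
                                   horizon = 120), table1, wheat)
  t_first <- function(d) vapply(Filter(function(e) e$solid_wet_mass > 0,
                                       d$schedule), `[[`, 0, "time")[1]
  expect_lt(t_first(ds), t_first(dh))
})

test_that("cumulative WIS loading reduces to the batch fraction without feeds", {
  s <- initial_state(1000, 0.07, wheat, enzyme_dosage = 0)
  sim <- sscf_simulate(s, table1, 12, "hydrolysis_only")
  expect_equal(cumulative_wis_loading(sim), 7)
})

test_that("one worked feed gives 13.0 % cumulative loading", {
  s <- initial_state(1000, 0.07, wheat, enzyme_dosage = 0)
  ev <- feed_event(6, solid_wet_mass = 222.222222)
  sim <- sscf_simulate(s, table1, 12, "hydrolysis_only", events = list(ev),
                       composition = wheat)
  expect_equal(cumulative_wis_loading(sim), 100 * 158.888889 / 1222.222222,
               tolerance = 1e-6)
})

test_that("performance metrics follow the yield definitions", {
  # complete conversion, nothing consumed: 100 % glucose yield
  x <- list(timecourse = data.frame(time_h = c(0, 96)),
            state = reactor_state(time = 96, total_mass = 1000,
                                  wis_mass = 52.1, cellulose_mass = 0,
                                  xylan_mass = 0, glucose = 53.2),
            wis_added = 100)
  perf <- evaluate_performance(x, wheat)
  expect_equal(perf$glucose_yield_pct, 100)
  expect_equal(perf$ethanol_yield_pct_theoretical, 0)
  # half the glucan released, none consumed: 50 %
  x$state$cellulose_mass <- wheat$glucan_frac * 100 / 2
  expect_equal(evaluate_performance(x, wheat)$glucose_yield_pct, 50)
  x$wis_added <- 0
  expect_error(evaluate_performance(x, wheat), "sugar basis")
})
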