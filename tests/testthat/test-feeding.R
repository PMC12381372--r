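# feeding: consumption accounting, cumulative capture, log curve fits.

make_event <- function(d0 = 1000, d1 = 600, vol = 40, sa = 200, dur = 2,
                       ...) {
  data.frame(density_initial = d0, density_final = d1, volume_L = vol,
             duration_h = dur, coral_surface_area_cm2 = sa, ...)
}

test_that("consumption arithmetic follows the density difference", {
  r <- consumption_from_densities(make_event())
  expect_equal(r$nauplii_consumed, 16000)
  expect_equal(r$biomass_consumed_mg, 51.2) # 16000 x 3.2 ug
  expect_equal(r$rate_nauplii_cm2_h, 40)
  expect_equal(r$biomass_per_area_mg_cm2, 0.256)
  expect_false(r$clamped)

  # no change in density: nothing consumed
  r0 <- consumption_from_densities(make_event(d1 = 1000))
  expect_equal(r0$nauplii_consumed, 0)
  expect_equal(r0$rate_nauplii_cm2_h, 0)

  # units audit: biomass always equals count x mass, to machine precision
  set.seed(8)
  ev <- make_event(d0 = runif(20, 500, 1500), d1 = runif(20, 100, 500))
  rr <- consumption_from_densities(ev)
  expect_equal(rr$biomass_consumed_mg, rr$nauplii_consumed * 3.2e-3)
})

test_that("apparent negative consumption is clamped with a warning", {
  expect_warning(r <- consumption_from_densities(make_event(d1 = 1100)),
                 class = "mixo_warning")
  expect_equal(r$nauplii_consumed, 0)
  expect_true(r$clamped)
})

test_that("invalid events are rejected", {
  expect_error(consumption_from_densities(make_event(vol = 0)),
               class = "mixo_validation_error")
  expect_error(consumption_from_densities(make_event(sa = -5)),
               class = "mixo_validation_error")
  expect_error(consumption_from_densities(make_event(dur = 0)),
               class = "mixo_validation_error")
  expect_error(consumption_from_densities(make_event(d0 = -1)),
               class = "mixo_validation_error")
})

test_that("raw triplicate density counts are averaged internally", {
  ev <- data.frame(density_initial_rep1 = 900, density_initial_rep2 = 1000,
                   density_initial_rep3 = 1100, density_final_rep1 = 500,
                   density_final_rep2 = 600, density_final_rep3 = 700,
                   volume_L = 40, duration_h = 2,
                   coral_surface_area_cm2 = 200)
  r <- consumption_from_densities(ev)
  expect_equal(r$density_initial, 1000)
  expect_equal(r$nauplii_consumed, 16000)
})

test_that("cumulative capture sums per-event biomass per tank", {
  one <- data.frame(tank_id = "T1", biomass_per_area_mg_cm2 = 0.3)
  expect_equal(cumulative_capture(one)$cumulative_mg_cm2, 0.3)
  many <- data.frame(tank_id = rep(c("T1", "T2"), each = 18),
                     treatment = rep(c("F_6x", "F_2x"), each = 18),
                     biomass_per_area_mg_cm2 = rep(c(0.5, 0.2), each = 18))
  cc <- cumulative_capture(many)
  expect_equal(cc$cumulative_mg_cm2[cc$tank_id == "T1"], 9.0)
  expect_equal(cc$n_events, c(18L, 18L))
  expect_error(cumulative_capture(many[0, ]),
               class = "mixo_validation_error")
})

test_that("generated cumulative capture recovers the configured curve total", {
  # independent oracle: the realized per-event rate is min(max(0, mu+e),
  # cap) where cap = d0 * volume / (area * duration) (a tank cannot yield
  # more prey than it holds); its expectation has a closed form via
  # E[max(0, X)] = mu*pnorm(mu/s) + s*dnorm(mu/s) for X ~ N(mu, s)
  relu_mean <- function(m, s) m * pnorm(m / s) + s * dnorm(m / s)
  cfg <- simulation_config(seed = 1)
  cp <- cfg$feeding_curve_params
  a <- cp$a[cp$treatment == "F_6x"]
  b <- cp$b[cp$treatment == "F_6x"]
  s <- cfg$sd_feeding_rate

  diffs <- c()
  for (sd_ in 1:5) {
    ex <- generate_experiment(simulation_config(seed = sd_))
    ev <- ex$feeding_events[ex$feeding_events$treatment == "F_6x", ]
    mu <- a + b * log(ev$density_initial)
    cap <- ev$density_initial * ev$volume_L /
      (ev$coral_surface_area_cm2 * ev$duration_h)
    e_rate <- relu_mean(mu, s) - relu_mean(mu - cap, s)
    expected <- tapply(e_rate * ev$duration_h * 3.2e-3, ev$tank_id, sum)
    got <- cumulative_capture(consumption_from_densities(ev))
    diffs <- c(diffs,
               got$cumulative_mg_cm2 - as.numeric(expected[got$tank_id]))
  }
  # 15 tank totals; mean deviation from the analytic expectation is small
  expect_lt(abs(mean(diffs)), 0.4)
})

test_that("log-curve fits recover all printed coefficient pairs exactly", {
  d <- c(250, 500, 900, 1400)
  curves <- default_feeding_curves()
  for (i in seq_len(nrow(curves))) {
    f <- fit_log_curve(d, curves$a[i] + curves$b[i] * log(d))
    expect_equal(f$a, curves$a[i], tolerance = 1e-8)
    expect_equal(f$b, curves$b[i], tolerance = 1e-8)
    expect_equal(f$r_squared, 1)
    expect_equal(f$n_points, 4L)
  }
  # prediction from the noiseless fit at 1000 nauplii / L
  f6 <- fit_log_curve(d, -209.1 + 41.0 * log(d))
  expect_equal(predict(f6, 1000), -209.1 + 41.0 * log(1000))
  expect_equal(round(predict(f6, 1000), 1), 74.1)
  # monotonicity for b > 0
  dense <- seq(100, 2000, by = 50)
  expect_true(all(diff(predict(f6, dense)) > 0))
})

test_that("degenerate log-curve inputs are handled", {
  expect_equal(fit_log_curve(c(100, 200, 400), rep(7, 3))$b, 0)
  expect_equal(fit_log_curve(c(100, 200, 400), rep(7, 3))$a, 7)
  expect_error(fit_log_curve(c(100, 200), c(1, 2)),
               class = "mixo_validation_error")
  expect_error(fit_log_curve(c(0, 200, 300), c(1, 2, 3)),
               class = "mixo_validation_error")
  expect_error(predict(fit_log_curve(c(100, 200, 400), 1:3), -5),
               class = "mixo_validation_error")
})

test_that("per-treatment curve fitting pools tank-level events", {
  ex <- generate_experiment(zero_noise_config(seed = 4))
  cap <- consumption_from_densities(ex$feeding_events)
  fits <- fit_feeding_curves(cap)
  truth <- ex$truth$feeding_curves
  m <- merge(fits, truth, by = "treatment")
  # noiseless generation: every treatment curve is recovered exactly
  expect_equal(m$a.x, m$a.y, tolerance = 1e-6)
  expect_equal(m$b.x, m$b.y, tolerance = 1e-6)
  per_tank <- fit_feeding_curves(cap, per = "tank_id")
  expect_equal(nrow(per_tank), length(unique(cap$tank_id)))
})
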