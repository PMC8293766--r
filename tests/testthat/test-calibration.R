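make_lwc_obs <- function(values, days = rep(2, length(values))) {
  observation_series(day = days, replicate = seq_along(values),
                     litter = "x", treatment = "alone",
                     variable = "lwc", value = values)
}

test_that("initial water content is the rounded-up first measurement", {
  expect_equal(initial_lwc_from_obs(make_lwc_obs(c(21.50, 21.62))), 22)
  expect_equal(initial_lwc_from_obs(make_lwc_obs(c(3.0, 3.0))), 3)
  expect_equal(initial_lwc_from_obs(make_lwc_obs(2.01)), 3)
  # only the earliest day counts
  obs <- make_lwc_obs(c(5.5, 1.2), days = c(2, 7))
  expect_equal(initial_lwc_from_obs(obs), 6)
  ms <- observation_series(2, 1, "x", "alone", "mass_fraction", 0.9)
  expect_error(initial_lwc_from_obs(ms), "no water-content")
})

test_that("evaporation fits recover the generating rate exactly", {
  days <- c(2, 7, 14, 28, 56, 84, 112)
  for (e_true in c(0.001, 0.01, 0.1, 0.5)) {
    obs <- make_lwc_obs(3 * (1 - e_true)^days, days = days)
    fit <- fit_evaporation(obs, lwc_max = 3)
    expect_equal(fit$e, e_true, tolerance = 1e-6)
  }
})

test_that("a constant water series fits to zero evaporation", {
  obs <- make_lwc_obs(rep(5, 8), days = rep(c(2, 7, 14, 28), each = 2))
  expect_equal(fit_evaporation(obs, 5)$e, 0)
  expect_error(fit_evaporation(make_lwc_obs(c(3, 3.1)), 4), "distinct days")
})

test_that("noisy evaporation fits stay close to the truth (median < 10%)", {
  truth <- molinia()
  errs <- vapply(1:40, function(s) {
    obs <- generate_single_litter_obs(truth, sampling_design(), seed = s)
    f <- fit_evaporation(obs, initial_lwc_from_obs(obs))
    abs(f$e - truth$e) / truth$e
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("decay fits recover the generating parameters on clean data", {
  p <- litter_params("x", 3, 0.006, 0.061, "bunnell", c = 1.5, d = 2)
  obs <- generate_single_litter_obs(p, noiseless_design())
  fit <- fit_decay(obs, lwc_max = 3, e = 0.061)
  expect_equal(fit$k_max, 0.006, tolerance = 1e-4 / 0.006)
  # {c, d} weakly identified: assert the identifiable combinations
  expect_equal(sort(c(fit$c, fit$d)), c(1.5, 2), tolerance = 0.05)
  expect_lt(fit$sse, 1e-12)
})

test_that("decay fits report their gauge in canonical order c <= d", {
  p <- litter_params("x", 5, 0.01, 0.05, "bunnell", c = 4, d = 1)
  obs <- generate_single_litter_obs(p, noiseless_design())
  fit <- fit_decay(obs, lwc_max = 5, e = 0.05)
  expect_lte(fit$c, fit$d)
  # the canonical copy reproduces the same rate curve as the truth
  refit <- litter_params("x", 5, fit$k_max, 0.05, "bunnell",
                         c = fit$c, d = fit$d)
  lwc <- seq(0.01, 5, length.out = 50)
  expect_equal(rate_bunnell(lwc, refit), rate_bunnell(lwc, p),
               tolerance = 1e-6)
})

test_that("an undecomposed litter fits to the k_max lower bound", {
  obs <- observation_series(day = rep(c(2, 7, 14, 28), each = 3),
                            replicate = rep(1:3, 4), litter = "x",
                            treatment = "alone",
                            variable = "mass_fraction", value = 1)
  fit <- fit_decay(obs, lwc_max = 5, e = 0.05)
  expect_lt(fit$k_max, 1e-6)
  expect_true(fit$bounds_active[["k_max"]])
})

test_that("the fitted objective never exceeds the objective at the truth", {
  truth <- molinia()
  obs <- generate_single_litter_obs(truth, sampling_design(), seed = 9)
  fit <- fit_decay(obs, lwc_max = 3, e = 0.061)
  ms <- obs[obs$variable == "mass_fraction", ]
  sse_at <- function(k_max, cc, dd) {
    t <- 0:max(ms$day); lwc <- 3 * (1 - 0.061)^t
    k <- k_max * lwc / (cc + lwc) * dd / (dd + lwc)
    m <- c(1, cumprod(1 - k[-1]))
    sum((ms$value - m[ms$day + 1])^2)
  }
  expect_lte(fit$sse, sse_at(truth$k_max, truth$c, truth$d) + 1e-12)
})

test_that("full two-phase calibration recovers the peatland litters", {
  for (truth in list(sphagnum(), molinia())) {
    obs <- generate_single_litter_obs(truth, noiseless_design())
    fit <- fit_litter_model(obs)
    co <- coef(fit)
    expect_equal(co[["lwc_max"]], truth$lwc_max)
    expect_equal(co[["e"]], truth$e, tolerance = 1e-6 / truth$e)
    expect_equal(co[["k_max"]], truth$k_max,
                 tolerance = 1e-4 / truth$k_max)
    # both sensitivity constants rest on the saturation bound
    expect_true(fit$bounds_active[["c"]] && fit$bounds_active[["d"]])
    expect_equal(co[["c"]], truth$lwc_max, tolerance = 1e-4)
    expect_equal(co[["d"]], truth$lwc_max, tolerance = 1e-4)
  }
})

test_that("repeated fits are bit-identical (no hidden randomness)", {
  truth <- molinia()
  obs <- generate_single_litter_obs(truth, sampling_design(), seed = 4)
  f1 <- fit_litter_model(obs)
  f2 <- fit_litter_model(obs)
  expect_identical(coef(f1), coef(f2))
})

test_that("calibrated models round-trip: refit curves match the generator", {
  truth <- molinia()
  obs <- generate_single_litter_obs(truth, noiseless_design())
  fit <- fit_litter_model(obs)
  horizon <- 112
  expect_equal(simulate_litter(fit$params, horizon)$mass_fraction,
               simulate_litter(truth, horizon)$mass_fraction,
               tolerance = 1e-6)
  expect_equal(simulate_litter(fit$params, horizon)$lwc,
               simulate_litter(truth, horizon)$lwc, tolerance = 1e-6)
})

test_that("litter_fit methods expose the fit coherently", {
  truth <- molinia()
  obs <- generate_single_litter_obs(truth, sampling_design(), seed = 2)
  fit <- fit_litter_model(obs)
  expect_named(coef(fit), c("lwc_max", "k_max", "c", "d", "e"))
  expect_output(print(fit), "Calibrated litter")
  expect_output(print(summary(fit)), "Goodness of fit")
  # residuals pair one-to-one with the pooled mass observations
  n_mass <- sum(obs$variable == "mass_fraction")
  expect_length(residuals(fit), n_mass)
  expect_length(fitted(fit), n_mass)
  # predictions at observed days reproduce fitted values
  ms_days <- sort(unique(obs$day))
  pred <- predict(fit, days = ms_days)
  expect_length(pred, length(ms_days))
  expect_true(all(diff(pred) < 0))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "observation_series")
})

test_that("fits refuse ambiguous or empty observation sets", {
  a <- generate_single_litter_obs(molinia(), sampling_design(), seed = 1)
  b <- generate_single_litter_obs(sphagnum(), sampling_design(), seed = 1)
  ab <- rbind(as.data.frame(a), as.data.frame(b))
  both <- observation_series(ab$day, ab$replicate, ab$litter,
                             ab$treatment, ab$variable, ab$value)
  expect_error(fit_litter_model(both), "several litters")
  fit <- fit_litter_model(both, litter = "M. caerulea")
  expect_equal(fit$params$name, "M. caerulea")
  expect_error(fit_litter_model(both, litter = "nope"), "no single-litter")
})
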