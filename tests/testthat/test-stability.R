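# Two-state chemical denaturation: simulation, fitting, melt summaries.

ref_params <- list(dG = 8.4, m = 1.6,
            baselines = list(a_f = 1, b_f = -0.01, a_u = 0.1, b_u = -0.005))

test_that("the simulated signal hits the baseline midpoint at Cm", {
  b <- list(a_f = 2, b_f = -0.05, a_u = 0.3, b_u = 0.02)
  cm <- 8.4 / 1.6
  cv <- simulate_curve(8.4, 1.6, b, x = cm, noise_sd = 0)
  mid <- ((b$a_f + b$b_f * cm) + (b$a_u + b$b_u * cm)) / 2
  expect_equal(cv$signal, mid, tolerance = 1e-12)
})

test_that("the folded limit dominates at zero denaturant", {
  cv <- simulate_curve(8.4, 1.6, list(a_f = 1, b_f = 0, a_u = 0, b_u = 0),
                       x = 0, noise_sd = 0)
  expect_equal(cv$signal, 1, tolerance = 1e-5)
})

test_that("the apparent transition midpoint sits at dG/m", {
  x <- seq(0, 7.5, by = 0.01)
  cv <- simulate_curve(8.4, 1.6, list(a_f = 1, b_f = 0, a_u = 0, b_u = 0),
                       x = x, noise_sd = 0)
  imid <- which.min(abs(cv$signal - 0.5))
  expect_equal(cv$denaturant[imid], 5.25, tolerance = 0.01)
})

test_that("noiseless curves invert exactly", {
  cv <- simulate_curve(ref_params$dG, ref_params$m, ref_params$baselines, noise_sd = 0)
  f <- fit_two_state(cv)
  expect_equal(f$dG, 8.4, tolerance = 1e-4)
  expect_equal(f$m_value, 1.6, tolerance = 1e-4)
  expect_equal(f$Cm, 5.25, tolerance = 1e-4)
  expect_equal(f$a_f, 1, tolerance = 1e-4)
  expect_equal(f$b_u, -0.005, tolerance = 1e-4)
})

test_that("parameters are recovered from noisy curves (20 seeds, 5%)", {
  fits <- lapply(1:20, function(s) {
    cv <- simulate_curve(ref_params$dG, ref_params$m, ref_params$baselines, noise_sd = 0.009,
                         seed = s)
    fit_two_state(cv)
  })
  dg <- vapply(fits, `[[`, numeric(1), "dG")
  mm <- vapply(fits, `[[`, numeric(1), "m_value")
  expect_lt(abs(stats::median(dg) - 8.4) / 8.4, 0.05)
  expect_lt(abs(stats::median(mm) - 1.6) / 1.6, 0.05)
  # no significant sign bias
  p <- stats::binom.test(sum(dg > 8.4), 20)$p.value
  expect_gt(p, 0.01)
})

test_that("Cm equals dG/m for every returned fit", {
  for (s in 1:5) {
    cv <- simulate_curve(6 + s / 2, 1.2 + s / 10, ref_params$baselines,
                         noise_sd = 0.005, seed = s)
    f <- fit_two_state(cv)
    expect_equal(f$Cm, f$dG / f$m_value, tolerance = 1e-10)
  }
})

test_that("the fit matches a coarse grid-search oracle", {
  # flat baselines and a grid reaching well past the transition, so the
  # oracle's endpoint-regression baselines are essentially exact
  cv <- simulate_curve(ref_params$dG, ref_params$m,
                       list(a_f = 1, b_f = 0, a_u = 0.1, b_u = 0),
                       x = seq(0, 9, length.out = 40), noise_sd = 0)
  f <- fit_two_state(cv)
  x <- cv$denaturant; y <- cv$signal
  n <- length(x)
  bl_lo <- stats::coef(stats::lm(y[1:8] ~ x[1:8]))
  bl_hi <- stats::coef(stats::lm(y[(n - 7):n] ~ x[(n - 7):n]))
  RT <- f$RT
  grid <- expand.grid(dG = seq(6, 11, 0.2), m = seq(1.0, 2.2, 0.05))
  sse <- apply(grid, 1, function(g) {
    K <- exp(-(g[1] - g[2] * x) / RT)
    pred <- ((bl_lo[1] + bl_lo[2] * x) + (bl_hi[1] + bl_hi[2] * x) * K) / (1 + K)
    sum((y - pred)^2)
  })
  best <- grid[which.min(sse), ]
  expect_lt(abs(f$dG - best$dG), 0.2 + 1e-9)
  expect_lt(abs(f$m_value - best$m), 0.05 + 1e-9)
})

test_that("fits are invariant to affine rescaling of the signal", {
  cv <- simulate_curve(ref_params$dG, ref_params$m, ref_params$baselines, noise_sd = 0.005,
                       seed = 6)
  f1 <- fit_two_state(cv)
  cv2 <- cv
  cv2$signal <- 3 * cv2$signal + 10
  f2 <- fit_two_state(cv2)
  expect_equal(f2$dG, f1$dG, tolerance = 1e-5)
  expect_equal(f2$m_value, f1$m_value, tolerance = 1e-5)
  expect_equal(f2$Cm, f1$Cm, tolerance = 1e-5)
  expect_equal(f2$a_f, 3 * f1$a_f + 10, tolerance = 1e-4)
})

test_that("fit preconditions and warnings fire", {
  cv <- simulate_curve(8.4, 1.6, ref_params$baselines, x = seq(0, 7.5, length.out = 5))
  expect_error(fit_two_state(cv), "at least 8")
  # a transition whose midpoint lies beyond the sampled range is flagged
  cv2 <- simulate_curve(11, 1.6, list(a_f = 1, b_f = 0, a_u = 0.1, b_u = 0),
                        x = seq(0, 5.5, length.out = 14), noise_sd = 0)
  expect_warning(fit_two_state(cv2), "midpoint")
})

test_that("tidy/glance expose fit results", {
  cv <- simulate_curve(ref_params$dG, ref_params$m, ref_params$baselines, noise_sd = 0.005, seed = 2)
  f <- fit_two_state(cv)
  td <- generics::tidy(f)
  expect_true(all(c("dG", "m", "Cm") %in% td$term))
  gl <- generics::glance(f)
  expect_equal(gl$Cm, f$Cm)
})

test_that("thermal melt summary distinguishes flat and sigmoidal traces", {
  tt <- seq(20, 95, by = 2.5)
  flat <- thermal_melt_summary(data.frame(temperature = tt,
                                          signal = rep(-1, length(tt))))
  expect_false(flat$transition)
  expect_lt(flat$fractional_change, 0.01)
  expect_match(flat$note, "no complete transition")

  y <- 1 / (1 + exp((60 - tt) / 4))
  sig <- thermal_melt_summary(data.frame(temperature = tt, signal = y))
  expect_true(sig$transition)
  expect_lt(abs(sig$midpoint - 60), 1)

  rev <- thermal_melt_summary(data.frame(temperature = tt, signal = y),
                              cooled_signal = y[1] + 1e-4)
  expect_true(rev$reversible)
  irr <- thermal_melt_summary(data.frame(temperature = tt, signal = y),
                              cooled_signal = y[1] + 0.5)
  expect_false(irr$reversible)
})

test_that("the synthetic curve panel is deterministic and fit-consistent", {
  p1 <- make_curve_panel(seed = 5)
  p2 <- make_curve_panel(seed = 5)
  expect_identical(p1, p2)
  ref_rows <- which(p1$dG == 8.4 & p1$noise == 0)
  f <- fit_two_state(p1$curve[[ref_rows[1]]])
  expect_equal(f$Cm, 5.25, tolerance = 1e-4)
  noisy <- which(p1$dG == 8.4 & p1$noise == 0.01)
  f2 <- fit_two_state(p1$curve[[noisy[1]]])
  expect_lt(abs(f2$Cm - 5.25) / 5.25, 0.05)
})
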