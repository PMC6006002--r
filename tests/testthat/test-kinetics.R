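test_that("two-point fit is the exact solution through both samples", {
  f <- fit_monoexp(data.frame(time_h = c(0, 24), conc = c(100, 50)))
  expect_equal(f$c0, 100)
  expect_equal(f$lambda_eff, log(2) / 24)
  expect_equal(f$half_life_h * f$lambda_eff, log(2))
  # both samples reproduced to float precision
  expect_lt(abs(f$c0 * exp(-f$lambda_eff * 24) / 50 - 1), 1e-10)

  s <- timed_samples("blood", c(18, 25), c(30, 22))
  f2 <- fit_monoexp(s)
  expect_lt(abs(f2$c0 * exp(-f2$lambda_eff * 18) / 30 - 1), 1e-10)
  expect_lt(abs(f2$c0 * exp(-f2$lambda_eff * 25) / 22 - 1), 1e-10)
})

test_that("noiseless multi-point samples recover the true parameters", {
  tt <- c(18, 25, 168)
  f <- fit_monoexp(data.frame(time_h = tt, conc = 100 * exp(-0.03 * tt)))
  expect_equal(f$c0, 100, tolerance = 1e-6)
  expect_equal(f$lambda_eff, 0.03, tolerance = 1e-6)
  expect_equal(f$n_points, 3L)

  # property: recovery across the (c0, lambda) domain, times scaled to
  # the half-life so late samples stay measurable
  set.seed(11)
  for (i in 1:25) {
    c0 <- 10^runif(1, 0, 4)
    lam <- 10^runif(1, -3, 0)
    tt <- c(0.5, 1, 2, 3.5) / lam
    f <- suppressWarnings(
      fit_monoexp(data.frame(time_h = tt, conc = c0 * exp(-lam * tt))))
    expect_equal(f$c0, c0, tolerance = 1e-6)
    expect_equal(f$lambda_eff, lam, tolerance = 1e-6)
  }
})

test_that("noisy fit agrees with an independent grid-search oracle", {
  set.seed(42)
  tt <- seq(10, 170, length.out = 10)
  y <- 250 * exp(-0.012 * tt) * exp(rnorm(10, 0, 0.05))
  f <- fit_monoexp(data.frame(time_h = tt, conc = y))
  g <- oracle_grid_fit(tt, y)
  expect_equal(f$c0, g$c0, tolerance = 1e-3)
  expect_equal(f$lambda_eff, g$lambda, tolerance = 1e-3)
})

test_that("fit rejects invalid inputs and non-decaying curves", {
  expect_error(fit_monoexp(data.frame(time_h = 18, conc = 10)),
               class = "prrtdose_insufficient_data")
  expect_error(fit_monoexp(data.frame(time_h = c(18, 25), conc = c(10, 0))),
               class = "prrtdose_domain_error")
  expect_error(fit_monoexp(data.frame(time_h = c(18, 18), conc = c(10, 9))),
               class = "prrtdose_domain_error")
  expect_error(fit_monoexp(data.frame(time_h = c(18, 25), conc = c(10, 12))),
               class = "prrtdose_nonphysical_fit")
  s <- rbind(timed_samples("kidneys", 18, 100),
             timed_samples("liver", 25, 50))
  expect_error(fit_monoexp(s), class = "prrtdose_domain_error")
})

test_that("a half-life above the 177Lu physical bound warns but fits", {
  # T_eff ~ 485 h >> 159.5 h physical: impossible, but only a warning
  expect_warning(
    f <- fit_monoexp(data.frame(time_h = c(18, 25), conc = c(100, 99))),
    class = "prrtdose_subphysical_lambda")
  expect_gt(f$half_life_h, LU177_HALF_LIFE_H)
})

test_that("rescale_to_cycle anchors the reference decay to one sample", {
  ref <- fit_monoexp(data.frame(time_h = c(1, log(2) / 0.02 + 1),
                                conc = c(100 * exp(-0.02), 50 * exp(-0.02))))
  f <- rescale_to_cycle(ref, list(time_h = 20, conc = 40, cycle = 2L))
  expect_equal(f$lambda_eff, ref$lambda_eff)
  expect_equal(f$c0, 40 * exp(ref$lambda_eff * 20))
  expect_equal(f$c0, 59.6730, tolerance = 1e-5)
  expect_equal(f$cycle, 2L)

  # a sample drawn from the reference curve itself returns its c0
  samp <- list(time_h = 33, conc = ref$c0 * exp(-ref$lambda_eff * 33))
  expect_equal(rescale_to_cycle(ref, samp)$c0, ref$c0)

  ref2 <- structure(list(c0 = 1, lambda_eff = 0.05, organ = "kidneys"),
                    class = "monoexp_fit")
  expect_equal(rescale_to_cycle(ref2, list(time_h = 10, conc = 10))$c0,
               16.4872, tolerance = 1e-4)
  expect_error(rescale_to_cycle(ref2, list(time_h = 10, conc = 0)),
               class = "prrtdose_domain_error")
})

test_that("residence time matches the closed form and scales correctly", {
  f <- structure(list(c0 = 100, lambda_eff = 0.03, organ = "kidneys",
                      cycle = 1L), class = "monoexp_fit")
  rt <- residence_time(f, 7400)
  expect_equal(rt$value, 100 * 3600 / (0.03 * 7400))
  expect_equal(rt$value, 1621.62, tolerance = 1e-5)
  # inverse proportionality in administered activity
  expect_equal(residence_time(f, 14800)$value, rt$value / 2)
  # linearity in c0, inverse proportionality in lambda
  f2 <- f; f2$c0 <- 300
  expect_equal(residence_time(f2, 7400)$value, 3 * rt$value)
  f3 <- f; f3$lambda_eff <- 0.06
  expect_equal(residence_time(f3, 7400)$value, rt$value / 2)
  expect_error(residence_time(f, 0), class = "prrtdose_domain_error")
})

test_that("closed-form residence time equals numerical quadrature", {
  set.seed(5)
  for (i in 1:100) {
    c0 <- runif(1, 1, 1e4)
    lam <- 10^runif(1, -3, 0)
    a <- runif(1, 1000, 9000)
    f <- structure(list(c0 = c0, lambda_eff = lam), class = "monoexp_fit")
    expect_equal(residence_time(f, a)$value,
                 oracle_quadrature_rt(c0, lam, a), tolerance = 1e-6)
  }
})
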