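test_that("two-point calibration solves the affine delay law algebraically", {
  fit <- calibrate_timing(reference_delay_points())
  # algebraic oracle: slope through the two points, intercept from the first
  A_ref <- (14.17 - 8.07) / (4 - 1)
  B_ref <- 8.07 - A_ref
  expect_equal(fit$A, A_ref, tolerance = 1e-12)
  expect_equal(fit$B, B_ref, tolerance = 1e-12)
  expect_error(calibrate_timing(tibble::tibble(factor = c(2, 2),
                                               delay_hours = c(1, 2))),
               "distinct factors")
})

test_that("noiseless calibration round-trips arbitrary (A, B) exactly", {
  for (s in 1:10) {
    AB <- withr::with_seed(900 + s, runif(2, 0.5, 10))
    f <- c(1, 2, 5, 16, 49)
    pts <- tibble::tibble(factor = f, delay_hours = f * AB[1] + AB[2])
    fit <- calibrate_timing(pts)
    expect_equal(fit$A, AB[1], tolerance = 1e-9)
    expect_equal(fit$B, AB[2], tolerance = 1e-9)
    # regenerated points reproduce the inputs exactly
    expect_equal(vapply(f, function(k) layer_delay(fit, k, 1), numeric(1)),
                 pts$delay_hours, tolerance = 1e-9)
  }
})

test_that("noisy calibration recovers stage constants within the noise scale", {
  recovered <- vapply(1:50, function(s) {
    withr::with_seed(2000 + s, {
      f <- c(1, 3, 8, 20, 50)
      pts <- tibble::tibble(factor = f,
                            delay_hours = f * 2 + 6 + runif(5, -0.05, 0.05))
      fit <- calibrate_timing(pts)
      c(fit$A, fit$B)
    })
  }, numeric(2))
  expect_lt(max(abs(recovered[1, ] - 2)), 0.05)
  expect_lt(max(abs(recovered[2, ] - 6)), 0.05 * 2)
})

test_that("the serialized delay law is affine and increasing in the factor", {
  p <- default_timing()
  expect_equal(layer_delay(p, 784, 784), 8.07, tolerance = 1e-9)
  d <- vapply(c(1, 2, 4, 16, 49, 196), function(f) layer_delay(p, f, 1),
              numeric(1))
  expect_true(all(diff(d) > 0))
  expect_equal(diff(d) / diff(c(1, 2, 4, 16, 49, 196)), rep(p$A, 5),
               tolerance = 1e-9)
  # with A = 0 the delay is independent of serialization
  p0 <- timing_params(t_transport = 0, t_mult = 0, t_gate = 5)
  expect_equal(layer_delay(p0, 784, 4), layer_delay(p0, 784, 784))
  # ceiling applies to partial passes
  expect_equal(layer_delay(p, 10, 4), 3 * p$A + p$B)
})

test_that("area model follows the quadratic law with exact scale invariance", {
  expect_equal(array_area(1, area_params(per_cell_coefficient = 1.44)), 1.44)
  for (k in c(2, 7, 49, 196)) {
    expect_identical(array_area(k, area_pessimistic()),
                     array_area(1, area_pessimistic()) * k^2)
    expect_identical(array_area(2 * k, area_pessimistic()),
                     4 * array_area(k, area_pessimistic()))
  }
  # optimistic preset: printed coefficient by default, exact on request
  expect_equal(area_optimistic()$per_cell_coefficient, 0.01)
  expect_equal(area_optimistic(use_printed = FALSE)$per_cell_coefficient,
               (3 * 0.035)^2)
  expect_equal(array_area(196, area_pessimistic(), "cm2", 2), 553.19)
})

test_that("the configuration report reproduces the published summary table", {
  rep <- config_report()
  expect_equal(rep$configuration, paste0("Config-", 1:4))
  expect_equal(rep$k_physical, c(196L, 49L, 16L, 4L))
  expect_equal(rep$factor, c(4L, 16L, 49L, 196L))
  expect_equal(rep$area_pessimistic_cm2, c(553.19, 34.57, 3.69, 0.23))
  expect_equal(rep$area_optimistic_cm2, c(3.84, 0.24, 0.03, 0.002))
  expect_true(all(abs(rep$delay_hours - c(14.17, 38.6, 105.6, 404.6)) <= 0.15))
  # a full-width 784 x 784 engine needs no serialization: delay is A + B
  p <- default_timing()
  expect_equal(layer_delay(p, 784, 784), p$A + p$B)
})

test_that("timing_fit has broom-style tidy and glance methods", {
  fit <- calibrate_timing()
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(td$estimate, c(fit$B, fit$A))
  gl <- glance(fit)
  expect_equal(gl$factor1_delay_hours, 8.07, tolerance = 1e-9)
  expect_equal(gl$n_points, 2L)
})

test_that("timing params derive activation and grouped constants", {
  p <- timing_params(t_transport = 0.1, t_mult = 1.9, t_merge = 0.5,
                     t_displacement = 1, t_threshold = 2, t_gate = 3,
                     t_translation = 0.25, t_nick = 0.25)
  expect_equal(p$t_activation, 6.5)
  expect_equal(p$A, 2)
  expect_equal(p$B, 7)
  expect_error(timing_params(t_transport = -1), "nonnegative")
})
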