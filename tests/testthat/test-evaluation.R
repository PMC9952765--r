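test_that("relative-error accuracy follows its arithmetic", {
  perfect <- error_percentage(c(5, 5, 5), c(5, 5, 5))
  expect_equal(perfect$e, 0)
  expect_equal(perfect$accuracy, 100)

  expect_equal(error_percentage(9, 10)$e, 10)
  # absolute values: no cancellation
  expect_equal(error_percentage(c(9, 11), c(10, 10))$e, 10)

  r <- error_percentage(c(42, 50), c(45, 48))
  expect_equal(r$accuracy + r$e, 100)
  # scale invariance
  r2 <- error_percentage(c(42, 50) * 3.5, c(45, 48) * 3.5)
  expect_equal(r2$e, r$e, tolerance = 1e-12)

  expect_error(error_percentage(c(1, 2), c(1, 0)), "undefined")
  expect_error(error_percentage(1:3, 1:2), "equal length")
})

test_that("reference quantification counts cycles at the sensor rate", {
  prof <- motion_profile("resting_tremor", frequency_spec = 5)
  tr <- generate_reference_trace(prof, duration = 20, seed = 14)
  q <- quantify_reference(tr, f_max = 6)
  expect_equal(q$count, 50L)
  expect_equal(q$mean_frequency, 5, tolerance = 0.05)

  null_tr <- list(values = numeric(4000), fs = 200)
  expect_equal(quantify_reference(null_tr, f_max = 6)$count, 0L)
})

test_that("OLS accuracy-distance fit matches the closed form", {
  d <- c(0, 1, 2, 3, 4, 5)
  fit <- fit_accuracy_vs_distance(d, -2 * d + 95)
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_equal(fit$intercept, 95, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- fit_accuracy_vs_distance(d, rep(90, 6))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_equal(flat$r_squared, 0)

  set.seed(60)
  x <- rnorm(10); y <- 3 * x + rnorm(10)
  got <- fit_accuracy_vs_distance(x, y)
  want <- ols_oracle(x, y)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)

  expect_error(fit_accuracy_vs_distance(rep(1, 5), rnorm(5)), "all equal")
  expect_error(fit_accuracy_vs_distance(1:2, 1:2), ">= 3")
})

test_that("contour interpolation reproduces nodes and mirrors exactly", {
  pts <- expand.grid(x = c(-2, -1, 0), y = 0:3)
  pts$accuracy <- 90 + 2 * pts$x - 1.5 * pts$y
  model <- build_accuracy_contour(pts, axis = list(type = "vertical",
                                                   at = 0))
  # measured nodes reproduced exactly
  expect_equal(model$predict(pts$x, pts$y), pts$accuracy,
               tolerance = 1e-12)
  # mirror image of every node gives the same value
  expect_equal(model$predict(-pts$x, pts$y), pts$accuracy,
               tolerance = 1e-12)
  # centre of a unit cell is the average of its corners (bilinear)
  corners <- pts$accuracy[pts$x %in% c(-2, -1) & pts$y %in% c(1, 2)]
  expect_equal(model$predict(-1.5, 1.5), mean(corners), tolerance = 1e-12)
  # outside the measured rectangle: missing, never extrapolated
  expect_true(is.na(model$predict(-3, 1)))
  expect_true(is.na(model$predict(-1, 9)))
})

test_that("reflection applied twice is the identity", {
  pts <- expand.grid(x = c(-2, -1, 0), y = 0:2)
  set.seed(61)
  pts$accuracy <- runif(nrow(pts), 80, 99)
  model <- build_accuracy_contour(pts, axis = list(type = "vertical",
                                                   at = 0))
  xq <- runif(20, -2, 2); yq <- runif(20, 0, 2)
  expect_equal(model$predict(xq, yq),
               model$predict(-(-xq), yq), tolerance = 1e-12)
  # and a point with its own mirror
  expect_equal(model$predict(xq, yq), model$predict(-xq, yq),
               tolerance = 1e-12)
})

test_that("validation points report the mirrored-prediction discrepancy", {
  pts <- expand.grid(x = c(-2, -1, 0), y = 0:2)
  pts$accuracy <- 95 - abs(pts$x) - pts$y
  val <- data.frame(x = c(1, 2), y = c(1, 0), accuracy = c(93.5, 92.4))
  model <- build_accuracy_contour(pts, axis = list(type = "vertical",
                                                   at = 0),
                                  validation = val)
  expect_equal(model$validation$predicted, c(93, 93), tolerance = 1e-12)
  expect_equal(model$validation$discrepancy, c(0.5, 0.6),
               tolerance = 1e-12)
})

test_that("contour grid export covers the mirrored extent", {
  pts <- expand.grid(x = c(-2, -1, 0), y = 0:2)
  pts$accuracy <- 90 + pts$x + pts$y
  model <- build_accuracy_contour(pts, axis = list(type = "vertical",
                                                   at = 0))
  g <- contour_grid(model, nx = 21, ny = 7)
  expect_equal(range(g$x), c(-2, 2))
  expect_equal(range(g$y), c(0, 2))
  expect_true(all(is.finite(g$accuracy)))
})
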