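test_that("noise calibration inverts the chi-mean relation", {
  expect_equal(calibrate_sigma(0), 0)
  expect_equal(calibrate_sigma(2 * 1.3), 2 * calibrate_sigma(1.3))
  expect_error(calibrate_sigma(-1), "non-negative")

  # Monte-Carlo oracle: with sigma = calibrate_sigma(1), the mean
  # consecutive-sample distance should be 1 within 3 standard errors.
  withr::with_seed(101, {
    sigma <- calibrate_sigma(1.0)
    n <- 1e5
    acc <- matrix(rnorm(3 * (n + 1), 0, sigma), ncol = 3)
    d <- sqrt(rowSums(diff(acc)^2))
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 1.0), 3 * se)
  })
})

test_that("simulated trials are seed-deterministic and carry annotations", {
  model <- surface_model("C", 60, 4.44, 0.09)
  a <- simulate_trial(model, duration = 5, f = 50, seed = 7)
  b <- simulate_trial(model, duration = 5, f = 50, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_equal(nrow(a$samples), 5 * 50)
  expect_setequal(a$annotations$kind, c("road_surface", "speed"))
  expect_equal(a$annotations$value[a$annotations$kind == "road_surface"], "C")

  c1 <- simulate_trial(model, duration = 5, f = 50, seed = 8)
  expect_false(identical(a$samples, c1$samples))
})

test_that("a silent model yields an identically zero index series", {
  model <- surface_model("A", 30, 0, 0, impulse_rate = 0)
  tr <- simulate_trial(model, duration = 10, f = 50, seed = 1)
  expect_equal(displacement_series(tr)$values, rep(0, 9))
})

test_that("the standardized design has the study's 12 cells and 120 trials", {
  d <- default_trial_design()
  expect_equal(nrow(d), 12)
  expect_equal(sum(d$replicates), 120)
  expect_setequal(unique(d$surface), c("A", "B", "C", "D"))
  expect_equal(sum(d$surface == "A"), 5)
  expect_equal(sum(d$surface == "B"), 4)
  expect_false(any(d$surface == "C" & d$speed == 150))
  expect_false(any(d$surface == "D" & d$speed > 30))
  expect_true(all(d$between_trial_sd > 0))
})

test_that("the generator recovers target intensities within 5%", {
  for (target in c(0.3, 1.0, 3.6)) {
    model <- surface_model("C", 30, target, 0.05 * target)
    dbars <- vapply(1:100, function(i) {
      trial_mean(displacement_series(
        simulate_trial(model, duration = 10, f = 50, seed = 5000 + i)
      ))
    }, 0)
    expect_lt(abs(mean(dbars) - target) / target, 0.05)
  }
})

test_that("gravity offset does not affect the simulated index", {
  model <- surface_model("B", 90, 0.78, 0.05)
  a <- simulate_trial(model, duration = 5, f = 50, seed = 12,
                      gravity = c(0, 0, 1))
  b <- simulate_trial(model, duration = 5, f = 50, seed = 12,
                      gravity = c(0.3, -0.2, 9.81))
  expect_equal(displacement_series(a)$values, displacement_series(b)$values,
               tolerance = 1e-12)
})

test_that("simulate_design splits one seed stream by trial counter", {
  design <- default_trial_design()[c(1, 11), ]
  design$replicates <- 2L
  traces <- simulate_design(design, duration = 2, f = 50, seed = 40)
  expect_length(traces, 4)
  # trial 3 is reproducible in isolation from its counter-derived seed
  lone <- simulate_trial(design[2, ], duration = 2, f = 50, seed = 42)
  expect_identical(traces[[3]]$samples, lone$samples)
  trials <- summarize_trials(traces)
  expect_equal(nrow(trials), 4)
  expect_setequal(unique(trials$surface), c("A", "C"))
})

test_that("a single-segment delivery reproduces the equivalent trial", {
  model <- surface_model("C", 30, 3.6, 0.18)
  plan <- route_plan(cbind(model, tibble::tibble(
    duration_s = 10, start_lat = 52, start_lon = 9,
    end_lat = 52.01, end_lon = 9.01
  )))
  del <- simulate_delivery(plan, f = 50, seed = 33)
  tri <- simulate_trial(model, duration = 10, f = 50, seed = 33)
  expect_equal(del$samples$ax, tri$samples$ax)
  expect_equal(del$samples$az, tri$samples$az)
  # 1 Hz GNSS from start to end, linearly interpolated
  expect_equal(nrow(del$gnss), 11)
  expect_equal(del$gnss$lat[1], 52)
  expect_equal(del$gnss$lat[11], 52.01)
  expect_equal(del$gnss$lon[6], 9.005, tolerance = 1e-9)
})

test_that("multi-segment deliveries conserve duration and mark boundaries", {
  plan <- route_plan(tibble::tibble(
    surface = c("A", "C"), speed = c(120, 30),
    target_dbar = c(0.74, 3.6), between_trial_sd = c(0.05, 0.18),
    duration_s = c(20, 10),
    start_lat = c(52, 52.1), start_lon = c(9, 9.1),
    end_lat = c(52.1, 52.2), end_lon = c(9.1, 9.2)
  ))
  del <- simulate_delivery(plan, f = 50, seed = 3)
  expect_equal(nrow(del$samples), 30 * 50)
  expect_equal(nrow(del$gnss), 31)
  expect_true(all(del$annotations$time %in% c(0, 20)))
  expect_identical(simulate_delivery(plan, f = 50, seed = 3)$samples,
                   del$samples)
  expect_error(route_plan(tibble::tibble()), "missing column|no segments")
})

test_that("route YAML files load into valid plans", {
  path <- system.file("extdata", "demo_route.yaml", package = "roadvib")
  plan <- read_route_yaml(path)
  expect_s3_class(plan, "route_plan")
  expect_equal(nrow(plan), 3)
  expect_equal(plan$t_start, c(0, 120, 180))
  expect_equal(plan$surface, c("A", "C", "D"))
  expect_equal(plan$impulse_rate, c(0, 0, 6))
})
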