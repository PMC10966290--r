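test_that("baseline is the mean of the first readings", {
  expect_equal(estimate_baseline(rep(0.05, 20)), 0.05)
  expect_equal(estimate_baseline(c(0.04, 0.05, 0.06, 0.9, 0.9)), 0.05)
  expect_error(estimate_baseline(1:5, n_points = 0), "n_points")
  expect_error(estimate_baseline(1:5, n_points = 6), "n_points")
})

test_that("baseline of a noisy flat trace is close to truth", {
  # SE of the mean of 10 readings at SD 0.003 is ~0.001; 0.003 is ~3 SE
  withr::with_seed(21, {
    noisy <- 0.05 + rnorm(50, 0, 0.003)
    expect_lt(abs(estimate_baseline(noisy, n_points = 10) - 0.05), 0.003)
  })
})

test_that("lag time interpolates the threshold crossing linearly", {
  expect_equal(find_lag_time(c(0, 12), c(0.050, 0.070), baseline = 0.050), 6)
  expect_true(is.na(find_lag_time(seq(0, 120, 12), rep(0.05, 11), 0.05)))
})

test_that("maximum is the highest recorded value, earliest on ties", {
  tt <- seq(0, 108, 12)
  rising <- seq(0.05, 0.5, length.out = 10)
  expect_equal(find_max(tt, rising),
               list(max_abs = 0.5, time_of_max = 108))
  plateau <- c(0.1, 0.2, 0.4, 0.4, 0.4, 0.3, 0.2, 0.1, 0.1, 0.1)
  expect_equal(find_max(tt, plateau)$time_of_max, 24)
})

test_that("lysis times follow the fractional-resolution definition on a linear decay", {
  # rise to 0.45 then linear fall back to the 0.05 baseline over 600 s
  tt <- seq(0, 1200, 12)
  aa <- ifelse(tt < 300, 0.05 + (0.45 - 0.05) * tt / 300,
               pmax(0.45 - (0.45 - 0.05) * (tt - 300) / 600, 0.05))
  expect_equal(find_lysis_time(tt, aa, baseline = 0.05, fraction = 0.5), 300)
  expect_equal(find_lysis_time(tt, aa, baseline = 0.05, fraction = 1,
                               return_tolerance = 0), 600)
  expect_error(find_lysis_time(tt, aa, 0.05, fraction = 0), "fraction")
  expect_error(find_lysis_time(tt, aa, 0.05, fraction = 1.2), "fraction")
  # censored: trace ends at plateau
  half <- aa[tt <= 480]
  expect_true(is.na(find_lysis_time(tt[tt <= 480], half, 0.05, 1)))
})

test_that("lysis area is the trapezoidal integral above baseline", {
  tt <- seq(0, 1200, 12)
  aa <- ifelse(tt < 300, 0.05 + 0.40 * tt / 300,
               pmax(0.45 - 0.40 * (tt - 300) / 600, 0.05))
  la <- lysis_area(tt, aa, baseline = 0.05, return_tolerance = 0)
  expect_equal(la$area, 0.5 * 0.40 * 600, tolerance = 1e-10)
  expect_false(la$truncated)
  # a trace whose post-maximum segment sits at baseline integrates to zero
  flat <- rep(0.05, length(tt))
  expect_equal(lysis_area(tt, flat, 0.05, return_tolerance = 0)$area, 0)
})

test_that("extraction matches the dense-grid oracle on noiseless curves", {
  grid <- time_grid()
  for (p in random_curve_params(40, seed = 77)) {
    cv <- generate_curve(p, grid, noise_sd = 0)
    ex <- extract_parameters(cv)
    gt <- ground_truth_parameters(p)
    expect_equal(ex$flags, "")
    expect_lt(abs(ex$lag_time_s - gt$lag_time_s), grid$step)
    expect_lt(abs(ex$time_of_max_s - gt$time_of_max_s), grid$step)
    expect_lt(abs(ex$t50_lysis_s - gt$t50_lysis_s), grid$step)
    expect_lt(abs(ex$t100_lysis_s - gt$t100_lysis_s), grid$step)
    expect_lt(abs(ex$max_abs - gt$max_abs), 1e-3)
    expect_lt(abs(ex$baseline - gt$baseline), 1e-3)
    expect_lt(abs(ex$lysis_area / gt$lysis_area - 1), 0.01)
  }
})

test_that("flat and censored curves are flagged, not numeric", {
  flat <- tibble::tibble(time_s = seq(0, 600, 12), abs_340 = 0.05)
  ex <- extract_parameters(flat)
  expect_match(ex$flags, "no_clot")
  expect_true(is.na(ex$lag_time_s))
  expect_true(is.na(ex$lysis_area))

  # trace stops mid-plateau: lysis censored
  p <- curve_gen_params()
  short <- generate_curve(p, time_grid(duration = 2400), noise_sd = 0)
  exs <- extract_parameters(short)
  expect_match(exs$flags, "no_return_to_baseline")
  expect_match(exs$flags, "truncated")
  expect_true(is.na(exs$t100_lysis_s))
  expect_gt(exs$lysis_area, 0)

  expect_error(
    extract_parameters(tibble::tibble(time_s = 1:5, abs_340 = 1:5 / 10)),
    "at least 10")
})

test_that("extracted parameters keep their ordering invariants on random curves", {
  grid <- time_grid()
  for (p in random_curve_params(25, seed = 55)) {
    ex <- extract_parameters(generate_curve(p, grid, noise_sd = 0.003,
                                            seed = 991))
    if (ex$flags != "") next
    expect_lt(ex$lag_time_s, ex$time_of_max_s)
    expect_lte(ex$t50_lysis_s, ex$t100_lysis_s)
    expect_gte(ex$lysis_area, 0)
    expect_gte(ex$max_abs, ex$baseline + 0.01)
  }
})

test_that("extraction responds monotonically to amplitude and lysis timescale", {
  grid <- time_grid(duration = 10000)
  amps <- seq(0.1, 0.5, by = 0.1)
  maxes <- vapply(amps, function(a) {
    p <- curve_gen_params(amplitude = a)
    extract_parameters(generate_curve(p, grid, noise_sd = 0))$max_abs
  }, numeric(1))
  expect_true(all(diff(maxes) >= 0))

  tls <- c(150, 250, 350, 450)
  t50s <- vapply(tls, function(tl) {
    p <- curve_gen_params(lysis_timescale = tl)
    extract_parameters(generate_curve(p, grid, noise_sd = 0))$t50_lysis_s
  }, numeric(1))
  expect_true(all(diff(t50s) >= 0))
})

test_that("noise leaves extraction nearly unbiased for maximum and lag", {
  p <- curve_gen_params()
  grid <- time_grid()
  gt <- ground_truth_parameters(p)
  withr::with_seed(303, {
    sims <- t(replicate(500, {
      ex <- extract_parameters(generate_curve(p, grid, noise_sd = 0.003))
      c(ex$max_abs, ex$lag_time_s)
    }))
  })
  expect_lt(abs(mean(sims[, 1]) - gt$max_abs) / gt$max_abs, 0.02)
  expect_lt(abs(mean(sims[, 2]) - gt$lag_time_s), grid$step)
})

test_that("replicate averaging pools unflagged wells and reports warnings", {
  grid <- time_grid()
  p1 <- curve_gen_params(amplitude = 0.35)
  p2 <- curve_gen_params(amplitude = 0.39)
  curves <- dplyr::bind_rows(
    generate_curve(p1, grid, 0, sample_id = "A", well_id = "w1", replicate = 1),
    generate_curve(p2, grid, 0, sample_id = "A", well_id = "w2", replicate = 2)
  )
  avg <- average_replicates(extract_parameters(curves))
  expect_equal(nrow(avg), 1)
  expect_equal(avg$max_abs, (0.35 + 0.39) / 2 + 0.05, tolerance = 1e-3)
  expect_equal(avg$n_used, 2)

  # simple numeric check: duplicate maxima 0.40 and 0.44 average to 0.42
  params <- dplyr::bind_rows(
    extract_parameters(generate_curve(curve_gen_params(amplitude = 0.40 - 0.05),
                                      grid, 0, sample_id = "B")),
    extract_parameters(generate_curve(curve_gen_params(amplitude = 0.44 - 0.05),
                                      grid, 0, sample_id = "B"))
  )
  expect_equal(average_replicates(params)$max_abs, 0.42, tolerance = 1e-3)

  # one flagged, one clean: clean passes through with a warning
  flat <- generate_curve(curve_gen_params(amplitude = 0), grid, 0,
                         sample_id = "A", well_id = "w3", replicate = 3)
  mixed <- extract_parameters(dplyr::bind_rows(curves, flat))
  expect_warning(avg2 <- average_replicates(mixed), "flagged")
  expect_equal(avg2$n_used, 2)
  expect_match(avg2$warnings, "no_clot")

  # idempotence: identical replicates average to themselves
  solo <- extract_parameters(
    generate_curve(p1, grid, 0, sample_id = "C", well_id = "w1"))
  trip <- dplyr::bind_rows(solo, solo, solo)
  trip$replicate <- 1:3
  avg3 <- average_replicates(trip)
  expect_equal(avg3$max_abs, solo$max_abs)
  expect_equal(avg3$lysis_area, solo$lysis_area)

  # all replicates flagged: sample-level failure
  allflat <- extract_parameters(
    generate_curve(curve_gen_params(amplitude = 0), grid, 0,
                   sample_id = "D"))
  expect_warning(avg4 <- average_replicates(allflat), "all replicates")
  expect_true(is.na(avg4$max_abs))
  expect_match(avg4$flags, "no_clot")
})

test_that("times convert to minutes for reporting", {
  ex <- extract_parameters(generate_curve(curve_gen_params(), time_grid(),
                                          noise_sd = 0))
  mins <- parameters_in_minutes(ex)
  expect_equal(mins$lag_time_min, ex$lag_time_s / 60)
  expect_equal(mins$lysis_area, ex$lysis_area / 60)
  expect_false("lag_time_s" %in% names(mins))
})
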