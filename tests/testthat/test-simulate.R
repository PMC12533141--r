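test_that("static profiles collapse to cohort means at sd 0 and recompute BMI", {
  zero_sd <- cohort_params(height_cm = c(169.89, 0), weight_kg = c(63.41, 0),
                           bmi = c(21.71, 0), bodyfat_pct = c(16.89, 0),
                           rest_hr_bpm = c(59.74, 0),
                           rest_vo2_mlkgmin = c(3.69, 0), seed = 5L)
  p <- sample_static_profile(zero_sd, 1)
  expect_equal(p$rest_hr_bpm, 59.74)
  expect_equal(p$rest_vo2_mlkgmin, 3.69)
  expect_equal(p$height_cm, 169.89)
  # BMI is recomputed from height/weight, not the marginal table mean
  expect_equal(p$bmi, 63.41 / 1.6989^2, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(p$bmi, 21.71, tolerance = 1e-3)))
})

test_that("static profile draws are deterministic in (seed, draw_index)", {
  cp <- cohort_params(seed = 99L)
  a <- sample_static_profile(cp, 3)
  b <- sample_static_profile(cp, 3)
  expect_identical(a, b)
  expect_false(identical(unclass(a)[-1],
                         unclass(sample_static_profile(cp, 4))[-1]))
  expect_true(all(unlist(unclass(a)[-1]) > 0))
  expect_error(sample_static_profile(cp, 100), "draw_index")
})

test_that("speed profile follows the incremental protocol", {
  pr <- protocol_params()
  expect_equal(speed_at(0, pr), 3.0)
  expect_equal(speed_at(29.9, pr), 3.0)
  expect_equal(speed_at(30, pr), 3.5)
  expect_equal(speed_at(60, pr), 4.0)
  expect_equal(speed_at(1e5, pr), 15.0)  # capped
  expect_error(speed_at(-1, pr), ">= 0")
  expect_error(protocol_params(increment_kmh = 0))
  expect_error(protocol_params(hr_stop_frac = 1.2))
})

test_that("noise-free RR stream satisfies rr * hr = 60 and converges to resting HR", {
  p <- fixture_profile()
  rr <- simulate_rr_stream(p, noise = quiet_noise(),
                           dynamics = short_dynamics(), seed = 1L)
  expect_equal(rr$rr_s * rr$hr_bpm, rep(60, nrow(rr)), tolerance = 1e-12)
  # speed held near zero: the lag fixed point is resting HR
  idle <- protocol_params(start_kmh = 0, increment_kmh = 1e-9, step_s = 1e6)
  rr0 <- simulate_rr_stream(p, protocol = idle, noise = quiet_noise(),
                            duration_s = 600, seed = 1L)
  expect_equal(utils::tail(rr0$hr_bpm, 1), p$rest_hr_bpm, tolerance = 1e-6)
})

test_that("mean HR per protocol step is non-decreasing over the ramp", {
  p <- fixture_profile()
  for (seed in 1:20) {
    s <- simulate_session(p, noise = noise_params(outlier_rate = 0,
                                                  missing_rate = 0),
                          dynamics = short_dynamics(), seed = seed)
    step <- floor(s$rr$t / 30)
    full <- names(which(table(step) == 30))  # partial final steps excluded
    step_means <- tapply(s$rr$hr_bpm, step, mean)[full]
    expect_true(all(diff(step_means) > -0.3),
                label = sprintf("HR step means non-decreasing (seed %d)", seed))
  }
})

test_that("acceleration axes are cadence-locked sinusoids with growing energy", {
  # constant speed: one giant step
  pr <- protocol_params(start_kmh = 6, step_s = 1e6)
  acc <- simulate_acc_stream(pr, quiet_noise(), duration_s = 120, seed = 2L)
  f_expected <- 1.2 + 0.1 * 6  # 1.8 Hz, exactly a 0.1 Hz bin
  for (ax in c("x", "y", "z")) {
    w <- acc[[ax]][1:100]
    spec <- Mod(stats::fft(w - mean(w)))[2:50]
    freqs <- (1:49) / 10
    expect_equal(freqs[which.max(spec)], f_expected,
                 label = sprintf("axis %s spectral peak", ax))
  }
  # noiseless ramp: per-axis window energy strictly increases across steps
  ramp <- simulate_acc_stream(protocol_params(), quiet_noise(),
                              duration_s = 300, seed = 2L)
  centers <- seq(20, 290, by = 30)  # one window well inside each 30-s step
  for (ax in c("x", "y", "z")) {
    e <- vapply(centers, function(tc) {
      fft_total_energy(ramp[[ax]][ramp$t > tc - 10 & ramp$t <= tc])
    }, numeric(1))
    expect_true(all(diff(e) > 0), label = sprintf("axis %s energy ramp", ax))
  }
  # cadence beyond Nyquist is rejected
  expect_error(simulate_acc_stream(protocol_params(max_kmh = 40),
                                   dynamics = dynamics_params()),
               "Nyquist")
})

test_that("artifact injection matches the configured binomial rate", {
  counts <- vapply(1:10, function(seed) {
    acc <- simulate_acc_stream(protocol_params(),
                               noise_params(outlier_rate = 0.01,
                                            missing_rate = 0),
                               duration_s = 600, seed = seed)
    mean(lengths(attr(acc, "outlier_idx")))
  }, numeric(1))
  # 6001 samples/axis at 1%: expectation ~60, MC mean well inside [45, 75]
  expect_gt(mean(counts), 45)
  expect_lt(mean(counts), 75)
})

test_that("gas exchange anchors at resting VO2 and ramps RER monotonically", {
  p <- fixture_profile()
  gas <- simulate_gas_stream(p, noise = quiet_noise(),
                             dynamics = short_dynamics(), seed = 1L)
  expect_equal(gas$vo2_lmin[1], p$rest_vo2_mlkgmin * p$weight_kg / 1000,
               tolerance = 1e-12)
  rer <- gas$vco2_lmin / gas$vo2_lmin
  expect_true(all(diff(rer) > -1e-9))
})

test_that("sessions terminate by the protocol criteria", {
  for (seed in 1:5) {
    s <- simulate_session(fixture_profile(), dynamics = short_dynamics(),
                          seed = seed)
    hr_end <- utils::tail(s$truth$hr_clean, 1)
    rer_end <- utils::tail(s$gas$vco2_lmin / s$gas$vo2_lmin, 1)
    expect_true(hr_end >= 0.9 * s$truth$hrmax_bpm - 1e-9 || rer_end > 1.15,
                label = sprintf("termination criterion holds (seed %d)", seed))
    # all streams end within one sampling interval of the common end time
    expect_lte(s$truth$t_end_s - utils::tail(s$acc$t, 1), 0.1 + 1e-9)
    expect_lte(s$truth$t_end_s - utils::tail(s$rr$t, 1), 1 + 1e-9)
    expect_lte(s$truth$t_end_s - utils::tail(s$gas$t, 1), 10 + 1e-9)
    # sampling-rate contract
    expect_lte(abs(nrow(s$acc) - 10 * s$truth$t_end_s), 1)
    expect_lte(abs(nrow(s$rr) - s$truth$t_end_s), 1)
  }
})

test_that("lower fitness terminates sessions earlier", {
  p <- fixture_profile()
  ends <- vapply(1:5, function(seed) {
    unfit <- simulate_session(p, dynamics = dynamics_params(
      fitness_mean_kmh = 9, fitness_sd_kmh = 0), seed = seed)
    fit <- simulate_session(p, dynamics = dynamics_params(
      fitness_mean_kmh = 13, fitness_sd_kmh = 0), seed = seed)
    c(unfit$truth$t_end_s, fit$truth$t_end_s)
  }, numeric(2))
  expect_true(all(ends[1, ] < ends[2, ]))
})

test_that("too-short sessions are flagged invalid", {
  s <- simulate_session(fixture_profile(),
                        dynamics = dynamics_params(fitness_mean_kmh = 4,
                                                   fitness_sd_kmh = 0),
                        seed = 1L)
  expect_lt(s$truth$t_end_s, 100)
  expect_false(s$valid)
})

test_that("sessions serialize deterministically and round-trip", {
  s <- simulate_session(fixture_profile(), dynamics = short_dynamics(),
                        seed = 7L)
  d1 <- file.path(tempdir(), "ses_a"); d2 <- file.path(tempdir(), "ses_b")
  write_session(s, d1)
  write_session(simulate_session(fixture_profile(),
                                 dynamics = short_dynamics(), seed = 7L), d2)
  for (f in c("acc.csv", "rr.csv", "gas.csv", "speed.csv", "static.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = sprintf("%s byte-identical", f))
  }
  back <- read_session(d1)
  expect_equal(back$acc$x, s$acc$x, tolerance = 1e-12)
  expect_equal(back$profile$weight_kg, s$profile$weight_kg)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohorts have one session per subject with a 15/4 style split", {
  co <- simulate_cohort(cohort_params(n_subjects = 6, n_test = 2),
                        dynamics = short_dynamics())
  expect_length(co$sessions, 6)
  roles <- vapply(co$sessions, function(s) s$role, character(1))
  expect_equal(sum(roles == "train"), 4)
  expect_equal(sum(roles == "test"), 2)
  co2 <- simulate_cohort(cohort_params(n_subjects = 6, n_test = 2, seed = 2L),
                         dynamics = short_dynamics())
  expect_false(identical(co$sessions[[1]]$acc, co2$sessions[[1]]$acc))
  expect_error(cohort_params(n_subjects = 0))
})
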