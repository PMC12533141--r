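test_that("vector magnitude is the Euclidean norm", {
  expect_equal(vector_magnitude(0, 0, 0), 0)
  expect_equal(vector_magnitude(3, 4, 0), 5)
  expect_equal(vector_magnitude(1, 1, 1), sqrt(3))
  expect_error(vector_magnitude(NA, 1, 1), "finite")
})

test_that("FFT total energy satisfies Parseval and the sinusoid closed form", {
  expect_equal(fft_total_energy(rep(2.7, 100)), 0)
  t <- seq(0, 9.9, by = 0.1)
  A <- 0.7
  x <- A * sin(2 * pi * 0.3 * t)  # bin-centered: 3 cycles over 100 samples
  expect_equal(fft_total_energy(x), A^2 * 100 / 2, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:20) {
    w <- rnorm(100, sd = runif(1, 0.1, 2))
    expect_equal(fft_total_energy(w), sum((w - mean(w))^2),
                 tolerance = 1e-9)   # independent time-domain oracle
  }
  expect_error(fft_total_energy(c(1, NA, 3)), "populated")
})

test_that("mean amplitude matches closed forms", {
  expect_equal(mean_amplitude(rep(5, 50)), 0)
  expect_equal(mean_amplitude(rep(c(2, -2), 50)), 2)
  t <- seq(0, 9.9, by = 0.1)
  expect_equal(mean_amplitude(1.3 * sin(2 * pi * 0.3 * t)), 2 * 1.3 / pi,
               tolerance = 1e-2)
})

test_that("RR time-domain features are plain window means", {
  f <- rr_window_features(rep(1, 10))
  expect_equal(f[["R_Interval_Sec"]], 1.0)
  expect_equal(f[["HeartRate"]], 60)
  expect_equal(rr_window_features(rep(c(0.8, 1.0), 5))[["R_Interval_Sec"]], 0.9)
  expect_error(rr_window_features(c(0.8, -0.1, 1)), "positive")
})

test_that("PSD band features localize tones and partition total power", {
  # constant window: flat zero spectrum
  f0 <- psd_band_features(rep(0.8, 10))
  expect_true(all(f0[c("R_Interval_TotalPower", "ULFPower", "VLFPower",
                       "LFPower", "HFPower")] == 0))
  expect_equal(f0[["R_Interval_PeakFrequency"]], 0)
  expect_equal(f0[["LF_HFRatio"]], 0)  # finite sentinel
  # extended validation window with an exactly representable 0.25 Hz tone
  t <- 0:19
  fh <- psd_band_features(0.8 + 0.05 * sin(2 * pi * 0.25 * t))
  expect_equal(fh[["R_Interval_PeakFrequency"]], 0.25)
  expect_gt(fh[["HFPower"]], 0.9 * fh[["R_Interval_TotalPower"]])
  # LF tone at 0.1 Hz on the native 10-sample window
  fl <- psd_band_features(0.9 + 0.04 * sin(2 * pi * 0.1 * (0:9)))
  expect_gt(fl[["LFPower"]], 0.9 * fl[["R_Interval_TotalPower"]])
  expect_gt(fl[["LF_HFRatio"]], 1)
  # bands partition the total for arbitrary windows
  set.seed(6)
  for (i in 1:20) {
    f <- psd_band_features(runif(10, 0.5, 1.2))
    bands <- sum(f[c("ULFPower", "VLFPower", "LFPower", "HFPower")])
    expect_equal(bands, f[["R_Interval_TotalPower"]], tolerance = 1e-9)
  }
})

test_that("the Weir equation maps gas exchange to kcal/min", {
  expect_equal(weir_ee(0, 0), 0)
  expect_equal(weir_ee(1.0, 0.8), 4.8258)
  expect_gt(weir_ee(1.1, 0.8), weir_ee(1.0, 0.8))
  expect_gt(weir_ee(1.0, 0.9), weir_ee(1.0, 0.8))
  expect_error(weir_ee(-0.1, 0.5), ">= 0")
})

test_that("featurization yields one 22-feature window per covered gas sample", {
  s <- simulate_session(fixture_profile(), noise = quiet_noise(),
                        dynamics = short_dynamics(), seed = 4L)
  w <- featurize_session(s)
  # gas samples every 10 s from 0 to t_end; the t = 0 sample has no history
  expect_equal(nrow(w), s$truth$t_end_s / 10)
  expect_true(all(dynamic_feature_names() %in% names(w)))
  expect_length(dynamic_feature_names(), 22)
  expect_length(acc_feature_names(), 12)
  expect_length(ecg_feature_names(), 10)
  expect_equal(w$speed_kmh, speed_at(w$t, s$protocol))
  # monotone simulator response across windows
  expect_true(all(diff(w$HeartRate) > -1e-6))
  expect_true(all(diff(w$R_Interval_Sec) < 1e-6))
  expect_true(all(diff(w$AccX_TotalEnergy) > -1e-6))
  step_means <- tapply(w$VM_TotalEnergy, floor((w$t - 0.01) / 30), mean)
  expect_true(all(diff(step_means) > 0))
})

test_that("fixed-speed noiseless windows are identical up to leakage tolerance", {
  pr <- protocol_params(start_kmh = 6, step_s = 1e6)
  p <- fixture_profile()
  acc <- simulate_acc_stream(pr, quiet_noise(), duration_s = 200, seed = 1L)
  s <- simulate_session(p, noise = quiet_noise(), dynamics = short_dynamics(),
                        seed = 1L)
  s$acc <- acc
  s$protocol <- pr
  s$gas <- s$gas[s$gas$t <= 200, ]
  s$rr <- s$rr[s$rr$t <= 200, ]
  w <- featurize_session(s)
  for (f in c("AccX_TotalEnergy", "VM_MeanAmplitude")) {
    expect_lt(stats::sd(w[[f]]) / mean(w[[f]]), 0.02, label = f)
  }
})

test_that("sequence building slides over contiguous windows", {
  s <- simulate_session(fixture_profile(), noise = quiet_noise(),
                        dynamics = short_dynamics(), seed = 4L)
  w <- featurize_session(s)
  sq <- build_sequences(w[1:12, ], s$profile)
  expect_equal(dim(sq$dynamic), c(3, 10, 22))
  expect_equal(ncol(sq$static), 6)
  sq1 <- build_sequences(w[1:10, ], s$profile)
  expect_length(sq1$target, 1)
  expect_equal(sq1$target, w$ee_kcal_min[10])
  expect_equal(sq1$speed_kmh, w$speed_kmh[10])
  expect_warning(sq0 <- build_sequences(w[1:9, ], s$profile), "fewer windows")
  expect_length(sq0$target, 0)
  gap <- w[c(1:5, 7:12), ]
  class(gap) <- class(w)
  expect_error(build_sequences(gap, s$profile), "contiguous")
})

test_that("the normalizer is exact, invertible and leakage-free", {
  sq <- make_sequences(60, n_subjects = 3L, seed = 2L)
  nz <- fit_normalizer(sq)
  z <- apply_normalizer(sq, nz)
  for (j in seq_along(sq$feature_names)) {
    expect_equal(mean(z$dynamic[, , j]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(as.vector(z$dynamic[, , j])), 1, tolerance = 1e-9)
  }
  expect_true(all(z$target >= 0 & z$target <= 1))
  back <- invert_normalizer(z, nz)
  expect_equal(back$dynamic, sq$dynamic, tolerance = 1e-9)
  expect_equal(back$static, sq$static, tolerance = 1e-9)
  expect_equal(back$target, sq$target, tolerance = 1e-9)
  expect_equal(denormalize_target(z$target, nz), sq$target, tolerance = 1e-9)
  # normalization statistics are a pure function of the training set
  other <- make_sequences(60, n_subjects = 3L, seed = 99L)
  expect_identical(fit_normalizer(sq), nz)
  expect_false(identical(fit_normalizer(other), nz))
  # zero-variance feature handled with a warning
  sq$dynamic[, , 1] <- 1
  expect_warning(nz0 <- fit_normalizer(sq), "zero-variance")
  expect_equal(unname(nz0$dyn_sd[1]), 1)
})
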