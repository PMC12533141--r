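test_that("attributions of a linear model are exact Shapley values", {
  fn <- c("AccX", "VM", "HeartRate", "LFPower")
  sq <- make_sequences(80, T = 5L, feature_names = fn, seed = 41L)
  w <- c(AccX = 1.5, VM = -0.8, HeartRate = 0.6, LFPower = 0)
  sq$target <- as.vector(sq$dynamic[, 5, ] %*% w) + 0.3
  m <- fit_ar(sq, p = 5L)
  bg <- subset_sequences(sq, 1:40)
  ex <- subset_sequences(sq, 41:60)
  rep <- shap_values(m, ex, bg)
  # attribution of feature j = sum_t w_jt * (x_jt - mean background x_jt)
  for (f in fn) {
    manual <- vapply(seq_len(20), function(i) {
      sum(vapply(1:5, function(t) {
        cf <- m$coef[[paste0(f, "_lag", 5 - t + 1)]]
        cf * (ex$dynamic[i, t, f] - mean(bg$dynamic[, t, f]))
      }, numeric(1)))
    }, numeric(1))
    expect_equal(unname(rep$attributions[, f]), manual, tolerance = 1e-9,
                 label = f)
  }
  # a feature the model is constant in gets zero attribution (within OLS noise)
  expect_lt(max(abs(rep$attributions[, "LFPower"])), 1e-6)
  # static features are not in the AR model: exactly zero
  expect_true(all(rep$attributions[, static_feature_names()] == 0))
  # completeness is exact for the linear path
  expect_equal(rowSums(rep$attributions), rep$pred - rep$base,
               tolerance = 1e-9)
  # a single-feature-dominated model ranks that feature first
  gs <- global_summary(rep, k = 3)
  expect_equal(gs$ranking$feature[1], "AccX")
})

test_that("duplicated linear features share their attribution", {
  fn <- c("AccX", "AccY")
  sq <- make_sequences(60, T = 3L, feature_names = fn, seed = 42L)
  sq$dynamic[, , "AccY"] <- sq$dynamic[, , "AccX"]
  sq$target <- 2 * sq$dynamic[, 3, "AccX"]
  expect_warning(m <- fit_ar(sq, p = 3L), "rank-deficient")
  bg <- subset_sequences(sq, 1:30)
  ex <- subset_sequences(sq, 31:40)
  rep <- shap_values(m, ex, bg)
  # the ridge-symmetrized solution splits the weight between the copies
  expect_equal(rep$attributions[, "AccX"], rep$attributions[, "AccY"],
               tolerance = 1e-6)
  single <- make_sequences(60, T = 3L, feature_names = "AccX", seed = 42L)
  single$dynamic[, , 1] <- sq$dynamic[, , "AccX"]
  single$target <- sq$target
  ms <- fit_ar(single, p = 3L)
  reps <- shap_values(ms, subset_sequences(single, 31:40),
                      subset_sequences(single, 1:30))
  expect_equal(rep$attributions[, "AccX"] + rep$attributions[, "AccY"],
               unname(reps$attributions[, "AccX"]), tolerance = 1e-6)
})

test_that("expected-gradients attributions satisfy the axioms on a fusion model", {
  sq <- make_sequences(60, n_subjects = 2L, seed = 43L)
  sq$target <- 0.6 * sq$dynamic[, 10, "HeartRate"] -
    0.4 * sq$dynamic[, 10, "VM_TotalEnergy"] + 0.3 * sq$static[, "bmi"]
  m <- train_model(build_fusion_model(tiny_config(feature_set = "ecg")), sq,
                   epochs = 60L)
  bg <- subset_sequences(sq, 1:30)
  ex <- subset_sequences(sq, 31:50)
  rep <- shap_values(m, ex, bg, n_background = 20, n_steps = 50)
  # completeness within tolerance for every explained sample (enforced
  # internally; recorded here)
  expect_lt(rep$max_completeness_err,
            0.02 * max(abs(rep$pred - rep$base)) + 1e-6)
  # null player: acceleration features are outside the model's feature set
  expect_true(all(rep$attributions[, acc_feature_names()] == 0))
  expect_false(all(rep$attributions[, ecg_feature_names()] == 0))
  # explaining a sample against itself as the only background gives zeros
  self <- subset_sequences(sq, 5)
  rep_self <- shap_values(m, self, self, n_background = 1, n_steps = 10)
  expect_equal(max(abs(rep_self$attributions)), 0)
  # attributions are sample-order invariant
  rep_perm <- shap_values(m, subset_sequences(sq, c(40, 31)), bg,
                          n_background = 20, n_steps = 50)
  expect_equal(rep_perm$attributions[2, ], rep$attributions[1, ],
               tolerance = 1e-12)
})

test_that("local scatter reports Pearson correlations against the formula", {
  fn <- c("AccX", "VM")
  sq <- make_sequences(500, T = 2L, feature_names = fn, seed = 44L)
  sq$target <- as.vector(sq$dynamic[, 2, ] %*% c(2, 0.5))
  m <- fit_ar(sq, p = 2L)
  rep <- shap_values(m, sq, sq)
  ls <- local_scatter(rep, "AccX")
  # attribution is linear in the value with positive slope
  expect_gt(ls$pearson_r, 0.7)
  # agreement with a direct covariance/sd computation
  manual <- sum((ls$values - mean(ls$values)) *
                  (ls$attributions - mean(ls$attributions))) /
    ((length(ls$values) - 1) * stats::sd(ls$values) * stats::sd(ls$attributions))
  expect_equal(ls$pearson_r, manual, tolerance = 1e-12)
  expect_s3_class(ls$intensity, "factor")
  # shuffled attributions are uncorrelated at n = 500
  rep_shuf <- rep
  rep_shuf$attributions[, "AccX"] <-
    sample(rep_shuf$attributions[, "AccX"])
  expect_lt(abs(local_scatter(rep_shuf, "AccX")$pearson_r), 0.2)
  expect_error(local_scatter(rep, "NotAFeature"), "unknown feature")
})

test_that("intensity bins follow the protocol speed ranges", {
  expect_equal(as.character(intensity_bin(c(3, 5, 7.4))),
               rep("low", 3))
  expect_equal(as.character(intensity_bin(c(7.5, 10.9))),
               rep("medium", 2))
  expect_equal(as.character(intensity_bin(c(11, 14, 15))),
               rep("high", 3))
  expect_error(intensity_bin(2.9), "range")
  expect_error(intensity_bin(15.1), "range")
})

test_that("group contribution curves detect designed dominance", {
  # model that only uses ECG features: ECG dominates every bin, so the
  # crossover is the first occupied bin
  sq <- make_sequences(300, n_subjects = 2L, seed = 45L)
  sq$speed_kmh <- runif(300, 3, 14.9)
  sq$target <- 0.9 * sq$dynamic[, 10, "HeartRate"]
  m <- train_model(build_fusion_model(tiny_config(feature_set = "ecg")), sq,
                   epochs = 60L)
  rep <- shap_values(m, sq, subset_sequences(sq, 1:50),
                     n_background = 10, n_steps = 50)
  cv <- group_contribution_curve(rep)
  occupied <- cv$curve$bin_lo[cv$curve$n >= 5]
  expect_equal(cv$crossover_kmh, occupied[1])
  # curves are invariant to sample order
  perm <- sample(300)
  rep_p <- rep
  rep_p$attributions <- rep$attributions[perm, ]
  rep_p$speed_kmh <- rep$speed_kmh[perm]
  rep_p$feature_values <- rep$feature_values[perm, ]
  cv_p <- group_contribution_curve(rep_p)
  expect_equal(cv_p$curve$Acc_raw, cv$curve$Acc_raw)
  expect_equal(cv_p$crossover_kmh, cv$crossover_kmh)
  # standardized values live in [0, 1]
  expect_true(all(cv$curve$ECG_std >= 0 & cv$curve$ECG_std <= 1, na.rm = TRUE))
})
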