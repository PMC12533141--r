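test_that("error metrics match hand-computed values", {
  y <- c(1, 2, 3); yhat <- c(2, 2, 2)
  expect_equal(rmse(y, yhat), sqrt(2 / 3))
  expect_equal(mae(y, yhat), 2 / 3)
  expect_equal(r2(y, yhat), 0)          # the null predictor scores exactly 0
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_equal(r2(y, y), 1)
  expect_error(r2(c(2, 2, 2), c(1, 2, 3)), "zero-variance")
  expect_error(rmse(1, 1), "at least")
  set.seed(21)
  for (i in 1:20) {
    yy <- rnorm(50); pp <- rnorm(50)
    expect_gte(rmse(yy, pp), mae(yy, pp))  # power-mean inequality
  }
})

test_that("Bland-Altman agreement matches hand computation", {
  y <- c(1, 2, 3)
  perfect <- bland_altman(y, y)
  expect_equal(perfect$bias, 0)
  expect_equal(c(perfect$loa_lower, perfect$loa_upper), c(0, 0))
  d <- c(0.1, -0.1, 0.3)
  ba <- bland_altman(rep(0, 3), d)  # differences are predicted - true
  expect_equal(ba$bias, 0.1)
  expect_equal(ba$sd, 0.2)
  expect_equal(ba$loa_lower, 0.1 - 1.96 * 0.2)
  expect_equal(ba$loa_upper, 0.1 + 1.96 * 0.2)
  expect_equal(ba$n, 3)
  # translation equivariance
  set.seed(22)
  yy <- rnorm(30); pp <- yy + rnorm(30, 0, 0.2)
  b0 <- bland_altman(yy, pp)
  b1 <- bland_altman(yy, pp + 0.7)
  expect_equal(b1$bias, b0$bias + 0.7)
  expect_equal(b1$loa_lower, b0$loa_lower + 0.7)
  expect_equal(b1$loa_upper, b0$loa_upper + 0.7)
})

test_that("LOSO folds cover every subject exactly once", {
  ids <- sprintf("S%02d", 1:15)
  folds <- loso_splits(ids)
  expect_length(folds, 15)
  vals <- vapply(folds, function(f) f$val, character(1))
  expect_setequal(vals, ids)
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val), ids)
  }
  two <- loso_splits(c("a", "b"))
  expect_length(two, 2)
  expect_length(two[[1]]$train, 1)
  expect_error(loso_splits(c("a", "a")), "duplicate")
  expect_error(loso_splits("a"), "at least 2")
})

test_that("the LOSO experiment refits per fold and aggregates correctly", {
  sq <- make_sequences(160, n_subjects = 4L, seed = 23L)
  # learnable target with a per-subject offset
  offs <- c(T01 = 0.5, T02 = -0.2, T03 = 0.1, T04 = -0.4)
  sq$target <- 2 + 0.8 * sq$dynamic[, 10, "HeartRate"] + offs[sq$subject_id] +
    rnorm(160, 0, 0.05)
  rep <- run_loso_experiment(sq, arch = "ar", feature_set = "acc_ecg",
                             config = model_config(arch = "ar"))
  expect_s3_class(rep, "ee_eval_report")
  expect_equal(nrow(rep$per_fold), 4)
  expect_setequal(rep$per_fold$val_subject, unique(sq$subject_id))
  # per-fold n equals that subject's sample count
  for (i in seq_len(4)) {
    expect_equal(rep$per_fold$n_val[i],
                 sum(sq$subject_id == rep$per_fold$val_subject[i]))
  }
  # reported mean +/- SD equals recomputation from the per-fold table
  expect_equal(rep$summary$mean[rep$summary$metric == "r2"],
               mean(rep$per_fold$r2))
  expect_equal(rep$summary$sd[rep$summary$metric == "rmse"],
               stats::sd(rep$per_fold$rmse))
})

test_that("the holdout experiment enforces subject separation and set semantics", {
  sq <- make_sequences(600, n_subjects = 5L, seed = 24L)
  sq$target <- 1 + 0.5 * sq$dynamic[, 10, "VM"] + rnorm(600, 0, 0.05)
  tr <- subset_sequences(sq, sq$subject_id %in% c("T01", "T02", "T03"))
  te <- subset_sequences(sq, sq$subject_id %in% c("T04", "T05"))
  expect_error(run_holdout_experiment(tr, tr, "ar", "acc_ecg",
                                      model_config(arch = "ar")), "overlap")
  rep <- run_holdout_experiment(tr, te, "ar", "acc_ecg",
                                model_config(arch = "ar"))
  expect_equal(rep$bland_altman$n, length(te$target))
  expect_equal(nrow(rep$per_subject), 2)
  # reordering training samples leaves a least-squares fit unchanged
  perm <- sample(length(tr$target))
  rep2 <- run_holdout_experiment(subset_sequences(tr, perm), te, "ar",
                                 "acc_ecg", model_config(arch = "ar"))
  expect_equal(rep2$metrics$r2, rep$metrics$r2, tolerance = 1e-6)
  expect_gt(rep$metrics$r2, 0.9)  # separable synthetic data
})

test_that("a fusion model reaches high accuracy on an easy noiseless cohort", {
  # fully separable conditions: homogeneous traits, no sensor noise
  cp <- cohort_params(n_subjects = 4, n_test = 0,
                      height_cm = c(169.89, 0), weight_kg = c(63.41, 0),
                      bmi = c(21.71, 0), bodyfat_pct = c(16.89, 0),
                      rest_hr_bpm = c(59.74, 0),
                      rest_vo2_mlkgmin = c(3.69, 0),
                      age_range = c(21, 21), seed = 31L)
  cohort <- simulate_cohort(cp, noise = quiet_noise(),
                            dynamics = dynamics_params(fitness_sd_kmh = 0,
                                                       subj_amp_sd = 0))
  seqs <- featurize_cohort(cohort)
  rep <- run_loso_experiment(seqs, "cnn_lstm", "acc_ecg",
                             model_config(seed = 31L), epochs = 120L)
  expect_gt(rep$summary$mean[rep$summary$metric == "r2"], 0.9)
})
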