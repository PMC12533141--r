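test_that("the AR baseline recovers a noiseless linear mapping exactly", {
  sq <- make_sequences(120, T = 10L, feature_names = c("AccX", "AccY", "VM"),
                       seed = 3L)
  w_true <- c(0.5, -1.2, 2.0)
  sq$target <- as.vector(sq$dynamic[, 10, ] %*% w_true) + 0.25
  m <- fit_ar(sq, p = 10L)
  pred <- predict(m, sq)
  expect_lt(rmse(sq$target, pred$pred), 1e-6)
  # coefficients: final-lag weights recovered, all other lags ~0
  expect_equal(unname(m$coef[["(Intercept)"]]), 0.25, tolerance = 1e-6)
  expect_equal(unname(m$coef[c("AccX_lag1", "AccY_lag1", "VM_lag1")]),
               w_true, tolerance = 1e-6)
  others <- setdiff(names(m$coef),
                    c("(Intercept)", "AccX_lag1", "AccY_lag1", "VM_lag1"))
  expect_lt(max(abs(m$coef[others])), 1e-6)
  # prediction equals the design-matrix product by definition
  X <- cbind(1, matrix(sq$dynamic, 120, 30))
  expect_equal(pred$pred, as.vector(X %*% unname(m$coef)), tolerance = 1e-9)
})

test_that("the AR baseline degrades gracefully", {
  sq <- make_sequences(80, T = 5L, feature_names = c("AccX", "AccY"), seed = 4L)
  sq$target <- rep(3, 80)
  m <- fit_ar(sq, p = 5L)
  expect_equal(unname(m$coef[["(Intercept)"]]), 3, tolerance = 1e-6)
  expect_lt(max(abs(m$coef[-1])), 1e-6)
  expect_error(fit_ar(sq, p = 10L), "sequence length")
  # duplicate column makes the design rank-deficient -> ridge fallback
  sq$dynamic[, , 2] <- sq$dynamic[, , 1]
  sq$target <- rnorm(80)
  expect_warning(fit_ar(sq, p = 5L), "rank-deficient")
})

test_that("fusion model structure follows the configuration", {
  m64 <- build_fusion_model(tiny_config(hidden_units = 64L))
  m128 <- build_fusion_model(tiny_config(hidden_units = 128L))
  expect_gt(n_model_params(m128), n_model_params(m64))
  expect_error(build_fusion_model(model_config(arch = "transformer")),
               "arg")
  # scalar output for any batch size, both architectures
  for (arch in c("lstm", "cnn_lstm")) {
    m <- build_fusion_model(tiny_config(arch = arch))
    for (n in c(1L, 7L)) {
      sq <- make_sequences(n, seed = n)
      expect_length(predict(m, sq)$pred, n)
    }
  }
  # identical seeds give identical initializations
  expect_identical(build_fusion_model(tiny_config())$params,
                   build_fusion_model(tiny_config())$params)
})

test_that("analytic gradients match finite differences", {
  # tiny network so central differences are affordable and well-conditioned
  cfg <- model_config(arch = "cnn_lstm", hidden_units = 4L,
                      conv_channels = c(3L, 4L), conv_kernel = 2L,
                      static_width = 3L, fusion_width = 3L, seed = 8L)
  for (arch in c("lstm", "cnn_lstm")) {
    cfg$arch <- arch
    n <- 5L; T <- 6L; d <- 3L
    set.seed(10)
    X <- array(rnorm(n * T * d), c(n, T, d))
    S <- matrix(rnorm(n * 6), n, 6)
    y <- rnorm(n)
    params <- eefusion:::with_seed(8L, eefusion:::nn_init(arch, d, 6L, cfg))
    loss_of <- function(p) {
      yhat <- eefusion:::nn_forward(p, X, S, arch, cfg)$yhat
      mean((yhat - y)^2)
    }
    fw <- eefusion:::nn_forward(params, X, S, arch, cfg)
    bw <- eefusion:::nn_backward(params, fw$cache, 2 * (fw$yhat - y) / n,
                                 arch, cfg, need_input_grad = TRUE)
    eps <- 1e-5
    for (nm in names(params)) {
      idx <- seq_len(min(5L, length(params[[nm]])))
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
        expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("%s grad %s[%d]", arch, nm, i))
      }
    }
    # input gradients (used by the attribution engine)
    for (probe in list(c(2L, 3L, 1L), c(4L, 1L, 2L))) {
      Xp <- X; Xp[probe[1], probe[2], probe[3]] <- X[probe[1], probe[2], probe[3]] + eps
      Xm <- X; Xm[probe[1], probe[2], probe[3]] <- X[probe[1], probe[2], probe[3]] - eps
      num <- (mean((eefusion:::nn_forward(params, Xp, S, arch, cfg)$yhat - y)^2) -
              mean((eefusion:::nn_forward(params, Xm, S, arch, cfg)$yhat - y)^2)) / (2 * eps)
      expect_equal(bw$dX[probe[1], probe[2], probe[3]], num, tolerance = 1e-4,
                   label = sprintf("%s input grad", arch))
    }
  }
})

test_that("training is deterministic, descends, and can overfit a linear target", {
  sq <- make_sequences(32, seed = 12L)
  sq$target <- 0.4 * sq$dynamic[, 10, "HeartRate"] -
    0.3 * sq$dynamic[, 10, "VM"] + 0.2 * sq$static[, "weight_kg"]
  cfg <- tiny_config(hidden_units = 32L, conv_channels = c(8L, 16L))
  m1 <- train_model(build_fusion_model(cfg), sq, epochs = 2000L)
  m2 <- train_model(build_fusion_model(cfg), sq, epochs = 2000L)
  expect_identical(m1$params, m2$params)
  expect_length(m1$history$train, 2000L)
  expect_lt(utils::tail(m1$history$train, 1), 1e-3)   # capacity/overfit probe
  # descent across seeds
  for (seed in 1:5) {
    cfg$seed <- seed
    m <- train_model(build_fusion_model(cfg), sq, epochs = 30L)
    expect_lt(utils::tail(m$history$train, 1), m$history$train[1])
  }
})

test_that("predictions are pure, order-invariant and feature-set ablated", {
  sq <- make_sequences(40, n_subjects = 2L, seed = 13L)
  m <- train_model(build_fusion_model(tiny_config(feature_set = "acc")), sq,
                   epochs = 10L)
  p1 <- predict(m, sq)$pred
  expect_true(all(is.finite(p1)))
  perm <- sample(40)
  expect_equal(predict(m, subset_sequences(sq, perm))$pred, p1[perm],
               tolerance = 1e-12)
  # acc-only model is exactly invariant to the ECG columns
  sq2 <- sq
  sq2$dynamic[, , ecg_feature_names()] <- 0
  expect_identical(predict(m, sq2)$pred, p1)
  # zeroing the static branch weights removes static sensitivity
  m0 <- m
  m0$params$static_W[] <- 0
  m0$params$static_b[] <- 0
  sq3 <- sq
  sq3$static <- sq3$static + 5
  expect_equal(predict(m0, sq3)$pred, predict(m0, sq)$pred, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(predict(m, sq3)$pred, p1)))
})

test_that("disjoint train/validation subject sets are enforced", {
  sq <- make_sequences(40, n_subjects = 4L, seed = 14L)
  tr <- subset_sequences(sq, sq$subject_id %in% c("T01", "T02"))
  va <- subset_sequences(sq, sq$subject_id %in% c("T02", "T03"))
  m <- build_fusion_model(tiny_config())
  expect_error(train_model(m, tr, va), "disjoint")
  va_ok <- subset_sequences(sq, sq$subject_id == "T03")
  mt <- train_model(m, tr, va_ok, epochs = 5L)
  expect_length(mt$history$val, 5L)
})

test_that("model checkpoints round-trip through JSON", {
  sq <- make_sequences(30, seed = 15L)
  m <- train_model(build_fusion_model(tiny_config()), sq, epochs = 5L)
  m$normalizer <- fit_normalizer(sq)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(predict(back, sq)$pred, predict(m, sq)$pred, tolerance = 1e-12)
  expect_equal(back$normalizer$target_min, m$normalizer$target_min)
  expect_equal(back$normalizer$dyn_mean, m$normalizer$dyn_mean)
  expect_identical(names(back$normalizer$dyn_sd), sq$feature_names)
  ar <- fit_ar(sq, p = 10L)
  save_model(ar, path)
  ar2 <- load_model(path)
  expect_equal(predict(ar2, sq)$pred, predict(ar, sq)$pred, tolerance = 1e-12)
  unlink(path)
})
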