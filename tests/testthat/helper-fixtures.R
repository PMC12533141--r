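# Shared fixtures: everything is generated in code at test time.

# A fixed mid-cohort subject used across tests.
fixture_profile <- function(seed = 11L) {
  sample_static_profile(cohort_params(seed = seed), 1)
}

# Noise settings that turn the generator deterministic (no jitter, no
# injected artifacts).
quiet_noise <- function() {
  noise_params(acc_sd_g = 0, rr_jitter_sd_s = 0, outlier_rate = 0,
               missing_rate = 0)
}

# Low-fitness dynamics give short (~250-300 s) sessions for fast tests.
short_dynamics <- function(...) {
  dynamics_params(fitness_mean_kmh = 8, fitness_sd_kmh = 0.4, ...)
}

# Direct O(n^2) LOF reference: full distance matrix, no shortcuts.
# Independent of the package implementation.
brute_lof <- function(x, k) {
  n <- length(x)
  P <- cbind(seq_len(n), x)
  for (j in 1:2) {
    s <- stats::sd(P[, j])
    P[, j] <- if (s > 0) (P[, j] - mean(P[, j])) / s else P[, j] - mean(P[, j])
  }
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  kd <- apply(D, 1, function(d) sort(d)[k])
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= kd[i]))
  lrd <- vapply(seq_len(n), function(i) {
    r <- pmax(kd[nb[[i]]], D[i, nb[[i]]])
    m <- mean(r)
    if (m > 0) 1 / m else 1e12
  }, numeric(1))
  vapply(seq_len(n), function(i) mean(lrd[nb[[i]]]) / lrd[i], numeric(1))
}

# Synthetic sequence container with arbitrary dimensions, for model and
# attribution tests that do not need the full simulator.
make_sequences <- function(n, T = 10L, feature_names = dynamic_feature_names(),
                           n_subjects = 1L, seed = 1L) {
  d <- length(feature_names)
  set.seed(seed)
  dyn <- array(stats::rnorm(n * T * d), dim = c(n, T, d),
               dimnames = list(NULL, NULL, feature_names))
  st <- matrix(stats::rnorm(n * 6), n, 6,
               dimnames = list(NULL, static_feature_names()))
  subj <- sort(rep_len(sprintf("T%02d", seq_len(n_subjects)), n))
  structure(list(dynamic = dyn, static = st, target = stats::rnorm(n),
                 subject_id = subj,
                 speed_kmh = stats::runif(n, 3, 15),
                 end_time = seq_len(n) * 10,
                 feature_names = feature_names),
            class = "ee_sequences")
}

# One full structure-recovery run: simulate a default 19-subject cohort
# (artifact-free so featurization is direct), train the fused CNN+LSTM,
# its acceleration-only ablation and the AR baseline on the 15 training
# subjects, score the 4 held-out subjects, and detect the Acc/ECG
# contribution crossover of the fused model.
recovery_run <- function(seed, epochs = 100L) {
  cohort <- simulate_cohort(cohort_params(seed = seed),
                            noise = noise_params(outlier_rate = 0,
                                                 missing_rate = 0))
  seqs <- featurize_cohort(cohort)
  tr <- subset_sequences(seqs, seqs$role == "train")
  te <- subset_sequences(seqs, seqs$role == "test")
  cfg <- model_config(seed = seed)
  h_fused <- run_holdout_experiment(tr, te, "cnn_lstm", "acc_ecg", cfg,
                                    epochs = epochs)
  h_acc <- run_holdout_experiment(tr, te, "cnn_lstm", "acc", cfg,
                                  epochs = epochs)
  h_ar <- run_holdout_experiment(tr, te, "ar", "acc_ecg", cfg)
  nz <- h_fused$model$normalizer
  pool <- combine_sequences(list(tr, te))
  thin <- seq(1, length(pool$target),
              by = max(1L, floor(length(pool$target) / 250)))
  rep <- shap_values(h_fused$model,
                     apply_normalizer(subset_sequences(pool, thin), nz),
                     apply_normalizer(tr, nz),
                     n_background = 8, n_steps = 25)
  curve <- group_contribution_curve(rep)
  list(r2_fused = h_fused$metrics$r2, r2_acc = h_acc$metrics$r2,
       r2_ar = h_ar$metrics$r2, crossover = curve$crossover_kmh)
}

# Small fusion-model config so NN tests stay fast; any model_config()
# argument can be overridden.
tiny_config <- function(...) {
  defaults <- list(arch = "cnn_lstm", feature_set = "acc_ecg",
                   hidden_units = 8L, conv_channels = c(4L, 6L),
                   static_width = 8L, fusion_width = 8L, epochs = 20L,
                   seed = 42L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}
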