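## Evaluation: RMSE/MAE/R2, Bland-Altman agreement, leave-one-subject-out
## cross-validation and the held-out-subject experiment.

check_pred_pair <- function(y, yhat, min_n = 2L) {
  if (length(y) != length(yhat)) {
    stop("`y` and `yhat` must have equal length", call. = FALSE)
  }
  if (length(y) < min_n) {
    stop(sprintf("need at least %d paired samples", min_n), call. = FALSE)
  }
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    stop("values must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Root mean square error
#' @param y true values.
#' @param yhat predicted values.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  check_pred_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return `mean(|y - yhat|)`.
#' @export
mae <- function(y, yhat) {
  check_pred_pair(y, yhat)
  mean(abs(y - yhat))
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Errors when the true
#' values have zero variance (the ratio is undefined).
#'
#' @inheritParams rmse
#' @return R-squared (can be negative for predictors worse than the mean).
#' @export
r2 <- function(y, yhat) {
  check_pred_pair(y, yhat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("R^2 undefined: zero-variance true values", call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Bland-Altman agreement analysis
#'
#' Differences are predicted minus true. Bias is the mean difference, the
#' limits of agreement are bias +/- 1.96 x sample SD (n - 1), and the
#' per-sample (mean, difference) pairs are returned for plotting.
#'
#' @inheritParams rmse
#' @return list with `bias`, `sd`, `loa_lower`, `loa_upper`, `n`, and a
#'   data.frame `pairs` of (mean, difference).
#' @export
bland_altman <- function(y, yhat) {
  check_pred_pair(y, yhat, min_n = 3L)
  d <- yhat - y
  b <- mean(d)
  s <- stats::sd(d)
  list(bias = b, sd = s, loa_lower = b - 1.96 * s, loa_upper = b + 1.96 * s,
       n = length(d),
       pairs = data.frame(mean = (y + yhat) / 2, diff = d))
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject is the validation set and all other
#' subjects form the training set.
#'
#' @param subject_ids character vector of unique subject ids.
#' @return list of folds, each `list(train = ids, val = id)`.
#' @export
loso_splits <- function(subject_ids) {
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  if (length(subject_ids) < 2L) stop("need at least 2 subjects", call. = FALSE)
  lapply(seq_along(subject_ids), function(i) {
    list(train = subject_ids[-i], val = subject_ids[i])
  })
}

## Fit one model on (already normalized) training sequences. Dispatches on
## architecture; `epochs` overrides the config epoch budget for the NN.
fit_one_model <- function(train_nz, arch, feature_set, config, epochs = NULL) {
  cfg <- config
  cfg$arch <- arch
  cfg$feature_set <- feature_set
  if (arch == "ar") {
    fit_ar(select_features(train_nz, feature_set), p = cfg$ar_lag)
  } else {
    model <- build_fusion_model(cfg)
    train_model(model, train_nz, epochs = epochs)
  }
}

eval_pair <- function(y, yhat, nz) {
  yk <- denormalize_target(y, nz)
  yhk <- denormalize_target(yhat, nz)
  list(r2 = r2(y, yhat), rmse = rmse(y, yhat), mae = mae(y, yhat),
       rmse_kcal = rmse(yk, yhk), mae_kcal = mae(yk, yhk))
}

#' Leave-one-subject-out cross-validation experiment
#'
#' For each fold the normalizer is refit on that fold's training subjects
#' only (no leakage), the model is trained at the per-fold epoch budget and
#' evaluated on the held-out subject. Metrics are reported on the
#' normalized target scale (headline) and in kcal/min, per fold and as
#' mean +/- SD across folds.
#'
#' @param seqs raw (unnormalized) `ee_sequences` of the cross-validation
#'   subjects only (test subjects must already be excluded).
#' @param arch `"ar"`, `"lstm"` or `"cnn_lstm"`.
#' @param feature_set `"acc"`, `"ecg"` or `"acc_ecg"`.
#' @param config an [model_config()].
#' @param epochs optional override of the per-fold epoch budget.
#' @return an `ee_eval_report`: list with `per_fold` data.frame and
#'   `summary` (mean/sd per metric).
#' @export
run_loso_experiment <- function(seqs, arch = "cnn_lstm",
                                feature_set = "acc_ecg",
                                config = model_config(), epochs = NULL) {
  ids <- unique(seqs$subject_id)
  folds <- loso_splits(ids)
  rows <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    res <- tryCatch({
      tr <- subset_sequences(seqs, seqs$subject_id %in% fold$train)
      va <- subset_sequences(seqs, seqs$subject_id == fold$val)
      nz <- fit_normalizer(tr)
      model <- fit_one_model(apply_normalizer(tr, nz), arch, feature_set,
                             config, epochs = epochs)
      model$normalizer <- nz
      pred <- predict(model, apply_normalizer(va, nz))
      yva <- (va$target - nz$target_min) / (nz$target_max - nz$target_min)
      m <- eval_pair(yva, pred$pred, nz)
      data.frame(fold = fi, val_subject = fold$val,
                 n_val = length(yva), r2 = m$r2, rmse = m$rmse, mae = m$mae,
                 rmse_kcal = m$rmse_kcal, mae_kcal = m$mae_kcal)
    }, error = function(e) {
      stop(sprintf("fold %d (val subject %s): %s", fi, fold$val,
                   conditionMessage(e)), call. = FALSE)
    })
    rows[[fi]] <- res
  }
  per_fold <- do.call(rbind, rows)
  metr <- c("r2", "rmse", "mae", "rmse_kcal", "mae_kcal")
  summary <- data.frame(metric = metr,
                        mean = vapply(metr, function(m) mean(per_fold[[m]]),
                                      numeric(1)),
                        sd = vapply(metr, function(m) stats::sd(per_fold[[m]]),
                                    numeric(1)))
  structure(list(kind = "loso", arch = arch, feature_set = feature_set,
                 per_fold = per_fold, summary = summary),
            class = "ee_eval_report")
}

#' Held-out-subject experiment
#'
#' Retrains a single model on all training subjects at the final epoch
#' budget and evaluates on the pooled test-subject sequences, including
#' Bland-Altman agreement of the pooled predictions.
#'
#' @param train_seqs raw `ee_sequences` of the training subjects.
#' @param test_seqs raw `ee_sequences` of the held-out test subjects
#'   (subject sets must be disjoint).
#' @inheritParams run_loso_experiment
#' @param epochs optional override of the final epoch budget.
#' @return an `ee_eval_report` with `metrics`, `bland_altman`,
#'   `per_subject` and the fitted `model`.
#' @export
run_holdout_experiment <- function(train_seqs, test_seqs,
                                   arch = "cnn_lstm", feature_set = "acc_ecg",
                                   config = model_config(), epochs = NULL) {
  tr_ids <- unique(train_seqs$subject_id)
  te_ids <- unique(test_seqs$subject_id)
  if (length(intersect(tr_ids, te_ids)) > 0) {
    stop("train and test subject sets overlap", call. = FALSE)
  }
  nz <- fit_normalizer(train_seqs)
  model <- fit_one_model(apply_normalizer(train_seqs, nz), arch, feature_set,
                         config, epochs = epochs %||% config$epochs_final)
  model$normalizer <- nz
  te_nz <- apply_normalizer(test_seqs, nz)
  pred <- predict(model, te_nz)
  y <- te_nz$target
  m <- eval_pair(y, pred$pred, nz)
  ba <- bland_altman(y, pred$pred)
  per_subject <- do.call(rbind, lapply(te_ids, function(id) {
    sel <- te_nz$subject_id == id
    data.frame(subject = id, n = sum(sel),
               r2 = r2(y[sel], pred$pred[sel]),
               rmse = rmse(y[sel], pred$pred[sel]),
               mae = mae(y[sel], pred$pred[sel]))
  }))
  structure(list(kind = "holdout", arch = arch, feature_set = feature_set,
                 metrics = m, bland_altman = ba, per_subject = per_subject,
                 n_test = length(y), model = model),
            class = "ee_eval_report")
}

#' @export
print.ee_eval_report <- function(x, ...) {
  if (x$kind == "loso") {
    cat(sprintf("<ee_eval_report LOSO %s/%s> %d folds\n", x$arch,
                x$feature_set, nrow(x$per_fold)))
    s <- x$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-10s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
    }
  } else {
    cat(sprintf("<ee_eval_report holdout %s/%s> n = %d\n", x$arch,
                x$feature_set, x$n_test))
    cat(sprintf("  R2 %.3f  RMSE %.3f  MAE %.3f (normalized)\n",
                x$metrics$r2, x$metrics$rmse, x$metrics$mae))
    cat(sprintf("  bias %.3f  LoA [%.3f, %.3f]\n", x$bland_altman$bias,
                x$bland_altman$loa_lower, x$bland_altman$loa_upper))
  }
  invisible(x)
}
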