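## Model families: autoregressive linear baseline (dynamic features only)
## and the personalized dynamic-static fusion regressors (LSTM and
## CNN+LSTM variants).

#' Model configuration
#'
#' Architecture and training hyperparameters. Defaults are the tuned
#' operating point: 64 hidden units, dropout 0.1, batch size 32, learning
#' rate 0.001, convolution kernel 3 with channels 64/128, pooling size 2
#' with stride 1, fusion layer width 32, AR lag 10, 500 epochs per
#' cross-validation fold and 1500 for the final refit.
#'
#' @param arch `"ar"`, `"lstm"` or `"cnn_lstm"`.
#' @param feature_set `"acc"` (12 features), `"ecg"` (10) or `"acc_ecg"`
#'   (all 22).
#' @param hidden_units LSTM hidden state size.
#' @param dropout dropout rate on the recurrent output.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs per cross-validation fold.
#' @param epochs_final training epochs for the final train-set refit.
#' @param conv_kernel 1-D convolution kernel size (time axis).
#' @param conv_channels channels of the two convolution blocks.
#' @param pool_size,pool_stride max-pooling geometry (valid, stride 1
#'   shrinks the sequence by `pool_size - 1` per block).
#' @param static_width width of the static-branch dense layer.
#' @param fusion_width width of the post-concatenation dense layer.
#' @param ar_lag lag order of the AR baseline (equals the sequence length).
#' @param seed master seed for initialization and batch shuffling.
#' @return an object of class `ee_model_config`.
#' @export
model_config <- function(arch = "cnn_lstm", feature_set = "acc_ecg",
                         hidden_units = 64L, dropout = 0.1,
                         learning_rate = 0.001, batch_size = 32L,
                         epochs = 500L, epochs_final = 1500L,
                         conv_kernel = 3L, conv_channels = c(64L, 128L),
                         pool_size = 2L, pool_stride = 1L,
                         static_width = 32L, fusion_width = 32L,
                         ar_lag = 10L, seed = 1L) {
  arch <- match.arg(arch, c("ar", "lstm", "cnn_lstm"))
  feature_set <- match.arg(feature_set, c("acc", "ecg", "acc_ecg"))
  for (nm in c("hidden_units", "learning_rate", "batch_size", "epochs",
               "epochs_final", "conv_kernel", "pool_size", "static_width",
               "fusion_width", "ar_lag")) {
    stop_if_not_scalar_number(get(nm), nm, 0, strict_lower = TRUE)
  }
  stop_if_not_scalar_number(dropout, "dropout", 0, upper = 0.999)
  structure(list(arch = arch, feature_set = feature_set,
                 hidden_units = as.integer(hidden_units), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 epochs_final = as.integer(epochs_final),
                 conv_kernel = as.integer(conv_kernel),
                 conv_channels = as.integer(conv_channels),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 static_width = as.integer(static_width),
                 fusion_width = as.integer(fusion_width),
                 ar_lag = as.integer(ar_lag), seed = as.integer(seed)),
            class = "ee_model_config")
}

#' Dynamic feature names of a feature set
#'
#' @param feature_set `"acc"`, `"ecg"` or `"acc_ecg"`.
#' @return character vector of feature names (12, 10 or 22).
#' @export
feature_set_names <- function(feature_set) {
  switch(match.arg(feature_set, c("acc", "ecg", "acc_ecg")),
         acc = acc_feature_names(),
         ecg = ecg_feature_names(),
         acc_ecg = dynamic_feature_names())
}

#' Restrict a sequence set to a feature set
#'
#' Models see only the selected dynamic feature columns, which makes the
#' ablation contract structural: an `"acc"` model is never presented the
#' ECG columns at all, and vice versa.
#'
#' @param seqs an `ee_sequences`.
#' @param feature_set `"acc"`, `"ecg"` or `"acc_ecg"`.
#' @return the restricted `ee_sequences`.
#' @export
select_features <- function(seqs, feature_set) {
  fn <- feature_set_names(feature_set)
  out <- seqs
  out$dynamic <- seqs$dynamic[, , fn, drop = FALSE]
  out$feature_names <- fn
  out
}

## Flatten the dynamic tensor to the AR design matrix (no intercept column).
ar_design <- function(seqs) {
  d <- dim(seqs$dynamic)
  X <- matrix(seqs$dynamic, d[1], d[2] * d[3])
  colnames(X) <- as.vector(outer(seq_len(d[2]), seqs$feature_names,
                                 function(t, f) paste0(f, "_lag", d[2] - t + 1L)))
  X
}

#' Fit the autoregressive linear baseline
#'
#' Ordinary least squares of the energy-expenditure target on the `p`
#' lagged dynamic-feature vectors, flattened (p x d + intercept
#' coefficients). Static features are excluded by definition of the
#' baseline. A rank-deficient design falls back to a tiny ridge penalty
#' (1e-6) with a warning.
#'
#' @param seqs training `ee_sequences` (normally normalized, with the
#'   feature set already selected).
#' @param p lag order; must equal the sequence length.
#' @return an object of class `c("ee_ar_model", "ee_model")`.
#' @export
fit_ar <- function(seqs, p = 10L) {
  stopifnot(inherits(seqs, "ee_sequences"))
  d <- dim(seqs$dynamic)
  if (p != d[2]) {
    stop(sprintf("lag order p = %d must equal the sequence length %d", p, d[2]),
         call. = FALSE)
  }
  X <- ar_design(seqs)
  n <- nrow(X)
  if (n <= ncol(X)) {
    warning("fewer samples than AR coefficients; using ridge fallback")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd) || n <= ncol(X)) {
    if (qrd$rank < ncol(Xd)) {
      warning("rank-deficient AR design; using ridge fallback (1e-6)")
    }
    A <- crossprod(Xd) + 1e-6 * diag(ncol(Xd))
    coef <- solve(A, crossprod(Xd, seqs$target))[, 1]
  } else {
    coef <- qr.coef(qrd, seqs$target)
  }
  structure(list(arch = "ar", coef = coef, p = as.integer(p),
                 feature_names = seqs$feature_names,
                 feature_set = NULL, normalizer = NULL),
            class = c("ee_ar_model", "ee_model"))
}

#' Build an untrained dynamic-static fusion model
#'
#' Constructs the network of the configured architecture: for
#' `"cnn_lstm"`, two valid 1-D convolution blocks over the time axis
#' (ReLU, max-pool size 2 stride 1) feeding an LSTM whose final hidden
#' state is retained; for `"lstm"`, the recurrent layer alone. The static
#' branch is a dense ReLU layer; branch outputs are concatenated, passed
#' through a dense fusion layer and a linear scalar output. Initialization
#' is Glorot-uniform, deterministic given `config$seed`.
#'
#' @param config an [model_config()] with `arch` `"lstm"` or `"cnn_lstm"`.
#' @return an object of class `c("ee_fusion_model", "ee_model")` with
#'   `trained = FALSE`.
#' @export
build_fusion_model <- function(config = model_config()) {
  stopifnot(inherits(config, "ee_model_config"))
  if (!config$arch %in% c("lstm", "cnn_lstm")) {
    stop(sprintf("unknown fusion architecture '%s'", config$arch), call. = FALSE)
  }
  fn <- feature_set_names(config$feature_set)
  params <- with_seed(config$seed,
                      nn_init(config$arch, length(fn),
                              length(static_feature_names()), config))
  structure(list(arch = config$arch, config = config, params = params,
                 feature_names = fn, trained = FALSE, history = NULL,
                 normalizer = NULL),
            class = c("ee_fusion_model", "ee_model"))
}

#' Number of learnable parameters of a model
#'
#' @param model an `ee_model`.
#' @return integer parameter count.
#' @export
n_model_params <- function(model) {
  if (inherits(model, "ee_ar_model")) return(length(model$coef))
  as.integer(nn_n_params(model$params))
}

#' Train a fusion model
#'
#' Adam optimization of the mean squared error at the configured batch
#' size, learning rate and a fixed epoch count (no early stopping).
#' Deterministic given the config seed, which governs both initialization
#' and batch shuffling. Training and validation subjects must be disjoint.
#'
#' @param model an untrained model from [build_fusion_model()].
#' @param train_seqs normalized training `ee_sequences`.
#' @param val_seqs optional normalized validation `ee_sequences` (held-out
#'   subjects); per-epoch validation loss is recorded when supplied.
#' @param epochs optional override of `config$epochs`.
#' @return the trained model with `history$train` (and `history$val`).
#' @export
train_model <- function(model, train_seqs, val_seqs = NULL, epochs = NULL) {
  stopifnot(inherits(model, "ee_fusion_model"))
  config <- model$config
  if (!is.null(epochs)) config$epochs <- as.integer(epochs)
  tr <- select_features(train_seqs, config$feature_set)
  if (!is.null(val_seqs)) {
    if (length(intersect(unique(tr$subject_id),
                         unique(val_seqs$subject_id))) > 0) {
      stop("training and validation subject sets must be disjoint",
           call. = FALSE)
    }
    va <- select_features(val_seqs, config$feature_set)
  }
  res <- with_seed(config$seed, {
    nn_train_cpp(model$params, unname(tr$dynamic), unname(tr$static),
                 tr$target, unclass(config),
                 if (is.null(val_seqs)) NULL else unname(va$dynamic),
                 if (is.null(val_seqs)) NULL else unname(va$static),
                 if (is.null(val_seqs)) NULL else va$target)
  })
  model$params <- res$params
  model$history <- list(train = as.vector(res$train),
                        val = if (is.null(res$val)) NULL else as.vector(res$val))
  model$trained <- TRUE
  model
}

#' @export
print.ee_fusion_model <- function(x, ...) {
  cat(sprintf("<ee_fusion_model %s/%s> %s, %d parameters\n", x$arch,
              x$config$feature_set,
              if (x$trained) "trained" else "untrained", n_model_params(x)))
  invisible(x)
}

#' @export
print.ee_ar_model <- function(x, ...) {
  cat(sprintf("<ee_ar_model> lag %d, %d coefficients\n", x$p, length(x$coef)))
  invisible(x)
}

#' Predict energy expenditure
#'
#' Pure function of (parameters, input); batch-order invariant. Predictions
#' are on the normalized target scale; when the model carries a normalizer
#' a `pred_kcal_min` column with the inverse-transformed kcal/min values is
#' added.
#'
#' @param object a trained `ee_fusion_model`.
#' @param seqs `ee_sequences` on the same normalization as training.
#' @param ... unused.
#' @return data.frame with `pred` (normalized scale) and, when possible,
#'   `pred_kcal_min`.
#' @export
predict.ee_fusion_model <- function(object, seqs, ...) {
  sel <- select_features(seqs, object$config$feature_set)
  if (!identical(sel$feature_names, object$feature_names)) {
    stop("feature-set mismatch between model and samples", call. = FALSE)
  }
  yhat <- as.vector(nn_forward_cpp(object$params, unname(sel$dynamic),
                                   unname(sel$static),
                                   unclass(object$config)))
  finish_prediction(yhat, object, seqs)
}

#' Predict from the AR baseline
#'
#' Dot product of the stored coefficients with the flattened dynamic
#' feature block (intercept included).
#'
#' @param object an `ee_ar_model`.
#' @param seqs `ee_sequences` on the training normalization, carrying the
#'   same feature names the model was fit on.
#' @param ... unused.
#' @return data.frame as for [predict.ee_fusion_model()].
#' @export
predict.ee_ar_model <- function(object, seqs, ...) {
  sel <- if (identical(seqs$feature_names, object$feature_names)) {
    seqs
  } else {
    out <- seqs
    if (!all(object$feature_names %in% seqs$feature_names)) {
      stop("feature-set mismatch between model and samples", call. = FALSE)
    }
    out$dynamic <- seqs$dynamic[, , object$feature_names, drop = FALSE]
    out$feature_names <- object$feature_names
    out
  }
  X <- cbind(1, ar_design(sel))
  yhat <- as.vector(X %*% object$coef)
  finish_prediction(yhat, object, seqs)
}

finish_prediction <- function(yhat, model, seqs) {
  if (any(!is.finite(yhat))) stop("non-finite predictions", call. = FALSE)
  out <- data.frame(pred = yhat)
  if (!is.null(model$normalizer)) {
    out$pred_kcal_min <- denormalize_target(yhat, model$normalizer)
  }
  if (!is.null(seqs$subject_id)) out$subject_id <- seqs$subject_id
  if (!is.null(seqs$speed_kmh)) out$speed_kmh <- seqs$speed_kmh
  out
}

#' Save a model as a portable JSON checkpoint
#'
#' Stores the configuration, flattened parameter arrays with their
#' dimensions, and the attached normalizer, so a checkpoint round-trips
#' across platforms without binary serialization.
#'
#' @param model a trained `ee_model`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  nz_json <- function(nz) {
    if (is.null(nz)) return(NULL)
    lapply(unclass(nz), function(x) if (!is.null(names(x))) as.list(x) else x)
  }
  if (inherits(model, "ee_ar_model")) {
    obj <- list(kind = "ar", coef = as.numeric(model$coef),
                coef_names = names(model$coef), p = model$p,
                feature_names = model$feature_names,
                normalizer = nz_json(model$normalizer))
  } else {
    obj <- list(kind = "fusion", config = unclass(model$config),
                trained = model$trained,
                feature_names = model$feature_names,
                params = lapply(model$params, function(p) {
                  list(dim = if (is.matrix(p)) dim(p) else length(p),
                       data = as.numeric(p))
                }),
                normalizer = nz_json(model$normalizer))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint path.
#' @return an `ee_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nz <- if (length(obj$normalizer) == 0L) NULL else {
    structure(lapply(obj$normalizer, function(x) {
      if (is.list(x)) unlist(x) else x
    }), class = "ee_normalizer")
  }
  if (identical(obj$kind, "ar")) {
    return(structure(list(arch = "ar",
                          coef = stats::setNames(obj$coef, obj$coef_names),
                          p = as.integer(obj$p),
                          feature_names = obj$feature_names,
                          normalizer = nz),
                     class = c("ee_ar_model", "ee_model")))
  }
  cfg <- obj$config
  config <- model_config(arch = cfg$arch, feature_set = cfg$feature_set,
                         hidden_units = cfg$hidden_units, dropout = cfg$dropout,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size, epochs = cfg$epochs,
                         epochs_final = cfg$epochs_final,
                         conv_kernel = cfg$conv_kernel,
                         conv_channels = cfg$conv_channels,
                         pool_size = cfg$pool_size,
                         pool_stride = cfg$pool_stride,
                         static_width = cfg$static_width,
                         fusion_width = cfg$fusion_width,
                         ar_lag = cfg$ar_lag, seed = cfg$seed)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  structure(list(arch = config$arch, config = config, params = params,
                 feature_names = obj$feature_names,
                 trained = isTRUE(obj$trained), history = NULL,
                 normalizer = nz),
            class = c("ee_fusion_model", "ee_model"))
}
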