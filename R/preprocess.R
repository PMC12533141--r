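## Stream cleaning: Local Outlier Factor anomaly flagging on (time, value)
## embeddings, linear interpolation of flagged/missing samples, and scalar
## random-walk Kalman smoothing.

#' Cleaning-stage configuration
#'
#' @param k_acc LOF neighborhood size for acceleration axes (default 300,
#'   i.e. 30 s of 10 Hz samples — one protocol step).
#' @param k_rr LOF neighborhood size for the RR series (default 30 = one
#'   protocol step at 1 Hz).
#' @param lof_threshold LOF score above which a sample is flagged (> 1).
#' @param acc_q_frac,acc_r_frac Kalman process/observation variance for the
#'   acceleration axes, as fractions of the stream variance. The defaults
#'   give a high-gain filter (~0.95) so the 1.2-2.7 Hz cadence band
#'   survives smoothing.
#' @param rr_q_frac,rr_r_frac same for the RR series, whose heart-rate
#'   variability bands (0.04-0.4 Hz at 1 Hz sampling) also sit near the
#'   Nyquist frequency: the smoother shaves white noise but must not
#'   flatten the spectral structure the feature bank measures.
#' @return an object of class `ee_cleaning_config`.
#' @export
cleaning_config <- function(k_acc = 300L, k_rr = 30L, lof_threshold = 1.5,
                            acc_q_frac = 1e-1, acc_r_frac = 1e-2,
                            rr_q_frac = 1e-1, rr_r_frac = 1e-2) {
  stop_if_not_scalar_number(k_acc, "k_acc", 2)
  stop_if_not_scalar_number(k_rr, "k_rr", 2)
  stop_if_not_scalar_number(lof_threshold, "lof_threshold", 1, strict_lower = TRUE)
  for (nm in c("acc_q_frac", "acc_r_frac", "rr_q_frac", "rr_r_frac")) {
    stop_if_not_scalar_number(get(nm), nm, 0, strict_lower = TRUE)
  }
  structure(list(k_acc = as.integer(k_acc), k_rr = as.integer(k_rr),
                 lof_threshold = lof_threshold,
                 acc_q_frac = acc_q_frac, acc_r_frac = acc_r_frac,
                 rr_q_frac = rr_q_frac, rr_r_frac = rr_r_frac),
            class = "ee_cleaning_config")
}

## z-standardize each column; a zero-variance column is left centred only.
standardize_cols <- function(P) {
  for (j in seq_len(ncol(P))) {
    m <- mean(P[, j]); s <- stats::sd(P[, j])
    P[, j] <- if (s > 0) (P[, j] - m) / s else P[, j] - m
  }
  P
}

#' Local Outlier Factor scores of a scalar series
#'
#' Classic LOF (k-distance, reachability distance, local reachability
#' density, density ratio) over the series embedded as standardized
#' (time index, value) points with the Euclidean metric, so contextual
#' spikes are separable from the local signal band. Scores near 1 indicate
#' inliers; scores well above 1 indicate density outliers. Neighborhoods
#' include every point within the k-distance (ties included). Distances are
#' computed exactly in blocks, so the scores match a direct O(n^2)
#' reference computation to floating-point accuracy.
#'
#' @param series numeric vector (missing values not allowed; impute first).
#' @param k neighborhood size (>= 2, < length(series)).
#' @return numeric vector of LOF scores, same length as `series`.
#' @export
lof_scores <- function(series, k) {
  n <- length(series)
  stop_if_not_scalar_number(k, "k", 2)
  k <- as.integer(k)
  if (n < k + 1L) stop("series shorter than k + 1", call. = FALSE)
  if (any(!is.finite(series))) {
    stop("`series` must be finite; impute missing values first", call. = FALSE)
  }
  P <- standardize_cols(cbind(seq_len(n), series))
  tv <- P[, 1]; vv <- P[, 2]
  st <- if (n > 1) tv[2] - tv[1] else 1   # uniform standardized time spacing
  kdist <- numeric(n)
  nbr <- vector("list", n)
  nbr_d <- vector("list", n)
  ## exact k-NN via a growing time window: points outside a window of
  ## half-width W are at least (W+1)*st away in the time dimension alone,
  ## so once the in-window k-distance is strictly below that bound the
  ## neighborhood is provably complete (ties included).
  W0 <- max(4L * k, 64L)
  for (i in seq_len(n)) {
    W <- W0
    repeat {
      lo <- max(1L, i - W); hi <- min(n, i + W)
      cand <- lo:hi
      cand <- cand[cand != i]
      d <- sqrt((tv[cand] - tv[i])^2 + (vv[cand] - vv[i])^2)
      kd <- sort(d, partial = k)[k]
      left_ok <- lo == 1L || kd < st * (i - lo + 1L) - 1e-12
      right_ok <- hi == n || kd < st * (hi - i + 1L) - 1e-12
      if (left_ok && right_ok) {
        keep <- d <= kd
        kdist[i] <- kd
        nbr[[i]] <- cand[keep]
        nbr_d[[i]] <- d[keep]
        break
      }
      W <- 2L * W
    }
  }
  ## local reachability density, capped to guard against zero k-distances
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nbr[[i]]], nbr_d[[i]])
    m <- mean(reach)
    lrd[i] <- if (m > 0) 1 / m else 1e12
  }
  vapply(seq_len(n), function(i) mean(lrd[nbr[[i]]]) / lrd[i], numeric(1))
}

#' Flag scored samples and impute flagged/missing values
#'
#' Samples whose LOF score exceeds the threshold are set missing; all
#' missing samples (flagged plus originally absent) are then linearly
#' interpolated from the nearest valid neighbors, with edge values held.
#'
#' @param series numeric vector, possibly containing `NA`.
#' @param scores LOF scores aligned with `series`.
#' @param threshold flag threshold (scores strictly above are flagged).
#' @return numeric vector with attribute `flagged` (logical: interpolated
#'   positions).
#' @export
flag_and_impute <- function(series, scores, threshold = 1.5) {
  if (length(scores) != length(series)) {
    stop("`scores` must align with `series`", call. = FALSE)
  }
  bad <- !is.finite(series) | (is.finite(scores) & scores > threshold)
  if (all(bad)) stop("all samples flagged: unusable stream", call. = FALSE)
  x <- series
  x[bad] <- NA_real_
  out <- interp_na(x)
  attr(out, "flagged") <- bad
  out
}

#' Scalar random-walk Kalman smoother
#'
#' One-dimensional Kalman filter with a level (random-walk) state model:
#' predict adds process variance `q`, update uses gain `P/(P + r)`.
#' Initialized at the first observation; causal single pass.
#'
#' @param series numeric vector (finite).
#' @param q process variance (> 0).
#' @param r observation variance (> 0).
#' @return smoothed numeric vector.
#' @export
kalman_smooth <- function(series, q, r) {
  stop_if_not_scalar_number(q, "q", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(r, "r", 0, strict_lower = TRUE)
  n <- length(series)
  if (n == 0L) stop("empty series", call. = FALSE)
  if (any(!is.finite(series))) stop("`series` must be finite", call. = FALSE)
  x <- numeric(n)
  x[1] <- series[1]
  P <- r
  for (i in 2:max(n, 2L)) {
    if (n == 1L) break
    P <- P + q
    K <- P / (P + r)
    x[i] <- x[i - 1] + K * (series[i] - x[i - 1])
    P <- (1 - K) * P
  }
  x
}

## Clean one scalar stream: LOF -> impute -> Kalman. Returns the cleaned
## vector, the flag mask, and counts for the provenance log.
##
## Boundary correction: density estimators are biased low at the series
## edges (the head of a steep ramp has no left-hand neighbors), which
## inflates LOF scores of perfectly good onset samples to ~2. Within the
## first/last k samples the flag bar is therefore doubled; genuine spikes
## score far above it.
clean_stream <- function(series, k, threshold, q_frac, r_frac) {
  miss <- !is.finite(series)
  provisional <- if (any(miss)) interp_na(series) else series
  scores <- lof_scores(provisional, k)
  n <- length(series)
  edge <- seq_len(n) <= k | seq_len(n) > n - k
  scores[edge] <- scores[edge] / 2
  scores[miss] <- Inf  # originally missing samples are always "flagged"
  imputed <- flag_and_impute(series, scores, threshold)
  v <- stats::var(imputed)
  if (v <= 0) v <- 1e-12
  smoothed <- kalman_smooth(imputed, q = q_frac * v, r = r_frac * v)
  list(series = smoothed, flagged = attr(imputed, "flagged"),
       n_missing = sum(miss), n_outlier = sum(attr(imputed, "flagged") & !miss))
}

#' Clean a raw session
#'
#' Applies, per stream, LOF anomaly flagging (k = `k_acc` on each
#' acceleration axis, k = `k_rr` on the RR series), linear interpolation of
#' flagged and missing samples, and Kalman smoothing. Gas and speed streams
#' are structural references and pass through untouched. Stream lengths and
#' timestamps are never changed.
#'
#' @param session an `ee_session`.
#' @param config an [cleaning_config()].
#' @return an `ee_clean_session` (an `ee_session` with cleaned streams, a
#'   `flags` list marking interpolated samples, and a `cleaning_log`).
#' @export
clean_session <- function(session, config = cleaning_config()) {
  stopifnot(inherits(session, "ee_session"))
  stopifnot(inherits(config, "ee_cleaning_config"))
  out <- session
  flags <- list()
  log <- list()
  for (ax in c("x", "y", "z")) {
    res <- tryCatch(
      clean_stream(session$acc[[ax]], config$k_acc, config$lof_threshold,
                   config$acc_q_frac, config$acc_r_frac),
      error = function(e) {
        stop(sprintf("acc axis %s: %s", ax, conditionMessage(e)), call. = FALSE)
      })
    out$acc[[ax]] <- res$series
    flags[[paste0("acc_", ax)]] <- res$flagged
    log[[paste0("acc_", ax)]] <- list(n = length(res$series),
                                      n_missing = res$n_missing,
                                      n_outlier = res$n_outlier)
  }
  res <- tryCatch(
    clean_stream(session$rr$rr_s, config$k_rr, config$lof_threshold,
                 config$rr_q_frac, config$rr_r_frac),
    error = function(e) stop(sprintf("rr: %s", conditionMessage(e)), call. = FALSE))
  out$rr$rr_s <- res$series
  out$rr$hr_bpm <- 60 / res$series
  flags$rr <- res$flagged
  log$rr <- list(n = length(res$series), n_missing = res$n_missing,
                 n_outlier = res$n_outlier)
  out$flags <- flags
  out$cleaning_log <- c(log, list(config = unclass(config)))
  class(out) <- c("ee_clean_session", "ee_session")
  out
}
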