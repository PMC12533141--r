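## 10-second window feature bank: 12 accelerometer features (window means,
## FFT total energies, mean amplitudes of the three axes and the vector
## magnitude) and 10 ECG features (RR mean, periodogram band powers over
## the standard HRV bands, peak frequency, mean power, LF/HF ratio, heart
## rate), plus the Weir-equation energy-expenditure target.

#' Window/sequence geometry
#'
#' @param window_s window length in seconds (default 10; windows are
#'   trailing and end at each gas-exchange sample).
#' @param acc_hz,rr_hz,gas_hz stream sampling rates.
#' @param seq_len number of consecutive windows per model sequence.
#' @return an object of class `ee_window_spec`.
#' @export
window_spec <- function(window_s = 10, acc_hz = 10, rr_hz = 1, gas_hz = 0.1,
                        seq_len = 10L) {
  stop_if_not_scalar_number(window_s, "window_s", 0, strict_lower = TRUE)
  if (abs(window_s * acc_hz - round(window_s * acc_hz)) > 1e-9) {
    stop("window_s * acc_hz must be an integer", call. = FALSE)
  }
  structure(list(window_s = window_s, acc_hz = acc_hz, rr_hz = rr_hz,
                 gas_hz = gas_hz, seq_len = as.integer(seq_len)),
            class = "ee_window_spec")
}

#' Names of the 22 dynamic features
#' @return character vector of length 22 (12 acceleration + 10 ECG).
#' @export
dynamic_feature_names <- function() c(acc_feature_names(), ecg_feature_names())

#' Names of the 12 accelerometer-derived features
#' @return character vector.
#' @export
acc_feature_names <- function() {
  c("AccX", "AccY", "AccZ", "VM",
    "AccX_TotalEnergy", "AccY_TotalEnergy", "AccZ_TotalEnergy",
    "VM_TotalEnergy",
    "AccX_MeanAmplitude", "AccY_MeanAmplitude", "AccZ_MeanAmplitude",
    "VM_MeanAmplitude")
}

#' Names of the 10 ECG (RR-interval) derived features
#' @return character vector.
#' @export
ecg_feature_names <- function() {
  c("R_Interval_Sec", "R_Interval_TotalPower", "ULFPower", "VLFPower",
    "LFPower", "HFPower", "R_Interval_PeakFrequency", "R_Interval_MeanPower",
    "LF_HFRatio", "HeartRate")
}

#' Vector magnitude of tri-axial acceleration
#'
#' `sqrt(x^2 + y^2 + z^2)`, applied per sample before windowing.
#'
#' @param x,y,z acceleration components (g), vectorized.
#' @return numeric vector (g).
#' @export
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
vector_magnitude <- function(x, y, z) {
  if (any(!is.finite(c(x, y, z)))) stop("inputs must be finite", call. = FALSE)
  sqrt(x^2 + y^2 + z^2)
}

#' FFT total energy of a window
#'
#' Energy of the mean-removed signal computed in the frequency domain:
#' `sum(|X_k|^2) / N` over all FFT bins, which by Parseval equals the
#' time-domain sum of squared deviations from the window mean.
#'
#' @param x fully populated window signal.
#' @return total energy (signal-units squared times samples).
#' @export
fft_total_energy <- function(x) {
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("window must be fully populated and finite", call. = FALSE)
  }
  xc <- x - mean(x)
  sum(Mod(stats::fft(xc))^2) / length(xc)
}

#' Mean amplitude of a window
#'
#' Mean absolute deviation from the window mean; for a sinusoid of
#' amplitude A this approaches 2A/pi.
#'
#' @param x window signal.
#' @return mean amplitude (signal units).
#' @export
mean_amplitude <- function(x) {
  if (any(!is.finite(x))) stop("window must be finite", call. = FALSE)
  mean(abs(x - mean(x)))
}

#' RR-interval time-domain window features
#'
#' @param rr RR intervals (s) in the window, all positive.
#' @param hr the device 1 Hz heart-rate samples (bpm) in the window.
#' @return named vector: `R_Interval_Sec` (mean RR) and `HeartRate` (mean
#'   of the device HR channel).
#' @export
rr_window_features <- function(rr, hr = 60 / rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("RR intervals must be positive and finite", call. = FALSE)
  }
  c(R_Interval_Sec = mean(rr), HeartRate = mean(hr))
}

## Standard HRV band edges (Hz); bands are (lower, upper] intervals and
## together cover (0, 0.4], the conventional ceiling of the HF band.
hrv_bands <- function() {
  list(ULFPower = c(0, 0.003), VLFPower = c(0.003, 0.04),
       LFPower = c(0.04, 0.15), HFPower = c(0.15, 0.4))
}

#' Spectral (PSD) features of an RR window
#'
#' One-sided periodogram of the mean-removed 1 Hz RR series. Band powers
#' integrate the PSD over the standard HRV bands ULF (<= 0.003 Hz), VLF
#' (0.003-0.04], LF (0.04-0.15] and HF (0.15-0.4]; `R_Interval_TotalPower`
#' integrates over the full HRV range (0, 0.4], so the four bands partition
#' it exactly. `R_Interval_PeakFrequency` is the frequency of the maximal
#' positive-frequency bin (0 for a flat spectrum); `R_Interval_MeanPower`
#' is total power divided by the number of in-range bins. When the HF band
#' holds no power the LF/HF ratio is reported as the finite sentinel 0.
#'
#' On a 10-sample window the spectral resolution is 0.1 Hz, so the ULF and
#' VLF bands lie below resolution and are identically 0; they are retained
#' for fidelity to the feature bank definition.
#'
#' @param rr RR intervals (s) in the window.
#' @param fs sampling rate (Hz), default 1.
#' @return named numeric vector with the 8 spectral features.
#' @export
psd_band_features <- function(rr, fs = 1) {
  n <- length(rr)
  if (n < 4L || any(!is.finite(rr))) {
    stop("window must be fully populated and finite", call. = FALSE)
  }
  xc <- rr - mean(rr)
  X <- stats::fft(xc)
  half <- floor(n / 2)
  kk <- seq_len(half)                    # positive-frequency bins
  freqs <- kk * fs / n
  psd <- (2 / (n * fs)) * Mod(X[kk + 1L])^2
  if (n %% 2 == 0) psd[half] <- psd[half] / 2   # Nyquist bin is not doubled
  df <- fs / n
  bands <- hrv_bands()
  in_range <- freqs <= bands$HFPower[2] + 1e-12
  bp <- vapply(bands, function(b) {
    sum(psd[freqs > b[1] + 1e-12 & freqs <= b[2] + 1e-12]) * df
  }, numeric(1))
  total <- sum(psd[in_range]) * df
  peak <- if (all(psd <= 1e-300)) 0 else freqs[which.max(psd)]
  nbins <- sum(in_range)
  lfhf <- if (bp[["HFPower"]] > 0) bp[["LFPower"]] / bp[["HFPower"]] else 0
  c(R_Interval_TotalPower = total, bp,
    R_Interval_PeakFrequency = peak,
    R_Interval_MeanPower = if (nbins > 0) total / nbins else 0,
    LF_HFRatio = lfhf)
}

#' Energy expenditure from gas exchange (abbreviated Weir equation)
#'
#' `EE (kcal/min) = 3.941 * VO2 + 1.106 * VCO2` with VO2/VCO2 in L/min
#' (protein-free abbreviated form).
#'
#' @param vo2,vco2 gas-exchange rates (L/min), >= 0, vectorized.
#' @return energy expenditure in kcal/min.
#' @export
#' @examples
#' weir_ee(1.0, 0.8)  # 4.8258
weir_ee <- function(vo2, vco2) {
  if (any(!is.finite(vo2)) || any(!is.finite(vco2)) ||
      any(vo2 < 0) || any(vco2 < 0)) {
    stop("vo2 and vco2 must be finite and >= 0", call. = FALSE)
  }
  3.941 * vo2 + 1.106 * vco2
}

## Extract the 22 dynamic features of one trailing window ending at `t_end`.
window_features <- function(session, t_end, spec) {
  eps <- 1e-9
  acc <- session$acc
  ai <- acc$t > t_end - spec$window_s + eps & acc$t <= t_end + eps
  n_acc <- as.integer(round(spec$window_s * spec$acc_hz))
  if (sum(ai) != n_acc) {
    stop(sprintf("acc stream does not fully cover window ending at %g s", t_end),
         call. = FALSE)
  }
  x <- acc$x[ai]; y <- acc$y[ai]; z <- acc$z[ai]
  if (any(!is.finite(c(x, y, z)))) {
    stop("acc stream contains missing samples; clean the session first",
         call. = FALSE)
  }
  vm <- vector_magnitude(x, y, z)
  rr <- session$rr
  ri <- rr$t > t_end - spec$window_s + eps & rr$t <= t_end + eps
  n_rr <- as.integer(round(spec$window_s * spec$rr_hz))
  if (sum(ri) != n_rr) {
    stop(sprintf("rr stream does not fully cover window ending at %g s", t_end),
         call. = FALSE)
  }
  rrw <- rr$rr_s[ri]; hrw <- rr$hr_bpm[ri]
  if (any(!is.finite(rrw))) {
    stop("rr stream contains missing samples; clean the session first",
         call. = FALSE)
  }
  td <- rr_window_features(rrw, hrw)
  sp <- psd_band_features(rrw, fs = spec$rr_hz)
  c(AccX = mean(x), AccY = mean(y), AccZ = mean(z), VM = mean(vm),
    AccX_TotalEnergy = fft_total_energy(x),
    AccY_TotalEnergy = fft_total_energy(y),
    AccZ_TotalEnergy = fft_total_energy(z),
    VM_TotalEnergy = fft_total_energy(vm),
    AccX_MeanAmplitude = mean_amplitude(x),
    AccY_MeanAmplitude = mean_amplitude(y),
    AccZ_MeanAmplitude = mean_amplitude(z),
    VM_MeanAmplitude = mean_amplitude(vm),
    R_Interval_Sec = td[["R_Interval_Sec"]],
    R_Interval_TotalPower = sp[["R_Interval_TotalPower"]],
    ULFPower = sp[["ULFPower"]], VLFPower = sp[["VLFPower"]],
    LFPower = sp[["LFPower"]], HFPower = sp[["HFPower"]],
    R_Interval_PeakFrequency = sp[["R_Interval_PeakFrequency"]],
    R_Interval_MeanPower = sp[["R_Interval_MeanPower"]],
    LF_HFRatio = sp[["LF_HFRatio"]],
    HeartRate = td[["HeartRate"]])
}

#' Convert a clean session into feature windows
#'
#' One window per gas-exchange sample whose trailing `window_s` seconds are
#' fully covered by the acceleration and RR streams (the sample at t = 0
#' has no history and yields no window). Each window carries the 22 dynamic
#' features, the treadmill speed at the window end, and the Weir-equation
#' energy-expenditure target computed from that gas sample.
#'
#' @param session a cleaned (or artifact-free) `ee_session`.
#' @param spec an [window_spec()].
#' @return data.frame of class `ee_feature_windows`: `subject_id`, `t`,
#'   the 22 feature columns, `speed_kmh`, `ee_kcal_min`.
#' @export
featurize_session <- function(session, spec = window_spec()) {
  stopifnot(inherits(session, "ee_session"))
  gas <- session$gas
  ends <- gas$t[gas$t >= spec$window_s - 1e-9]
  if (length(ends) == 0L) stop("session shorter than one window", call. = FALSE)
  feats <- t(vapply(ends, function(te) window_features(session, te, spec),
                    numeric(22L)))
  ee <- weir_ee(gas$vo2_lmin[match(ends, gas$t)],
                gas$vco2_lmin[match(ends, gas$t)])
  out <- data.frame(subject_id = session$subject_id, t = ends,
                    feats, check.names = FALSE)
  out$speed_kmh <- if (!is.null(session$protocol)) {
    speed_at(ends, session$protocol)
  } else {
    ## sessions restored from disk carry the speed profile instead
    session$speed$kmh[match(ends, session$speed$t)]
  }
  out$ee_kcal_min <- ee
  class(out) <- c("ee_feature_windows", "data.frame")
  out
}

#' Build model sequences from consecutive feature windows
#'
#' Sliding blocks of `seq_len` consecutive windows (stride 1, oldest to
#' newest); the target is the energy expenditure of the final window and
#' the speed label is that window's speed. Requires contiguous windows from
#' a single subject.
#'
#' @param windows an `ee_feature_windows` data frame (one subject).
#' @param profile the subject's `ee_static_profile`.
#' @param seq_len sequence length (default 10).
#' @param stride stride between sequence starts (default 1).
#' @return an `ee_sequences` object: list with `dynamic` (n x seq_len x 22
#'   array), `static` (n x 6), `target` (n), `subject_id`, `speed_kmh`,
#'   `end_time`, `feature_names`. Fewer windows than `seq_len` yields an
#'   empty object with a warning.
#' @export
build_sequences <- function(windows, profile, seq_len = 10L, stride = 1L) {
  stopifnot(inherits(windows, "ee_feature_windows"))
  if (length(unique(windows$subject_id)) > 1L) {
    stop("`windows` must come from a single subject", call. = FALSE)
  }
  fn <- dynamic_feature_names()
  n_w <- nrow(windows)
  dt <- diff(windows$t)
  if (n_w > 1L && any(abs(dt - dt[1]) > 1e-9)) {
    stop("windows must be contiguous", call. = FALSE)
  }
  if (n_w < seq_len) {
    warning("fewer windows than sequence length; returning empty sequence set")
    starts <- integer(0)
  } else {
    starts <- seq(1L, n_w - seq_len + 1L, by = stride)
  }
  n <- length(starts)
  dyn <- array(NA_real_, dim = c(n, seq_len, length(fn)),
               dimnames = list(NULL, NULL, fn))
  F <- as.matrix(windows[, fn])
  for (i in seq_along(starts)) {
    dyn[i, , ] <- F[starts[i]:(starts[i] + seq_len - 1L), ]
  }
  last <- starts + seq_len - 1L
  structure(list(dynamic = dyn,
                 static = matrix(rep(static_features(profile), each = max(n, 1)),
                                 nrow = max(n, 1),
                                 dimnames = list(NULL, static_feature_names()))[
                                   seq_len(n), , drop = FALSE],
                 target = windows$ee_kcal_min[last],
                 subject_id = rep(as.character(windows$subject_id[1] %||% ""), n),
                 speed_kmh = windows$speed_kmh[last],
                 end_time = windows$t[last],
                 feature_names = fn),
            class = "ee_sequences")
}

#' Concatenate sequence sets from several subjects
#'
#' @param seq_list list of `ee_sequences`.
#' @return a single `ee_sequences`.
#' @export
combine_sequences <- function(seq_list) {
  seq_list <- Filter(function(s) length(s$target) > 0, seq_list)
  if (length(seq_list) == 0L) stop("no non-empty sequence sets", call. = FALSE)
  fn <- seq_list[[1]]$feature_names
  dyn <- do.call(abind_1, lapply(seq_list, `[[`, "dynamic"))
  structure(list(dynamic = dyn,
                 static = do.call(rbind, lapply(seq_list, `[[`, "static")),
                 target = unlist(lapply(seq_list, `[[`, "target"), use.names = FALSE),
                 subject_id = unlist(lapply(seq_list, `[[`, "subject_id"), use.names = FALSE),
                 speed_kmh = unlist(lapply(seq_list, `[[`, "speed_kmh"), use.names = FALSE),
                 end_time = unlist(lapply(seq_list, `[[`, "end_time"), use.names = FALSE),
                 feature_names = fn),
            class = "ee_sequences")
}

## rbind for 3-D arrays along the first margin.
abind_1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, dim = c(total, d[2], d[3]),
               dimnames = list(NULL, NULL, dimnames(arrs[[1]])[[3]]))
  at <- 1L
  for (a in arrs) {
    n <- dim(a)[1]
    if (n > 0) out[at:(at + n - 1L), , ] <- a
    at <- at + n
  }
  out
}

#' Subset a sequence set
#'
#' @param seqs an `ee_sequences`.
#' @param idx integer or logical index over samples.
#' @return the subset `ee_sequences`.
#' @export
subset_sequences <- function(seqs, idx) {
  structure(list(dynamic = seqs$dynamic[idx, , , drop = FALSE],
                 static = seqs$static[idx, , drop = FALSE],
                 target = seqs$target[idx],
                 subject_id = seqs$subject_id[idx],
                 speed_kmh = seqs$speed_kmh[idx],
                 end_time = seqs$end_time[idx],
                 feature_names = seqs$feature_names),
            class = "ee_sequences")
}

#' Featurize a cohort into one combined sequence set
#'
#' Runs [featurize_session()] and [build_sequences()] per subject and
#' concatenates. Invalid (too-short) sessions are dropped with a warning.
#'
#' @param sessions an `ee_cohort` or list of sessions.
#' @param spec an [window_spec()].
#' @return an `ee_sequences` with an extra `role` element (train/test label
#'   per sample) when sessions carry roles.
#' @export
featurize_cohort <- function(sessions, spec = window_spec()) {
  sessions <- cohort_sessions(sessions)
  sessions <- Filter(function(s) {
    if (!isTRUE(s$valid)) {
      warning(sprintf("dropping invalid session %s", s$subject_id))
      FALSE
    } else TRUE
  }, sessions)
  seq_list <- lapply(sessions, function(s) {
    build_sequences(featurize_session(s, spec), s$profile,
                    seq_len = spec$seq_len)
  })
  out <- combine_sequences(seq_list)
  roles <- stats::setNames(vapply(sessions, function(s) s$role %||% NA_character_,
                                  character(1)),
                           vapply(sessions, function(s) s$subject_id, character(1)))
  out$role <- unname(roles[out$subject_id])
  out
}

#' Fit a leakage-free normalizer on training sequences
#'
#' Dynamic features are z-scored per feature (statistics pooled over
#' samples and time steps), static features z-scored per feature, and the
#' energy-expenditure target min-max scaled to [0, 1] - all statistics
#' computed from the supplied (training) sequences only. Zero-variance
#' features get scale 1 with a warning.
#'
#' @param seqs training `ee_sequences`.
#' @return an `ee_normalizer`.
#' @export
fit_normalizer <- function(seqs) {
  stopifnot(inherits(seqs, "ee_sequences"))
  fn <- seqs$feature_names
  dyn <- seqs$dynamic
  dm <- apply(dyn, 3, mean)
  ds <- apply(dyn, 3, stats::sd)
  if (any(ds == 0)) {
    warning("zero-variance dynamic feature(s): scale set to 1")
    ds[ds == 0] <- 1
  }
  sm <- colMeans(seqs$static)
  ss <- apply(seqs$static, 2, stats::sd)
  if (any(ss == 0)) {
    warning("zero-variance static feature(s): scale set to 1")
    ss[ss == 0] <- 1
  }
  lo <- min(seqs$target); hi <- max(seqs$target)
  if (hi - lo <= 0) {
    warning("constant target: range set to 1")
    hi <- lo + 1
  }
  structure(list(dyn_mean = stats::setNames(dm, fn),
                 dyn_sd = stats::setNames(ds, fn),
                 static_mean = sm, static_sd = ss,
                 target_min = lo, target_max = hi),
            class = "ee_normalizer")
}

#' Apply a fitted normalizer to a sequence set
#'
#' @param seqs an `ee_sequences`.
#' @param nz an `ee_normalizer` from [fit_normalizer()].
#' @return the normalized `ee_sequences` (target on the [0, 1] scale).
#' @export
apply_normalizer <- function(seqs, nz) {
  stopifnot(inherits(nz, "ee_normalizer"))
  out <- seqs
  fn <- seqs$feature_names
  for (j in seq_along(fn)) {
    out$dynamic[, , j] <- (seqs$dynamic[, , j] - nz$dyn_mean[[fn[j]]]) /
      nz$dyn_sd[[fn[j]]]
  }
  out$static <- sweep(sweep(seqs$static, 2, nz$static_mean), 2, nz$static_sd, "/")
  out$target <- (seqs$target - nz$target_min) / (nz$target_max - nz$target_min)
  out$normalized <- TRUE
  out
}

#' Invert a normalizer
#'
#' Recovers physical-scale sequences from normalized ones, or (via
#' [denormalize_target()]) kcal/min predictions from normalized ones.
#'
#' @param seqs a normalized `ee_sequences`.
#' @param nz the `ee_normalizer` used to normalize.
#' @return the physical-scale `ee_sequences`.
#' @export
invert_normalizer <- function(seqs, nz) {
  stopifnot(inherits(nz, "ee_normalizer"))
  out <- seqs
  fn <- seqs$feature_names
  for (j in seq_along(fn)) {
    out$dynamic[, , j] <- seqs$dynamic[, , j] * nz$dyn_sd[[fn[j]]] +
      nz$dyn_mean[[fn[j]]]
  }
  out$static <- sweep(sweep(seqs$static, 2, nz$static_sd, "*"), 2,
                      -nz$static_mean)
  out$target <- seqs$target * (nz$target_max - nz$target_min) + nz$target_min
  out$normalized <- NULL
  out
}

#' Map a normalized energy-expenditure value back to kcal/min
#'
#' @param y normalized target values.
#' @param nz an `ee_normalizer`.
#' @return kcal/min values.
#' @export
denormalize_target <- function(y, nz) {
  y * (nz$target_max - nz$target_min) + nz$target_min
}
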