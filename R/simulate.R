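## Synthetic incremental-exercise session generator.
##
## Emulates the measurement setup of a treadmill ramp test: wrist-worn
## tri-axial accelerometer at 10 Hz, chest-strap RR-interval telemetry at
## 1 Hz, breath-gas exchange (VO2/VCO2) at 0.1 Hz, plus six static resting
## traits per subject. Every session stores its generative ground truth so
## downstream stages can be tested by parameter recovery.

#' Cohort-level trait distribution parameters
#'
#' Means and standard deviations of the six static traits measured at rest,
#' the age range, the cohort size and the master seed. Defaults reproduce a
#' typical young-adult treadmill cohort (19 subjects, 15 train / 4 test).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_test number of subjects reserved as the held-out test set.
#' @param age_range integer range (years) ages are drawn from, uniformly.
#' @param height_cm,weight_kg,bmi,bodyfat_pct,rest_hr_bpm,rest_vo2_mlkgmin
#'   numeric `c(mean, sd)` pairs for each trait. `bmi` is a reference
#'   marginal only: sampled profiles always recompute BMI from height and
#'   weight.
#' @param seed master seed; all per-subject randomness derives from it.
#' @return an object of class `ee_cohort_params`.
#' @export
cohort_params <- function(n_subjects = 19L,
                          n_test = 4L,
                          age_range = c(18L, 25L),
                          height_cm = c(169.89, 8.42),
                          weight_kg = c(63.41, 11.74),
                          bmi = c(21.71, 2.65),
                          bodyfat_pct = c(16.89, 6.68),
                          rest_hr_bpm = c(59.74, 7.09),
                          rest_vo2_mlkgmin = c(3.69, 0.76),
                          seed = 1L) {
  stop_if_not_scalar_number(n_subjects, "n_subjects", lower = 1)
  stop_if_not_scalar_number(n_test, "n_test", lower = 0)
  if (n_test >= n_subjects) stop("`n_test` must be < `n_subjects`", call. = FALSE)
  traits <- list(height_cm = height_cm, weight_kg = weight_kg, bmi = bmi,
                 bodyfat_pct = bodyfat_pct, rest_hr_bpm = rest_hr_bpm,
                 rest_vo2_mlkgmin = rest_vo2_mlkgmin)
  for (nm in names(traits)) {
    v <- traits[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v))) {
      stop(sprintf("`%s` must be a numeric c(mean, sd) pair", nm), call. = FALSE)
    }
    if (v[2] < 0) stop(sprintf("`%s` sd must be >= 0", nm), call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    stop("`age_range` must be c(min, max) with min <= max", call. = FALSE)
  }
  structure(c(list(n_subjects = as.integer(n_subjects),
                   n_test = as.integer(n_test),
                   age_range = as.numeric(age_range), seed = as.integer(seed)),
              lapply(traits, as.numeric)),
            class = "ee_cohort_params")
}

#' Incremental treadmill protocol parameters
#'
#' RAMP-style protocol: constant start speed, fixed increment every step,
#' terminated once heart rate reaches `hr_stop_frac` of the age-predicted
#' maximum (220 - age) or the respiratory exchange ratio exceeds
#' `rer_stop`.
#'
#' @param start_kmh start speed (km/h).
#' @param increment_kmh speed increment per step (> 0).
#' @param step_s step duration in seconds (> 0).
#' @param hr_stop_frac stop when HR reaches this fraction of (220 - age).
#' @param rer_stop stop when RER exceeds this value.
#' @param max_kmh treadmill speed cap.
#' @return an object of class `ee_protocol_params`.
#' @export
protocol_params <- function(start_kmh = 3.0, increment_kmh = 0.5, step_s = 30,
                            hr_stop_frac = 0.90, rer_stop = 1.15,
                            max_kmh = 15.0) {
  stop_if_not_scalar_number(increment_kmh, "increment_kmh", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(step_s, "step_s", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(hr_stop_frac, "hr_stop_frac", 0, 1, strict_lower = TRUE)
  stop_if_not_scalar_number(start_kmh, "start_kmh", 0)
  stop_if_not_scalar_number(max_kmh, "max_kmh", start_kmh)
  stop_if_not_scalar_number(rer_stop, "rer_stop", 0, strict_lower = TRUE)
  structure(list(start_kmh = start_kmh, increment_kmh = increment_kmh,
                 step_s = step_s, hr_stop_frac = hr_stop_frac,
                 rer_stop = rer_stop, max_kmh = max_kmh),
            class = "ee_protocol_params")
}

#' Measurement-noise and artifact-injection parameters
#'
#' Controls sensor noise, heart-rate-variability jitter band structure and
#' the injected artifacts (amplitude spikes, dropped samples) that exercise
#' the cleaning stage. Injected indices are recorded in the session ground
#' truth so cleaning recall can be measured exactly.
#'
#' @param acc_sd_g white-noise sd added to each acceleration axis (g).
#' @param rr_jitter_sd_s total HRV jitter sd on the RR series at rest (s).
#' @param lf_frac_rest fraction of jitter variance in the LF band (0.04-0.15
#'   Hz) at rest; the fraction rises linearly with speed and reaches 0.5 at
#'   the configured crossover speed (see [dynamics_params()]), the remainder
#'   sitting in the HF band (0.15-0.4 Hz).
#' @param hrv_atten fractional reduction of total jitter sd at top speed
#'   (HRV shrinks as intensity rises).
#' @param outlier_rate per-sample probability of an injected spike.
#' @param missing_rate per-sample probability of a dropped (NA) sample.
#' @return an object of class `ee_noise_params`.
#' @export
noise_params <- function(acc_sd_g = 0.02, rr_jitter_sd_s = 0.05,
                         lf_frac_rest = 0.2, hrv_atten = 0.7,
                         outlier_rate = 0.01, missing_rate = 0.005) {
  stop_if_not_scalar_number(acc_sd_g, "acc_sd_g", 0)
  stop_if_not_scalar_number(rr_jitter_sd_s, "rr_jitter_sd_s", 0)
  stop_if_not_scalar_number(lf_frac_rest, "lf_frac_rest", 0, 1)
  stop_if_not_scalar_number(hrv_atten, "hrv_atten", 0, 1)
  stop_if_not_scalar_number(outlier_rate, "outlier_rate", 0, 1)
  stop_if_not_scalar_number(missing_rate, "missing_rate", 0, 1)
  structure(list(acc_sd_g = acc_sd_g, rr_jitter_sd_s = rr_jitter_sd_s,
                 lf_frac_rest = lf_frac_rest, hrv_atten = hrv_atten,
                 outlier_rate = outlier_rate, missing_rate = missing_rate),
            class = "ee_noise_params")
}

#' Physiological and biomechanical response parameters
#'
#' The generative model linking treadmill speed to the three measured
#' streams:
#' * cadence `f(s) = cadence_c0_hz + cadence_c1 * s` and arm-swing amplitude
#'   `a(s) = amp_a0_g + amp_a1_g * s` drive the wrist accelerometer;
#' * heart rate follows a first-order lag (time constant `hr_tau_s`) toward
#'   a target that ramps from resting HR toward 220 - age as speed
#'   approaches the subject's aerobic-fitness speed;
#' * VO2 rises from the resting value with a speed-scheduled mixture of the
#'   movement (acceleration-envelope) drive and the cardiac (relative HR)
#'   drive; the mixture weights are equal at `crossover_kmh`, so by design
#'   movement dominates the energy-expenditure signal below the crossover
#'   and cardiac state dominates above it.
#'
#' @param cadence_c0_hz,cadence_c1 cadence model coefficients (Hz, Hz per
#'   km/h). Cadence must remain below the 5 Hz Nyquist limit of the 10 Hz
#'   accelerometer at the protocol's top speed.
#' @param amp_a0_g,amp_a1_g swing amplitude coefficients (g, g per km/h).
#' @param axis_gains relative amplitude of the x/y/z axes.
#' @param axis_baseline_g constant gravity projection per axis (g).
#' @param hr_tau_s heart-rate lag time constant (s).
#' @param hr_speed0_kmh speed at which the HR target starts rising above
#'   resting HR.
#' @param fitness_mean_kmh,fitness_sd_kmh cohort distribution of the
#'   aerobic-fitness speed (speed at which the HR target reaches 220 - age
#'   and RER reaches its ceiling).
#' @param subj_amp_sd sd of the per-subject arm-swing gain (mean 1).
#' @param crossover_kmh speed at which the cardiac drive overtakes the
#'   movement drive in the VO2 mixture.
#' @param mix_width_kmh half-width of the linear mixing ramp (km/h).
#' @param vo2_gain_mlkgmin VO2 above rest at full drive (ml/kg/min).
#' @param rer_rest,rer_gain respiratory exchange ratio at rest and its total
#'   rise at the fitness speed.
#' @param max_duration_s hard safety cap on session length (s).
#' @return an object of class `ee_dynamics_params`.
#' @export
dynamics_params <- function(cadence_c0_hz = 1.2, cadence_c1 = 0.1,
                            amp_a0_g = 0.2, amp_a1_g = 0.08,
                            axis_gains = c(x = 1.0, y = 0.6, z = 0.35),
                            axis_baseline_g = c(x = 0.10, y = 0.15, z = 0.95),
                            hr_tau_s = 30, hr_speed0_kmh = 1.0,
                            fitness_mean_kmh = 12.5, fitness_sd_kmh = 1.0,
                            subj_amp_sd = 0.15,
                            crossover_kmh = 10.5, mix_width_kmh = 4.5,
                            vo2_gain_mlkgmin = 45,
                            rer_rest = 0.80, rer_gain = 0.40,
                            max_duration_s = 1800) {
  stop_if_not_scalar_number(cadence_c0_hz, "cadence_c0_hz", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(cadence_c1, "cadence_c1", 0)
  stop_if_not_scalar_number(amp_a0_g, "amp_a0_g", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(amp_a1_g, "amp_a1_g", 0)
  stop_if_not_scalar_number(hr_tau_s, "hr_tau_s", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(crossover_kmh, "crossover_kmh", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(mix_width_kmh, "mix_width_kmh", 0, strict_lower = TRUE)
  structure(list(cadence_c0_hz = cadence_c0_hz, cadence_c1 = cadence_c1,
                 amp_a0_g = amp_a0_g, amp_a1_g = amp_a1_g,
                 axis_gains = axis_gains, axis_baseline_g = axis_baseline_g,
                 hr_tau_s = hr_tau_s, hr_speed0_kmh = hr_speed0_kmh,
                 fitness_mean_kmh = fitness_mean_kmh,
                 fitness_sd_kmh = fitness_sd_kmh,
                 subj_amp_sd = subj_amp_sd, crossover_kmh = crossover_kmh,
                 mix_width_kmh = mix_width_kmh,
                 vo2_gain_mlkgmin = vo2_gain_mlkgmin,
                 rer_rest = rer_rest, rer_gain = rer_gain,
                 max_duration_s = max_duration_s),
            class = "ee_dynamics_params")
}

#' Treadmill speed at a given time
#'
#' Step function of the incremental protocol: `start + increment *
#' floor(t / step)`, capped at the maximum speed.
#'
#' @param t time in seconds (vectorized, must be >= 0).
#' @param protocol an [protocol_params()] object.
#' @return speed in km/h, same length as `t`.
#' @export
#' @examples
#' speed_at(c(0, 29.9, 60), protocol_params())
speed_at <- function(t, protocol = protocol_params()) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  pmin(protocol$start_kmh + protocol$increment_kmh * floor(t / protocol$step_s),
       protocol$max_kmh)
}

## Truncated-normal draw with a strictly positive floor; sd = 0 returns the
## mean exactly.
draw_trait <- function(mean_sd, floor = 1e-8) {
  m <- mean_sd[1]; s <- mean_sd[2]
  if (m <= floor) stop("trait mean must be positive", call. = FALSE)
  if (s == 0) return(m)
  for (i in 1:1000) {
    v <- stats::rnorm(1, m, s)
    if (v > floor) return(v)
  }
  stop("failed to draw a positive trait value", call. = FALSE)
}

#' Draw one subject's static profile
#'
#' Each trait is drawn from a normal law with the cohort mean/sd, truncated
#' to be strictly positive; BMI is recomputed as weight / height(m)^2 rather
#' than drawn, so the profile is internally consistent. Age is drawn
#' uniformly on the cohort age range. Reproducible: the draw depends only on
#' the cohort master seed and `draw_index`.
#'
#' @param cohort an [cohort_params()] object.
#' @param draw_index subject index in `1:n_subjects`.
#' @return an object of class `ee_static_profile`.
#' @export
sample_static_profile <- function(cohort, draw_index) {
  stopifnot(inherits(cohort, "ee_cohort_params"))
  stop_if_not_scalar_number(draw_index, "draw_index", 1, cohort$n_subjects)
  with_seed(child_seed(cohort$seed, draw_index, salt = 1L), {
    height <- draw_trait(cohort$height_cm)
    weight <- draw_trait(cohort$weight_kg)
    bodyfat <- draw_trait(cohort$bodyfat_pct)
    rest_hr <- draw_trait(cohort$rest_hr_bpm)
    rest_vo2 <- draw_trait(cohort$rest_vo2_mlkgmin)
    age <- if (cohort$age_range[1] == cohort$age_range[2]) {
      cohort$age_range[1]
    } else {
      floor(stats::runif(1, cohort$age_range[1], cohort$age_range[2] + 1))
    }
    structure(list(subject_id = sprintf("S%02d", as.integer(draw_index)),
                   height_cm = height, weight_kg = weight,
                   bmi = weight / (height / 100)^2,
                   bodyfat_pct = bodyfat, rest_hr_bpm = rest_hr,
                   rest_vo2_mlkgmin = rest_vo2, age_yr = as.numeric(age)),
              class = "ee_static_profile")
  })
}

#' Static feature vector of a profile
#'
#' The six static model inputs (age is used only for the 220 - age maximal
#' heart rate and is not a model feature).
#'
#' @param profile an `ee_static_profile`.
#' @return named numeric vector of length 6.
#' @export
static_features <- function(profile) {
  stopifnot(inherits(profile, "ee_static_profile"))
  c(height_cm = profile$height_cm, weight_kg = profile$weight_kg,
    bmi = profile$bmi, bodyfat_pct = profile$bodyfat_pct,
    rest_hr_bpm = profile$rest_hr_bpm,
    rest_vo2_mlkgmin = profile$rest_vo2_mlkgmin)
}

#' Names of the six static features
#' @return character vector of length 6.
#' @export
static_feature_names <- function() {
  c("height_cm", "weight_kg", "bmi", "bodyfat_pct", "rest_hr_bpm",
    "rest_vo2_mlkgmin")
}

## 1 Hz physiological backbone: speed, HR target, lagged HR, RER, and the
## termination time. Deterministic given (profile, fitness).
sim_backbone <- function(profile, protocol, dynamics, fitness) {
  tmax <- dynamics$max_duration_s
  t <- 0:tmax
  s <- speed_at(t, protocol)
  hrmax <- 220 - profile$age_yr
  rest <- profile$rest_hr_bpm
  s0 <- dynamics$hr_speed0_kmh
  intensity <- pmin(pmax((s - s0) / (fitness - s0), 0), 1.05)
  hr_target <- rest + (hrmax - rest) * intensity
  hr <- numeric(length(t))
  hr[1] <- rest
  alpha <- 1 / dynamics$hr_tau_s
  for (i in seq_len(length(t) - 1L)) {
    hr[i + 1L] <- hr[i] + alpha * (hr_target[i] - hr[i])
  }
  rer <- dynamics$rer_rest + dynamics$rer_gain *
    pmin(pmax((s - protocol$start_kmh) / (fitness - protocol$start_kmh), 0), 1.2)
  fired <- which(hr >= protocol$hr_stop_frac * hrmax | rer > protocol$rer_stop)
  if (length(fired) == 0L) {
    t_fire <- tmax
    reason <- "max_duration"
  } else {
    t_fire <- t[fired[1L]]
    reason <- if (hr[fired[1L]] >= protocol$hr_stop_frac * hrmax) {
      "hr_max_fraction"
    } else {
      "rer_threshold"
    }
  }
  ## round termination up to the next gas sample so all streams end on a
  ## common 10 s boundary and the terminal gas sample satisfies the criterion
  t_end <- min(10 * ceiling(t_fire / 10), tmax)
  keep <- t <= t_end
  list(t = t[keep], speed = s[keep], hr_target = hr_target[keep],
       hr = hr[keep], rer = rer[keep], t_end = t_end, t_fire = t_fire,
       termination = reason, hrmax = hrmax)
}

## LF-band variance fraction of the HRV jitter as a function of speed.
lf_fraction <- function(speed, protocol, noise, dynamics) {
  slope <- (0.5 - noise$lf_frac_rest) /
    (dynamics$crossover_kmh - protocol$start_kmh)
  pmin(pmax(noise$lf_frac_rest + slope * (speed - protocol$start_kmh),
            0.05), 0.95)
}

#' Simulate the 1 Hz RR-interval stream
#'
#' Instantaneous heart rate follows a first-order lag toward a target that
#' rises monotonically with speed from resting HR toward 220 - age. The RR
#' series is 60/HR plus zero-mean HRV jitter composed of an LF tone (0.1 Hz)
#' and an HF tone (0.3 Hz) whose variance split shifts toward LF as
#' intensity rises; total jitter sd shrinks with intensity.
#'
#' @param profile an `ee_static_profile`.
#' @param protocol,noise,dynamics parameter objects.
#' @param duration_s optional fixed duration; by default the protocol runs
#'   until a termination criterion fires.
#' @param seed optional seed for a standalone reproducible draw.
#' @return data.frame with columns `t`, `rr_s`, `hr_bpm` plus attribute
#'   `hr_clean` (the noise-free lagged HR path).
#' @export
simulate_rr_stream <- function(profile, protocol = protocol_params(),
                               noise = noise_params(),
                               dynamics = dynamics_params(),
                               duration_s = NULL, seed = NULL) {
  run <- function() {
    fitness <- dynamics$fitness_mean_kmh
    bb <- sim_backbone(profile, protocol, dynamics, fitness)
    if (!is.null(duration_s)) {
      keep <- bb$t <= duration_s
      bb$t <- bb$t[keep]; bb$hr <- bb$hr[keep]; bb$speed <- bb$speed[keep]
    }
    make_rr_from_backbone(bb, profile, protocol, noise, dynamics)$rr
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## Build the RR data frame (with artifact injection) from a backbone.
make_rr_from_backbone <- function(bb, profile, protocol, noise, dynamics) {
  t <- bb$t
  n <- length(t)
  nspeed <- pmin(pmax((bb$speed - protocol$start_kmh) /
                        (protocol$max_kmh - protocol$start_kmh), 0), 1)
  sd_tot <- noise$rr_jitter_sd_s * (1 - noise$hrv_atten * nspeed)
  lf <- lf_fraction(bb$speed, protocol, noise, dynamics)
  ph_lf <- stats::runif(1, 0, 2 * pi)
  ph_hf <- stats::runif(1, 0, 2 * pi)
  jitter <- sd_tot * (sqrt(2 * lf) * sin(2 * pi * 0.1 * t + ph_lf) +
                        sqrt(2 * (1 - lf)) * sin(2 * pi * 0.3 * t + ph_hf))
  rr <- pmax(60 / bb$hr + jitter, 0.25)
  out_idx <- which(stats::runif(n) < noise$outlier_rate)
  if (length(out_idx)) {
    rr[out_idx] <- rr[out_idx] +
      sample(c(-1, 1), length(out_idx), replace = TRUE) *
        stats::runif(length(out_idx), 0.3, 0.6)
    rr[out_idx] <- pmax(rr[out_idx], 0.2)
  }
  miss_idx <- setdiff(which(stats::runif(n) < noise$missing_rate), out_idx)
  if (length(miss_idx)) rr[miss_idx] <- NA_real_
  df <- data.frame(t = t, rr_s = rr, hr_bpm = 60 / rr)
  attr(df, "hr_clean") <- bb$hr
  list(rr = df, outlier_idx = out_idx, missing_idx = miss_idx)
}

#' Simulate the 10 Hz tri-axial acceleration stream
#'
#' Each axis is a cadence-locked sinusoid: frequency `c0 + c1 * speed`,
#' amplitude `(a0 + a1 * speed)` scaled by an axis gain, riding on a
#' constant gravity projection, plus white noise. The oscillation phase is
#' the integral of the instantaneous cadence, so speed steps produce no
#' phase discontinuities. Spikes and missing samples are injected at the
#' configured rates.
#'
#' @param protocol,noise,dynamics parameter objects.
#' @param duration_s stream duration in seconds.
#' @param amp_gain per-subject arm-swing gain (default 1).
#' @param seed optional seed for a standalone reproducible draw.
#' @return data.frame with columns `t`, `x`, `y`, `z`; attributes
#'   `outlier_idx` and `missing_idx` list the injected artifact positions
#'   per axis.
#' @export
simulate_acc_stream <- function(protocol = protocol_params(),
                                noise = noise_params(),
                                dynamics = dynamics_params(),
                                duration_s = 600, amp_gain = 1.0,
                                seed = NULL) {
  f_top <- dynamics$cadence_c0_hz + dynamics$cadence_c1 * protocol$max_kmh
  if (f_top >= 5) {
    stop("cadence at max speed reaches the 5 Hz Nyquist limit of the 10 Hz stream",
         call. = FALSE)
  }
  run <- function() {
    dt <- 0.1
    t <- seq(0, duration_s, by = dt)
    s <- speed_at(t, protocol)
    freq <- dynamics$cadence_c0_hz + dynamics$cadence_c1 * s
    amp <- amp_gain * (dynamics$amp_a0_g + dynamics$amp_a1_g * s)
    phase <- 2 * pi * cumsum(freq * dt)
    n <- length(t)
    axes <- c("x", "y", "z")
    out <- list(t = t)
    outlier_idx <- list()
    missing_idx <- list()
    ph0 <- stats::runif(3, 0, 2 * pi)
    for (i in seq_along(axes)) {
      g <- dynamics$axis_gains[[i]]
      v <- dynamics$axis_baseline_g[[i]] + g * amp * sin(phase + ph0[i]) +
        stats::rnorm(n, 0, noise$acc_sd_g)
      oi <- which(stats::runif(n) < noise$outlier_rate)
      if (length(oi)) {
        v[oi] <- v[oi] + sample(c(-1, 1), length(oi), replace = TRUE) *
          stats::runif(length(oi), 5, 8) * g * amp[oi]
      }
      mi <- setdiff(which(stats::runif(n) < noise$missing_rate), oi)
      if (length(mi)) v[mi] <- NA_real_
      out[[axes[i]]] <- v
      outlier_idx[[axes[i]]] <- oi
      missing_idx[[axes[i]]] <- mi
    }
    df <- as.data.frame(out)
    attr(df, "outlier_idx") <- outlier_idx
    attr(df, "missing_idx") <- missing_idx
    df
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## Movement-drive envelope in [0, ~1]: normalized swing amplitude above the
## protocol start speed, scaled by the subject gain.
acc_envelope <- function(speed, protocol, dynamics, amp_gain) {
  a <- function(s) dynamics$amp_a0_g + dynamics$amp_a1_g * s
  amp_gain * (a(speed) - a(protocol$start_kmh)) /
    (a(protocol$max_kmh) - a(protocol$start_kmh))
}

## Speed-scheduled weight of the cardiac drive in the VO2 mixture.
ecg_weight <- function(speed, dynamics) {
  pmin(pmax(0.5 + (speed - dynamics$crossover_kmh) /
              (2 * dynamics$mix_width_kmh), 0), 1)
}

#' Simulate the 0.1 Hz gas-exchange stream
#'
#' VO2 starts at the resting value (ml/kg/min converted to L/min via body
#' weight) and rises with a speed-scheduled mixture of the movement envelope
#' and the lagged relative heart rate; VCO2 = RER x VO2 with RER ramping
#' from ~0.80 past the termination threshold as speed approaches the
#' subject's fitness speed.
#'
#' @inheritParams simulate_rr_stream
#' @param amp_gain per-subject arm-swing gain entering the movement drive.
#' @param fitness subject aerobic-fitness speed (km/h); default cohort mean.
#' @return data.frame with columns `t`, `vo2_lmin`, `vco2_lmin`.
#' @export
simulate_gas_stream <- function(profile, protocol = protocol_params(),
                                noise = noise_params(),
                                dynamics = dynamics_params(),
                                duration_s = NULL, amp_gain = 1.0,
                                fitness = NULL, seed = NULL) {
  fitness <- fitness %||% dynamics$fitness_mean_kmh
  bb <- sim_backbone(profile, protocol, dynamics, fitness)
  if (!is.null(duration_s)) {
    keep <- bb$t <= duration_s
    bb$t <- bb$t[keep]; bb$hr <- bb$hr[keep]
    bb$speed <- bb$speed[keep]; bb$rer <- bb$rer[keep]
  }
  make_gas_from_backbone(bb, profile, protocol, dynamics, amp_gain)
}

make_gas_from_backbone <- function(bb, profile, protocol, dynamics, amp_gain) {
  gi <- which(bb$t %% 10 == 0)
  t <- bb$t[gi]
  s <- bb$speed[gi]
  hr <- bb$hr[gi]
  rer <- bb$rer[gi]
  rest_abs <- profile$rest_vo2_mlkgmin * profile$weight_kg / 1000
  hr_rel <- pmin(pmax((hr - profile$rest_hr_bpm) /
                        (protocol$hr_stop_frac * bb$hrmax - profile$rest_hr_bpm),
                      0), 1.2)
  env <- acc_envelope(s, protocol, dynamics, amp_gain)
  w <- ecg_weight(s, dynamics)
  drive <- (1 - w) * env + w * hr_rel
  vo2 <- rest_abs + dynamics$vo2_gain_mlkgmin * profile$weight_kg / 1000 * drive
  data.frame(t = t, vo2_lmin = vo2, vco2_lmin = rer * vo2)
}

#' Simulate one complete exercise session
#'
#' Composes the acceleration, RR and gas streams on a shared time origin,
#' truncated at the first firing termination criterion (rounded up to the
#' next gas sample), and records all generative ground truth (termination
#' time and reason, fitness, arm-swing gain, injected artifact indices,
#' crossover design) for downstream recovery tests.
#'
#' @param profile an `ee_static_profile`.
#' @param protocol,noise,dynamics parameter objects.
#' @param seed session seed (all within-session randomness derives from it).
#' @return an object of class `ee_session`. Sessions shorter than one full
#'   model sequence (100 s) carry `valid = FALSE`.
#' @export
simulate_session <- function(profile, protocol = protocol_params(),
                             noise = noise_params(),
                             dynamics = dynamics_params(), seed = 1L) {
  stopifnot(inherits(profile, "ee_static_profile"))
  with_seed(seed, {
    fitness <- max(stats::rnorm(1, dynamics$fitness_mean_kmh,
                                dynamics$fitness_sd_kmh),
                   protocol$start_kmh + 1)
    amp_gain <- max(stats::rnorm(1, 1, dynamics$subj_amp_sd), 0.3)
    bb <- sim_backbone(profile, protocol, dynamics, fitness)
    rrres <- make_rr_from_backbone(bb, profile, protocol, noise, dynamics)
    acc <- simulate_acc_stream(protocol, noise, dynamics,
                               duration_s = bb$t_end, amp_gain = amp_gain)
    gas <- make_gas_from_backbone(bb, profile, protocol, dynamics, amp_gain)
    speed <- data.frame(t = bb$t, kmh = bb$speed)
    truth <- list(seed = seed, t_end_s = bb$t_end, t_fire_s = bb$t_fire,
                  termination = bb$termination, hrmax_bpm = bb$hrmax,
                  fitness_kmh = fitness, amp_gain = amp_gain,
                  crossover_kmh = dynamics$crossover_kmh,
                  mix_width_kmh = dynamics$mix_width_kmh,
                  hr_clean = bb$hr,
                  acc_outlier_idx = attr(acc, "outlier_idx"),
                  acc_missing_idx = attr(acc, "missing_idx"),
                  rr_outlier_idx = rrres$outlier_idx,
                  rr_missing_idx = rrres$missing_idx)
    structure(list(subject_id = profile$subject_id, role = NA_character_,
                   profile = profile, acc = acc, rr = rrres$rr, gas = gas,
                   speed = speed, protocol = protocol, noise = noise,
                   dynamics = dynamics, truth = truth,
                   valid = bb$t_end >= 100),
              class = "ee_session")
  })
}

#' Simulate a full cohort
#'
#' One session per subject; per-subject profiles and session seeds are
#' derived deterministically from the cohort master seed. The last `n_test`
#' subjects are labelled `"test"`, the rest `"train"`.
#'
#' @param cohort an [cohort_params()] object.
#' @param protocol,noise,dynamics parameter objects.
#' @return an object of class `ee_cohort` (list with `sessions` plus the
#'   parameter objects).
#' @export
simulate_cohort <- function(cohort = cohort_params(),
                            protocol = protocol_params(),
                            noise = noise_params(),
                            dynamics = dynamics_params()) {
  stopifnot(inherits(cohort, "ee_cohort_params"))
  if (cohort$n_subjects < 1L) stop("empty cohort", call. = FALSE)
  sessions <- vector("list", cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    profile <- sample_static_profile(cohort, i)
    s <- simulate_session(profile, protocol, noise, dynamics,
                          seed = child_seed(cohort$seed, i, salt = 2L))
    s$role <- if (i > cohort$n_subjects - cohort$n_test) "test" else "train"
    sessions[[i]] <- s
  }
  structure(list(sessions = sessions, cohort = cohort, protocol = protocol,
                 noise = noise, dynamics = dynamics),
            class = "ee_cohort")
}

#' @export
print.ee_session <- function(x, ...) {
  cat(sprintf("<ee_session %s> %.0f s, %s, terminated by %s%s\n",
              x$subject_id, x$truth$t_end_s, x$role %||% "unassigned",
              x$truth$termination, if (x$valid) "" else " [INVALID: too short]"))
  invisible(x)
}

#' @export
print.ee_cohort <- function(x, ...) {
  roles <- vapply(x$sessions, function(s) s$role, character(1))
  cat(sprintf("<ee_cohort> %d subjects (%d train / %d test), seed %d\n",
              length(x$sessions), sum(roles == "train"), sum(roles == "test"),
              x$cohort$seed))
  invisible(x)
}

#' Write a session to a directory of tidy CSV/JSON files
#'
#' Layout: `acc.csv` (t,x,y,z), `rr.csv` (t,rr_s,hr_bpm), `gas.csv`
#' (t,vo2_lmin,vco2_lmin), `speed.csv` (t,kmh), `static.json`,
#' `truth.json`.
#'
#' @param session an `ee_session` (or cleaned session).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$acc, file.path(dir, "acc.csv"), row.names = FALSE)
  utils::write.csv(session$rr, file.path(dir, "rr.csv"), row.names = FALSE)
  utils::write.csv(session$gas, file.path(dir, "gas.csv"), row.names = FALSE)
  utils::write.csv(session$speed, file.path(dir, "speed.csv"), row.names = FALSE)
  static <- c(list(subject_id = session$subject_id, role = session$role,
                   valid = session$valid), unclass(session$profile))
  jsonlite::write_json(static, file.path(dir, "static.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(session$flags)) {
    jsonlite::write_json(session$cleaning_log, file.path(dir, "cleaning_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return an `ee_session`.
#' @export
read_session <- function(dir) {
  static <- jsonlite::read_json(file.path(dir, "static.json"),
                                simplifyVector = TRUE)
  profile <- structure(static[c("subject_id", "height_cm", "weight_kg", "bmi",
                                "bodyfat_pct", "rest_hr_bpm",
                                "rest_vo2_mlkgmin", "age_yr")],
                       class = "ee_static_profile")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(subject_id = static$subject_id,
                 role = static$role %||% NA_character_, profile = profile,
                 acc = utils::read.csv(file.path(dir, "acc.csv")),
                 rr = utils::read.csv(file.path(dir, "rr.csv")),
                 gas = utils::read.csv(file.path(dir, "gas.csv")),
                 speed = utils::read.csv(file.path(dir, "speed.csv")),
                 truth = truth, valid = isTRUE(static$valid)),
            class = "ee_session")
}

#' Write a cohort as one directory per subject
#'
#' @param cohort an `ee_cohort` or list of sessions.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  sessions <- if (inherits(cohort, "ee_cohort")) cohort$sessions else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sessions) write_session(s, file.path(dir, s$subject_id))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory (one subdirectory per subject).
#' @return list of `ee_session` objects.
#' @export
read_cohort <- function(dir) {
  dirs <- sort(list.dirs(dir, recursive = FALSE))
  lapply(dirs, read_session)
}

## Uniform accessor: sessions from either an ee_cohort or a plain list.
cohort_sessions <- function(x) {
  if (inherits(x, "ee_cohort")) x$sessions else x
}
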