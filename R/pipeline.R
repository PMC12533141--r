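## Configuration, sequence-container I/O, and the end-to-end pipeline with
## a reproducibility manifest.

#' Default pipeline configuration
#'
#' Nested sections mirroring the parameter constructors (`cohort`,
#' `protocol`, `noise`, `dynamics`, `cleaning`, `window`, `model`,
#' `evaluation`, `explain`) plus the master `seed`. Every default equals
#' the corresponding constructor default, so an empty config file yields
#' exactly this configuration.
#'
#' @return a nested list of class `ee_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    cohort = unclass(cohort_params())[setdiff(names(unclass(cohort_params())),
                                              "seed")],
    protocol = unclass(protocol_params()),
    noise = unclass(noise_params()),
    dynamics = lapply(unclass(dynamics_params()), function(x) {
      if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
    }),
    cleaning = unclass(cleaning_config()),
    window = unclass(window_spec()),
    model = unclass(model_config())[setdiff(names(unclass(model_config())),
                                            c("arch", "feature_set"))],
    evaluation = list(
      grid = do.call(c, lapply(c("ar", "lstm", "cnn_lstm"), function(a) {
        lapply(c("acc", "ecg", "acc_ecg"), function(f) {
          list(arch = a, feature_set = f)
        })
      }))
    ),
    explain = list(n_background = 100L, n_steps = 50L, bin_width = 0.5,
                   top_k = 15L, max_samples = 300L)
  ), class = "ee_config")
}

check_unknown_keys <- function(user, default, path = "") {
  bad <- character(0)
  for (nm in names(user)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(default)) {
      bad <- c(bad, here)
    } else if (is.list(user[[nm]]) && is.list(default[[nm]]) &&
               !is.null(names(default[[nm]])) && nm != "grid") {
      bad <- c(bad, check_unknown_keys(user[[nm]], default[[nm]], here))
    }
  }
  bad
}

merge_config <- function(default, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(default[[nm]]) &&
        !is.null(names(default[[nm]])) && nm != "grid") {
      default[[nm]] <- merge_config(default[[nm]], user[[nm]])
    } else {
      default[[nm]] <- user[[nm]]
    }
  }
  default
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys (all violations listed), fills
#' every missing value with its default, and materializes the typed
#' parameter objects (which run their own invariant checks). An empty file
#' yields the all-defaults configuration.
#'
#' @param path YAML configuration file.
#' @return an `ee_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  default <- default_config()
  bad <- check_unknown_keys(user, default)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- merge_config(default, user)
  class(cfg) <- "ee_config"
  config_objects(cfg)  # runs the constructors' validation
  cfg
}

#' Save a configuration to YAML
#'
#' @param config an `ee_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

## Materialize typed parameter objects from a config (with validation).
config_objects <- function(cfg) {
  co <- cfg$cohort
  cohort <- cohort_params(n_subjects = co$n_subjects, n_test = co$n_test,
                          age_range = unlist(co$age_range),
                          height_cm = unlist(co$height_cm),
                          weight_kg = unlist(co$weight_kg),
                          bmi = unlist(co$bmi),
                          bodyfat_pct = unlist(co$bodyfat_pct),
                          rest_hr_bpm = unlist(co$rest_hr_bpm),
                          rest_vo2_mlkgmin = unlist(co$rest_vo2_mlkgmin),
                          seed = cfg$seed)
  protocol <- do.call(protocol_params, cfg$protocol)
  noise <- do.call(noise_params, cfg$noise)
  dyn <- cfg$dynamics
  dyn$axis_gains <- unlist(dyn$axis_gains)
  dyn$axis_baseline_g <- unlist(dyn$axis_baseline_g)
  dynamics <- do.call(dynamics_params, dyn)
  cleaning <- do.call(cleaning_config, cfg$cleaning)
  window <- do.call(window_spec, cfg$window)
  model <- do.call(model_config, c(list(arch = "cnn_lstm",
                                        feature_set = "acc_ecg"),
                                   cfg$model))
  model$seed <- as.integer(cfg$seed)
  list(cohort = cohort, protocol = protocol, noise = noise,
       dynamics = dynamics, cleaning = cleaning, window = window,
       model = model)
}

#' Write a sequence container to CSV
#'
#' Wide layout: one row per sequence sample with metadata columns
#' (`subject_id`, `end_time`, `speed_kmh`, `target`), the six static
#' features (`static.<name>`) and the dynamic block flattened as
#' `dyn<t>.<feature>` columns (t = 1 oldest ... seq_len newest).
#'
#' @param seqs an `ee_sequences`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequences_csv <- function(seqs, path) {
  d <- dim(seqs$dynamic)
  flat <- matrix(aperm(seqs$dynamic, c(1, 3, 2)), d[1], d[2] * d[3])
  ## aperm -> columns ordered feature-fastest within time blocks
  cn <- as.vector(outer(seqs$feature_names, seq_len(d[2]),
                        function(f, t) paste0("dyn", t, ".", f)))
  colnames(flat) <- cn
  st <- seqs$static
  colnames(st) <- paste0("static.", colnames(st))
  df <- data.frame(subject_id = seqs$subject_id, end_time = seqs$end_time,
                   speed_kmh = seqs$speed_kmh, target = seqs$target,
                   st, flat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sequence container written by [write_sequences_csv()]
#'
#' @param path CSV path.
#' @return an `ee_sequences`.
#' @export
read_sequences_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  dyn_cols <- grep("^dyn[0-9]+\\.", names(df), value = TRUE)
  tt <- as.integer(sub("^dyn([0-9]+)\\..*$", "\\1", dyn_cols))
  fn <- unique(sub("^dyn[0-9]+\\.", "", dyn_cols))
  Tlen <- max(tt)
  n <- nrow(df)
  dyn <- array(NA_real_, dim = c(n, Tlen, length(fn)),
               dimnames = list(NULL, NULL, fn))
  for (t in seq_len(Tlen)) {
    for (f in fn) dyn[, t, f] <- df[[paste0("dyn", t, ".", f)]]
  }
  st_cols <- grep("^static\\.", names(df), value = TRUE)
  st <- as.matrix(df[, st_cols])
  colnames(st) <- sub("^static\\.", "", st_cols)
  structure(list(dynamic = dyn, static = st, target = df$target,
                 subject_id = as.character(df$subject_id),
                 speed_kmh = df$speed_kmh, end_time = df$end_time,
                 feature_names = fn),
            class = "ee_sequences")
}

report_to_list <- function(rep) {
  if (rep$kind == "loso") {
    list(kind = "loso", arch = rep$arch, feature_set = rep$feature_set,
         per_fold = rep$per_fold, summary = rep$summary)
  } else {
    list(kind = "holdout", arch = rep$arch, feature_set = rep$feature_set,
         metrics = rep$metrics, n_test = rep$n_test,
         bland_altman = rep$bland_altman[c("bias", "sd", "loa_lower",
                                           "loa_upper", "n")],
         per_subject = rep$per_subject)
  }
}

#' Run the full pipeline
#'
#' simulate -> clean -> featurize -> train/evaluate every (architecture,
#' feature set) combination in the evaluation grid (LOSO-CV on the
#' training subjects plus a held-out test evaluation) -> Shapley
#' explanation of the fused CNN+LSTM model, writing all artifacts and a
#' run manifest (config hash, seed, per-file checksums) under `out_dir`.
#' Identical (config, seed) reproduce identical report files.
#'
#' @param config an `ee_config` (see [default_config()], [load_config()]).
#' @param out_dir output directory.
#' @param seed optional override of `config$seed`.
#' @param quiet suppress stage messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL,
                         quiet = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  obj <- config_objects(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] %d subjects, seed %d", obj$cohort$n_subjects, config$seed)
  cohort <- simulate_cohort(obj$cohort, obj$protocol, obj$noise, obj$dynamics)
  write_cohort(cohort, file.path(out_dir, "sessions"))

  say("[preprocess] LOF k_acc=%d k_rr=%d, threshold %.2f",
      obj$cleaning$k_acc, obj$cleaning$k_rr, obj$cleaning$lof_threshold)
  clean <- lapply(cohort$sessions, clean_session, config = obj$cleaning)
  write_cohort(clean, file.path(out_dir, "clean_sessions"))

  say("[featurize] %d-s windows, sequence length %d", obj$window$window_s,
      obj$window$seq_len)
  windows <- do.call(rbind, lapply(clean, function(s) {
    if (isTRUE(s$valid)) featurize_session(s, obj$window) else NULL
  }))
  utils::write.csv(windows, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  seqs <- featurize_cohort(clean, obj$window)
  write_sequences_csv(seqs, file.path(out_dir, "sequences.csv"))
  say("[featurize] %d sequence samples (%d train / %d test)",
      length(seqs$target), sum(seqs$role == "train"), sum(seqs$role == "test"))

  train_seqs <- subset_sequences(seqs, seqs$role == "train")
  test_seqs <- subset_sequences(seqs, seqs$role == "test")
  loso_reports <- list()
  holdout_reports <- list()
  explain_model <- NULL
  for (combo in config$evaluation$grid) {
    tag <- paste(combo$arch, combo$feature_set, sep = "_")
    say("[evaluate] %s: LOSO over %d subjects + holdout on %d",
        tag, length(unique(train_seqs$subject_id)),
        length(unique(test_seqs$subject_id)))
    lr <- run_loso_experiment(train_seqs, combo$arch, combo$feature_set,
                              obj$model)
    hr <- run_holdout_experiment(train_seqs, test_seqs, combo$arch,
                                 combo$feature_set, obj$model)
    loso_reports[[tag]] <- report_to_list(lr)
    holdout_reports[[tag]] <- report_to_list(hr)
    utils::write.csv(lr$per_fold,
                     file.path(out_dir, sprintf("loso_folds_%s.csv", tag)),
                     row.names = FALSE)
    if (combo$arch == "cnn_lstm" && combo$feature_set == "acc_ecg") {
      explain_model <- hr$model
    }
  }
  jsonlite::write_json(loso_reports, file.path(out_dir, "loso_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  jsonlite::write_json(holdout_reports,
                       file.path(out_dir, "holdout_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  if (!is.null(explain_model)) {
    say("[explain] expected-gradients attribution of cnn_lstm/acc_ecg")
    nz <- explain_model$normalizer
    tr_nz <- apply_normalizer(train_seqs, nz)
    ## explain the whole exercise process (train + test), thinned evenly
    pool <- combine_sequences(list(train_seqs, test_seqs))
    thin <- seq(1, length(pool$target),
                by = max(1L, floor(length(pool$target) /
                                     config$explain$max_samples)))
    rep <- shap_values(explain_model,
                       apply_normalizer(subset_sequences(pool, thin), nz),
                       tr_nz,
                       n_background = config$explain$n_background,
                       n_steps = config$explain$n_steps)
    gs <- global_summary(rep, k = config$explain$top_k)
    jsonlite::write_json(list(base = rep$base, ranking = gs$ranking),
                         file.path(out_dir, "global_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    curve <- group_contribution_curve(rep,
                                      bin_width = config$explain$bin_width)
    out_curve <- curve$curve
    out_curve$crossover_kmh <- curve$crossover_kmh
    utils::write.csv(out_curve, file.path(out_dir, "contribution_curve.csv"),
                     row.names = FALSE)
    save_model(explain_model, file.path(out_dir, "model_cnn_lstm_acc_ecg.json"))
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_path)
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("eefusion")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   checksums = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %d artifacts in %s", length(files) + 1L, out_dir)
  invisible(manifest)
}
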