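## Shapley-value attribution for the fusion models: path-integral expected
## gradients for the differentiable architectures, exact weighted linear
## attribution for the AR baseline; global ranking, local feature-value /
## attribution relations, and speed-stratified group contribution curves.

#' Shapley-value attributions for a trained model
#'
#' For the differentiable fusion models, attributions are expected
#' gradients: for each sample, the input gradient is integrated along the
#' straight path from each background sample to the explained sample
#' (midpoint rule, `n_steps` points) and averaged over the background set;
#' each input entry's attribution is the averaged path gradient times its
#' displacement from the background. For the linear AR baseline the exact
#' Shapley values of a linear model are used: coefficient times
#' displacement from the background mean. Per-time-step attributions of
#' each dynamic feature are summed to one value per feature per sample, so
#' additivity is preserved; features outside the model's feature set (and
#' static features for the AR baseline) receive exactly zero attribution.
#'
#' The completeness property (base value + attribution sum = prediction) is
#' checked for every explained sample and a violation beyond tolerance is
#' an error.
#'
#' @param model a trained `ee_model`.
#' @param seqs normalized `ee_sequences` to explain.
#' @param background normalized `ee_sequences` drawn from training data.
#' @param n_background background samples used (evenly thinned if the
#'   background set is larger; default 100).
#' @param n_steps path-integral resolution per background sample.
#' @param tol relative completeness tolerance (default 2%).
#' @return an `ee_shap_report`: attribution matrix (samples x features,
#'   dynamic features time-summed, then static features), `base` value,
#'   `pred`, per-sample feature values (final time step for dynamic
#'   features), sample metadata and the bookkeeping of the check.
#' @export
shap_values <- function(model, seqs, background, n_background = 100L,
                        n_steps = 50L, tol = 0.02) {
  stopifnot(inherits(model, "ee_model"), inherits(seqs, "ee_sequences"))
  nb_all <- length(background$target)
  take <- unique(round(seq(1, nb_all, length.out = min(n_background, nb_all))))
  bg <- subset_sequences(background, take)
  all_feats <- c(seqs$feature_names, colnames(seqs$static))
  n <- length(seqs$target)
  Tlen <- dim(seqs$dynamic)[2]
  attr_mat <- matrix(0, n, length(all_feats),
                     dimnames = list(NULL, all_feats))
  vals <- cbind(matrix(seqs$dynamic[, Tlen, ], n, dim(seqs$dynamic)[3],
                       dimnames = list(NULL, seqs$feature_names)),
                seqs$static)
  if (inherits(model, "ee_ar_model")) {
    sel <- select_shap_input(seqs, model$feature_names)
    bgs <- select_shap_input(bg, model$feature_names)
    X <- ar_design(sel)
    Xb <- ar_design(bgs)
    w <- model$coef[-1]
    mu <- colMeans(Xb)
    contrib <- sweep(X, 2, mu) * matrix(w, nrow(X), length(w), byrow = TRUE)
    base <- as.numeric(model$coef[1] + sum(w * mu))
    pred <- as.vector(cbind(1, X) %*% model$coef)
    d_sel <- length(model$feature_names)
    ## ar_design columns are ordered time-major within feature blocks:
    ## columns (f-1)*T + (1:T) belong to feature f
    for (f in seq_len(d_sel)) {
      cols <- ((f - 1L) * Tlen + 1L):(f * Tlen)
      attr_mat[, model$feature_names[f]] <- rowSums(contrib[, cols, drop = FALSE])
    }
  } else {
    config <- unclass(model$config)
    sel <- select_features(seqs, config$feature_set)
    bgs <- select_features(bg, config$feature_set)
    nb <- length(bgs$target)
    pred <- as.vector(nn_forward_cpp(model$params, unname(sel$dynamic),
                                     unname(sel$static), config))
    base <- mean(nn_forward_cpp(model$params, unname(bgs$dynamic),
                                unname(bgs$static), config))
    alphas <- (seq_len(n_steps) - 0.5) / n_steps
    d_sel <- dim(sel$dynamic)[3]
    n_stat <- ncol(sel$static)
    rows_bg <- rep(seq_len(nb), each = n_steps)
    a_vec <- rep(alphas, times = nb)
    for (i in seq_len(n)) {
      Xi <- sel$dynamic[i, , ]                      # T x d
      Si <- sel$static[i, ]
      m <- nb * n_steps
      Xp <- array(0, dim = c(m, Tlen, d_sel))
      Sp <- matrix(0, m, n_stat)
      diffX <- array(0, dim = c(m, Tlen, d_sel))
      diffS <- matrix(0, m, n_stat)
      for (r in seq_len(m)) {
        b <- rows_bg[r]; a <- a_vec[r]
        Xb <- matrix(bgs$dynamic[b, , ], Tlen, d_sel)
        dX <- Xi - Xb
        Xp[r, , ] <- Xb + a * dX
        diffX[r, , ] <- dX
        dS <- Si - bgs$static[b, ]
        Sp[r, ] <- bgs$static[b, ] + a * dS
        diffS[r, ] <- dS
      }
      bw <- nn_input_grad_cpp(model$params, Xp, Sp, config)
      ig_dyn <- apply(bw$dX * diffX, c(2, 3), mean)   # T x d
      ig_stat <- colMeans(bw$dS * diffS)
      attr_mat[i, sel$feature_names] <- colSums(matrix(ig_dyn, Tlen, d_sel))
      attr_mat[i, colnames(sel$static)] <- ig_stat
    }
  }
  gap <- pred - base
  err <- abs(rowSums(attr_mat) - gap)
  ## floor: 2% of the largest deviation being explained in this batch, so
  ## near-base samples are not held to a vanishing absolute tolerance
  tol_i <- pmax(tol * abs(gap), tol * max(abs(gap), 1e-8))
  if (any(err > tol_i)) {
    stop(sprintf(paste0("attribution completeness violated: max error %.4g ",
                        "against tolerance %.4g; increase n_steps/n_background"),
                 max(err), min(tol_i[err > tol_i])), call. = FALSE)
  }
  structure(list(attributions = attr_mat, base = base, pred = pred,
                 feature_values = vals, subject_id = seqs$subject_id,
                 speed_kmh = seqs$speed_kmh, feature_names = all_feats,
                 model_features = if (inherits(model, "ee_ar_model")) {
                   model$feature_names
                 } else {
                   c(model$feature_names, colnames(seqs$static))
                 },
                 max_completeness_err = max(err)),
            class = "ee_shap_report")
}

## restrict a sequence set to named dynamic features (for the AR path).
select_shap_input <- function(seqs, feature_names) {
  out <- seqs
  out$dynamic <- seqs$dynamic[, , feature_names, drop = FALSE]
  out$feature_names <- feature_names
  out
}

#' @export
print.ee_shap_report <- function(x, ...) {
  cat(sprintf("<ee_shap_report> %d samples x %d features, base %.4f, max completeness err %.2g\n",
              nrow(x$attributions), ncol(x$attributions), x$base,
              x$max_completeness_err))
  invisible(x)
}

#' Global feature importance ranking
#'
#' Features ranked by mean absolute attribution, descending; the top `k`
#' are returned together with per-sample (feature value, attribution)
#' pairs for beeswarm-style plots.
#'
#' @param report an `ee_shap_report`.
#' @param k number of features to keep (default 15; capped at the feature
#'   count).
#' @return list with `ranking` (data.frame feature / mean_abs_shap / rank)
#'   and `pairs` (named list of data.frames value/shap).
#' @export
global_summary <- function(report, k = 15L) {
  stopifnot(inherits(report, "ee_shap_report"))
  if (nrow(report$attributions) == 0L) stop("empty report", call. = FALSE)
  ma <- colMeans(abs(report$attributions))
  ord <- order(ma, decreasing = TRUE)
  k <- min(k, length(ma))
  top <- ord[seq_len(k)]
  ranking <- data.frame(feature = names(ma)[top], mean_abs_shap = ma[top],
                        rank = seq_len(k), row.names = NULL)
  pairs <- lapply(names(ma)[top], function(f) {
    data.frame(value = report$feature_values[, f],
               shap = report$attributions[, f])
  })
  names(pairs) <- names(ma)[top]
  list(ranking = ranking, pairs = pairs)
}

#' Local feature-attribution relation
#'
#' Paired (feature value, attribution) vectors for one feature, the
#' Pearson correlation between them, and each sample's exercise-intensity
#' class.
#'
#' @param report an `ee_shap_report`.
#' @param feature feature name.
#' @return list with `values`, `attributions`, `pearson_r`, `intensity`.
#' @export
local_scatter <- function(report, feature) {
  stopifnot(inherits(report, "ee_shap_report"))
  if (!feature %in% colnames(report$attributions)) {
    stop(sprintf("unknown feature '%s'", feature), call. = FALSE)
  }
  v <- report$feature_values[, feature]
  a <- report$attributions[, feature]
  if (length(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(v) == 0 || stats::sd(a) == 0) {
    stop("Pearson r undefined: zero variance", call. = FALSE)
  }
  list(values = v, attributions = a, pearson_r = stats::cor(v, a),
       intensity = intensity_bin(report$speed_kmh))
}

#' Exercise-intensity class of a treadmill speed
#'
#' Half-open bins low [3.0, 7.5), medium [7.5, 11.0), high [11.0, 15.0].
#'
#' @param speed speed in km/h (vectorized); must lie within [3, 15].
#' @return factor with levels low/medium/high.
#' @export
intensity_bin <- function(speed) {
  if (any(!is.finite(speed)) || any(speed < 3) || any(speed > 15)) {
    stop("speed out of the protocol range [3, 15] km/h", call. = FALSE)
  }
  out <- ifelse(speed < 7.5, "low", ifelse(speed < 11, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Speed-stratified group contribution curves
#'
#' For each speed bin (default width 0.5 km/h, the protocol increment) the
#' absolute attributions are summed within each feature group (default:
#' the 12 accelerometer features vs the 10 ECG features) and averaged over
#' the bin's samples; each group's curve is then standardized across bins
#' (min-max to [0, 1] by default, z-score optional). The crossover speed
#' is the lower edge of the lowest bin at which the second group's curve
#' reaches the first group's and stays at or above it for every later
#' non-empty bin (persistence guards against noise-triggered crossings);
#' `NA` if no such bin exists.
#'
#' @param report an `ee_shap_report`.
#' @param speeds per-sample speeds (defaults to the report metadata).
#' @param groups named list of two feature-name vectors; the crossover is
#'   where the second overtakes the first.
#' @param bin_width speed bin width (km/h).
#' @param speed_range speed range covered by the bins.
#' @param standardize `"minmax"` or `"zscore"`.
#' @param min_bin_n bins with fewer samples are treated as unoccupied
#'   (default 5): a bin average over a handful of sequences is
#'   noise-dominated and would distort both the standardization range and
#'   the crossover search.
#' @return an `ee_contribution_curve`: data.frame `curve` (bin edges,
#'   counts, raw and standardized group contributions) plus
#'   `crossover_kmh`.
#' @export
group_contribution_curve <- function(report, speeds = report$speed_kmh,
                                     groups = list(Acc = acc_feature_names(),
                                                   ECG = ecg_feature_names()),
                                     bin_width = 0.5,
                                     speed_range = c(3, 15),
                                     standardize = c("minmax", "zscore"),
                                     min_bin_n = 5L) {
  stopifnot(inherits(report, "ee_shap_report"))
  standardize <- match.arg(standardize)
  if (length(speeds) != nrow(report$attributions)) {
    stop("`speeds` must align with the report samples", call. = FALSE)
  }
  if (length(groups) != 2L || is.null(names(groups))) {
    stop("`groups` must be a named list of two feature sets", call. = FALSE)
  }
  edges <- seq(speed_range[1], speed_range[2], by = bin_width)
  bin <- findInterval(speeds, edges, rightmost.closed = TRUE)
  gsum <- vapply(groups, function(g) {
    cols <- intersect(g, colnames(report$attributions))
    if (length(cols) == 0L) return(rep(0, nrow(report$attributions)))
    rowSums(abs(report$attributions[, cols, drop = FALSE]))
  }, numeric(nrow(report$attributions)))
  nb <- length(edges) - 1L
  curve <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  curve$bin_mid <- (curve$bin_lo + curve$bin_hi) / 2
  curve$n <- vapply(seq_len(nb), function(b) sum(bin == b), numeric(1))
  for (gi in seq_along(groups)) {
    curve[[paste0(names(groups)[gi], "_raw")]] <-
      vapply(seq_len(nb), function(b) {
        if (curve$n[b] < min_bin_n) NA_real_ else mean(gsum[bin == b, gi])
      }, numeric(1))
  }
  empty <- curve$n < min_bin_n
  if (any(empty)) {
    warning(sprintf("%d empty or sparse speed bin(s) skipped", sum(empty)))
  }
  if (all(empty)) stop("no occupied speed bins", call. = FALSE)
  for (gi in seq_along(groups)) {
    raw <- curve[[paste0(names(groups)[gi], "_raw")]]
    ok <- !is.na(raw)
    std <- rep(NA_real_, nb)
    if (standardize == "minmax") {
      rng <- range(raw[ok])
      std[ok] <- if (diff(rng) > 0) {
        (raw[ok] - rng[1]) / diff(rng)
      } else if (rng[1] == 0) 0 else 0.5   # no attribution mass at all
    } else {
      m <- mean(raw[ok]); s <- stats::sd(raw[ok])
      std[ok] <- if (s > 0) (raw[ok] - m) / s else 0
    }
    curve[[paste0(names(groups)[gi], "_std")]] <- std
  }
  g1 <- curve[[paste0(names(groups)[1], "_std")]]
  g2 <- curve[[paste0(names(groups)[2], "_std")]]
  occupied <- which(!empty)
  crossover <- NA_real_
  for (b in occupied) {
    later <- occupied[occupied >= b]
    if (all(g2[later] >= g1[later])) {
      crossover <- curve$bin_lo[b]
      break
    }
  }
  structure(list(curve = curve, crossover_kmh = crossover,
                 groups = lapply(groups, identity),
                 standardize = standardize),
            class = "ee_contribution_curve")
}

#' @export
print.ee_contribution_curve <- function(x, ...) {
  cat(sprintf("<ee_contribution_curve> %d bins, crossover at %s km/h\n",
              nrow(x$curve),
              if (is.na(x$crossover_kmh)) "none" else
                sprintf("%.1f", x$crossover_kmh)))
  invisible(x)
}
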