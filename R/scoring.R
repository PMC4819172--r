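#' Peak-normalized Gaussian density
#'
#' The Gaussian density centered at `center` with standard deviation `sd`,
#' divided by its own peak value: `exp(-(x - center)^2 / (2 sd^2))`. Its
#' maximum over `x` is exactly 1, so densities from features with different
#' spreads combine on a common \[0,1\] scale.
#'
#' @param x Candidate quality value(s).
#' @param center Density center (the feature's bias-adjusted score).
#' @param sd Standard deviation (> 0; floored upstream).
#' @return Value(s) in (0, 1\].
#' @export
normalized_density <- function(x, center, sd) {
  if (any(sd <= 0)) stop("sd must be positive (floor it upstream)")
  exp(-((x - center)^2) / (2 * sd^2))
}

# Resolve the per-feature scoring context: present features, adjusted
# centers (pre - M, optionally clipped), SDs and renormalized weights.
scoring_context <- function(fv, stats, weights, config = qprob_config()) {
  feats <- qprob_features()
  if (is.null(names(weights))) {
    if (length(weights) != 11) stop("weights must be named or length 11")
    names(weights) <- feats
  }
  if (is.null(names(fv))) {
    if (length(fv) != 11) stop("feature vector must be named or length 11")
    names(fv) <- feats
  }
  fv <- fv[feats]
  m <- stats$M[match(feats, stats$feature)]
  s <- stats$SD[match(feats, stats$feature)]
  w <- weights[feats]
  present <- !is.na(fv) & !is.na(m) & !is.na(s) & !is.na(w)
  if (!any(present)) stop("no usable features (all missing or unweighted)")
  centers <- fv[present] - m[present]
  if (isTRUE(config$scoring$clip_adjusted)) centers <- clip01(centers)
  w_present <- w[present]
  if (all(w_present == 0)) stop("all weights zero for the present features")
  # renormalize so a partially-observed vector carries the full weight mass
  total_w <- sum(weights[feats], na.rm = TRUE)
  if (sum(w_present) != 0 && total_w != 0) {
    w_present <- w_present * total_w / sum(w_present)
  }
  list(centers = unname(centers), sd = unname(s[present]),
       w = unname(w_present), features = feats[present])
}

#' Combined probability score
#'
#' The weighted sum, over present features, of each feature's peak-normalized
#' Gaussian density evaluated at candidate quality `x`. When some features
#' are missing, the remaining weights are scaled so they carry the full
#' weight mass of the complete set.
#'
#' @param x Candidate quality value(s) in \[0,1\].
#' @param fv Named feature vector (see [assemble_feature_vector()]).
#' @param stats A `feature_error_stats`.
#' @param weights Named weight vector (default the published set).
#' @param config A [qprob_config()] list.
#' @return Combined score(s), same length as `x`.
#' @export
combined_probability <- function(x, fv, stats, weights = qprob_default_weights(),
                                 config = qprob_config()) {
  ctx <- scoring_context(fv, stats, weights, config)
  vapply(x, function(xi) {
    sum(ctx$w * normalized_density(xi, ctx$centers, ctx$sd))
  }, numeric(1))
}

# Grid argmax of the combined score; ties toward the smallest X.
grid_argmax <- function(ctx, grid_step) {
  grid <- seq(0, 1, by = grid_step)
  dens <- vapply(seq_along(ctx$centers), function(k) {
    normalized_density(grid, ctx$centers[k], ctx$sd[k])
  }, numeric(length(grid)))
  total <- as.numeric(dens %*% ctx$w)
  grid[which.max(total)]  # which.max takes the first (smallest X) on ties
}

#' Predict the global quality of one model
#'
#' Each present feature score is bias-adjusted (`pre - M`, clipped to
#' \[0,1\]) and contributes a peak-normalized Gaussian with its fitted error
#' SD; the weighted sum of these densities is scanned over a fixed grid on
#' \[0,1\] and the maximizing `X` is the predicted GDT-TS.
#'
#' @param fv Named feature vector over [qprob_features()].
#' @param stats A `feature_error_stats`.
#' @param weights Named weight vector (default the published set).
#' @param config A [qprob_config()] list (`scoring$grid_step`, default
#'   0.001; `scoring$clip_adjusted`).
#' @return Predicted quality in \[0,1\] (grid-resolution).
#' @export
predict_quality <- function(fv, stats, weights = qprob_default_weights(),
                            config = qprob_config()) {
  ctx <- scoring_context(fv, stats, weights, config)
  grid_argmax(ctx, config$scoring$grid_step)
}

#' Score a pool of structural models
#'
#' Assembles each model's feature vector, predicts its quality and returns a
#' ranked table (descending score, ties by model id). Models that fail to
#' score are dropped with a warning.
#'
#' @param models List of `structural_model`s.
#' @param sequence A `sequence_record` (optional, see
#'   [assemble_feature_vector()]).
#' @param predicted_ss,predicted_sa Optional sequence-based predictions.
#' @param raw_table Optional [read_feature_table()] data frame; rows are
#'   matched to models by `model_id`.
#' @param dssp_list Optional named list of [read_dssp()] results per model.
#' @param stats A `feature_error_stats` (default the shipped file).
#' @param weights Named weight vector (default the published set).
#' @param config A [qprob_config()] list.
#' @return Data frame `model_id`, `score` (3 decimals), best first.
#' @export
score_pool <- function(models, sequence = NULL, predicted_ss = NULL,
                       predicted_sa = NULL, raw_table = NULL, dssp_list = NULL,
                       stats = qprob_default_stats(),
                       weights = qprob_default_weights(),
                       config = qprob_config()) {
  if (length(models) == 0) stop("empty model pool")
  rows <- lapply(models, function(m) {
    res <- tryCatch({
      raw <- NULL
      if (!is.null(raw_table)) {
        hit <- raw_table[raw_table$model_id == m$model_id, , drop = FALSE]
        if (nrow(hit) == 1) raw <- hit
      }
      dssp <- if (!is.null(dssp_list)) dssp_list[[m$model_id]] else NULL
      fv <- assemble_feature_vector(m, sequence, predicted_ss, predicted_sa,
                                    raw, dssp, config)
      data.frame(model_id = m$model_id,
                 score = round(predict_quality(fv, stats, weights, config), 3),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("model ", m$model_id, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no model could be scored")
  out <- out[order(-out$score, out$model_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
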