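#' Per-feature prediction errors against true GDT-TS
#'
#' For each (feature, model) pair where the feature is present, the error is
#' `FE = F - R`: the feature's score minus the model's real GDT-TS. These
#' errors are the raw material of the Gaussian error model.
#'
#' @param features Data frame with a `model_id` column and one column per
#'   canonical feature (as written by [make_feature_dataset()] or assembled
#'   via [assemble_feature_vector()]).
#' @param truths Named numeric vector (or data frame with `model_id`,
#'   `gdtts`) of true GDT-TS scores in \[0,1\].
#' @return Named list, one numeric error vector per canonical feature.
#' @export
compute_feature_errors <- function(features, truths) {
  if (is.data.frame(truths)) {
    truths <- stats::setNames(truths$gdtts, truths$model_id)
  }
  if (any(truths < 0 | truths > 1, na.rm = TRUE)) {
    stop("true GDT-TS scores must lie in [0,1]")
  }
  ids <- intersect(features$model_id, names(truths))
  if (length(ids) == 0) stop("no overlap between feature table and truths")
  feats <- qprob_features()
  feats <- intersect(feats, names(features))
  rows <- match(ids, features$model_id)
  out <- lapply(feats, function(f) {
    fe <- features[[f]][rows] - truths[ids]
    unname(fe[!is.na(fe)])
  })
  stats::setNames(out, feats)
}

#' Fit per-feature error statistics
#'
#' Fits each feature's error sample with a normal distribution: the mean
#' `M_i` and the population standard deviation `SD_i`. Standard deviations
#' are floored (default 0.01) so no feature degenerates into a delta
#' function; features with fewer than `min_samples` errors are flagged
#' unusable (`NA` statistics).
#'
#' @param errors Named list of error vectors, as from
#'   [compute_feature_errors()].
#' @param config A [qprob_config()] list (`error_model$sd_floor`,
#'   `error_model$min_samples`).
#' @return A `feature_error_stats`: data frame with columns `feature`, `M`,
#'   `SD`, `n` over the canonical features.
#' @export
fit_error_stats <- function(errors, config = qprob_config()) {
  floor_sd <- config$error_model$sd_floor
  min_n <- config$error_model$min_samples
  feats <- qprob_features()
  M <- SD <- rep(NA_real_, length(feats))
  n <- integer(length(feats))
  for (k in seq_along(feats)) {
    e <- errors[[feats[k]]]
    n[k] <- length(e)
    if (n[k] >= min_n) {
      M[k] <- mean(e)
      SD[k] <- max(sqrt(mean((e - M[k])^2)), floor_sd)  # population SD
    }
  }
  unusable <- n > 0 & n < min_n
  if (any(unusable)) {
    warning("feature(s) ", paste(feats[unusable], collapse = ", "),
            " have fewer than ", min_n, " samples; flagged unusable",
            call. = FALSE)
  }
  structure(data.frame(feature = feats, M = M, SD = SD, n = n,
                       stringsAsFactors = FALSE),
            class = c("feature_error_stats", "data.frame"))
}

#' Save / load feature error statistics
#'
#' YAML round trip at full float precision, keyed by canonical feature name.
#' A config missing a feature loads with `NA` statistics for it; unknown
#' feature names are an error.
#'
#' @param stats A `feature_error_stats`.
#' @param path File path.
#' @return `save_error_stats()` returns `path` invisibly;
#'   `load_error_stats()` returns a `feature_error_stats`.
#' @export
save_error_stats <- function(stats, path) {
  stopifnot(inherits(stats, "feature_error_stats"))
  obj <- lapply(seq_len(nrow(stats)), function(i) {
    list(M = stats$M[i], SD = stats$SD[i], n = stats$n[i])
  })
  names(obj) <- stats$feature
  yaml::write_yaml(list(error_stats = obj), path, precision = 17)
  invisible(path)
}

#' @rdname save_error_stats
#' @export
load_error_stats <- function(path) {
  obj <- yaml::read_yaml(path)
  entries <- obj$error_stats
  if (is.null(entries)) stop("no 'error_stats' block in ", path)
  unknown <- setdiff(names(entries), qprob_features())
  if (length(unknown) > 0) {
    stop("unknown feature name(s) in stats file: ",
         paste(unknown, collapse = ", "))
  }
  feats <- qprob_features()
  get_num <- function(f, field) {
    v <- entries[[f]][[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  structure(data.frame(
    feature = feats,
    M = vapply(feats, get_num, numeric(1), "M"),
    SD = vapply(feats, get_num, numeric(1), "SD"),
    n = vapply(feats, function(f) {
      v <- entries[[f]][["n"]]; if (is.null(v)) 0L else as.integer(v)
    }, integer(1)),
    stringsAsFactors = FALSE), class = c("feature_error_stats", "data.frame"))
}

#' Default shipped error statistics
#'
#' Loads the error-statistics file shipped with the package. Two entries are
#' published constants (the ModelEvaluator error mean -0.0219 with the
#' smallest spread, and the Euclidean compact score's 0.4119 mean error
#' magnitude — the largest of the 11); the remaining entries are documented
#' placeholders. Retrain with [fit_error_stats()] for production use.
#'
#' @return A `feature_error_stats`.
#' @export
qprob_default_stats <- function() {
  load_error_stats(system.file("extdata", "default_stats.yaml",
                               package = "qprob", mustWork = TRUE))
}

#' Convenience trainer from feature and truth tables
#'
#' @param features Feature data frame (see [compute_feature_errors()]).
#' @param truths Truths (named vector or data frame).
#' @param config A [qprob_config()] list.
#' @return A `feature_error_stats`.
#' @export
train_error_stats <- function(features, truths, config = qprob_config()) {
  fit_error_stats(compute_feature_errors(features, truths), config)
}
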