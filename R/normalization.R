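#' Min-max normalization of a raw score
#'
#' Maps `raw` linearly from `[lower, upper]` onto \[0,1\] and clips. With
#' `lower_is_best = TRUE` (energies: more negative is better) the lower bound
#' maps to 1 and the upper to 0, so every normalized feature is positively
#' oriented with model quality.
#'
#' @param raw Raw score(s).
#' @param lower,upper Range endpoints, `upper > lower`.
#' @param lower_is_best Logical; `TRUE` maps `lower` to 1.
#' @return Normalized score(s) in \[0,1\].
#' @export
normalize_min_max <- function(raw, lower, upper, lower_is_best = TRUE) {
  if (any(upper <= lower)) stop("normalization range requires upper > lower")
  x <- if (lower_is_best) (upper - raw) / (upper - lower)
       else (raw - lower) / (upper - lower)
  clip01(x)
}

#' Normalize a raw DFIRE2 energy
#'
#' DFIRE2 grows linearly with length; the score is mapped from the range
#' `[-1.971 L, 0]` (best energy to 1). DFIRE2 is a comparison baseline, not
#' one of the 11 combined features.
#'
#' @param raw Raw DFIRE2 score(s).
#' @param L Sequence length (>= 1).
#' @param config A [qprob_config()] list.
#' @return Score(s) in \[0,1\].
#' @export
normalize_dfire2 <- function(raw, L, config = qprob_config()) {
  stopifnot(L >= 1)
  normalize_min_max(raw, config$normalization$dfire_slope * L, 0,
                    lower_is_best = TRUE)
}

#' Normalize a raw RWplus energy
#'
#' Mapped from the range `[-232.6 L, 0]`.
#'
#' @inheritParams normalize_dfire2
#' @return Score(s) in \[0,1\].
#' @export
normalize_rwplus <- function(raw, L, config = qprob_config()) {
  stopifnot(L >= 1)
  normalize_min_max(raw, config$normalization$rwplus_slope * L, 0,
                    lower_is_best = TRUE)
}

#' Normalize a raw RF_CB_SRS_OD energy
#'
#' Mapped from the range `[0.4823 L - 300, 700]`.
#'
#' @inheritParams normalize_dfire2
#' @return Score(s) in \[0,1\].
#' @export
normalize_rf <- function(raw, L, config = qprob_config()) {
  stopifnot(L >= 1)
  nz <- config$normalization
  lower <- nz$rf_lower_slope * L + nz$rf_lower_intercept
  normalize_min_max(raw, lower, nz$rf_upper, lower_is_best = TRUE)
}

#' Normalize a raw Dope energy
#'
#' No published range constants exist for Dope; the default maps from
#' `[dope_slope * L, 0]` with `dope_slope = -1` per residue, a configuration
#' choice documented as such.
#'
#' @inheritParams normalize_dfire2
#' @return Score(s) in \[0,1\].
#' @export
normalize_dope <- function(raw, L, config = qprob_config()) {
  stopifnot(L >= 1)
  normalize_min_max(raw, config$normalization$dope_slope * L, 0,
                    lower_is_best = TRUE)
}

#' Assemble the 11-entry feature vector for one model
#'
#' Computes the seven structural/physicochemical features from the model and
#' its annotations, normalizes the raw external energies, and returns the
#' canonical-order feature vector. Missing externals stay `NA` and are
#' handled downstream by weight renormalization.
#'
#' @param model A `structural_model`.
#' @param sequence A `sequence_record` for the target; its length `N` is the
#'   normalization length and similarity denominator. Defaults to the model's
#'   own length.
#' @param predicted_ss,predicted_sa Optional sequence-based predictions
#'   (`per_residue_annotation` or plain strings). Without them the
#'   corresponding similarity features are `NA`.
#' @param raw_scores Optional one-row slice of a [read_feature_table()] table
#'   (or named list) with raw `rwplus`, `rf_cb_srs_od`, `dope`, `modeleval`.
#' @param dssp Optional [read_dssp()] result; overrides the internal
#'   secondary-structure and surface-area assigners.
#' @param config A [qprob_config()] list.
#' @return Named numeric vector over [qprob_features()], values in \[0,1\] or
#'   `NA`. Errors if fewer than 4 features are computable.
#' @export
assemble_feature_vector <- function(model, sequence = NULL,
                                    predicted_ss = NULL, predicted_sa = NULL,
                                    raw_scores = NULL, dssp = NULL,
                                    config = qprob_config()) {
  stopifnot(inherits(model, "structural_model"))
  N <- if (is.null(sequence)) model$L else sequence$N

  if (!is.null(dssp)) {
    model_ss <- dssp$model_ss
    sasa <- dssp$acc
  } else {
    model_ss <- assign_secondary_structure(model)
    sasa <- NULL
  }
  surf <- residue_surface(model, sasa = sasa, config = config)
  model_sa <- model_exposure_annotation(surf, config$exposure_threshold)

  fv <- stats::setNames(rep(NA_real_, 11), config$features)
  fv["euclidean_compact"] <- euclidean_compact_score(model, config)
  fv["surface_nonpolar"] <- surface_nonpolar_score(surf)
  fv["exposed_mass"] <- exposed_mass_score(surf, config$exposure_threshold)
  fv["exposed_surface"] <- exposed_surface_score(surf)

  if (!is.null(predicted_ss)) {
    if (!inherits(predicted_ss, "per_residue_annotation")) {
      predicted_ss <- per_residue_annotation("predicted_ss", predicted_ss)
    }
    fv["ss_similarity"] <- ss_similarity_score(predicted_ss, model_ss)
    fv["ss_penalty"] <- ss_penalty_score(predicted_ss, model_ss, N)
  }
  if (!is.null(predicted_sa)) {
    if (!inherits(predicted_sa, "per_residue_annotation")) {
      predicted_sa <- per_residue_annotation("predicted_sa", predicted_sa)
    }
    fv["sa_similarity"] <- sa_similarity_score(predicted_sa, model_sa)
  }
  if (!is.null(raw_scores)) {
    raw <- as.list(raw_scores)
    if (!is.null(raw$rwplus) && !is.na(raw$rwplus)) {
      fv["rwplus"] <- normalize_rwplus(raw$rwplus, N, config)
    }
    if (!is.null(raw$rf_cb_srs_od) && !is.na(raw$rf_cb_srs_od)) {
      fv["rf_cb_srs_od"] <- normalize_rf(raw$rf_cb_srs_od, N, config)
    }
    if (!is.null(raw$dope) && !is.na(raw$dope)) {
      fv["dope"] <- normalize_dope(raw$dope, N, config)
    }
    if (!is.null(raw$modeleval) && !is.na(raw$modeleval)) {
      if (raw$modeleval < 0 || raw$modeleval > 1) {
        stop("modeleval score must already lie in [0,1]")
      }
      fv["modeleval"] <- raw$modeleval
    }
  }
  if (sum(!is.na(fv)) < 4) {
    stop("insufficient features: only ", sum(!is.na(fv)),
         " of 11 computable (need >= 4)")
  }
  fv
}
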