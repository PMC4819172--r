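#' Per-residue surface bookkeeping
#'
#' Assembles, per residue: exposed area `S` (from [compute_sasa()] or a DSSP
#' accessibility column), reference total area `ST` (Gly-X-Gly table),
#' nonpolar-only copies `SE` (= `S` for nonpolar residues else 0) and `STN`
#' (= `ST` for nonpolar residues else 0), and residue mass `Mass` (Da).
#' Nonstandard residues are mapped to their closest standard residue with a
#' warning.
#'
#' @param model A `structural_model`.
#' @param sasa Optional per-residue exposed areas (Angstrom^2); computed via
#'   [compute_sasa()] when omitted.
#' @param config A [qprob_config()] list.
#' @return A `residue_surface`: list of numeric vectors `S`, `ST`, `SE`,
#'   `STN`, `Mass` and character vector `aa` (1-letter codes).
#' @export
residue_surface <- function(model, sasa = NULL,
                            config = qprob_config()) {
  stopifnot(inherits(model, "structural_model"))
  if (is.null(sasa)) {
    sasa <- compute_sasa(model, config$sasa$probe_radius, config$sasa$n_points)
  }
  if (length(sasa) != model$L) {
    stop("sasa length ", length(sasa), " != residue count ", model$L)
  }
  aa <- residue_one_letter(model$residues$resid)
  ST <- unname(config$reference_areas[aa])
  Mass <- unname(config$residue_masses[aa])
  S <- pmin(unname(sasa), ST)  # lattice noise can nick the reference ceiling
  nonpolar <- aa %in% config$nonpolar_set
  structure(list(S = S, ST = ST, SE = ifelse(nonpolar, S, 0),
                 STN = ifelse(nonpolar, ST, 0), Mass = Mass, aa = aa,
                 nonpolar = nonpolar),
            class = "residue_surface")
}

#' Euclidean compactness score
#'
#' Mean pairwise CA-CA distance over all residue pairs, divided by a
#' length-dependent reference distance `D_ref(L) = c * L^(1/3) * s` (the
#' radius-of-gyration scaling law; defaults c = 5.54 A, s = 2) and clipped
#' to \[0,1\]. Higher means less compact.
#'
#' @param model A `structural_model` with L >= 2.
#' @param config A [qprob_config()] list (`compact_c`, `compact_s`).
#' @return Score in \[0,1\].
#' @export
euclidean_compact_score <- function(model, config = qprob_config()) {
  stopifnot(inherits(model, "structural_model"))
  if (model$L < 2) stop("compactness needs at least 2 residues")
  xyz <- ca_coords(model)
  mean_d <- mean(stats::dist(xyz))
  d_ref <- config$compact_c * nrow(xyz)^(1 / 3) * config$compact_s
  clip01(mean_d / d_ref)
}

#' Fraction of exposed area contributed by nonpolar residues
#'
#' `sum(SE) / sum(S)`: how much of the model's exposed surface belongs to
#' hydrophobic residues. Well-packed models bury hydrophobics, giving low
#' values.
#'
#' @param surf A `residue_surface`.
#' @return Score in \[0,1\].
#' @export
surface_nonpolar_score <- function(surf) {
  stopifnot(inherits(surf, "residue_surface"))
  total <- sum(surf$S)
  if (total <= 0) {
    warning("model has zero exposed area; nonpolar surface score set to 0",
            call. = FALSE)
    return(0)
  }
  clip01(sum(surf$SE) / total)
}

#' Fraction of mass in exposed residues
#'
#' A residue is exposed when its relative accessibility `S/ST` exceeds
#' `threshold`; the score is the exposed residues' share of total mass.
#'
#' @param surf A `residue_surface`.
#' @param threshold Relative-accessibility exposure cutoff (default 0.25).
#' @return Score in \[0,1\].
#' @export
exposed_mass_score <- function(surf, threshold = 0.25) {
  stopifnot(inherits(surf, "residue_surface"))
  exposed <- (surf$S / surf$ST) > threshold
  sum(surf$Mass[exposed]) / sum(surf$Mass)
}

#' Fraction of reference area exposed
#'
#' `sum(S) / sum(ST)`, clipped to \[0,1\].
#'
#' @param surf A `residue_surface`.
#' @return Score in \[0,1\].
#' @export
exposed_surface_score <- function(surf) {
  stopifnot(inherits(surf, "residue_surface"))
  clip01(sum(surf$S) / sum(surf$ST))
}

# Positions where two annotations are both non-NA.
comparable_positions <- function(a, b) {
  if (length(a) != length(b)) {
    stop("annotation lengths differ (", length(a), " vs ", length(b), ")")
  }
  which(!is.na(unclass(a)) & !is.na(unclass(b)))
}

#' Secondary-structure similarity score
#'
#' Fraction of residues whose sequence-predicted 3-state code equals the
#' model's assigned code. Positions annotated `NA` on either side (chain
#' breaks, unresolved residues) are excluded from numerator and denominator.
#'
#' @param predicted,model_ss `per_residue_annotation`s of equal length.
#' @return Score in \[0,1\].
#' @export
ss_similarity_score <- function(predicted, model_ss) {
  idx <- comparable_positions(predicted, model_ss)
  if (length(idx) == 0) stop("no comparable residues")
  mean(unclass(predicted)[idx] == unclass(model_ss)[idx])
}

#' Secondary-structure penalty score
#'
#' `(F_H + F_S) / N` where `F_H` counts residues predicted helix that the
#' model also assigns helix, `F_S` the same for strand, and `N` is the
#' sequence length. Coil agreement earns nothing, so the score rewards
#' realizing the predicted regular structure.
#'
#' @param predicted,model_ss `per_residue_annotation`s of equal length.
#' @param N Sequence length used as denominator; defaults to the annotation
#'   length.
#' @return Score in \[0,1\].
#' @export
ss_penalty_score <- function(predicted, model_ss, N = length(predicted)) {
  if (N <= 0) stop("N must be positive")
  idx <- comparable_positions(predicted, model_ss)
  p <- unclass(predicted)[idx]; m <- unclass(model_ss)[idx]
  f_h <- sum(p == "H" & m == "H")
  f_s <- sum(p == "E" & m == "E")
  (f_h + f_s) / N
}

#' Solvent-accessibility similarity score
#'
#' Fraction of residues whose sequence-predicted 2-state exposure code
#' (`e`/`b`) matches the model's, the latter obtained by thresholding
#' relative accessibility (see [model_exposure_annotation()]).
#'
#' @param predicted_sa,model_sa `per_residue_annotation`s of equal length.
#' @return Score in \[0,1\].
#' @export
sa_similarity_score <- function(predicted_sa, model_sa) {
  idx <- comparable_positions(predicted_sa, model_sa)
  if (length(idx) == 0) stop("no comparable residues")
  mean(unclass(predicted_sa)[idx] == unclass(model_sa)[idx])
}
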