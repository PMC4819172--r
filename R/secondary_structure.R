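# Dihedral angle (degrees, in (-180, 180]) of four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Backbone phi/psi per residue (NA where undefined or atoms missing).
backbone_dihedrals <- function(model) {
  L <- model$L
  get_atom <- function(i, name) {
    sel <- model$atoms$resno == model$residues$resno[i] &
      model$atoms$insert == model$residues$insert[i] &
      model$atoms$elety == name
    if (!any(sel)) return(NULL)
    as.numeric(model$atoms[which(sel)[1], c("x", "y", "z")])
  }
  N <- lapply(seq_len(L), get_atom, "N")
  CA <- lapply(seq_len(L), get_atom, "CA")
  C <- lapply(seq_len(L), get_atom, "C")
  phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1 && !is.null(C[[i - 1]]) && !is.null(N[[i]]) &&
        !is.null(CA[[i]]) && !is.null(C[[i]])) {
      phi[i] <- dihedral(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    }
    if (i < L && !is.null(N[[i]]) && !is.null(CA[[i]]) &&
        !is.null(C[[i]]) && !is.null(N[[i + 1]])) {
      psi[i] <- dihedral(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
    }
  }
  list(phi = phi, psi = psi)
}

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' An internal stand-in for a DSSP run: residues are classified by their
#' phi/psi angles, then run-length filtered. Helix requires phi in
#' \[-100, -30\] and psi in \[-80, -5\] over at least 4 consecutive residues;
#' strand requires phi in \[-180, -40\] and psi in \[50, 180\] or
#' \[-180, -170\] over at least 3; everything else (including residues with
#' missing backbone atoms, which trigger a warning) is coil. When DSSP output
#' is available, prefer [read_dssp()].
#'
#' @param model A `structural_model`. Chains shorter than the run-length
#'   minima come out all coil.
#' @return A `per_residue_annotation` of kind `model_ss`.
#' @export
assign_secondary_structure <- function(model) {
  stopifnot(inherits(model, "structural_model"))
  di <- backbone_dihedrals(model)
  phi <- di$phi; psi <- di$psi
  incomplete <- (is.na(phi) & is.na(psi))
  # interior residues with no dihedral at all lack backbone atoms
  if (any(incomplete[-c(1, model$L)])) {
    warning("residue(s) with missing backbone atoms assigned coil",
            call. = FALSE)
  }
  helix_ok <- !is.na(phi) & !is.na(psi) &
    phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  sheet_ok <- !is.na(phi) & !is.na(psi) & phi >= -180 & phi <= -40 &
    ((psi >= 50 & psi <= 180) | (psi >= -180 & psi <= -170))

  keep_runs <- function(ok, min_len) {
    r <- rle(ok)
    r$values <- r$values & r$lengths >= min_len
    inverse.rle(r)
  }
  states <- rep("C", model$L)
  states[keep_runs(sheet_ok, 3)] <- "E"
  states[keep_runs(helix_ok, 4)] <- "H"  # helix wins where windows overlap
  per_residue_annotation("model_ss", states)
}

#' Two-state exposure annotation from relative accessibility
#'
#' Thresholds each residue's relative accessibility (exposed area over its
#' Gly-X-Gly reference area) to call it exposed (`e`) or buried (`b`).
#'
#' @param surf A `residue_surface` (see [residue_surface()]).
#' @param threshold Relative accessibility above which a residue is exposed
#'   (default 0.25).
#' @return A `per_residue_annotation` of kind `model_sa`.
#' @export
model_exposure_annotation <- function(surf, threshold = 0.25) {
  rel <- surf$S / surf$ST
  per_residue_annotation("model_sa", ifelse(rel > threshold, "e", "b"))
}
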