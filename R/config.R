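#' Canonical feature order
#'
#' The eleven quality features in their fixed canonical order. This order
#' indexes everything downstream: the error statistics (`M_i`, `SD_i`), the
#' combination weights (`W_i`) and the columns of feature tables. It must
#' never be permuted silently.
#'
#' @return Character vector of the 11 feature names.
#' @export
qprob_features <- function() {
  c("rf_cb_srs_od", "ss_similarity", "ss_penalty", "euclidean_compact",
    "surface_nonpolar", "exposed_mass", "exposed_surface", "sa_similarity",
    "rwplus", "modeleval", "dope")
}

#' Published combination weights
#'
#' The fitted weight vector for the 11 canonical features, obtained by
#' coordinate-descent minimization of per-target GDT-TS loss on the CASP9
#' training set. One weight (dope) is negative; the combination is a weighted
#' sum of peak-normalized densities, so negative weights are meaningful.
#'
#' @return Named numeric vector of length 11 in canonical feature order.
#' @seealso [train_weights()] to refit on your own data.
#' @export
qprob_default_weights <- function() {
  w <- c(0.03, 0.09, 0.04, 0.08, 0.08, 0.01, 0.03, 0.10, 0.00, 0.09, -0.02)
  names(w) <- qprob_features()
  w
}

# Average amino-acid residue masses (Da), i.e. free amino acid minus water.
.residue_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

# Maximal per-residue accessible areas (A^2) in an extended Gly-X-Gly
# tripeptide (theoretical values, Tien et al. 2013). Denominators for
# relative accessibility.
.reference_areas <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  E = 223, Q = 225, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 285, Y = 263, V = 174
)

# 3-letter -> 1-letter residue codes, plus common nonstandard mappings.
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.nonstandard_map <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", SEP = "SER", TPO = "THR",
  PTR = "TYR", CSO = "CYS", HYP = "PRO", MLY = "LYS", M3L = "LYS",
  UNK = "GLY"
)

# Van der Waals radii (A) by element for the Shrake-Rupley surface.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                P = 1.80, SE = 1.90)

#' Default configuration
#'
#' All tunable constants in one nested list. Length-dependent normalization
#' ranges for the raw statistical potentials come from linear fits of score
#' against sequence length on a non-redundant structure set: DFIRE2 is mapped
#' from \[-1.971 L, 0\], RWplus from \[-232.6 L, 0\] and RF_CB_SRS_OD from
#' \[0.4823 L - 300, 700\]. The Dope range has no published constants and is
#' a free configuration choice (default lower bound -1.0 L). Remaining knobs
#' cover the internal surface-area and secondary-structure assigners, the
#' scoring grid and the weight-training grid.
#'
#' @param ... Named overrides merged (shallowly, per top-level block) into the
#'   defaults, e.g. `qprob_config(sasa = list(n_points = 2000))`.
#' @return Nested list of configuration blocks.
#' @export
qprob_config <- function(...) {
  cfg <- list(
    features = qprob_features(),
    normalization = list(
      dfire_slope = -1.971,
      rwplus_slope = -232.6,
      rf_lower_slope = 0.4823,
      rf_lower_intercept = -300,
      rf_upper = 700,
      dope_slope = -1.0
    ),
    sasa = list(probe_radius = 1.4, n_points = 960),
    exposure_threshold = 0.25,
    compact_c = 5.54,
    compact_s = 2.0,
    nonpolar_set = c("A", "V", "L", "I", "P", "F", "M", "W", "G", "C"),
    residue_masses = .residue_masses,
    reference_areas = .reference_areas,
    error_model = list(sd_floor = 0.01, min_samples = 10),
    scoring = list(grid_step = 0.001, clip_adjusted = TRUE),
    training = list(w_min = -0.8, w_max = 0.8, w_step = 0.01,
                    max_sweeps = 100, n_restarts = 5,
                    validation_frac = 0.25, min_targets_for_validation = 8),
    evaluation = list(zscore_floor = -2)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

# Map a 3-letter residue name to its standard equivalent, warning on
# nonstandard names. Unknown names fall back to GLY with a warning.
standardize_residue <- function(resid) {
  resid <- toupper(resid)
  out <- resid
  ns <- !(resid %in% names(.aa3to1))
  if (any(ns)) {
    mapped <- .nonstandard_map[resid[ns]]
    unknown <- is.na(mapped)
    if (any(unknown)) {
      warning("unknown residue(s) ", paste(unique(resid[ns][unknown]), collapse = ", "),
              " mapped to GLY", call. = FALSE)
      mapped[unknown] <- "GLY"
    } else {
      warning("nonstandard residue(s) ", paste(unique(resid[ns]), collapse = ", "),
              " mapped to standard equivalents", call. = FALSE)
    }
    out[ns] <- mapped
  }
  out
}

# 3-letter -> 1-letter, standardizing first.
residue_one_letter <- function(resid) {
  unname(.aa3to1[standardize_residue(resid)])
}

clip01 <- function(x) pmin(1, pmax(0, x))
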