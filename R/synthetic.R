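# Place atom D from A-B-C with bond length |CD|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg): the natural extension reference frame.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  theta <- angle * pi / 180
  chi <- -dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-bond * cos(theta),
               bond * sin(theta) * cos(chi),
               bond * sin(theta) * sin(chi))
  c + d_local[1] * bc + d_local[2] * m2 + d_local[3] * n
}

.aa1to3 <- stats::setNames(names(.aa3to1), unname(.aa3to1))

# Assemble a structural_model from backbone atom coordinates.
backbone_model <- function(coords, aa, model_id) {
  L <- length(aa)
  resid3 <- unname(.aa1to3[aa])
  rows <- do.call(rbind, lapply(seq_len(L), function(i) {
    at <- coords[[i]]
    data.frame(elety = names(at),
               element = substr(names(at), 1, 1),
               resid = resid3[i], resno = i, insert = "",
               x = vapply(at, `[`, numeric(1), 1),
               y = vapply(at, `[`, numeric(1), 2),
               z = vapply(at, `[`, numeric(1), 3),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  structure(list(model_id = model_id, atoms = rows,
                 residues = data.frame(resno = seq_len(L), insert = "",
                                       resid = resid3,
                                       stringsAsFactors = FALSE),
                 L = L),
            class = "structural_model")
}

#' Build a polypeptide backbone from dihedral angles
#'
#' Grows an N/CA/C/O backbone residue by residue with ideal bond geometry
#' (N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231 Angstrom; trans peptide
#' bond) and the requested phi/psi angles. The workhorse behind
#' [make_helix()] and other conformational fixtures.
#'
#' @param L Number of residues (>= 1).
#' @param phi,psi Backbone dihedrals in degrees; recycled to length `L`.
#' @param aa Amino-acid sequence (1-letter string or vector); default cycles
#'   through the 20 standard residues.
#' @param model_id Identifier for the resulting model.
#' @return A `structural_model` with N, CA, C, O atoms per residue.
#' @export
make_chain <- function(L, phi = -57, psi = -47, aa = NULL,
                       model_id = "chain") {
  stopifnot(L >= 1)
  phi <- rep_len(phi, L); psi <- rep_len(psi, L)
  if (is.null(aa)) {
    aa <- rep_len(names(.aa1to3), L)
  } else {
    if (length(aa) == 1 && nchar(aa) > 1) aa <- strsplit(aa, "")[[1]]
    aa <- rep_len(toupper(aa), L)
  }
  stopifnot(all(aa %in% names(.aa1to3)))

  coords <- vector("list", L)
  # first residue laid out in the xy-plane
  n1 <- c(0, 0, 0)
  ca1 <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  c1 <- ca1 + 1.525 * c(-cos(ang), sin(ang), 0)
  coords[[1]] <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_len(L)) {
    res <- coords[[i]]
    # carbonyl O opposite the next N across the C-O plane
    res$O <- place_atom(res$N, res$CA, res$C, 1.231, 120.8, psi[i] - 180)
    coords[[i]] <- res[c("N", "CA", "C", "O")]
    if (i < L) {
      n_next <- place_atom(res$N, res$CA, res$C, 1.329, 116.2, psi[i])
      ca_next <- place_atom(res$CA, res$C, n_next, 1.458, 121.7, 180)
      c_next <- place_atom(res$C, n_next, ca_next, 1.525, 111.2, phi[i + 1])
      coords[[i + 1]] <- list(N = n_next, CA = ca_next, C = c_next)
    }
  }
  backbone_model(coords, aa, model_id)
}

#' Ideal alpha-helix fixture
#'
#' A backbone with phi = -57, psi = -47 degrees throughout: CA rise about
#' 1.5 Angstrom per residue, about 100 degrees of twist, CA trace radius
#' about 2.3 Angstrom, consecutive CA-CA distances 3.8 Angstrom.
#'
#' @inheritParams make_chain
#' @return A `structural_model`.
#' @export
make_helix <- function(L, aa = NULL, model_id = "helix") {
  make_chain(L, phi = -57, psi = -47, aa = aa, model_id = model_id)
}

#' Perturbed decoy of a native structure
#'
#' Adds seeded isotropic Gaussian noise to every atom, with per-coordinate
#' SD `rms_target / sqrt(3)` so the expected CA RMSD from the native equals
#' `rms_target`. Larger `rms_target` gives stochastically lower GDT-TS.
#'
#' @param native A `structural_model`.
#' @param rms_target Target CA RMSD in Angstrom (>= 0).
#' @param seed Integer seed.
#' @param model_id Identifier for the decoy.
#' @return A `structural_model`.
#' @export
make_decoy <- function(native, rms_target, seed = 1,
                       model_id = paste0(native$model_id, "_decoy")) {
  stopifnot(inherits(native, "structural_model"), rms_target >= 0)
  decoy <- native
  decoy$model_id <- model_id
  if (rms_target > 0) {
    set.seed(seed)
    n <- nrow(decoy$atoms)
    sd <- rms_target / sqrt(3)
    decoy$atoms$x <- decoy$atoms$x + stats::rnorm(n, 0, sd)
    decoy$atoms$y <- decoy$atoms$y + stats::rnorm(n, 0, sd)
    decoy$atoms$z <- decoy$atoms$z + stats::rnorm(n, 0, sd)
  }
  decoy
}

#' Specification for a synthetic feature dataset
#'
#' Bundles the generator parameters: number of targets and models per
#' target, true-quality range (uniform draw), and per-feature error means
#' and SDs. The defaults emulate a reduced CASP-like training pool: 20
#' targets of 30 models, true GDT-TS uniform on \[0.2, 0.8\], and an error
#' profile in which the ModelEvaluator feature is the least biased and
#' tightest and the compactness score carries the largest bias.
#'
#' @param seed Integer seed.
#' @param n_targets,models_per_target Pool dimensions.
#' @param L Residue count recorded for provenance.
#' @param q_range Length-2 true-quality range inside \[0,1\].
#' @param feature_means,feature_sds Named numeric vectors over
#'   [qprob_features()] (defaults above); SDs must be >= 0.01.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 42, n_targets = 20, models_per_target = 30,
                           L = 50, q_range = c(0.2, 0.8),
                           feature_means = NULL, feature_sds = NULL) {
  feats <- qprob_features()
  mu <- stats::setNames(
    c(0.05, 0.10, -0.05, 0.4119, -0.10, 0.05, 0.10, 0.12, 0.05, -0.0219, 0.03),
    feats)
  sigma <- stats::setNames(
    c(0.15, 0.12, 0.18, 0.15, 0.20, 0.20, 0.18, 0.15, 0.16, 0.08, 0.14),
    feats)
  if (!is.null(feature_means)) mu[names(feature_means)] <- feature_means
  if (!is.null(feature_sds)) sigma[names(feature_sds)] <- feature_sds
  if (any(sigma < 0.01)) stop("feature SDs must be >= 0.01")
  stopifnot(n_targets >= 1, models_per_target >= 1,
            q_range[1] >= 0, q_range[2] <= 1, q_range[1] < q_range[2])
  structure(list(seed = seed, n_targets = n_targets,
                 models_per_target = models_per_target, L = L,
                 q_range = q_range, feature_means = mu, feature_sds = sigma),
            class = "synthetic_spec")
}

#' Generate a synthetic feature dataset
#'
#' Draws, per model, a true quality `R` uniform on the spec's range, then
#' sets each feature to `clip(R + Normal(mu_i, sigma_i), 0, 1)`: every
#' feature is a noisy, possibly biased estimator of the true GDT-TS, which
#' is exactly the assumption of the Gaussian error model. A fixed seed
#' reproduces the dataset bit for bit.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `features` (data frame `target_id`, `model_id`, 11
#'   canonical feature columns) and `truths` (`target_id`, `model_id`,
#'   `gdtts`).
#' @export
make_feature_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  feats <- qprob_features()
  n <- spec$n_targets * spec$models_per_target
  target_id <- rep(sprintf("T%04d", seq_len(spec$n_targets)),
                   each = spec$models_per_target)
  model_id <- paste0(target_id, "_M",
                     sprintf("%03d", rep(seq_len(spec$models_per_target),
                                         times = spec$n_targets)))
  R <- stats::runif(n, spec$q_range[1], spec$q_range[2])
  fmat <- vapply(feats, function(f) {
    clip01(R + stats::rnorm(n, spec$feature_means[f], spec$feature_sds[f]))
  }, numeric(n))
  features <- data.frame(target_id = target_id, model_id = model_id,
                         fmat, stringsAsFactors = FALSE)
  truths <- data.frame(target_id = target_id, model_id = model_id,
                       gdtts = R, stringsAsFactors = FALSE)
  list(features = features, truths = truths)
}

#' Write a synthetic dataset as TSV files
#'
#' Emits `features.tsv` (`model_id`, `target_id`, 11 canonical feature
#' columns) and `truths.tsv` (`target_id`, `model_id`, `gdtts`) in the
#' formats the trainers consume.
#'
#' @param dataset A [make_feature_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset_tsv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truths, file.path(dir, "truths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
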