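# Fixture builders shared by the test files.

# Write PDB text lines to a temp file and return its path.
write_pdb_text <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resid, resno, x, y, z,
                          occ = 1, alt = " ", chain = "A", element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          serial, name4, alt, resid, chain, resno,
          x, y, z, occ, element)
}

# CA-only model from a coordinate matrix (rows = residues).
ca_only_model <- function(xyz, resid = "ALA", model_id = "ca_only") {
  n <- nrow(xyz)
  resid <- rep_len(resid, n)
  lines <- vapply(seq_len(n), function(i) {
    pdb_atom_line(i, "CA", resid[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3],
                  element = "C")
  }, character(1))
  read_pdb(write_pdb_text(c(lines, "END")), model_id = model_id)
}

# Feature table where one feature tracks the truth exactly and the rest are
# uniform noise: the canonical "one perfect feature" training instance.
perfect_feature_dataset <- function(n_targets = 20, models_per_target = 30,
                                    informative = "modeleval", seed = 11) {
  set.seed(seed)
  feats <- qprob_features()
  n <- n_targets * models_per_target
  target_id <- rep(sprintf("T%03d", seq_len(n_targets)),
                   each = models_per_target)
  model_id <- paste0(target_id, "_M",
                     sprintf("%03d", rep(seq_len(models_per_target),
                                         n_targets)))
  truth <- stats::runif(n, 0.1, 0.9)
  fmat <- vapply(feats, function(f) {
    if (f == informative) truth else stats::runif(n)
  }, numeric(n))
  list(features = data.frame(target_id = target_id, model_id = model_id,
                             fmat, stringsAsFactors = FALSE),
       truths = data.frame(target_id = target_id, model_id = model_id,
                           gdtts = truth, stringsAsFactors = FALSE))
}

# Error stats with zero bias and a common SD: scoring then centers each
# density exactly on the feature value.
flat_stats <- function(sd = 0.1, m = 0) {
  st <- qprob_default_stats()
  st$M[] <- m
  st$SD[] <- sd
  st
}
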