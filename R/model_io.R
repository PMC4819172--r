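#' Read a protein structural model from a PDB file
#'
#' Parses ATOM records of a single-chain model into a `structural_model`
#' object. Only the first MODEL block of a multi-model file is used.
#' Alternate locations are resolved per atom by highest occupancy, ties by
#' first appearance. Residues lacking a CA atom are dropped with a warning;
#' HETATM records are ignored.
#'
#' @param path Path to a PDB file.
#' @param model_id Identifier for the model; default the file name without
#'   extension.
#' @return A `structural_model`: list with `model_id`, `atoms` (data frame of
#'   `elety`, `element`, `resid`, `resno`, `insert`, `x`, `y`, `z`),
#'   `residues` (ordered per-residue data frame) and `L` (residue count).
#' @export
read_pdb <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("no residues parsable from ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no residues: file contains no ATOM records")
  structural_model_from_atoms(at, model_id)
}

# Shared constructor from a bio3d-style atom data frame.
structural_model_from_atoms <- function(at, model_id) {
  chains <- unique(at$chain[!is.na(at$chain)])
  if (length(chains) > 1) {
    stop("multi-chain input (chains ", paste(chains, collapse = ","),
         "); quality assessment is single-chain")
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep, per (residue, atom name), the highest-occupancy record;
  # ties broken by file order
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "\r")), ,
           drop = FALSE]

  if (is.null(at$elesy)) at$elesy <- NA_character_
  element <- toupper(at$elesy)
  bad <- is.na(element) | element == ""
  element[bad] <- toupper(substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1))

  atoms <- data.frame(elety = at$elety, element = element, resid = at$resid,
                      resno = at$resno, insert = at$insert,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  # residues ordered by (resno, insertion code)
  atoms <- atoms[order(atoms$resno, atoms$insert), , drop = FALSE]

  rkey <- paste(atoms$resno, atoms$insert, sep = "\r")
  first <- !duplicated(rkey)
  residues <- data.frame(resno = atoms$resno[first],
                         insert = atoms$insert[first],
                         resid = atoms$resid[first],
                         stringsAsFactors = FALSE)
  has_ca <- vapply(seq_len(nrow(residues)), function(i) {
    sel <- atoms$resno == residues$resno[i] & atoms$insert == residues$insert[i]
    any(atoms$elety[sel] == "CA")
  }, logical(1))
  if (any(!has_ca)) {
    warning(sum(!has_ca), " residue(s) without CA dropped", call. = FALSE)
    keep <- paste(residues$resno[has_ca], residues$insert[has_ca], sep = "\r")
    atoms <- atoms[paste(atoms$resno, atoms$insert, sep = "\r") %in% keep, ,
                   drop = FALSE]
    residues <- residues[has_ca, , drop = FALSE]
  }
  if (nrow(residues) == 0) stop("no residues: no residue with a CA atom")
  rownames(atoms) <- NULL
  rownames(residues) <- NULL
  structure(list(model_id = model_id, atoms = atoms, residues = residues,
                 L = nrow(residues)),
            class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat("structural_model '", x$model_id, "': ", x$L, " residues, ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' CA coordinates of a model
#'
#' @param model A `structural_model`.
#' @return L x 3 matrix of CA coordinates (Angstrom), rows in residue order,
#'   rownames the residue numbers (with insertion code appended if any).
#' @export
ca_coords <- function(model) {
  stopifnot(inherits(model, "structural_model"))
  ca <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  ord <- order(ca$resno, ca$insert)
  ca <- ca[ord, , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- paste0(ca$resno, ca$insert)
  m
}

#' One-letter sequence of a model
#' @param model A `structural_model`.
#' @return Character vector of 1-letter codes in residue order.
#' @export
model_sequence <- function(model) {
  residue_one_letter(model$residues$resid)
}

#' Write a model to a minimal PDB file
#'
#' Emits fixed-width ATOM records (first chain "A", occupancy 1.00, B-factor
#' 0.00). Coordinates are written at the PDB's 3-decimal precision, so a
#' write/read round trip preserves coordinates to 0.001 Angstrom.
#'
#' @param model A `structural_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structural_model"))
  a <- model$atoms
  name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  lines <- sprintf("ATOM  %5d %4s %3s A%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   seq_len(nrow(a)), name4, a$resid, a$resno,
                   ifelse(a$insert == "", " ", a$insert),
                   a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a single-record FASTA sequence
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A `sequence_record`: list with `target_id`, `sequence` (uppercase)
#'   and `N` (length).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  if (length(set) > 1) {
    stop("expected a single-record FASTA, found ", length(set), " records")
  }
  seq <- toupper(as.character(set[[1]]))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", seq)) {
    stop("sequence contains letters outside the 20 standard amino acids + X")
  }
  id <- sub("\\s.*", "", names(set)[1])
  structure(list(target_id = id, sequence = seq, N = nchar(seq)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat("sequence_record '", x$target_id, "': N=", x$N, "\n", sep = "")
  invisible(x)
}

#' Per-residue annotation string
#'
#' Constructor/validator for per-residue 3-state secondary structure
#' (`H`/`E`/`C`) or 2-state solvent accessibility (`e` exposed / `b` buried)
#' annotations. `NA` marks residues with no annotation (e.g. chain breaks);
#' these are excluded from similarity numerators and denominators.
#'
#' @param kind One of `"predicted_ss"`, `"model_ss"`, `"predicted_sa"`,
#'   `"model_sa"`.
#' @param states Character vector of single-character states (or a single
#'   string, which is split), `NA` allowed.
#' @return A `per_residue_annotation` (character vector with attributes).
#' @export
per_residue_annotation <- function(kind, states) {
  kind <- match.arg(kind, c("predicted_ss", "model_ss",
                            "predicted_sa", "model_sa"))
  if (length(states) == 1 && !is.na(states) && nchar(states) > 1) {
    states <- strsplit(states, "")[[1]]
  }
  states <- as.character(states)
  alphabet <- if (grepl("_ss$", kind)) c("H", "E", "C") else c("e", "b")
  ok <- is.na(states) | states %in% alphabet
  if (!all(ok)) {
    stop("invalid state(s) ", paste(unique(states[!ok]), collapse = ","),
         " for ", kind, " (alphabet ", paste(alphabet, collapse = ""), ")")
  }
  structure(states, kind = kind, class = "per_residue_annotation")
}

# DSSP 8-state -> 3-state collapse; total over the 8 codes plus blank.
collapse_dssp_code <- function(code) {
  out <- rep("C", length(code))
  out[code %in% c("H", "G", "I")] <- "H"
  out[code %in% c("E", "B")] <- "E"
  out
}

#' Read DSSP output
#'
#' Parses classic DSSP output into a 3-state secondary-structure annotation
#' (8-state codes collapsed: H/G/I to H, E/B to E, everything else C) and
#' per-residue accessible areas. Chain-break records (`!`) become `NA`
#' annotation gaps.
#'
#' @param path Path to a DSSP output file.
#' @return List with `model_ss` (a `per_residue_annotation`) and `acc`
#'   (numeric vector, Angstrom^2, `NA` at gaps).
#' @export
read_dssp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) {
    stop("malformed DSSP file (missing '  #  RESIDUE' header): ", path)
  }
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 38]
  if (length(body) == 0) stop("DSSP file has no residue records: ", path)
  aa <- substr(body, 14, 14)
  ss8 <- substr(body, 17, 17)
  acc <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  gap <- aa == "!"
  states <- collapse_dssp_code(ss8)
  states[gap] <- NA
  acc[gap] <- NA
  list(model_ss = per_residue_annotation("model_ss", states), acc = acc)
}

#' Read a raw external feature table
#'
#' Reads a tab-separated table of raw (un-normalized) external scores with a
#' header row. Recognized columns: `model_id`, `dfire2`, `rwplus`,
#' `rf_cb_srs_od`, `dope`, `modeleval`. Unknown columns are dropped with a
#' warning; empty cells become missing values.
#'
#' @param path Path to the TSV file.
#' @return Data frame keyed by `model_id` with the recognized score columns
#'   (all present, `NA` where absent).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = c("", "NA"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"model_id" %in% names(tab)) stop("feature table lacks a model_id column")
  known <- c("model_id", "dfire2", "rwplus", "rf_cb_srs_od", "dope", "modeleval")
  extra <- setdiff(names(tab), known)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  tab <- tab[, intersect(known, names(tab)), drop = FALSE]
  if (anyDuplicated(tab$model_id)) {
    stop("duplicate model_id in feature table: ",
         paste(unique(tab$model_id[duplicated(tab$model_id)]), collapse = ", "))
  }
  for (col in setdiff(known, names(tab))) tab[[col]] <- NA_real_
  tab <- tab[, known, drop = FALSE]
  for (col in setdiff(known, "model_id")) tab[[col]] <- as.numeric(tab[[col]])
  if (!is.null(tab$modeleval)) {
    bad <- !is.na(tab$modeleval) & (tab$modeleval < 0 | tab$modeleval > 1)
    if (any(bad)) stop("modeleval scores must already lie in [0,1]")
  }
  tab
}
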