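test_that("read_pdb parses a hand-written model and applies the dialect rules", {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", 1, 1.458, 0, 0, element = "C"),
    pdb_atom_line(3, "CA", "GLY", 2, 4.1, 1.2, 0.5, element = "C"),
    pdb_atom_line(4, "CA", "SER", 3, 7.9, 2.0, 1.1, element = "C"),
    "END")
  m <- read_pdb(write_pdb_text(lines))
  expect_s3_class(m, "structural_model")
  expect_equal(m$L, 3)
  expect_equal(unname(ca_coords(m)[1, ]), c(1.458, 0, 0))
  expect_equal(model_sequence(m), c("A", "G", "S"))

  # only the first MODEL block is read
  two_models <- c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "ALA", 1, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "CA", "GLY", 2, 3.8, 0, 0, element = "C"),
    pdb_atom_line(3, "CA", "SER", 3, 7.6, 0, 0, element = "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", 1, 99, 0, 0, element = "C"),
    pdb_atom_line(2, "CA", "GLY", 2, 102.8, 0, 0, element = "C"),
    pdb_atom_line(3, "CA", "SER", 3, 106.6, 0, 0, element = "C"),
    "ENDMDL", "END")
  m2 <- read_pdb(write_pdb_text(two_models))
  expect_equal(m2$L, 3)
  expect_equal(unname(ca_coords(m2)[1, 1]), 0)

  # HETATM-only file has no parseable residues
  het <- c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
           "END")
  expect_error(read_pdb(write_pdb_text(het)), "no residues|no ATOM")
})

test_that("read_pdb resolves altlocs by occupancy and rejects multi-chain input", {
  alt <- c(
    pdb_atom_line(1, "CA", "ALA", 1, 1, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", 1, 2, 0, 0, occ = 0.6, alt = "B"),
    pdb_atom_line(3, "CA", "GLY", 2, 5, 0, 0),
    pdb_atom_line(4, "CA", "SER", 3, 9, 0, 0),
    "END")
  m <- read_pdb(write_pdb_text(alt))
  expect_equal(unname(ca_coords(m)[1, 1]), 2)  # highest occupancy wins

  two_chains <- c(
    pdb_atom_line(1, "CA", "ALA", 1, 0, 0, 0, chain = "A"),
    pdb_atom_line(2, "CA", "GLY", 2, 3.8, 0, 0, chain = "B"),
    "END")
  expect_error(read_pdb(write_pdb_text(two_chains)), "multi-chain")
})

test_that("residues without CA are dropped with a warning", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", 1, 0, 0, 0),
    pdb_atom_line(2, "N", "GLY", 2, 3.8, 0, 0, element = "N"),
    pdb_atom_line(3, "CA", "SER", 3, 7.6, 0, 0),
    "END")
  expect_warning(m <- read_pdb(write_pdb_text(lines)), "without CA")
  expect_equal(m$L, 2)
  expect_equal(m$residues$resno, c(1, 3))
})

test_that("PDB write/read round trip preserves CA coordinates to 3 decimals", {
  h <- make_helix(10)
  path <- tempfile(fileext = ".pdb")
  write_pdb(h, path)
  back <- read_pdb(path)
  expect_true(max(abs(ca_coords(back) - ca_coords(h))) <= 5e-4 + 1e-9)
  expect_equal(ca_coords(back), round(ca_coords(h), 3), tolerance = 1e-12)
})

test_that("read_fasta handles wrapping, case, and rejects bad files", {
  p1 <- tempfile(fileext = ".fasta"); writeLines(c(">t", "ACDEF"), p1)
  r1 <- read_fasta(p1)
  expect_equal(r1$N, 5)
  expect_equal(r1$target_id, "t")

  p2 <- tempfile(fileext = ".fasta"); writeLines(c(">t", "ac", "def"), p2)
  expect_equal(read_fasta(p2)$sequence, "ACDEF")

  p3 <- tempfile(fileext = ".fasta"); writeLines(character(0), p3)
  expect_error(read_fasta(p3))

  p4 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "EFG"), p4)
  expect_error(read_fasta(p4), "2")
})

test_that("DSSP collapse is total over the 8 codes and the reader handles gaps", {
  codes8 <- c("H", "G", "I", "E", "B", "T", "S", " ", "P")
  collapsed <- qprob:::collapse_dssp_code(codes8)
  expect_true(all(collapsed %in% c("H", "E", "C")))
  expect_equal(collapsed[1:5], c("H", "H", "H", "E", "E"))
  expect_equal(collapsed[6:9], rep("C", 4))

  dssp <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
    "    1    1 A A  H >         0   0  105",
    "    2    2 A G  G <         0   0   42",
    "    3        !              0   0    0",
    "    4    4 A S              0   0   77")
  path <- tempfile(fileext = ".dssp"); writeLines(dssp, path)
  res <- read_dssp(path)
  st <- unclass(res$model_ss)
  expect_equal(st[1:2], c("H", "H"))   # G collapses to H
  expect_true(is.na(st[3]))            # chain break
  expect_equal(st[4], "C")             # blank code
  expect_equal(res$acc[c(1, 2, 4)], c(105, 42, 77))
  expect_true(is.na(res$acc[3]))

  bad <- tempfile(); writeLines("not dssp at all", bad)
  expect_error(read_dssp(bad), "malformed")
})

test_that("read_feature_table enforces ids and treats empty cells as missing", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("model_id\tdfire2\trwplus",
               "m1\t-120.5\t-9000",
               "m2\t-130.0\t"), tsv)
  tab <- read_feature_table(tsv)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$dfire2, c(-120.5, -130.0))
  expect_true(is.na(tab$rwplus[2]))
  expect_true(all(is.na(tab$dope)))  # absent column materialized as missing

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("model_id\tdfire2", "m1\t-1", "m1\t-2"), dup)
  expect_error(read_feature_table(dup), "duplicate")

  extra <- tempfile(fileext = ".tsv")
  writeLines(c("model_id\tdfire2\tmystery", "m1\t-1\t9"), extra)
  expect_warning(read_feature_table(extra), "unknown column")
})

test_that("per_residue_annotation validates alphabets", {
  expect_error(per_residue_annotation("predicted_ss", "HEX"), "invalid state")
  a <- per_residue_annotation("predicted_sa", "ebbe")
  expect_length(unclass(a), 4)
  expect_error(per_residue_annotation("model_sa", c("e", "H")), "invalid")
})
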