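test_that("dihedral-window secondary structure classifies ideal conformations", {
  h <- make_helix(12)
  ss_h <- unclass(assign_secondary_structure(h))
  expect_true(all(ss_h[2:11] == "H"))  # interior all helix

  ext <- make_chain(12, phi = -120, psi = 130)
  ss_e <- unclass(assign_secondary_structure(ext))
  expect_true(all(ss_e[2:11] == "E"))

  # 4 residues: only 2 interior dihedral pairs, below both run-length minima
  frag <- make_chain(4, phi = -57, psi = -47)
  expect_equal(as.character(assign_secondary_structure(frag)), rep("C", 4))
})

test_that("Shrake-Rupley area is exact for an isolated sphere and monotone under occlusion", {
  one <- ca_only_model(matrix(c(0, 0, 0), 1, 3))
  a1 <- unname(compute_sasa(one))
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)

  two <- ca_only_model(matrix(c(0, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE))
  a2 <- compute_sasa(two)
  expect_lte(sum(a2), a1 + 1e-9)  # coincident atoms contest the surface

  # tangent pair: each loses some area, total below two free spheres
  pair <- ca_only_model(matrix(c(0, 0, 0, 3.4, 0, 0), 2, 3, byrow = TRUE))
  ap <- compute_sasa(pair)
  expect_lt(sum(ap), 2 * a1)
  expect_gt(sum(ap), a1)
})

test_that("sphere-point sampling converges: 960 vs 10000 points within 5% per atom", {
  set.seed(402)
  xyz <- matrix(stats::rnorm(30, sd = 2.5), 10, 3)
  m <- ca_only_model(xyz)
  coarse <- compute_sasa(m, n_points = 960)
  dense <- compute_sasa(m, n_points = 10000)
  nz <- dense > 1
  expect_true(all(abs(coarse[nz] - dense[nz]) / dense[nz] < 0.05))
})

test_that("SASA is invariant under rigid motion within lattice tolerance", {
  h <- make_helix(15)
  s0 <- compute_sasa(h)
  s1 <- compute_sasa(rigid_transform_model(h))
  expect_lt(abs(sum(s1) - sum(s0)) / sum(s0), 0.005)
  expect_lt(max(abs(s1 - s0)) / max(s0), 0.02)  # per-residue lattice noise
})

test_that("reference areas and nonpolar bookkeeping follow the residue tables", {
  cfg <- qprob_config()
  m <- ca_only_model(matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3,
                            byrow = TRUE),
                     resid = c("ALA", "ASP", "MSE"))
  expect_warning(surf <- residue_surface(m, sasa = c(50, 60, 70)),
                 "nonstandard")
  expect_equal(surf$ST[1], unname(cfg$reference_areas["A"]))
  expect_equal(surf$STN[1], surf$ST[1])   # ALA nonpolar
  expect_equal(surf$STN[2], 0)            # ASP polar
  expect_equal(surf$ST[3], unname(cfg$reference_areas["M"]))  # MSE -> MET
  expect_true(all(surf$S <= surf$ST + 1e-9))
  expect_true(all(surf$SE <= surf$S + 1e-9))
})

test_that("euclidean compact score matches the hand-computed reference", {
  two <- ca_only_model(matrix(c(0, 0, 0, 11.08, 0, 0), 2, 3, byrow = TRUE))
  d_ref <- 5.54 * 2^(1 / 3) * 2
  expect_equal(euclidean_compact_score(two), 11.08 / d_ref, tolerance = 1e-12)
  expect_equal(round(euclidean_compact_score(two), 3), 0.794)

  near0 <- ca_only_model(matrix(1e-9 * seq_len(6), 2, 3))
  expect_equal(euclidean_compact_score(near0), 0, tolerance = 1e-6)

  # fully extended 100-residue chain: mean pairwise distance of a 3.8 A line
  # is 3.8 * (L+1)/3 = 127.9 >> D_ref = 51.4, so the score clips at 1
  line <- ca_only_model(cbind(3.8 * (0:99), 0, 0))
  expect_equal(euclidean_compact_score(line), 1)

  expect_error(euclidean_compact_score(ca_only_model(matrix(0, 1, 3))),
               "at least 2")
})

test_that("compact score is rigid-invariant and monotone under uniform scaling", {
  h <- make_helix(20)
  s0 <- euclidean_compact_score(h)
  expect_equal(euclidean_compact_score(rigid_transform_model(h)), s0,
               tolerance = 1e-9)
  scaled <- h
  scaled$atoms[, c("x", "y", "z")] <- scaled$atoms[, c("x", "y", "z")] * 1.5
  expect_gt(euclidean_compact_score(scaled), s0)
})

test_that("surface ratio scores follow their definitions", {
  surf <- structure(list(S = c(10, 30), ST = c(40, 40), SE = c(10, 0),
                         STN = c(40, 0), Mass = c(100, 100),
                         aa = c("A", "D"), nonpolar = c(TRUE, FALSE)),
                    class = "residue_surface")
  expect_equal(surface_nonpolar_score(surf), 0.25)
  expect_equal(exposed_surface_score(surf), 0.5)
  # S/ST = 0.25 and 0.75: only the second residue clears the 0.25 threshold
  expect_equal(exposed_mass_score(surf), 0.5)

  all_np <- surf; all_np$SE <- surf$S
  expect_equal(surface_nonpolar_score(all_np), 1)
  none_np <- surf; none_np$SE <- c(0, 0)
  expect_equal(surface_nonpolar_score(none_np), 0)

  buried <- surf; buried$S <- c(0, 0); buried$SE <- c(0, 0)
  expect_warning(expect_equal(surface_nonpolar_score(buried), 0),
                 "zero exposed")
  expect_equal(exposed_surface_score(buried), 0)
  expect_equal(exposed_mass_score(buried), 0)
})

test_that("similarity and penalty scores count matches correctly", {
  pss <- function(s) per_residue_annotation("predicted_ss", s)
  mss <- function(s) per_residue_annotation("model_ss", s)
  expect_equal(ss_similarity_score(pss("HHEC"), mss("HHEC")), 1)
  expect_equal(ss_similarity_score(pss("HHEC"), mss("CCHE")), 0)
  expect_equal(ss_similarity_score(pss("HHCC"), mss("HECC")), 0.75)

  # gaps drop out of numerator and denominator
  gap <- mss(c("H", NA, "C", "C"))
  expect_equal(ss_similarity_score(pss("HHCC"), gap), 1)

  expect_equal(ss_penalty_score(pss(strrep("H", 10)), mss(strrep("H", 10))), 1)
  expect_equal(ss_penalty_score(pss(strrep("C", 10)), mss(strrep("H", 10))), 0)
  expect_equal(ss_penalty_score(pss("HHEEECCCCC"), mss("HHEEEHHHHH")), 0.5)

  psa <- function(s) per_residue_annotation("predicted_sa", s)
  msa <- function(s) per_residue_annotation("model_sa", s)
  expect_equal(sa_similarity_score(psa("eebb"), msa("eebb")), 1)
  expect_equal(sa_similarity_score(psa("eebb"), msa("bbee")), 0)
  expect_equal(sa_similarity_score(psa("eebb"), msa("ebbb")), 0.75)
  expect_error(sa_similarity_score(psa(c(NA, NA)), msa(c("e", NA))),
               "no comparable")
})

test_that("all structural features stay in [0,1] across random decoys", {
  native <- make_helix(18)
  for (seed in 1:5) {
    decoy <- make_decoy(native, rms_target = seed * 2, seed = seed)
    surf <- residue_surface(decoy)
    vals <- c(euclidean_compact_score(decoy),
              surface_nonpolar_score(surf),
              exposed_mass_score(surf),
              exposed_surface_score(surf))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})
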