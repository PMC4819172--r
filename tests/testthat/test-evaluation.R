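test_that("gdt_ts is 1 for identity and rigid transforms of the native", {
  h <- make_helix(20)
  expect_equal(gdt_ts(h, h), 1.0)
  moved <- rigid_transform_model(h)
  expect_equal(gdt_ts(moved, h), 1.0, tolerance = 1e-6)
})

test_that("gdt_ts scores a half-displaced toy model at 0.5", {
  set.seed(12)
  native <- ca_only_model(matrix(stats::rnorm(30, sd = 2), 10, 3))
  model <- native
  # displace residues 6..10 by 200 A: they can never re-enter any threshold
  idx <- model$atoms$resno >= 6
  model$atoms$x[idx] <- model$atoms$x[idx] + 200
  expect_equal(gdt_ts(model, native), 0.5)
  # and the exhaustive oracle agrees
  oracle <- gdt_exhaustive_oracle(ca_coords(model), ca_coords(native))
  expect_equal(gdt_ts(model, native), oracle)
})

test_that("gdt_ts equals the exhaustive subset oracle on small decoys", {
  native <- make_helix(8)
  for (seed in 1:6) {
    decoy <- make_decoy(native, rms_target = seed, seed = seed)
    got <- gdt_ts(decoy, native)
    oracle <- gdt_exhaustive_oracle(ca_coords(decoy), ca_coords(native))
    expect_equal(got, oracle, info = paste("decoy seed", seed))
  }
})

test_that("the large-chain heuristic never overshoots and stays near the optimum", {
  native <- make_helix(8)
  for (seed in 1:6) {
    decoy <- make_decoy(native, rms_target = seed, seed = seed)
    heur <- gdt_ts(decoy, native, exact_n = 0)  # force the fragment search
    oracle <- gdt_exhaustive_oracle(ca_coords(decoy), ca_coords(native))
    expect_lte(heur, oracle + 1e-12)
    expect_gte(heur, oracle - 0.1)  # undershoot bounded on small instances
  }
})

test_that("gdt_ts requires at least 3 common residues and uses the native denominator", {
  a <- ca_only_model(matrix(stats::rnorm(6), 2, 3))
  expect_error(gdt_ts(a, a), ">= 3 common")

  # model missing residues: fractions are over the native count
  native <- make_helix(10)
  partial <- native
  keep <- partial$atoms$resno <= 5
  partial$atoms <- partial$atoms[keep, , drop = FALSE]
  partial$residues <- partial$residues[partial$residues$resno <= 5, ,
                                       drop = FALSE]
  partial$L <- 5
  expect_equal(gdt_ts(partial, native), 0.5)
})

test_that("kabsch superposition agrees with bio3d's fit", {
  set.seed(8)
  P <- matrix(stats::rnorm(30), 10, 3)
  ang <- c(0.3, 0.8, -0.5)
  Q <- rigid_transform_model(
    ca_only_model(P))
  Qm <- ca_coords(Q)
  fit <- qprob:::kabsch_fit(P, Qm)
  moved <- qprob:::kabsch_apply(fit, P)
  expect_lt(max(abs(moved - Qm)), 1e-3)  # PDB write rounding only
  xyz_fit <- bio3d::fit.xyz(fixed = as.numeric(t(Qm)),
                            mobile = as.numeric(t(P)),
                            fixed.inds = 1:30, mobile.inds = 1:30)
  expect_lt(max(abs(matrix(xyz_fit, ncol = 3, byrow = TRUE) - moved)), 1e-3)
})

test_that("correlations hit their closed forms and kendall matches the O(n^2) oracle", {
  x <- 1:10
  expect_equal(spearman_cor(x, x), 1)
  expect_equal(kendall_cor(x, x), 1)
  expect_equal(spearman_cor(x, rev(x)), -1)
  expect_equal(kendall_cor(x, rev(x)), -1)

  set.seed(66)
  for (rep in 1:20) {
    a <- stats::runif(20)
    b <- stats::runif(20)
    expect_equal(kendall_cor(a, b), tau_b_oracle(a, b), tolerance = 1e-12)
  }
  # tie-corrected (tau-b) on tied data
  a <- c(1, 1, 2, 3, 3, 4)
  b <- c(2, 1, 1, 3, 4, 4)
  expect_equal(kendall_cor(a, b), tau_b_oracle(a, b), tolerance = 1e-12)

  expect_warning(expect_true(is.na(pearson_cor(rep(1, 5), 1:5))), "constant")
})

test_that("spearman equals pearson on ranks for tie-free data", {
  set.seed(4)
  a <- sample(100, 15)
  b <- sample(100, 15)
  expect_equal(spearman_cor(a, b), pearson_cor(rank(a), rank(b)),
               tolerance = 1e-12)
})

test_that("gdt_loss follows its definition including ties", {
  expect_equal(gdt_loss(c(0.9, 0.1), c(0.8, 0.3)), 0)
  expect_equal(gdt_loss(c(0.1, 0.9), c(0.9, 0.6)), 0.3)
  expect_equal(gdt_loss(0.4, 0.7), 0)  # single model is best and picked
  # tie: first by model_id order, not the optimistic pick
  expect_equal(gdt_loss(c(0.5, 0.5), c(0.2, 0.9), model_ids = c("a", "b")),
               0.7)
  expect_equal(gdt_loss(c(0.5, 0.5), c(0.9, 0.2), model_ids = c("b", "a")),
               0.7)
})

test_that("wilcoxon wrapper drops zeros and matches exact enumeration", {
  expect_warning(p <- wilcoxon_signed_rank(1:10, 1:10), "all differences")
  expect_equal(p, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 5), c(1.5, 1, 2, 5)),
               "too few")

  set.seed(123)
  for (rep in 1:5) {
    a <- stats::runif(10)
    b <- stats::runif(10)
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got, wilcoxon_enum_oracle(a - b), tolerance = 1e-12)
  }
})

test_that("z-score sums standardize each target across methods", {
  sel <- matrix(0.5, nrow = 4, ncol = 3,
                dimnames = list(NULL, c("qa1", "qa2", "qa3")))
  expect_equal(zscore_top1(sel), c(qa1 = 0, qa2 = 0, qa3 = 0))

  # two methods: symmetric +/- 1/sqrt(2) per target before flooring
  sel2 <- cbind(best = c(0.8, 0.7), worse = c(0.6, 0.5))
  z <- zscore_top1(sel2)
  expect_equal(unname(z["best"]), 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(z["worse"]), -2 / sqrt(2), tolerance = 1e-12)

  # seeded 5 methods x 10 targets vs direct recomputation
  set.seed(55)
  m <- matrix(stats::runif(50), 10, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  direct <- colSums(t(apply(m, 1, function(r) {
    pmax((r - mean(r)) / stats::sd(r), -2)
  })))
  expect_equal(zscore_top1(m), direct, tolerance = 1e-12)

  # floor applies: one far outlier among 10 methods exceeds z = -2
  row <- c(rep(1, 9), 0)
  sel3 <- matrix(row, nrow = 2, ncol = 10, byrow = TRUE,
                 dimnames = list(NULL, paste0("q", 1:10)))
  raw_z <- (0 - mean(row)) / stats::sd(row)
  expect_lt(raw_z, -2)
  expect_equal(unname(zscore_top1(sel3)["q10"]), -4, tolerance = 1e-9)
})

test_that("evaluate_dataset summarizes per-target metrics and handles edge targets", {
  preds <- data.frame(
    target_id = c("T1", "T1", "T1", "T2", "T2", "T3"),
    model_id = c("a", "b", "c", "a", "b", "a"),
    score = c(0.9, 0.5, 0.1, 0.2, 0.8, 0.4))
  truths <- data.frame(
    target_id = preds$target_id, model_id = preds$model_id,
    gdtts = c(0.8, 0.6, 0.2, 0.9, 0.3, 0.5))
  res <- evaluate_dataset(preds, truths)
  expect_equal(res$summary$n_targets, 3)
  expect_equal(res$per_target$loss, c(0, 0.6, 0))
  # T3 has one model: excluded from correlation averages, counted in loss
  expect_true(is.na(res$per_target$pearson[3]))
  expect_equal(res$summary$ave_loss, 0.2)
  expect_equal(res$summary$ave_corr,
               mean(res$per_target$pearson[1:2]))
  expect_error(evaluate_dataset(preds[0, ], truths), "no predictions")
})
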