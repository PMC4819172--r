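# Kabsch superposition: rotation R and translation that best fit mobile
# points P onto fixed points Q (least-squares), with reflection correction.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

# Apply a kabsch_fit to arbitrary points.
kabsch_apply <- function(fit, X) {
  sweep(sweep(X, 2, fit$cp) %*% t(fit$R), 2, fit$cq, "+")
}

# Count of model CAs within `thr` of their native counterparts after
# superposing on the rows `idx`.
superpose_count <- function(mob, ref, idx, thr) {
  fit <- kabsch_fit(mob[idx, , drop = FALSE], ref[idx, , drop = FALSE])
  moved <- kabsch_apply(fit, mob)
  d <- sqrt(rowSums((moved - ref)^2))
  list(within = d <= thr, count = sum(d <= thr))
}

# Exact within-threshold optimum by enumerating every residue subset of
# size >= 3 as the superposition set. Only feasible for small chains.
gdt_threshold_count_exact <- function(mob, ref, thr) {
  n <- nrow(mob)
  best <- 0L
  for (size in 3:n) {
    combs <- utils::combn(n, size)
    for (k in seq_len(ncol(combs))) {
      best <- max(best, superpose_count(mob, ref, combs[, k], thr)$count)
      if (best == n) return(best)
    }
  }
  best
}

# Best within-threshold count via seeded iterative superposition. Seeds:
# every contiguous fragment of the given lengths plus the full common set.
# Each seed is refined two ways: iterative inclusion (refit on all
# in-threshold residues) and iterative exclusion (drop the farthest residue
# from the current fit set), both bounded.
gdt_threshold_count <- function(mob, ref, thr, frag_lengths = c(3, 5, 7),
                                max_rounds = 10) {
  n <- nrow(mob)
  seeds <- list(seq_len(n))
  for (fl in frag_lengths) {
    if (fl <= n) {
      for (s in seq_len(n - fl + 1)) seeds[[length(seeds) + 1]] <- s:(s + fl - 1)
    }
  }
  best <- 0L
  for (seed in seeds) {
    # inclusion refinement
    idx <- seed
    for (round in seq_len(max_rounds)) {
      res <- superpose_count(mob, ref, idx, thr)
      best <- max(best, res$count)
      inc <- which(res$within)
      if (length(inc) < 3 || identical(inc, idx)) break
      idx <- inc
    }
    # exclusion refinement: peel the worst-fitting residue and refit
    idx <- seed
    while (length(idx) > 3) {
      fit <- kabsch_fit(mob[idx, , drop = FALSE], ref[idx, , drop = FALSE])
      moved <- kabsch_apply(fit, mob)
      d <- sqrt(rowSums((moved - ref)^2))
      best <- max(best, sum(d <= thr))
      idx <- idx[-which.max(d[idx])]
    }
    if (best == n) break  # cannot improve further
  }
  best
}

#' GDT-TS of a model against its native structure
#'
#' The Global Distance Test Total Score: the mean, over distance thresholds
#' 1, 2, 4 and 8 Angstrom, of the largest fraction of common CA atoms that
#' can be superposed within the threshold. Chains with at most `exact_n`
#' common residues are solved exactly by enumerating every superposition
#' subset of size >= 3. Larger chains use a search heuristic: Kabsch
#' superpositions seeded from every contiguous fragment of length 3, 5 and
#' 7 plus the full common set, each refined by iterative inclusion of
#' in-threshold residues (up to 10 rounds) and by iterative exclusion of
#' the worst-fitting residue. The heuristic can undershoot the exact
#' optimum slightly (never overshoot); the test suite bounds the gap on
#' small instances. Residues are matched by residue number (and insertion
#' code); fractions are over the native residue count.
#'
#' @param model,native `structural_model`s with >= 3 common CA residues.
#' @param thresholds Distance thresholds in Angstrom (default `c(1,2,4,8)`).
#' @param exact_n Largest common-residue count solved exactly (default 10;
#'   the enumeration cost grows as 2^n). Set to 0 to force the heuristic.
#' @return GDT-TS in \[0,1\].
#' @export
gdt_ts <- function(model, native, thresholds = c(1, 2, 4, 8), exact_n = 10) {
  stopifnot(inherits(model, "structural_model"),
            inherits(native, "structural_model"))
  mc <- ca_coords(model); nc <- ca_coords(native)
  common <- intersect(rownames(mc), rownames(nc))
  if (length(common) < 3) {
    stop("need >= 3 common CA residues, found ", length(common))
  }
  # preserve native residue order for contiguous fragment seeding
  common <- rownames(nc)[rownames(nc) %in% common]
  mob <- mc[common, , drop = FALSE]
  ref <- nc[common, , drop = FALSE]
  counter <- if (nrow(mob) <= exact_n) gdt_threshold_count_exact
             else gdt_threshold_count
  fractions <- vapply(thresholds, function(thr) {
    counter(mob, ref, thr) / nrow(nc)
  }, numeric(1))
  mean(fractions)
}

#' Correlation measures between predicted and true qualities
#'
#' Thin wrappers over [stats::cor()]: Pearson on the raw values, Spearman on
#' ranks, Kendall with tie correction (tau-b). Constant input makes the
#' coefficient undefined; it is returned as `NA` with a warning so callers
#' can exclude it from averages.
#'
#' @param pred,true Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1,1\], or `NA` for degenerate input.
#' @export
pearson_cor <- function(pred, true) .safe_cor(pred, true, "pearson")

#' @rdname pearson_cor
#' @export
spearman_cor <- function(pred, true) .safe_cor(pred, true, "spearman")

#' @rdname pearson_cor
#' @export
kendall_cor <- function(pred, true) .safe_cor(pred, true, "kendall")

.safe_cor <- function(pred, true, method) {
  if (length(pred) != length(true)) stop("length mismatch")
  if (length(pred) < 2) stop("need >= 2 pairs")
  if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    warning("constant input; ", method, " correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pred, true, method = method)
}

#' GDT-TS loss of a predicted ranking
#'
#' The true GDT-TS of the best model in the pool minus that of the model the
#' predictor ranks first. Predicted ties resolve to the first model in
#' `model_id` order (no optimistic tie-breaking).
#'
#' @param pred Predicted quality scores.
#' @param true True GDT-TS scores.
#' @param model_ids Optional ids used to fix the tie order; default the
#'   input order.
#' @return Loss >= 0 (0 when the pick is a true best).
#' @export
gdt_loss <- function(pred, true, model_ids = NULL) {
  if (length(pred) != length(true)) stop("length mismatch")
  if (length(pred) == 0) stop("empty pool")
  if (!is.null(model_ids)) {
    ord <- order(model_ids)
    pred <- pred[ord]; true <- true[ord]
  }
  max(true) - true[which.max(pred)]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired metric lists. Zero differences are dropped; with
#' up to 25 non-zero differences and no tied magnitudes the exact null
#' distribution is used, otherwise the normal approximation with continuity
#' correction.
#'
#' @param a,b Paired numeric vectors (>= 6 non-zero differences).
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences zero; p = 1", call. = FALSE)
    return(1)
  }
  if (length(d) < 6) stop("too few pairs: ", length(d), " non-zero differences")
  ties <- any(duplicated(abs(d)))
  use_exact <- length(d) <= 25 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = TRUE))
  unname(res$p.value)
}

#' Summed top-1 Z-scores across targets
#'
#' CASP-style comparison of model-selection ability: per target, each
#' method's selected-model true score is standardized against the mean and
#' SD of all methods' selections for that target, floored (default at -2),
#' and the per-target Z-scores are summed per method. Targets where every
#' method picks equally (SD = 0) contribute 0.
#'
#' @param selected Numeric matrix or data frame, targets in rows, methods in
#'   columns; entries are the true GDT-TS of each method's top-1 pick.
#' @param floor Z-score floor (default -2).
#' @return Named numeric vector of per-method Z-score sums.
#' @export
zscore_top1 <- function(selected, floor = -2) {
  m <- as.matrix(selected)
  if (ncol(m) < 2) stop("need >= 2 methods per target")
  z <- t(apply(m, 1, function(row) {
    s <- stats::sd(row)
    if (is.na(s) || s == 0) return(rep(0, length(row)))
    pmax((row - mean(row)) / s, floor)
  }))
  stats::setNames(colSums(z), colnames(m))
}

#' Evaluate predictions over a multi-target dataset
#'
#' Computes per-target Pearson, Spearman and Kendall correlations and the
#' GDT-TS loss, then the unweighted means across targets. Targets with a
#' single model (or constant scores) are excluded from the correlation
#' averages but still counted in the loss average.
#'
#' @param predictions Data frame `target_id`, `model_id`, `score`.
#' @param truths Data frame `target_id`, `model_id`, `gdtts`.
#' @return List with `per_target` (data frame) and `summary` (one-row data
#'   frame with `ave_corr`, `ave_spearman`, `ave_kendall`, `ave_loss`,
#'   `n_targets`).
#' @export
evaluate_dataset <- function(predictions, truths) {
  if (nrow(predictions) == 0) stop("no predictions to evaluate")
  merged <- merge(predictions, truths, by = c("target_id", "model_id"))
  if (nrow(merged) == 0) stop("predictions and truths share no models")
  per_target <- do.call(rbind, lapply(split(merged, merged$target_id),
    function(g) {
      g <- g[order(g$model_id), , drop = FALSE]
      can_cor <- nrow(g) >= 2 && stats::sd(g$score) > 0 &&
        stats::sd(g$gdtts) > 0
      data.frame(
        target_id = g$target_id[1],
        n_models = nrow(g),
        pearson = if (can_cor) pearson_cor(g$score, g$gdtts) else NA_real_,
        spearman = if (can_cor) spearman_cor(g$score, g$gdtts) else NA_real_,
        kendall = if (can_cor) kendall_cor(g$score, g$gdtts) else NA_real_,
        loss = gdt_loss(g$score, g$gdtts),
        stringsAsFactors = FALSE)
    }))
  rownames(per_target) <- NULL
  summary <- data.frame(
    ave_corr = mean(per_target$pearson, na.rm = TRUE),
    ave_spearman = mean(per_target$spearman, na.rm = TRUE),
    ave_kendall = mean(per_target$kendall, na.rm = TRUE),
    ave_loss = mean(per_target$loss),
    n_targets = nrow(per_target))
  list(per_target = per_target, summary = summary)
}
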