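# Precompute, per target, the grid-by-feature density blocks used by both
# per_target_loss and the coordinate-descent trainer. Missing features get
# an all-zero column so any weight leaves them inert. Returns a list of
# targets, each with D ((n_grid * n_models) x 11, model-major blocks),
# model_ids, truths.
build_training_blocks <- function(features, truths, stats,
                                  config = qprob_config()) {
  feats <- qprob_features()
  stopifnot(all(c("target_id", "model_id") %in% names(features)))
  if (is.data.frame(truths)) {
    tr <- stats::setNames(truths$gdtts, truths$model_id)
  } else {
    tr <- truths
  }
  grid <- seq(0, 1, by = config$scoring$grid_step)
  m_stats <- stats$M[match(feats, stats$feature)]
  s_stats <- stats$SD[match(feats, stats$feature)]
  # keep the table's target order (targets are exchangeable in the loss)
  tids <- factor(features$target_id, levels = unique(features$target_id))
  targets <- split(seq_len(nrow(features)), tids)
  model_rows <- unlist(targets, use.names = FALSE)
  ids <- features$model_id[model_rows]
  true_q <- unname(tr[ids])
  if (anyNA(true_q)) stop("missing truth for model(s) ",
                          paste(ids[is.na(true_q)], collapse = ", "))
  fmat <- vapply(feats, function(f) {
    if (f %in% names(features)) as.numeric(features[[f]][model_rows])
    else rep(NA_real_, length(model_rows))
  }, numeric(length(model_rows)))
  if (length(model_rows) == 1) fmat <- matrix(fmat, nrow = 1)
  D <- matrix(0, nrow = length(grid) * length(model_rows),
              ncol = length(feats))
  for (j in seq_along(model_rows)) {
    fv <- fmat[j, ]
    centers <- clip01(fv - m_stats)
    block <- (j - 1) * length(grid) + seq_along(grid)
    for (k in seq_along(feats)) {
      if (!is.na(fv[k]) && !is.na(m_stats[k]) && !is.na(s_stats[k])) {
        D[block, k] <- normalized_density(grid, centers[k], s_stats[k])
      }
    }
  }
  target_of_model <- rep(seq_along(targets),
                         vapply(targets, length, integer(1)))
  target_index <- split(seq_along(model_rows), target_of_model)
  best_true <- vapply(split(true_q, target_of_model), max, numeric(1))
  list(D = D, model_ids = ids, truths = true_q,
       target_index = target_index,
       target_sizes = vapply(targets, length, integer(1)),
       best_true = best_true,
       n_grid = length(grid), n_models = length(model_rows), grid = grid,
       n_targets = length(targets))
}

# Per-target average loss for one score vector S (grid-major per model):
# rank models by the grid argmax of their combined score, take each
# target's top pick, charge the gap to the target's best true GDT-TS.
score_vector_loss <- function(blocks, S) {
  sm <- matrix(S, nrow = blocks$n_grid)             # grid x all models
  x_hat <- blocks$grid[max.col(t(sm), ties.method = "first")]
  loss_sum <- 0
  for (t in seq_len(blocks$n_targets)) {
    sel <- blocks$target_index[[t]]
    pick <- which.max(x_hat[sel])  # ties -> first model in table order
    loss_sum <- loss_sum + blocks$best_true[t] - blocks$truths[sel][pick]
  }
  loss_sum / blocks$n_targets
}

# Loss of each candidate-weight column over precomputed blocks.
blocks_loss <- function(blocks, W) {
  W <- as.matrix(W)
  S <- blocks$D %*% W
  vapply(seq_len(ncol(W)), function(cc) score_vector_loss(blocks, S[, cc]),
         numeric(1))
}

#' Per-target average GDT-TS loss of a weight set
#'
#' For each target: predict every model's quality with the given weights,
#' take the top-ranked model, and charge the gap between the pool's best
#' true GDT-TS and the picked model's true GDT-TS. Returns the unweighted
#' mean over targets. Predicted ties resolve to the first model in the
#' table's order (no optimistic tie-breaking).
#'
#' @param weights Named (or canonical-order) numeric weight vector.
#' @param features Data frame with `target_id`, `model_id` and the 11
#'   canonical feature columns.
#' @param truths Data frame with `model_id`, `gdtts` (or named vector).
#' @param stats A `feature_error_stats`.
#' @param config A [qprob_config()] list.
#' @return Mean loss in \[0,1\].
#' @export
per_target_loss <- function(weights, features, truths, stats,
                            config = qprob_config()) {
  if (nrow(features) == 0) stop("empty dataset")
  if (is.null(names(weights))) names(weights) <- qprob_features()
  blocks <- build_training_blocks(features, truths, stats, config)
  unname(blocks_loss(blocks, matrix(weights[qprob_features()], ncol = 1)))
}

#' Train combination weights by coordinate descent
#'
#' Weights live on the grid -0.8 to 0.8 in steps of 0.01 and Min-Loss
#' starts at 1. The first restart initializes all weights at zero (greedy
#' forward selection from the null model, which empirically lands in
#' sparse, well-generalizing optima); further restarts draw each weight
#' uniformly from the grid. Each run sweeps the 11 features in canonical
#' order: for each feature it scans all 161 grid values with the
#' other weights fixed and accepts the value that strictly lowers the
#' per-target average GDT-TS loss (ties among minimizers go to the value
#' closest to zero, negative before positive); a value matching the current
#' loss is also accepted when it moves the weight strictly toward zero,
#' which is what makes the closest-to-zero tie-break actually drain
#' uninformative weights. Sweeps repeat until one full sweep changes
#' nothing. The loss trajectory is non-increasing by construction and every
#' accepted move strictly decreases (loss, sum of |w|), so the finite grid
#' guarantees termination; a sweep cap
#' (default 100) guards against pathological inputs. Coordinate descent on a
#' non-convex loss is initialization-sensitive, so `n_restarts` (default 5)
#' independent seeded starts are run. When the dataset has at least
#' `training$min_targets_for_validation` targets (default 8), a seeded
#' target-level validation slice (default 25%) is withheld from the descent
#' and the winning restart is the one with the strictly lowest validation
#' loss (ties keep the earliest run, i.e. the zero start) — restarts are
#' compared on targets they never saw, which suppresses selection of
#' overfit runs. With fewer targets the best training loss wins. The
#' restart loop stops early at loss 0, the global lower bound.
#'
#' @param features Data frame with `target_id`, `model_id` and the 11
#'   canonical feature columns (every target needs >= 2 models).
#' @param truths Data frame with `model_id`, `gdtts` (or named vector).
#' @param stats A `feature_error_stats`.
#' @param seed Integer seed for the random initialization (default 42).
#' @param config A [qprob_config()] list (`training$*`, `scoring$grid_step`).
#' @return A `weight_set`: list with `weights` (named, canonical order),
#'   `min_loss` (training), `val_loss` (`NA` without a validation slice),
#'   `sweeps`, `trajectory` (Min-Loss after each accepted update),
#'   `converged`.
#' @export
train_weights <- function(features, truths, stats, seed = 42,
                          config = qprob_config()) {
  if (nrow(features) == 0) stop("empty dataset")
  n_per_target <- table(features$target_id)
  if (any(n_per_target < 2)) {
    stop("every target needs >= 2 models with truths")
  }
  tc <- config$training

  # with several restarts and enough targets, hold out a target-level
  # validation slice: restarts are compared on targets the descent never
  # saw, so the winner is the restart that generalizes, not the one that
  # memorized the training ranking
  all_targets <- unique(features$target_id)
  val_targets <- character(0)
  if (tc$n_restarts > 1 && tc$validation_frac > 0 &&
      length(all_targets) >= tc$min_targets_for_validation) {
    set.seed(seed)
    n_val <- max(2L, round(tc$validation_frac * length(all_targets)))
    n_val <- min(n_val, length(all_targets) - 2L)
    val_targets <- sample(all_targets, n_val)
  }
  in_val <- features$target_id %in% val_targets
  blocks <- build_training_blocks(features[!in_val, , drop = FALSE],
                                  truths, stats, config)
  blocks_val <- if (length(val_targets) > 0) {
    build_training_blocks(features[in_val, , drop = FALSE],
                          truths, stats, config)
  } else NULL
  grid_w <- round(seq(tc$w_min, tc$w_max, by = tc$w_step), 10)
  feats <- qprob_features()

  run_once <- function(run_seed, init = NULL) {
    set.seed(run_seed)
    w <- if (is.null(init)) sample(grid_w, length(feats), replace = TRUE)
         else rep_len(init, length(feats))
    min_loss <- 1
    trajectory <- numeric(0)
    sweeps <- 0L
    converged <- FALSE
    # candidate order implements the tie-break: |w| ascending, negative first
    cand_order <- order(abs(grid_w), grid_w)
    cand <- grid_w[cand_order]
    S_all <- as.numeric(blocks$D %*% w)
    while (sweeps < tc$max_sweeps) {
      sweeps <- sweeps + 1L
      changed <- FALSE
      for (i in seq_along(feats)) {
        base <- S_all - blocks$D[, i] * w[i]
        losses <- coord_candidate_losses(base, blocks$D[, i], cand,
                                         blocks$n_grid, blocks$target_sizes,
                                         blocks$truths, blocks$best_true)
        best <- which.min(losses)  # first minimizer = preferred tie-break
        # accept a strict improvement, or an equal-loss move that shrinks
        # the weight toward zero (the sparsity tie-break); both strictly
        # decrease (loss, sum|w|), so the sweep loop terminates
        improves <- losses[best] < min_loss
        shrinks <- losses[best] == min_loss &&
          (abs(cand[best]) < abs(w[i]) ||
             (abs(cand[best]) == abs(w[i]) && cand[best] < w[i]))
        if (improves || shrinks) {
          min_loss <- losses[best]
          if (w[i] != cand[best]) changed <- TRUE
          w[i] <- cand[best]
          S_all <- base + blocks$D[, i] * w[i]
          if (improves) trajectory <- c(trajectory, min_loss)
        }
      }
      if (!changed) { converged <- TRUE; break }
    }
    if (!converged) {
      warning("coordinate descent hit the sweep cap (", tc$max_sweeps,
              "); returning best weights so far", call. = FALSE)
    }
    val_loss <- if (!is.null(blocks_val)) {
      blocks_loss(blocks_val, matrix(w, ncol = 1))
    } else NA_real_
    list(weights = stats::setNames(w, feats), min_loss = min_loss,
         val_loss = val_loss, sweeps = sweeps, trajectory = trajectory,
         converged = converged)
  }

  # selection: validation loss when available (train loss breaks ties),
  # else train loss; stop early at the global lower bound 0
  run_key <- function(run) {
    if (is.na(run$val_loss)) c(run$min_loss, 0) else
      c(run$val_loss, run$min_loss)
  }
  # restart 1 starts from the all-zero vector: greedy forward selection
  # from the null model adds only strictly-improving weights and lands in
  # sparse optima; the remaining restarts are random per the grid
  best <- NULL
  fallback <- NULL
  for (k in seq_len(tc$n_restarts) - 1L) {
    run <- run_once(seed + k, init = if (k == 0L) 0 else NULL)
    if (all(run$weights == 0)) {
      # the all-zero vector can "win" degenerate instances through the
      # predicted-tie rule but cannot score models; keep it only as a
      # last resort
      if (is.null(fallback)) fallback <- run
      next
    }
    if (is.null(best)) {
      best <- run
    } else {
      ka <- run_key(run); kb <- run_key(best)
      if (ka[1] < kb[1]) best <- run  # ties keep the earlier (zero-init) run
    }
    if (all(run_key(best) == 0)) break
  }
  if (is.null(best)) {
    warning("all restarts converged to the all-zero weight vector; ",
            "the dataset does not constrain the weights", call. = FALSE)
    best <- fallback
  }
  structure(best, class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight_set: Min-Loss =", format(x$min_loss, digits = 4),
      "after", x$sweeps, "sweep(s)\n")
  print(round(x$weights, 2))
  invisible(x)
}

#' Save / load a weight set
#'
#' YAML round trip in canonical feature order. `load_weights(NULL)` (or a
#' missing file) returns the packaged published weights.
#'
#' @param weights A `weight_set` or named numeric vector of 11 weights.
#' @param path File path (for `load_weights`, `NULL` or a missing file falls
#'   back to the packaged defaults).
#' @return `save_weights()` returns `path` invisibly; `load_weights()` a
#'   `weight_set`.
#' @export
save_weights <- function(weights, path) {
  if (inherits(weights, "weight_set")) {
    w <- weights$weights
    ml <- weights$min_loss
  } else {
    w <- weights
    ml <- NA_real_
  }
  if (length(w) != 11) stop("expected 11 weights, got ", length(w))
  if (is.null(names(w))) names(w) <- qprob_features()
  yaml::write_yaml(list(weights = as.list(w[qprob_features()]),
                        min_loss = ml), path, precision = 17)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path = NULL) {
  if (is.null(path) || !file.exists(path)) {
    path <- system.file("extdata", "default_weights.yaml",
                        package = "qprob", mustWork = TRUE)
  }
  obj <- yaml::read_yaml(path)
  w <- unlist(obj$weights)
  if (length(w) != 11) {
    stop("weight file must carry exactly 11 weights, found ", length(w))
  }
  missing <- setdiff(qprob_features(), names(w))
  if (length(missing) > 0) {
    stop("weight file missing feature(s): ", paste(missing, collapse = ", "))
  }
  structure(list(weights = w[qprob_features()],
                 min_loss = if (is.null(obj$min_loss)) NA_real_
                            else as.numeric(obj$min_loss),
                 val_loss = NA_real_,
                 sweeps = NA_integer_, trajectory = numeric(0),
                 converged = NA),
            class = "weight_set")
}
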