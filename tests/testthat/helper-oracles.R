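# Independent oracles used across the suite. Each deliberately takes a
# different algorithmic route from the implementation it checks.

# Kendall tau-b by direct O(n^2) concordant/discordant counting with tie
# correction.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the |difference| ranks (tie-free differences only),
# mirroring the usual two-sided doubling rule.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (t_obs > mu) mean(t_all >= t_obs) else mean(t_all <= t_obs)
  min(1, 2 * p)
}

# Quaternion-based optimal superposition (Horn 1987): an algorithmically
# independent alternative to the SVD Kabsch fit.
quaternion_superpose <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- crossprod(Pc, Qc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[3, 1] + M[1, 3]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  list(R = R, cp = cp, cq = cq)
}

# Exhaustive GDT oracle: the largest within-threshold count over
# superpositions fitted on every residue subset of size >= 3. Feasible for
# <= 10 residues.
gdt_exhaustive_oracle <- function(mob, ref, thresholds = c(1, 2, 4, 8)) {
  n <- nrow(mob)
  stopifnot(n <= 12)
  subsets <- list()
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) >= 3) subsets[[length(subsets) + 1]] <- idx
  }
  counts <- sapply(thresholds, function(thr) {
    best <- 0
    for (idx in subsets) {
      fit <- quaternion_superpose(mob[idx, , drop = FALSE],
                                  ref[idx, , drop = FALSE])
      moved <- sweep(sweep(mob, 2, fit$cp) %*% t(fit$R), 2, fit$cq, "+")
      d <- sqrt(rowSums((moved - ref)^2))
      best <- max(best, sum(d <= thr))
    }
    best
  })
  mean(counts / n)
}

# Combined-score argmax on an arbitrary grid straight from the density
# definition (dnorm ratio), independent of the package's grid scan.
fine_grid_argmax <- function(centers, sds, weights, step = 1e-5) {
  grid <- seq(0, 1, by = step)
  total <- numeric(length(grid))
  for (k in seq_along(centers)) {
    total <- total + weights[k] *
      stats::dnorm(grid, centers[k], sds[k]) / stats::dnorm(0, 0, sds[k])
  }
  grid[which.max(total)]
}

# A rigid rotation + translation used by invariance tests.
rigid_transform_model <- function(model, angles = c(0.4, -1.1, 2.0),
                                  shift = c(5, -3, 8)) {
  Rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}
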