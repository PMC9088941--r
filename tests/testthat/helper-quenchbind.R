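# shared fixtures and independent brute-force oracles

# Table of printed tri-exponential lifetime components (blank protein and the
# two ligand ratios): used across lifetime tests.
lifetime_rows <- list(
  list(tau = c(1.836, 5.719, 0.474), alpha_pct = c(16.71, 76.01, 7.27)),
  list(tau = c(1.709, 5.776, 0.360), alpha_pct = c(18.64, 75.04, 6.32)),
  list(tau = c(1.773, 5.799, 0.425), alpha_pct = c(18.86, 74.26, 6.88))
)

# Printed per-temperature constants reused in tests
table2 <- tibble::tibble(
  temperature = c(298, 304, 310),
  ksv = c(4.142, 3.447, 2.338) * 1e4,
  ka = c(8.978, 4.998, 1.782) * 1e4,
  n = c(1.073, 1.039, 0.972)
)

# closed-form OLS slope/intercept via normal equations (oracle for lm-based fits)
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# toy trajectory from a list of n x 3 coordinate matrices
toy_traj <- function(frames, element = "C", name = "CA", ligand = NULL,
                     resid = NULL) {
  n <- nrow(frames[[1]])
  purrr::imap_dfr(frames, function(m, f) {
    tibble::tibble(frame = as.integer(f), atom = seq_len(n),
                   name = name, element = element, resname = "UNK",
                   resid = resid %||% seq_len(n), chain = "A",
                   ligand = ligand %||% rep(FALSE, n),
                   x = m[, 1], y = m[, 2], z = m[, 3])
  }) |> quenchbind::as_trajectory()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rotation_matrix <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, 3,
               byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, 3,
               byrow = TRUE)
  rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}

# brute-force minimum RMSD over rotations: coarse Euler-angle grid scan,
# then a derivative-free simplex polish of the angles (independent of the
# SVD route used by kabsch)
grid_rmsd_oracle <- function(mobile, reference, n = 24) {
  ang <- seq(0, 2 * pi, length.out = n)
  half <- seq(-pi / 2, pi / 2, length.out = n %/% 2)
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  obj <- function(a) {
    r <- rotation_matrix(a[1], a[2], a[3])
    sqrt(mean(rowSums((p %*% t(r) - q)^2)))
  }
  best <- Inf; best_a <- c(0, 0, 0)
  for (ax in ang) for (ay in half) for (az in ang) {
    v <- obj(c(ax, ay, az))
    if (v < best) { best <- v; best_a <- c(ax, ay, az) }
  }
  opt <- optim(best_a, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  min(best, opt$value)
}

# brute-force hydrogen-bond triple enumeration (oracle for hbond_count)
hbond_oracle <- function(xyz, don_idx, h_attach, acc_idx, d_max, angle_min) {
  n <- 0L
  for (i in seq_along(don_idx)) {
    d <- xyz[don_idx[i], ]
    h <- xyz[h_attach[i], ]
    for (a_id in acc_idx) {
      if (a_id == don_idx[i] || a_id == h_attach[i]) next
      a <- xyz[a_id, ]
      dist_ha <- sqrt(sum((a - h)^2))
      if (dist_ha > d_max) next
      v1 <- d - h; v2 <- a - h
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang >= angle_min) n <- n + 1L
    }
  }
  n
}
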