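# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# two-loop magnitude matrix: norm of mean-centered position, per residue/frame
naive_magnitude <- function(traj) {
  n <- dim(traj$coords)[1]
  m <- dim(traj$coords)[3]
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    mu <- c(mean(traj$coords[i, 1, ]), mean(traj$coords[i, 2, ]),
            mean(traj$coords[i, 3, ]))
    for (k in seq_len(m)) {
      out[i, k] <- sqrt(sum((traj$coords[i, , k] - mu)^2))
    }
  }
  out
}

# explicit double-loop second-moment matrix, (1/M) sum_m R_i(t_m) R_j(t_m)
naive_covariance <- function(mag) {
  n <- nrow(mag)
  m <- ncol(mag)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(m)) s <- s + mag[i, k] * mag[j, k]
      out[i, j] <- s / m
    }
  }
  out
}

# cyclic-Jacobi symmetric eigendecomposition
jacobi_eigen <- function(a, tol = 1e-13, max_sweeps = 100) {
  n <- nrow(a)
  v <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(a[upper.tri(a)]^2))
    if (off < tol) break
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        if (abs(a[p, q]) < tol / n^2) next
        theta <- (a[q, q] - a[p, p]) / (2 * a[p, q])
        t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
        if (theta == 0) t <- 1
        c_ <- 1 / sqrt(t^2 + 1)
        s <- t * c_
        rot <- diag(n)
        rot[p, p] <- c_; rot[q, q] <- c_
        rot[p, q] <- s; rot[q, p] <- -s
        a <- t(rot) %*% a %*% rot
        v <- v %*% rot
      }
    }
  }
  ord <- order(diag(a), decreasing = TRUE)
  list(values = diag(a)[ord], vectors = v[, ord, drop = FALSE])
}

# brute-force minimum RMSD over a grid of rotations (translation solved by
# centroid matching); a lower envelope for the closed-form rigid fit
grid_min_rmsd <- function(mobile, target, step_deg = 10) {
  ang <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  half <- seq(0, pi, by = step_deg * pi / 180)
  pc <- sweep(mobile, 2, colMeans(mobile))
  qc <- sweep(target, 2, colMeans(target))
  best <- Inf
  for (a1 in ang) {
    r1 <- matrix(c(cos(a1), -sin(a1), 0, sin(a1), cos(a1), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    for (a2 in half) {
      r2 <- matrix(c(cos(a2), 0, sin(a2), 0, 1, 0, -sin(a2), 0, cos(a2)), 3, 3, byrow = TRUE)
      for (a3 in ang) {
        r3 <- matrix(c(1, 0, 0, 0, cos(a3), -sin(a3), 0, sin(a3), cos(a3)), 3, 3, byrow = TRUE)
        rot <- r1 %*% r2 %*% r3
        rmsd <- sqrt(mean(rowSums((pc %*% t(rot) - qc)^2)))
        if (rmsd < best) best <- rmsd
      }
    }
  }
  best
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# arbitrary rigid transform for invariance checks
apply_rigid_all_frames <- function(traj, angle = 0.7, axis = c(0, 0, 1),
                                   translation = c(5, -2, 1)) {
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  rot <- cos(angle) * diag(3) + sin(angle) * ux + (1 - cos(angle)) * (u %o% u)
  for (k in seq_len(dim(traj$coords)[3])) {
    traj$coords[, , k] <- sweep(traj$coords[, , k] %*% t(rot), 2, translation, "+")
  }
  traj
}
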