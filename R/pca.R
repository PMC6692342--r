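#' Magnitude matrix of mean-centered residue positions
#'
#' For each residue i and frame m, the entry is the Euclidean norm of the
#' residue's position after subtracting its temporal mean,
#' `|| r_i(t_m) - <r_i> ||` (Angstrom).  Rows are residues, columns frames.
#' This N x M matrix is the input to [fit_pca()].
#'
#' @param traj an aligned `ca_trajectory`.
#' @return An `N x M` numeric matrix with attributes `condition` and `times`.
#' @export
magnitude_matrix <- function(traj) {
  require_aligned(traj, "magnitude_matrix()")
  if (n_frames(traj) < 1L) abort("empty trajectory")
  dev2 <- 0
  for (d in 1:3) {
    xd <- traj$coords[, d, , drop = TRUE]
    if (is.null(dim(xd))) xd <- matrix(xd, ncol = 1L)
    dev2 <- dev2 + (xd - rowMeans(xd))^2
  }
  mag <- sqrt(dev2)
  attr(mag, "condition") <- traj$condition
  attr(mag, "times") <- traj$times
  mag
}

## deterministic eigenvector sign: largest-magnitude component positive
fix_eigen_signs <- function(v) {
  for (k in seq_len(ncol(v))) {
    piv <- which.max(abs(v[, k]))
    if (v[piv, k] < 0) v[, k] <- -v[, k]
  }
  v
}

#' Principal component analysis of the magnitude matrix
#'
#' Forms the N x N second-moment matrix `C = (1/M) * mag %*% t(mag)` --
#' deliberately without re-centering the magnitude rows, so C is a second
#' moment rather than a covariance in the textbook sense -- and
#' diagonalizes it with a symmetric eigendecomposition.  Eigenpairs are
#' sorted by descending eigenvalue; each eigenvector's sign is fixed so its
#' largest-magnitude component is positive.
#'
#' @param mag an `N x M` magnitude matrix from [magnitude_matrix()].
#' @return An object of class `traj_pca`: list with `covariance` (N x N),
#'   `vectors` (N x N, columns are modes), `values` (length N, descending)
#'   and `condition`.
#' @export
fit_pca <- function(mag) {
  if (!all(is.finite(mag))) abort("magnitude matrix has non-finite entries")
  if (ncol(mag) < 2L) abort("PCA needs at least 2 frames")
  m <- ncol(mag)
  cov <- mag %*% t(mag) / m
  cov <- (cov + t(cov)) / 2
  eig <- eigen(cov, symmetric = TRUE)
  structure(
    list(covariance = cov,
         vectors = fix_eigen_signs(eig$vectors),
         values = pmax(eig$values, 0),
         condition = attr(mag, "condition") %||% ""),
    class = "traj_pca"
  )
}

#' @export
print.traj_pca <- function(x, ...) {
  cat(sprintf("<traj_pca> %d modes; top eigenvalues: %s\n",
              length(x$values),
              paste(signif(head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Project the magnitude matrix onto a PCA mode
#'
#' The projection at frame m is `sum_n V[n, mode] * mag[n, m]`.
#'
#' @param mag magnitude matrix.
#' @param model a `traj_pca` from [fit_pca()].
#' @param mode 1-based mode index.
#' @return Numeric vector of length M with attribute `mode`.
#' @export
project <- function(mag, model, mode = 1L) {
  if (mode < 1L || mode > ncol(model$vectors)) abort("mode index out of range")
  v <- as.vector(t(model$vectors[, mode]) %*% mag)
  attr(v, "mode") <- as.integer(mode)
  v
}

#' Projection series onto the first two PCA modes
#'
#' Convenience wrapper returning a tidy frame-by-frame table used for state
#' partitioning and for export.
#'
#' @param mag magnitude matrix.
#' @param model a `traj_pca`.
#' @return Tibble with columns `frame`, `time`, `pc1`, `pc2`.
#' @export
projection_series <- function(mag, model) {
  times <- attr(mag, "times") %||% (seq_len(ncol(mag)) - 1) * 10
  tibble::tibble(
    frame = seq_len(ncol(mag)),
    time = times,
    pc1 = as.numeric(project(mag, model, 1L)),
    pc2 = as.numeric(project(mag, model, 2L))
  )
}

#' @describeIn fit_pca tidy method: one row per mode with `eigenvalue` and
#'   `variance_fraction` (fraction of the trace).
#' @param x a `traj_pca`.
#' @param ... unused.
#' @export
tidy.traj_pca <- function(x, ...) {
  tot <- sum(x$values)
  tibble::tibble(
    mode = seq_along(x$values),
    eigenvalue = x$values,
    variance_fraction = if (tot > 0) x$values / tot else rep(0, length(x$values))
  )
}

#' @describeIn fit_pca glance method: one-row summary.
#' @export
glance.traj_pca <- function(x, ...) {
  tot <- sum(x$values)
  tibble::tibble(
    n_modes = length(x$values),
    total_moment = tot,
    top2_fraction = if (tot > 0) sum(x$values[1:2]) / tot else 0
  )
}
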