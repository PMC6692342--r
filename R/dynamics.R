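#' Per-residue root-mean-square fluctuation
#'
#' `RMSF_i = sqrt(weighted mean over frames of || r_i(t) - <r_i> ||^2)`, with
#' `<r_i>` the weighted temporal mean position.  The trajectory must be
#' aligned first, otherwise rigid-body motion inflates the fluctuations.
#'
#' @param traj an aligned `ca_trajectory` with at least 2 frames.
#' @param weights optional weighted frame set.
#' @return A tibble `residue, name, rmsf` (Angstrom) with attribute
#'   `condition` and `effective_frames` (effective sample size of the
#'   weights, for error bars).
#' @export
rmsf <- function(traj, weights = NULL) {
  require_aligned(traj, "rmsf()")
  if (n_frames(traj) < 2L) abort("RMSF needs at least 2 frames")
  rw <- resolve_weights(traj, weights)
  wn <- rw$w / sum(rw$w)
  dev2 <- 0
  for (d in 1:3) {
    xd <- traj$coords[, d, rw$idx, drop = TRUE]
    if (is.null(dim(xd))) xd <- matrix(xd, ncol = length(rw$idx))
    mu <- as.vector(xd %*% wn)
    dev2 <- dev2 + (xd - mu)^2 %*% wn
  }
  out <- tibble::tibble(residue = traj$residues$index,
                        name = traj$residues$name,
                        rmsf = as.vector(sqrt(dev2)))
  attr(out, "condition") <- traj$condition
  attr(out, "effective_frames") <- 1 / sum(wn^2)
  out
}

#' Dynamic cross-correlation map of residue fluctuations
#'
#' The standard dynamic cross-correlation convention on 3-D fluctuation
#' vectors: `C_ij = <dr_i . dr_j> / sqrt(<dr_i . dr_i> <dr_j . dr_j>)` with
#' `dr_i(t) = r_i(t) - <r_i>` (weighted averages).  Values lie in `[-1, 1]`;
#' 1 is perfect positive coupling, -1 perfect anti-coupling, 0 uncoupled.
#' A scalar-magnitude variant (correlating `||dr_i||` series) is exposed for
#' sensitivity checks.  Residues with zero fluctuation yield flagged (`NA`)
#' rows/columns rather than propagating NaN.
#'
#' @param traj an aligned `ca_trajectory`, M >= 2.
#' @param weights optional weighted frame set.
#' @param method `"vector"` (default, 3-D dot products) or `"magnitude"`.
#' @return An `N x N` matrix of class `correlation_map` with attributes
#'   `condition` and `flagged` (logical vector of zero-fluctuation residues).
#' @export
correlation_map <- function(traj, weights = NULL,
                            method = c("vector", "magnitude")) {
  require_aligned(traj, "correlation_map()")
  method <- match.arg(method)
  if (n_frames(traj) < 2L) abort("correlation map needs at least 2 frames")
  rw <- resolve_weights(traj, weights)
  wn <- rw$w / sum(rw$w)
  n <- n_residues(traj)

  if (method == "vector") {
    g <- matrix(0, n, n)
    for (d in 1:3) {
      xd <- traj$coords[, d, rw$idx, drop = TRUE]
      if (is.null(dim(xd))) xd <- matrix(xd, ncol = length(rw$idx))
      xc <- xd - as.vector(xd %*% wn)
      g <- g + xc %*% (t(xc) * wn)
    }
  } else {
    mag <- matrix(0, n, length(rw$idx))
    for (d in 1:3) {
      xd <- traj$coords[, d, rw$idx, drop = TRUE]
      if (is.null(dim(xd))) xd <- matrix(xd, ncol = length(rw$idx))
      mag <- mag + (xd - as.vector(xd %*% wn))^2
    }
    mag <- sqrt(mag)
    mc <- mag - as.vector(mag %*% wn)
    g <- mc %*% (t(mc) * wn)
  }

  v <- diag(g)
  flagged <- v <= 1e-12
  denom <- sqrt(outer(v, v))
  cmap <- g / denom
  cmap[flagged, ] <- NA_real_
  cmap[, flagged] <- NA_real_
  diag(cmap)[!flagged] <- 1
  cmap <- pmin(pmax(cmap, -1), 1)
  structure(cmap, condition = traj$condition, flagged = flagged,
            class = c("correlation_map", "matrix", "array"))
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d x %d (%s), %d flagged residue(s)\n",
              nrow(x), ncol(x), attr(x, "condition"),
              sum(attr(x, "flagged"))))
  invisible(x)
}

#' @describeIn correlation_map tidy method: long tibble `i, j, correlation`
#'   over the upper triangle.
#' @param x a `correlation_map`.
#' @param ... unused.
#' @export
tidy.correlation_map <- function(x, ...) {
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2],
                 correlation = x[idx],
                 condition = attr(x, "condition"))
}

#' Difference map between two conditions
#'
#' Elementwise `b - a`.  For correlation maps a categorical map is also
#' produced using a magnitude threshold (default 0.4): `"gained-positive"`
#' (weak in `a`, strongly positive in `b`), `"gained-negative"`,
#' `"lost"` (strong in `a`, weak in `b`), `"unchanged"` otherwise, and
#' `"undefined"` where either input is flagged.  For RMSF profiles a joined
#' tibble with a `delta` column is returned.  Swapping the arguments negates
#' the numeric delta exactly.
#'
#' @param a,b two objects of the same type (both `correlation_map` or both
#'   [rmsf()] tibbles) with matching size.
#' @param threshold magnitude threshold for the categorical correlation map.
#' @return For correlation maps: list of class `correlation_difference` with
#'   `delta` (matrix) and `category` (character matrix).  For RMSF tibbles:
#'   a tibble `residue, name, rmsf_a, rmsf_b, delta`.
#' @export
difference_map <- function(a, b, threshold = 0.4) {
  if (inherits(a, "correlation_map") && inherits(b, "correlation_map")) {
    if (!all(dim(a) == dim(b))) abort("correlation maps have different sizes")
    delta <- unclass(b) - unclass(a)
    am <- unclass(a); bm <- unclass(b)
    cat_map <- matrix("unchanged", nrow(a), ncol(a))
    cat_map[abs(am) < threshold & bm >= threshold] <- "gained-positive"
    cat_map[abs(am) < threshold & bm <= -threshold] <- "gained-negative"
    cat_map[abs(am) >= threshold & abs(bm) < threshold] <- "lost"
    cat_map[is.na(am) | is.na(bm)] <- "undefined"
    return(structure(list(delta = delta, category = cat_map,
                          threshold = threshold,
                          a_condition = attr(a, "condition"),
                          b_condition = attr(b, "condition")),
                     class = "correlation_difference"))
  }
  if (is.data.frame(a) && is.data.frame(b) && "rmsf" %in% names(a)) {
    if (nrow(a) != nrow(b)) abort("RMSF profiles have different lengths")
    return(tibble::tibble(residue = a$residue, name = a$name,
                          rmsf_a = a$rmsf, rmsf_b = b$rmsf,
                          delta = b$rmsf - a$rmsf))
  }
  abort("difference_map() expects two correlation maps or two RMSF profiles")
}

#' @export
print.correlation_difference <- function(x, ...) {
  tab <- table(x$category[upper.tri(x$category)])
  cat(sprintf("<correlation_difference> %s -> %s (threshold %.2f): %s\n",
              x$a_condition, x$b_condition, x$threshold,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Pairs carrying a given category in a correlation difference map
#'
#' @param diff a [difference_map()] result for correlation maps.
#' @param category category to extract (default `"gained-negative"`).
#' @return A tibble `i, j, delta` over the upper triangle.
#' @export
category_pairs <- function(diff, category = "gained-negative") {
  idx <- which(upper.tri(diff$category) & diff$category == category,
               arr.ind = TRUE)
  tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                 delta = diff$delta[idx]) |>
    dplyr::arrange(.data$i, .data$j)
}
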