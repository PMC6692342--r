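## peak finder on a (midpoint, density) grid: local maxima above a height
## floor expressed as a fraction of the maximal density.  A plateau counts
## once, at its first bin; a floor >= 1 returns the global maximum only.
find_density_peaks <- function(mid, density, min_prominence) {
  nb <- length(density)
  if (nb == 0L) return(tibble::tibble(position = numeric(), height = numeric()))
  if (min_prominence >= 1) {
    k <- which.max(density)
    return(tibble::tibble(position = mid[k], height = density[k]))
  }
  left <- c(-Inf, density[-nb])
  right <- c(density[-1], -Inf)
  is_peak <- density > left & density >= right
  floor_h <- min_prominence * max(density)
  keep <- which(is_peak & density >= floor_h)
  tibble::tibble(position = mid[keep], height = density[keep]) |>
    dplyr::arrange(.data$position)
}

weighted_hist <- function(d, w, edges) {
  bin <- pmin(length(edges) - 1L, pmax(1L, findInterval(d, edges, rightmost.closed = TRUE)))
  mass <- vapply(seq_len(length(edges) - 1L),
                 function(b) sum(w[bin == b]), numeric(1))
  mass / sum(mass)
}

gaussian_smooth <- function(density, sd_bins) {
  if (sd_bins <= 0) return(density)
  half <- max(1L, ceiling(4 * sd_bins))
  kern <- stats::dnorm(-half:half, sd = sd_bins)
  kern <- kern / sum(kern)
  nb <- length(density)
  padded <- c(rep(0, half), density, rep(0, half))
  out <- vapply(seq_len(nb),
                function(i) sum(padded[i:(i + 2 * half)] * rev(kern)), numeric(1))
  out
}

#' Distance distribution W(R_ij) of a residue pair
#'
#' Estimates the (optionally frame-weighted) distribution of the
#' instantaneous Cα-Cα distance of one residue pair as a normalized,
#' Gaussian-kernel-smoothed histogram, detects its peaks (the local
#' conformational states of the pair) and the fraction of frames belonging
#' to each peak (1-D Voronoi assignment to the nearest peak).
#'
#' @param traj a `ca_trajectory`.
#' @param pair length-2 integer vector of residue indices.
#' @param weights optional weighted frame set.
#' @param binwidth histogram bin width in Angstrom; `NULL` (default) uses the
#'   Freedman-Diaconis rule.  A fixed width (e.g. 0.25) makes distributions
#'   comparable across conditions and bounds peak-position quantization.
#' @param smooth_bins Gaussian smoothing bandwidth in units of bins
#'   (default 1).
#' @param min_prominence peak height floor as a fraction of the maximal
#'   density (default 0.05).
#' @param min_frames minimal number of frames required (default 30).
#' @return An object of class `distance_distribution`: list with `pair`,
#'   `condition`, `edges`, `mid`, `density` (integrates to 1), `binwidth`,
#'   `peaks` (tibble `position, height`), `occupancies` (tibble
#'   `peak, position, occupancy`), `n_frames`, and the raw weighted samples
#'   (`samples`, `sample_weights`) used for exact re-binning.
#' @export
distance_distribution <- function(traj, pair, weights = NULL, binwidth = NULL,
                                  smooth_bins = 1, min_prominence = 0.05,
                                  min_frames = 30) {
  stopifnot(length(pair) == 2L)
  if (any(pair < 1L | pair > n_residues(traj))) abort("pair indices out of range")
  rw <- resolve_weights(traj, weights)
  d <- pair_distance_series(traj, pair[1], pair[2])[rw$idx]
  if (length(d) < min_frames) abort(sprintf("too few frames (%d < %d)", length(d), min_frames))
  w <- rw$w / sum(rw$w)

  rng <- range(d)
  if (diff(rng) < 1e-12) {
    bw <- binwidth %||% 0.1
    edges <- c(rng[1] - bw / 2, rng[1] + bw / 2)
  } else {
    bw <- binwidth %||% max(2 * stats::IQR(d) * length(d)^(-1 / 3), diff(rng) / 200)
    nb <- ceiling(diff(rng) / bw)
    edges <- rng[1] + bw * (0:nb)
  }
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  mass <- weighted_hist(d, w, edges)
  dens <- gaussian_smooth(mass, smooth_bins)
  dens <- dens / sum(dens) / bw  # renormalize: integrates to exactly 1

  peaks <- find_density_peaks(mid, dens, min_prominence)
  occ <- if (nrow(peaks)) {
    nearest <- apply(abs(outer(d, peaks$position, "-")), 1, which.min)
    tibble::tibble(peak = seq_len(nrow(peaks)), position = peaks$position,
                   occupancy = vapply(seq_len(nrow(peaks)),
                                      function(k) sum(w[nearest == k]), numeric(1)))
  } else {
    tibble::tibble(peak = integer(), position = numeric(), occupancy = numeric())
  }

  structure(
    list(pair = as.integer(pair), condition = traj$condition,
         edges = edges, mid = mid, density = dens, binwidth = bw,
         peaks = peaks, occupancies = occ, n_frames = length(d),
         samples = d, sample_weights = w),
    class = "distance_distribution"
  )
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> pair %d-%d (%s): %d frames, %d peak(s) at %s A\n",
              x$pair[1], x$pair[2],
              if (nzchar(x$condition)) x$condition else "untagged",
              x$n_frames, nrow(x$peaks),
              paste(signif(x$peaks$position, 3), collapse = ", ")))
  invisible(x)
}

#' @describeIn distance_distribution tidy method: `bin_mid, density` tibble.
#' @param x a `distance_distribution`.
#' @param ... unused.
#' @export
tidy.distance_distribution <- function(x, ...) {
  tibble::tibble(bin_mid = x$mid, density = x$density,
                 pair = paste0(x$pair[1], "-", x$pair[2]),
                 condition = x$condition)
}

#' Peaks of a distance distribution
#'
#' Local maxima of the smoothed density exceeding a height floor, sorted by
#' position.  The number of peaks is the pair's multimodality count.
#'
#' @param dist a [distance_distribution()].
#' @param min_prominence height floor as a fraction of the maximal density;
#'   1.0 returns the global maximum only.
#' @return A tibble `position, height`.
#' @export
find_peaks <- function(dist, min_prominence = 0.05) {
  find_density_peaks(dist$mid, dist$density, min_prominence)
}

#' Fraction of frames beyond a distance boundary
#'
#' The weighted fraction of frames in which the pair's Cα distance exceeds
#' `boundary` (and its complement).  The boundary is an explicit parameter:
#' occupancy readouts like "the pair visits distant states ~22% of the time"
#' depend on it and it is never inferred silently.
#'
#' @param traj a `ca_trajectory`.
#' @param pair length-2 residue index vector.
#' @param boundary distance boundary in Angstrom.
#' @param weights optional weighted frame set.
#' @return A one-row tibble `i, j, boundary, beyond, below`.
#' @export
state_occupancy <- function(traj, pair, boundary, weights = NULL) {
  rw <- resolve_weights(traj, weights)
  d <- pair_distance_series(traj, pair[1], pair[2])[rw$idx]
  w <- rw$w / sum(rw$w)
  beyond <- sum(w[d > boundary])
  tibble::tibble(i = pair[1], j = pair[2], boundary = boundary,
                 beyond = beyond, below = 1 - beyond)
}

#' Population shift between two conditions of the same pair
#'
#' Re-bins both distributions onto common edges (union range, the finer of
#' the two bin widths), reports the change in peak count, greedily matches
#' peaks across conditions by nearest position within a tolerance, and the
#' total-variation distance between the two densities (0 = identical,
#' 1 = disjoint supports).
#'
#' @param wt,mut [distance_distribution()] objects for the same pair.
#' @param match_tol peak matching tolerance in Angstrom (default 1.0).
#' @return An object of class `population_shift`: list with `pair`,
#'   `peak_count_change` (mut minus wt), `matched` (tibble
#'   `wt_position, mut_position, shift`), `unmatched_wt`, `unmatched_mut`,
#'   `total_variation` and `pattern` (`"state collapse"`, `"state
#'   splitting"` or `"stable"`).
#' @export
population_shift <- function(wt, mut, match_tol = 1.0) {
  if (!all(wt$pair == mut$pair)) abort("distributions describe different pairs")
  bw <- min(wt$binwidth, mut$binwidth)
  rng <- range(c(wt$samples, mut$samples))
  if (diff(rng) < 1e-12) rng <- rng + c(-bw / 2, bw / 2)
  nb <- max(1L, ceiling(diff(rng) / bw))
  edges <- rng[1] + bw * (0:nb)
  p <- weighted_hist(wt$samples, wt$sample_weights, edges)
  q <- weighted_hist(mut$samples, mut$sample_weights, edges)
  tv <- 0.5 * sum(abs(p - q))

  wt_pos <- wt$peaks$position
  mut_pos <- mut$peaks$position
  used_w <- logical(length(wt_pos))
  used_m <- logical(length(mut_pos))
  matched <- tibble::tibble(wt_position = numeric(), mut_position = numeric(),
                            shift = numeric())
  if (length(wt_pos) && length(mut_pos)) {
    cand <- expand.grid(w = seq_along(wt_pos), m = seq_along(mut_pos))
    cand$dist <- abs(wt_pos[cand$w] - mut_pos[cand$m])
    cand <- cand[order(cand$dist, cand$w, cand$m), ]
    for (r in seq_len(nrow(cand))) {
      wi <- cand$w[r]; mi <- cand$m[r]
      if (cand$dist[r] > match_tol) break
      if (used_w[wi] || used_m[mi]) next
      used_w[wi] <- TRUE; used_m[mi] <- TRUE
      matched <- dplyr::bind_rows(matched, tibble::tibble(
        wt_position = wt_pos[wi], mut_position = mut_pos[mi],
        shift = mut_pos[mi] - wt_pos[wi]))
    }
  }
  dpk <- length(mut_pos) - length(wt_pos)
  structure(
    list(pair = wt$pair,
         peak_count_change = dpk,
         matched = matched,
         unmatched_wt = wt_pos[!used_w],
         unmatched_mut = mut_pos[!used_m],
         total_variation = tv,
         pattern = if (dpk < 0) "state collapse" else if (dpk > 0) "state splitting" else "stable"),
    class = "population_shift"
  )
}

#' @export
print.population_shift <- function(x, ...) {
  cat(sprintf("<population_shift> pair %d-%d: peak count %+d (%s), TV = %.3f\n",
              x$pair[1], x$pair[2], x$peak_count_change, x$pattern,
              x$total_variation))
  invisible(x)
}
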