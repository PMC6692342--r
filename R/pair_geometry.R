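#' Second coordination shell radius
#'
#' The second coordination shell of a residue is defined as the sphere with
#' twice the volume of the first shell, i.e. radius `r1 * 2^(1/3)`.  With the
#' conventional first-shell radius of 7.2 Angstrom this gives ~9.1 Angstrom.
#'
#' @param r1 first-shell radius in Angstrom (default 7.2).
#' @return The second-shell radius in Angstrom.
#' @export
second_shell_radius <- function(r1 = 7.2) {
  if (!is.numeric(r1) || any(r1 <= 0)) abort("first-shell radius must be positive")
  r1 * 2^(1 / 3)
}

## weighted time-averaged all-pairs Calpha distance matrix (N x N)
mean_distance_matrix_full <- function(traj, weights = NULL) {
  rw <- resolve_weights(traj, weights)
  n <- n_residues(traj)
  acc <- matrix(0, n, n)
  for (k in seq_along(rw$idx)) {
    acc <- acc + rw$w[k] * as.matrix(stats::dist(traj$coords[, , rw$idx[k]]))
  }
  denom <- if (rw$convention == "multiply") length(rw$idx) else sum(rw$w)
  acc / denom
}

#' Build the coordination-shell neighbor graph on the reference condition
#'
#' A residue pair (i, j), i < j, is a neighbor pair iff its (optionally
#' state-weighted) time-averaged Cα distance in the *reference* trajectory is
#' at most `radius`.  The graph is built once on the reference condition and
#' reused for the perturbed condition, so the difference map is defined on a
#' fixed pair set.
#'
#' @param ref aligned reference `ca_trajectory`.
#' @param radius shell radius in Angstrom; default the second coordination
#'   shell of a 7.2 Angstrom first shell (~9.1 Angstrom).
#' @param weights optional weighted frame set (see [state_weighted_frames()]);
#'   off by default for the graph build.
#' @return A tibble `i, j, r_ref` (class `neighbor_graph`) with attributes
#'   `radius`, `condition` and `n_residues`.
#' @export
build_neighbor_graph <- function(ref, radius = second_shell_radius(7.2),
                                 weights = NULL) {
  require_aligned(ref, "build_neighbor_graph()")
  if (radius <= 0) abort("shell radius must be positive")
  dm <- mean_distance_matrix_full(ref, weights)
  n <- n_residues(ref)
  idx <- which(upper.tri(dm) & dm <= radius, arr.ind = TRUE)
  out <- tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                        r_ref = dm[idx]) |>
    dplyr::arrange(.data$i, .data$j)
  attr(out, "radius") <- radius
  attr(out, "condition") <- ref$condition
  attr(out, "n_residues") <- n
  class(out) <- c("neighbor_graph", class(out))
  out
}

#' Time-averaged Cα distances on a neighbor graph
#'
#' @param traj aligned `ca_trajectory` (either condition).
#' @param graph a [build_neighbor_graph()] result.
#' @param weights optional weighted frame set; by convention state weighting
#'   is applied here (on by default in [run_comparison()]).
#' @return A tibble `i, j, r_mean` (Angstrom) with attribute `condition`.
#' @export
mean_distances <- function(traj, graph, weights = NULL) {
  require_aligned(traj, "mean_distances()")
  if (max(graph$j) > n_residues(traj)) abort("graph residues exceed trajectory size")
  rw <- resolve_weights(traj, weights)
  if (!length(rw$idx)) abort("empty frame set")
  dm <- mean_distance_matrix_full(traj, weights)
  out <- tibble::tibble(i = graph$i, j = graph$j,
                        r_mean = dm[cbind(graph$i, graph$j)])
  attr(out, "condition") <- traj$condition
  attr(out, "graph_radius") <- attr(graph, "radius")
  out
}

#' Pair-distance difference map between two conditions
#'
#' `delta = r_mut - r_wt` per neighbor pair: positive values mean the pair
#' moves apart in the perturbed condition, negative values mean it gets
#' closer.  Swapping the two arguments negates every entry.
#'
#' @param wt,mut [mean_distances()] tibbles computed on the same neighbor
#'   graph (reference and perturbed condition).
#' @return A tibble `i, j, r_wt, r_mut, delta` of class `delta_map`, with
#'   attributes `wt_condition` and `mut_condition`.
#' @export
delta_matrix <- function(wt, mut) {
  if (nrow(wt) != nrow(mut) || !all(wt$i == mut$i & wt$j == mut$j)) {
    abort("mean-distance tables were not computed on the same neighbor graph")
  }
  out <- tibble::tibble(i = wt$i, j = wt$j, r_wt = wt$r_mean,
                        r_mut = mut$r_mean, delta = mut$r_mean - wt$r_mean)
  attr(out, "wt_condition") <- attr(wt, "condition")
  attr(out, "mut_condition") <- attr(mut, "condition")
  class(out) <- c("delta_map", class(out))
  out
}

#' Pairs with the most significant distance changes
#'
#' Selects pairs with `delta > pos_thresh` (tagged `"apart"`) or
#' `delta < neg_thresh` (tagged `"closer"`).  The default thresholds,
#' +2.50 and -1.40 Angstrom, are the conventional cutoffs for calling a
#' pair's change significant; both are plain configuration values.
#'
#' @param delta a [delta_matrix()] result.
#' @param pos_thresh positive threshold in Angstrom (> 0).
#' @param neg_thresh negative threshold in Angstrom (< 0).
#' @return The filtered tibble with an added `direction` column.
#' @export
significant_pairs <- function(delta, pos_thresh = 2.50, neg_thresh = -1.40) {
  if (!(pos_thresh > 0 && neg_thresh < 0)) {
    abort("need pos_thresh > 0 > neg_thresh")
  }
  delta |>
    tibble::as_tibble() |>
    dplyr::filter(.data$delta > pos_thresh | .data$delta < neg_thresh) |>
    dplyr::mutate(direction = ifelse(.data$delta > 0, "apart", "closer")) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta)))
}

#' Per-residue neighborhood expansion profile
#'
#' For each residue i, the mean of its incident pair differences,
#' `sum_j delta_ij / N_n`, where `N_n` is the residue's number of
#' second-shell neighbors.  A positive value means the residue moves away
#' from its neighborhood (local expansion); residues with no neighbors are
#' flagged undefined (`NA`).
#'
#' @param delta a [delta_matrix()] result.
#' @param graph the neighbor graph the map was computed on.
#' @return A tibble `residue, n_neighbors, delta_mean` of length
#'   `n_residues`.
#' @export
delta_residue_profile <- function(delta, graph) {
  n <- attr(graph, "n_residues")
  long <- dplyr::bind_rows(
    tibble::tibble(residue = delta$i, delta = delta$delta),
    tibble::tibble(residue = delta$j, delta = delta$delta)
  )
  agg <- long |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(n_neighbors = dplyr::n(),
                     delta_mean = mean(.data$delta), .groups = "drop")
  tibble::tibble(residue = seq_len(n)) |>
    dplyr::left_join(agg, by = "residue") |>
    dplyr::mutate(n_neighbors = dplyr::coalesce(.data$n_neighbors, 0L))
}
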