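#' Partition frames into conformational states on the (PC1, PC2) plane
#'
#' Frames are binned on a 2-D histogram of the first two PCA projections
#' (Freedman-Diaconis bin widths by default).  Bins whose count exceeds a
#' density floor (a fraction of the maximal bin count) are kept, and states
#' are the connected components (4-neighborhood) of the kept bins.  Frames
#' falling in below-floor bins are attached to the nearest dense bin, so
#' every frame is labeled.  States are relabeled 1..K by descending
#' occupancy (ties broken by state centroid, lexicographically), so the
#' dominant state is always state 1; an exact occupancy tie therefore
#' resolves to the lower label.
#'
#' @param pc1,pc2 numeric projection series of equal length (see
#'   [projection_series()]).
#' @param density_floor fraction of the maximal bin count below which a bin
#'   is not a state seed (default 0.10).
#' @param binwidth optional fixed bin width used for both axes; default
#'   `NULL` uses Freedman-Diaconis per axis.
#' @return An object of class `state_partition`: list with `assignments`
#'   (tibble `frame, pc1, pc2, state`), `states` (tibble
#'   `state, n_frames, probability, pc1_centroid, pc2_centroid`) and
#'   `dominant` (integer label, always 1).
#' @export
partition_states <- function(pc1, pc2, density_floor = 0.10, binwidth = NULL) {
  stopifnot(length(pc1) == length(pc2))
  n <- length(pc1)
  if (n < 1L) abort("no frames to partition")

  degenerate <- (max(pc1) - min(pc1) < 1e-12) && (max(pc2) - min(pc2) < 1e-12)
  if (degenerate) {
    assignments <- tibble::tibble(frame = seq_len(n), pc1 = pc1, pc2 = pc2,
                                  state = rep(1L, n))
    states <- tibble::tibble(state = 1L, n_frames = n, probability = 1,
                             pc1_centroid = mean(pc1), pc2_centroid = mean(pc2))
    return(structure(list(assignments = assignments, states = states,
                          dominant = 1L), class = "state_partition"))
  }

  ## Freedman-Diaconis width, with the bin count per axis capped so that a
  ## tight, well-separated cluster fills contiguous cells instead of
  ## fragmenting a sparse 2-D histogram into spurious components
  max_bins <- max(8, ceiling(2 * n^(1 / 3)))
  fd_width <- function(v) {
    h <- 2 * stats::IQR(v) * n^(-1 / 3)
    rng <- max(v) - min(v)
    if (!is.finite(h) || h <= 0) h <- if (rng > 0) rng / 10 else 1
    max(h, rng / max_bins)
  }
  h1 <- binwidth %||% fd_width(pc1)
  h2 <- binwidth %||% fd_width(pc2)

  bin_index <- function(v, h) {
    rng <- max(v) - min(v)
    if (rng < 1e-12) return(list(idx = rep(1L, n), centers = mean(v), nb = 1L))
    nb <- max(1L, ceiling(rng / h))
    idx <- pmin(nb, 1L + floor((v - min(v)) / h))
    centers <- min(v) + (seq_len(nb) - 0.5) * h
    list(idx = idx, centers = centers, nb = nb)
  }
  b1 <- bin_index(pc1, h1)
  b2 <- bin_index(pc2, h2)

  cell <- (b2$idx - 1L) * b1$nb + b1$idx
  counts <- table(cell)
  cell_ids <- as.integer(names(counts))
  cnt <- as.integer(counts)
  floor_n <- density_floor * max(cnt)
  dense <- cell_ids[cnt >= floor_n]

  ## connected components of dense cells, 4-neighborhood, deterministic order
  dense <- sort(dense)
  comp <- setNames(rep(NA_integer_, length(dense)), dense)
  dense_set <- as.character(dense)
  next_comp <- 0L
  for (start in dense) {
    key <- as.character(start)
    if (!is.na(comp[key])) next
    next_comp <- next_comp + 1L
    queue <- start
    comp[key] <- next_comp
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cx <- ((cur - 1L) %% b1$nb) + 1L
      cy <- ((cur - 1L) %/% b1$nb) + 1L
      nb_cells <- c(
        if (cx > 1L) cur - 1L,
        if (cx < b1$nb) cur + 1L,
        if (cy > 1L) cur - b1$nb,
        if (cy < b2$nb) cur + b1$nb
      )
      for (nc in nb_cells) {
        k <- as.character(nc)
        if (k %in% dense_set && is.na(comp[k])) {
          comp[k] <- next_comp
          queue <- c(queue, nc)
        }
      }
    }
  }

  ## frame -> component: dense cells directly, sparse frames to nearest dense cell
  cell_center <- function(cells) {
    cx <- ((cells - 1L) %% b1$nb) + 1L
    cy <- ((cells - 1L) %/% b1$nb) + 1L
    cbind(b1$centers[cx], b2$centers[cy])
  }
  dense_centers <- cell_center(dense)
  frame_comp <- integer(n)
  cell_chr <- as.character(cell)
  in_dense <- cell_chr %in% dense_set
  frame_comp[in_dense] <- comp[cell_chr[in_dense]]
  if (any(!in_dense)) {
    for (f in which(!in_dense)) {
      d2 <- (dense_centers[, 1] - pc1[f])^2 + (dense_centers[, 2] - pc2[f])^2
      frame_comp[f] <- comp[as.character(dense[which.min(d2)])]
    }
  }

  ## relabel by descending occupancy, ties by centroid lexicographic order
  summ <- tibble::tibble(comp = frame_comp, pc1 = pc1, pc2 = pc2) |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(n_frames = dplyr::n(),
                     pc1_centroid = mean(.data$pc1),
                     pc2_centroid = mean(.data$pc2), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_frames), .data$pc1_centroid, .data$pc2_centroid)
  relabel <- setNames(seq_len(nrow(summ)), summ$comp)
  state <- as.integer(relabel[as.character(frame_comp)])

  states <- summ |>
    dplyr::mutate(state = seq_len(nrow(summ)),
                  probability = .data$n_frames / n) |>
    dplyr::select("state", "n_frames", "probability", "pc1_centroid", "pc2_centroid")

  structure(
    list(assignments = tibble::tibble(frame = seq_len(n), pc1 = pc1,
                                      pc2 = pc2, state = state),
         states = states, dominant = 1L),
    class = "state_partition"
  )
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("<state_partition> %d states over %d frames; dominant state %d (p = %.3f)\n",
              nrow(x$states), nrow(x$assignments), x$dominant,
              x$states$probability[x$dominant]))
  invisible(x)
}

#' @describeIn partition_states tidy method: the frame assignments table.
#' @param x a `state_partition`.
#' @param ... unused.
#' @export
tidy.state_partition <- function(x, ...) x$assignments

#' @describeIn partition_states glance method: one-row summary.
#' @export
glance.state_partition <- function(x, ...) {
  tibble::tibble(
    n_states = nrow(x$states),
    n_frames = nrow(x$assignments),
    dominant_state = x$dominant,
    dominant_probability = x$states$probability[x$dominant]
  )
}

#' Frames of the most densely populated state, with weights
#'
#' Returns the dominant-state frames, each carrying a weight equal to the
#' dominant state's occupancy probability, for use as the `weights` argument
#' of downstream averages.  See the package's weighted-frames conventions:
#' with the default `"select"` convention weighted averages reduce to plain
#' means over the dominant-state frames; with `"multiply"` they are
#' additionally scaled by the state probability.
#'
#' @param part a `state_partition`.
#' @param convention `"select"` (default) or `"multiply"`.
#' @return A tibble `frame, weight` with a `convention` attribute.
#' @export
state_weighted_frames <- function(part, convention = c("select", "multiply")) {
  convention <- match.arg(convention)
  dom <- part$dominant
  p <- part$states$probability[part$states$state == dom]
  frames <- part$assignments$frame[part$assignments$state == dom]
  if (!length(frames)) abort("dominant state is empty (cannot happen by construction)")
  new_frame_weights(frames, rep(p, length(frames)), convention)
}
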