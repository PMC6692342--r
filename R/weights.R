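#' Weighted frame sets
#'
#' Several stages of the comparison (mean pair distances, distributions,
#' correlation maps) can be restricted to, and weighted by, the most densely
#' populated conformational state.  A weighted frame set is a tibble with
#' columns `frame` and `weight` plus a `convention` attribute:
#'
#' * `"select"` (default): averages are ordinary weighted means over the
#'   listed frames, `sum(w * x) / sum(w)`.  With a single state carrying a
#'   constant weight this reduces to the plain mean over the state's frames.
#' * `"multiply"`: averages are additionally scaled by the state probability,
#'   `sum(w * x) / n`, i.e. the dominant-state mean times its occupancy.
#'
#' Both conventions are exposed because the underlying convention
#' ("weighted the calculations by the probability of the state") admits
#' either reading; `"select"` keeps distances in Angstrom and is the
#' pipeline default.
#'
#' @name weighted-frames
#' @keywords internal
NULL

new_frame_weights <- function(frame, weight, convention = "select") {
  out <- tibble::tibble(frame = as.integer(frame), weight = as.numeric(weight))
  attr(out, "convention") <- convention
  out
}

## Resolve a weighted frame set against a trajectory: returns list(w, idx)
## with one weight per retained frame.  weights = NULL means all frames,
## weight 1.
resolve_weights <- function(traj, weights) {
  m <- n_frames(traj)
  if (is.null(weights)) {
    return(list(idx = seq_len(m), w = rep(1, m), convention = "select"))
  }
  stopifnot(all(c("frame", "weight") %in% names(weights)))
  if (any(weights$frame < 1L | weights$frame > m)) {
    abort("weighted frame set refers to frames outside the trajectory")
  }
  list(idx = weights$frame, w = weights$weight,
       convention = attr(weights, "convention") %||% "select")
}

weighted_frame_mean <- function(x, rw) {
  if (rw$convention == "multiply") sum(rw$w * x) / length(x) else
    sum(rw$w * x) / sum(rw$w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
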