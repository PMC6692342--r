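#' Plot a pair-distance difference map
#'
#' @param object a `delta_map` from [delta_matrix()].
#' @param ... unused.
#' @return A ggplot: residue-vs-residue points colored by the distance
#'   change (red = apart, blue = closer).
#' @export
autoplot.delta_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::bind_rows(df, dplyr::rename(df, i = "j", j = "i"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, color = .data$delta)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_gradient2(low = "blue", mid = "grey90", high = "red",
                                   name = expression(Delta * bar(R)[ij] ~ "(Å)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue i", y = "residue j") +
    ggplot2::theme_minimal()
}

#' Plot a correlation map
#'
#' @param object a [correlation_map()].
#' @param ... unused.
#' @return A ggplot raster of the pairwise fluctuation correlations.
#' @export
autoplot.correlation_map <- function(object, ...) {
  n <- nrow(object)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$correlation <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = expression(C[ij])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue i", y = "residue j",
                  title = attr(object, "condition")) +
    ggplot2::theme_minimal()
}

#' Plot a distance distribution
#'
#' @param object a [distance_distribution()].
#' @param ... unused.
#' @return A ggplot of the smoothed density with detected peaks marked.
#' @export
autoplot.distance_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peaks$position, linetype = "dashed",
                        color = "red") +
    ggplot2::labs(x = expression(R[ij] ~ "(Å)"), y = expression(W(R[ij])),
                  title = sprintf("pair %d-%d (%s)", object$pair[1],
                                  object$pair[2], object$condition)) +
    ggplot2::theme_minimal()
}

#' Plot a conformational state partition
#'
#' @param object a [partition_states()] result.
#' @param ... unused.
#' @return A ggplot of the (PC1, PC2) projections colored by state.
#' @export
autoplot.state_partition <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               color = factor(.data$state))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "PCA 1", y = "PCA 2", color = "state") +
    ggplot2::theme_minimal()
}

#' Plot RMSF profiles of both conditions
#'
#' @param rmsf_delta the `rmsf$delta` tibble of a [compare_conditions()]
#'   bundle (or any [difference_map()] of two RMSF profiles).
#' @return A ggplot with one line per condition.
#' @export
plot_rmsf <- function(rmsf_delta) {
  df <- tidyr::pivot_longer(rmsf_delta, c("rmsf_a", "rmsf_b"),
                            names_to = "condition", values_to = "rmsf")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$rmsf,
                                   color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
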