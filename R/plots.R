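#' Plot a correlation-distance profile
#'
#' Individual pair coefficients as points with the binned mean overlaid,
#' the standard view of distance-dependent noise correlations.
#'
#' @param object A `correlation_profile`.
#' @param points Show individual pairs (subsampled to at most
#'   `max_points`).
#' @param max_points Point cap for readability.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_profile <- function(object, points = TRUE,
                                         max_points = 5000, ...) {
  p <- ggplot2::ggplot(object$binned,
                       ggplot2::aes(.data$distance, .data$mean_r_sc))
  if (points && nrow(object$pairs) > 0) {
    pr <- object$pairs
    if (nrow(pr) > max_points) pr <- pr[sample.int(nrow(pr), max_points), ]
    p <- p + ggplot2::geom_point(
      data = pr, ggplot2::aes(.data$distance, .data$r_sc),
      alpha = 0.15, size = 0.4, colour = "steelblue")
  }
  p + ggplot2::geom_line(colour = "darkgreen", linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "pair distance (px)", y = expression(r[SC]))
}

#' Plot a spatial autocorrelation map
#'
#' @param object An `autocorr_map`.
#' @param ... Unused.
#' @return A ggplot object (lags centred on zero).
#' @export
autoplot.autocorr_map <- function(object, ...) {
  L <- object$L
  sh <- function(i) ifelse(i - 1 <= L / 2, i - 1, i - 1 - L)
  df <- tibble(
    dx = sh(rep(seq_len(L), times = L)),
    dy = sh(rep(seq_len(L), each = L)),
    acf = as.vector(object$acf)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$dx, .data$dy, fill = .data$acf)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lag x (px)", y = "lag y (px)", fill = "ACF")
}

#' Raster plot of spiking activity
#'
#' Spike positions on the grid within a time slice, the standard snapshot
#' view of bump and stripe patterns.
#'
#' @param object A `spike_data` with positions.
#' @param from,to Time slice (s); defaults to a 100 ms window after
#'   warm-up.
#' @param trial Trial to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_data <- function(object, from = NULL, to = NULL, trial = 1,
                                ...) {
  pos <- attr(object, "positions")
  if (is.null(pos)) abort("spike raster needs positions")
  warmup <- attr(object, "warmup") %||% 0
  if (is.null(from)) from <- warmup
  if (is.null(to)) to <- from + 0.1
  sp <- object[object$trial == trial & object$time >= from &
                 object$time < to, ]
  df <- tibble(x = pos$x[match(sp$neuron, pos$id)],
               y = pos$y[match(sp$neuron, pos$id)],
               pop = pos$pop[match(sp$neuron, pos$id)])
  ggplot2::ggplot(df[df$pop == "E", ], ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.5, colour = "navy") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("%.0f-%.0f ms", from * 1000, to * 1000))
}

#' Plot information measures
#'
#' @param object An `info_estimate`.
#' @param ... Unused.
#' @return A ggplot bar chart of the information triple.
#' @export
autoplot.info_estimate <- function(object, ...) {
  df <- tidy(object)
  df$measure <- factor(df$measure, levels = c("I_shuff", "I_LOLE", "I_diag"))
  ggplot2::ggplot(df, ggplot2::aes(.data$measure, .data$information,
                                   fill = .data$measure)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression(information~(deg^-2)))
}

#' Plot an activity-centre trajectory
#'
#' @param traj Output of [activity_center_trajectory()].
#' @param L Torus side (px), for axis limits.
#' @return A ggplot path per trial.
#' @export
plot_trajectory <- function(traj, L = NULL) {
  p <- ggplot2::ggplot(traj[traj$defined, ],
                       ggplot2::aes(.data$x, .data$y,
                                    group = .data$trial,
                                    colour = .data$t)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "t (s)")
  if (!is.null(L)) p <- p + ggplot2::lims(x = c(0, L), y = c(0, L))
  p
}
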