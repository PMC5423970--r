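#' Artificial orientation-preference map with pinwheels
#'
#' Builds a smooth, doubly periodic preferred-orientation map with a stated
#' number of pinwheel singularities, mimicking the pinwheel structure of
#' primary visual cortex. The construction is deterministic:
#' `po(x, y) = 1/2 * atan2(cos(2 pi m y / L), cos(2 pi m x / L))` in degrees,
#' which places `4 m^2` pinwheels of alternating chirality at the zero
#' crossings of the two cosines (for `m = 1`, at `(L/4, L/4)`, `(3L/4, L/4)`,
#' `(L/4, 3L/4)`, `(3L/4, 3L/4)`). Walking a full circle around any pinwheel
#' centre accumulates +-180 degrees of preferred orientation.
#'
#' @param grid A [grid_spec()].
#' @param n_pinwheels Number of pinwheels; must be `4 m^2` for integer `m`
#'   (4 for parity with a 100 x 100 network at 2 pinwheel pairs per axis).
#' @return An `orientation_map`: an `n_side` x `n_side` matrix of preferred
#'   orientations in degrees, wrapped to `[-90, 90)`, with attributes `L` and
#'   `n_pinwheels`. Entry `[ix, iy]` is the angle at lattice position
#'   `(ix - 1, iy - 1)`.
#' @examples
#' m <- build_orientation_map(grid_spec(50), 4)
#' count_pinwheels(m)  # 4
#' @export
build_orientation_map <- function(grid, n_pinwheels = 4) {
  if (!inherits(grid, "grid_spec")) abort("`grid` must be a grid_spec")
  m <- sqrt(n_pinwheels / 4)
  if (!isTRUE(all.equal(m, round(m))) || m < 1)
    abort("`n_pinwheels` must be 4 m^2 for an integer m (4, 16, 36, ...)")
  m <- as.integer(round(m))
  L <- grid$n_side
  xs <- 0:(L - 1)
  cx <- cos(2 * pi * m * xs / L)
  po <- 0.5 * atan2(rep(cx, each = L), rep(cx, times = L)) * 180 / pi
  po <- wrap_orientation(matrix(po, nrow = L, ncol = L))
  # po[ix, iy]: atan2(cos y, cos x) with x along rows
  structure(po, L = L, n_pinwheels = 4L * m^2, class = "orientation_map")
}

#' Preferred orientation at arbitrary positions
#'
#' Looks the map up at the nearest lattice point (used for off-lattice
#' inhibitory neurons, which inherit the map value at their position).
#'
#' @param map An `orientation_map`.
#' @param x,y Positions in px (any real values; wrapped periodically).
#' @return Preferred orientations in degrees in `[-90, 90)`.
#' @export
orientation_at <- function(map, x, y) {
  L <- attr(map, "L")
  ix <- (round(x) %% L) + 1L
  iy <- (round(y) %% L) + 1L
  map[cbind(ix, iy)]
}

#' Count pinwheel singularities in an orientation map
#'
#' Computes the winding number of the doubled orientation angle around every
#' unit plaquette of the (periodic) lattice; plaquettes with winding +-360
#' degrees contain a pinwheel.
#'
#' @param map An `orientation_map` (or plain matrix of orientations in
#'   degrees).
#' @return Integer count of singularities.
#' @export
count_pinwheels <- function(map) {
  L <- nrow(map)
  phi <- 2 * unclass(map)  # doubled angle, period 360
  nxt <- c(2:L, 1L)
  wrap180 <- function(a) ((a + 180) %% 360) - 180
  d1 <- wrap180(phi[nxt, ] - phi)          # (x,y) -> (x+1,y)
  d2 <- wrap180(phi[nxt, nxt] - phi[nxt, ])  # -> (x+1,y+1)
  d3 <- wrap180(phi[, nxt] - phi[nxt, nxt])  # -> (x,y+1)
  d4 <- wrap180(phi - phi[, nxt])          # -> (x,y)
  winding <- d1 + d2 + d3 + d4
  sum(abs(winding) > 180)
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("<orientation_map> %d x %d px, %d pinwheels\n",
              attr(x, "L"), attr(x, "L"), attr(x, "n_pinwheels")))
  invisible(x)
}

#' @rdname build_orientation_map
#' @param object An `orientation_map`.
#' @param ... Unused.
#' @export
autoplot.orientation_map <- function(object, ...) {
  L <- attr(object, "L")
  df <- tibble(
    x = rep(0:(L - 1), times = L),
    y = rep(0:(L - 1), each = L),
    po = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$po)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("#d73027", "#fee090", "#1a9850", "#4575b4", "#d73027"),
      limits = c(-90, 90), name = "PO (deg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
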