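#' Grid specification for a two-dimensional network
#'
#' Excitatory neurons sit on a regular `n_side` x `n_side` lattice (1 px
#' spacing, 1 px corresponding to 15 um of cortex); inhibitory neurons are
#' placed uniformly at random over the same periodic sheet at a 1:4 ratio to
#' the excitatory population.
#'
#' @param n_side Excitatory neurons per axis (the torus side length in px).
#' @param n_inh Number of inhibitory neurons; defaults to `n_side^2 / 4` and
#'   must equal it (the 1:4 inhibitory-to-excitatory ratio).
#' @param px_to_um Length scale, micrometres per pixel.
#' @return A `grid_spec` list.
#' @examples
#' grid_spec(10)
#' @export
grid_spec <- function(n_side, n_inh = n_side^2 / 4, px_to_um = 15) {
  stopifnot_scalar(n_side, "n_side", positive = TRUE)
  stopifnot_scalar(px_to_um, "px_to_um", positive = TRUE)
  if (n_side %% 2 != 0)
    abort("`n_side` must be even so that n_side^2 / 4 is an integer")
  if (!isTRUE(all.equal(n_inh * 4, n_side^2)))
    abort(sprintf(
      "`n_inh` must equal n_side^2 / 4 = %d (1:4 inhibitory ratio), got %s",
      as.integer(n_side^2 / 4), format(n_inh)))
  structure(list(n_side = as.integer(n_side), n_inh = as.integer(n_inh),
                 px_to_um = px_to_um, periodic = TRUE),
            class = "grid_spec")
}

#' Connectivity kernel specification
#'
#' Recurrent connections are drawn from Gaussian probability kernels over
#' pairwise torus distance, with fixed in-degrees. Kernel widths classify the
#' topology: `sigma_E < sigma_I` is a Mexican hat, equality a balanced hat,
#' `sigma_E > sigma_I` an inverse Mexican hat.
#'
#' @param sigma_E,sigma_I Gaussian widths (px) of excitatory and inhibitory
#'   connection kernels.
#' @param K_E,K_I Recurrent in-degrees (every neuron receives exactly `K_E`
#'   excitatory and `K_I` inhibitory connections).
#' @param D Dimensionality of the model space (2; 1 is allowed for line
#'   networks).
#' @return A `kernel_spec` list with a `profile` field in
#'   `c("mexican", "balanced", "inverse")`.
#' @examples
#' kernel_spec(sigma_E = 10, sigma_I = 15)$profile
#' @export
kernel_spec <- function(sigma_E = 10, sigma_I = 15, K_E = 400, K_I = 200,
                        D = 2) {
  stopifnot_scalar(sigma_E, "sigma_E", positive = TRUE)
  stopifnot_scalar(sigma_I, "sigma_I", positive = TRUE)
  if (K_E < 1 || K_I < 1) abort("in-degrees K_E and K_I must be >= 1")
  if (!D %in% c(1, 2)) abort("`D` must be 1 or 2")
  profile <- if (sigma_E < sigma_I) "mexican"
             else if (sigma_E > sigma_I) "inverse" else "balanced"
  structure(list(sigma_E = sigma_E, sigma_I = sigma_I,
                 K_E = as.integer(K_E), K_I = as.integer(K_I),
                 D = as.integer(D), profile = profile),
            class = "kernel_spec")
}

#' Neuron positions on the periodic sheet
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed controlling the random inhibitory placement.
#' @return A tibble with columns `id`, `pop` (`"E"`/`"I"`), `x`, `y` (px).
#'   Excitatory neurons occupy the integer lattice `{0, ..., n_side-1}^2`
#'   (row-major, x fastest); inhibitory positions are uniform on
#'   `[0, n_side)^2`.
#' @examples
#' build_positions(grid_spec(4), seed = 1)
#' @export
build_positions <- function(grid, seed = NULL) {
  if (!inherits(grid, "grid_spec")) abort("`grid` must be a grid_spec")
  L <- grid$n_side
  ex <- expand.grid(x = 0:(L - 1), y = 0:(L - 1))
  pos_I <- with_seed(seed, matrix(runif(2 * grid$n_inh, 0, L), ncol = 2))
  tibble(
    id = seq_len(L^2 + grid$n_inh),
    pop = rep(c("E", "I"), c(L^2, grid$n_inh)),
    x = c(ex$x, pos_I[, 1]),
    y = c(ex$y, pos_I[, 2])
  )
}

#' Torus (minimal-image) Euclidean distance
#'
#' @param p,q Positions: numeric vectors of length 2, or two-column matrices
#'   of matching size (recycled row-wise).
#' @param L Side length of the periodic domain (px).
#' @return Distances in px, at most `L * sqrt(2) / 2` in 2D.
#' @examples
#' torus_distance(c(0, 0), c(99, 0), L = 100)  # 1
#' @export
torus_distance <- function(p, q, L) {
  stopifnot_scalar(L, "L", positive = TRUE)
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  n <- max(nrow(p), nrow(q))
  p <- p[rep_len(seq_len(nrow(p)), n), , drop = FALSE]
  q <- q[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  if (any(!is.finite(p)) || any(!is.finite(q)))
    abort("positions must be finite")
  torus_distance_cpp(p[, 1], p[, 2], q[, 1], q[, 2], L)
}

#' Sample the distance-dependent random connectivity
#'
#' For every target neuron, exactly `K_E` excitatory and `K_I` inhibitory
#' presynaptic partners are drawn without replacement with probability
#' proportional to `exp(-d^2 / (2 sigma_Y^2))` over torus distance `d`
#' (`Y` the source population), excluding self-connections. Synaptic delays
#' grow linearly with distance at the conduction velocity and are floored at
#' one integration step at simulation time.
#'
#' @param positions Output of [build_positions()].
#' @param kernel A [kernel_spec()].
#' @param grid The [grid_spec()] used to build `positions`.
#' @param conduction_velocity Conduction velocity in px/s (0.2 m/s at
#'   15 um/px is about 13,000 px/s).
#' @param n_pinwheels Pinwheels of the artificial orientation map attached to
#'   the topology (see [build_orientation_map()]).
#' @param seed Integer seed; identical seeds give identical topologies.
#' @return A `network_topology` object: positions (with preferred
#'   orientations), per-target presynaptic source lists and delays (ms), and
#'   the specs used.
#' @examples
#' topo <- build_topology(grid_spec(10), kernel_spec(3, 4, K_E = 20, K_I = 10),
#'                        seed = 1)
#' @export
sample_connections <- function(positions, kernel, grid,
                               conduction_velocity = 13000, seed = NULL) {
  if (!inherits(kernel, "kernel_spec")) abort("`kernel` must be a kernel_spec")
  L <- grid$n_side
  pop <- ifelse(positions$pop == "E", 0L, 1L)
  res <- with_seed(seed,
    sample_connections_cpp(positions$x, positions$y, pop, L,
                           kernel$sigma_E, kernel$sigma_I,
                           kernel$K_E, kernel$K_I))
  n <- nrow(positions)
  ktot <- res$k_tot
  delay_ms <- res$dist / conduction_velocity * 1000
  structure(list(
    positions = positions,
    grid = grid, kernel = kernel,
    conduction_velocity = conduction_velocity,
    target = rep(seq_len(n), each = ktot),
    source = res$src + 1L,
    distance = res$dist,
    delay_ms = delay_ms,
    seed = seed
  ), class = "network_topology")
}

#' Build a complete network topology
#'
#' Convenience wrapper: positions, orientation map, and sampled connectivity
#' in one call, with component seeds spawned from one master seed.
#'
#' @inheritParams sample_connections
#' @inheritParams grid_spec
#' @param grid A [grid_spec()].
#' @param kernel A [kernel_spec()].
#' @param n_pinwheels Number of pinwheels in the attached orientation map.
#' @param seed Master seed.
#' @return A `network_topology` object (see [sample_connections()]) whose
#'   positions carry a `po` column of preferred orientations in degrees.
#' @export
build_topology <- function(grid, kernel, n_pinwheels = 4,
                           conduction_velocity = 13000, seed = NULL) {
  seeds <- child_seeds(seed, 2)
  positions <- build_positions(grid, seed = seeds[[1]])
  omap <- build_orientation_map(grid, n_pinwheels = n_pinwheels)
  positions$po <- orientation_at(omap, positions$x, positions$y)
  topo <- sample_connections(positions, kernel, grid,
                             conduction_velocity = conduction_velocity,
                             seed = seeds[[2]])
  topo$orientation_map <- omap
  topo$seed <- seed
  topo
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(
    "<network_topology> %d E + %d I neurons on a %d px torus (%s hat)\n",
    sum(x$positions$pop == "E"), sum(x$positions$pop == "I"),
    x$grid$n_side, x$kernel$profile))
  cat(sprintf("  sigma_E = %g px, sigma_I = %g px, K_E = %d, K_I = %d\n",
              x$kernel$sigma_E, x$kernel$sigma_I, x$kernel$K_E, x$kernel$K_I))
  cat(sprintf("  %d synapses, delays %.3f-%.3f ms\n", length(x$source),
              min(x$delay_ms), max(x$delay_ms)))
  invisible(x)
}

#' Tidy a network topology into an edge table
#'
#' @param x A `network_topology`.
#' @param ... Unused.
#' @return A tibble with one row per synapse: `target_id`, `source_id`,
#'   `source_pop`, `distance_px`, `delay_ms`.
#' @export
tidy.network_topology <- function(x, ...) {
  tibble(
    target_id = x$target,
    source_id = x$source,
    source_pop = x$positions$pop[x$source],
    distance_px = x$distance,
    delay_ms = x$delay_ms
  )
}
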