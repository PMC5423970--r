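#' Bump-field specification for surrogate spike data
#'
#' Describes a planted firing-rate field on the torus: a baseline rate plus
#' Gaussian bumps that may drift at a fixed speed. Surrogate spikes drawn
#' from this field emulate the moving-bump activity of the marginal phase
#' with known ground truth, so bump width, drift speed and the induced
#' correlation structure can be recovered and checked.
#'
#' @param L Grid side (px); one neuron per lattice site.
#' @param amplitude Bump peak rate above baseline (Hz).
#' @param width Bump Gaussian width (px).
#' @param n_bumps Number of bumps, placed on a regular lattice and offset by
#'   a per-trial random phase.
#' @param drift_speed Bump drift speed (px/s); direction resampled uniformly
#'   per trial.
#' @param baseline Baseline rate (Hz).
#' @param n_trials Number of trials.
#' @param duration Duration per trial (s).
#' @param random_phase Draw a uniform random bump-lattice offset per trial.
#' @return A `bump_field_spec` list.
#' @export
bump_field_spec <- function(L = 50, amplitude = 30, width = 6, n_bumps = 4,
                            drift_speed = 0, baseline = 1, n_trials = 1,
                            duration = 1, random_phase = TRUE) {
  if (amplitude < 0 || baseline < 0) abort("rates must be non-negative")
  stopifnot_scalar(L, "L", positive = TRUE)
  m <- sqrt(n_bumps)
  if (!isTRUE(all.equal(m, round(m))))
    abort("`n_bumps` must be a perfect square (regular bump lattice)")
  structure(list(L = as.integer(L), amplitude = amplitude, width = width,
                 n_bumps = as.integer(n_bumps), drift_speed = drift_speed,
                 baseline = baseline, n_trials = as.integer(n_trials),
                 duration = duration, random_phase = random_phase),
            class = "bump_field_spec")
}

# rate field (Hz) at grid positions for bump centres cx, cy
bump_rate_field <- function(spec, cx, cy) {
  L <- spec$L
  xs <- 0:(L - 1)
  rate <- matrix(spec$baseline, L, L)
  for (b in seq_along(cx)) {
    dx <- pmin(abs(xs - cx[b]), L - abs(xs - cx[b]))
    dy <- pmin(abs(xs - cy[b]), L - abs(xs - cy[b]))
    rate <- rate + spec$amplitude *
      outer(exp(-dx^2 / (2 * spec$width^2)), exp(-dy^2 / (2 * spec$width^2)))
  }
  rate
}

#' Generate inhomogeneous-Poisson spikes from a planted bump field
#'
#' One neuron per lattice site fires as an inhomogeneous Poisson process
#' whose rate is the bump field; with drift the centres move at the planted
#' speed with periodic wrap-around (direction resampled per trial). Rates
#' are piecewise constant over short slices (`dt_rate`), counts per slice
#' are Poisson, and spike times uniform within the slice.
#'
#' @param spec A [bump_field_spec()].
#' @param seed Integer seed.
#' @param dt_rate Rate discretisation step (s).
#' @param warmup Warm-up attribute attached to the output (the surrogate
#'   has no transient; defaults to 0).
#' @return A `spike_data` tibble (trial, neuron, time) with grid positions.
#' @export
generate_bump_spikes <- function(spec, seed = NULL, dt_rate = 0.01,
                                 warmup = 0) {
  L <- spec$L
  m <- as.integer(sqrt(spec$n_bumps))
  base_centers <- as.matrix(expand.grid(
    x = (seq_len(m) - 0.5) * L / m, y = (seq_len(m) - 0.5) * L / m))
  positions <- tibble(id = seq_len(L * L),
                      pop = "E",
                      x = rep(0:(L - 1), times = L),
                      y = rep(0:(L - 1), each = L))
  # positions: id = ix + iy*L + 1 must match bump_rate_field vectorisation,
  # which is rate[ix+1, iy+1] with x the row index
  with_seed(seed, {
    out <- vector("list", spec$n_trials)
    for (tr in seq_len(spec$n_trials)) {
      phase <- if (spec$random_phase) runif(2, 0, L) else c(0, 0)
      ang <- runif(1, 0, 2 * pi)
      vx <- spec$drift_speed * cos(ang)
      vy <- spec$drift_speed * sin(ang)
      nslices <- max(1L, ceiling(spec$duration / dt_rate))
      sl <- vector("list", nslices)
      for (s in seq_len(nslices)) {
        t0 <- (s - 1) * dt_rate
        len <- min(dt_rate, spec$duration - t0)
        cx <- (base_centers[, 1] + phase[1] + vx * (t0 + len / 2)) %% L
        cy <- (base_centers[, 2] + phase[2] + vy * (t0 + len / 2)) %% L
        rate <- bump_rate_field(spec, cx, cy)
        k <- rpois(L * L, as.vector(rate) * len)
        tot <- sum(k)
        if (tot == 0) next
        sl[[s]] <- tibble(
          trial = tr,
          neuron = rep.int(seq_len(L * L), k),
          time = t0 + runif(tot, 0, len))
      }
      out[[tr]] <- dplyr::bind_rows(sl) |> arrange(.data$neuron, .data$time)
    }
    new_spike_data(dplyr::bind_rows(out), n_neurons = L * L,
                   duration = spec$duration, warmup = warmup, L = L,
                   positions = positions)
  })
}

#' Trial-count matrix with planted distance-dependent correlations
#'
#' Draws trial spike counts from a discretised multivariate Gaussian with
#' given means, variances, and a planted correlation-versus-distance
#' function (counts rounded and floored at zero; with means at least three
#' standard deviations above zero the truncation bias is negligible).
#' Serves as the closed-form oracle for correlation recovery and for the
#' Fisher-information estimators.
#'
#' @param n_neurons Number of neurons.
#' @param n_trials Number of trials (observations).
#' @param mean Mean count, scalar or per neuron; or a function of the
#'   stimulus (see `stimulus`).
#' @param variance Count variance, scalar or per neuron.
#' @param rho Correlation as a function of pair distance, e.g.
#'   `function(d) 0.3 * exp(-d / 10)`; ignored off-diagonal if `NULL`
#'   (independent neurons).
#' @param positions Two-column matrix of neuron positions (px); default a
#'   1D line with unit spacing (distances on the circle).
#' @param L Torus side for the distance metric.
#' @param stimulus Optional per-trial stimulus labels; when `mean` is a
#'   function it is evaluated per stimulus value and must return a vector
#'   of per-neuron means.
#' @param discretize Round and floor the Gaussian draws (default TRUE).
#' @param seed Integer seed.
#' @return A [count_matrix] with distance metadata and stimulus labels.
#' @export
generate_correlated_counts <- function(n_neurons, n_trials, mean = 20,
                                       variance = 25, rho = NULL,
                                       positions = NULL, L = NULL,
                                       stimulus = NULL, discretize = TRUE,
                                       seed = NULL) {
  if (is.null(positions)) {
    positions <- cbind(seq_len(n_neurons) - 1, 0)
    if (is.null(L)) L <- n_neurons
  }
  if (is.null(L)) L <- max(positions) + 1
  d <- matrix(0, n_neurons, n_neurons)
  for (i in seq_len(n_neurons))
    d[i, ] <- torus_distance_cpp(rep(positions[i, 1], n_neurons),
                                 rep(positions[i, 2], n_neurons),
                                 positions[, 1], positions[, 2], L)
  R <- if (is.null(rho)) diag(n_neurons) else rho(d)
  diag(R) <- 1
  sdv <- sqrt(rep_len(variance, n_neurons))
  Sigma <- R * tcrossprod(sdv)
  ch <- tryCatch(chol(Sigma), error = function(e)
    abort("implied covariance matrix is not positive definite"))

  mu_for <- function(s) {
    if (is.function(mean)) rep_len(mean(s), n_neurons)
    else rep_len(mean, n_neurons)
  }
  with_seed(seed, {
    Z <- matrix(rnorm(n_trials * n_neurons), n_trials, n_neurons) %*% ch
    if (is.null(stimulus)) {
      Z <- sweep(Z, 2, mu_for(NA), "+")
    } else {
      stopifnot(length(stimulus) == n_trials)
      for (s in unique(stimulus)) {
        rows <- stimulus == s
        Z[rows, ] <- sweep(Z[rows, , drop = FALSE], 2, mu_for(s), "+")
      }
    }
    counts <- t(Z)
    if (discretize) counts <- pmax(round(counts), 0)
    new_count_matrix(counts, kind = "trial", T = NA_real_,
                     neurons = seq_len(n_neurons),
                     x = positions[, 1], y = positions[, 2], L = L,
                     stimulus = stimulus)
  })
}

#' Linear-Gaussian tuning fixture with closed-form Fisher information
#'
#' Counts `r = f + s f' + noise`, noise Gaussian with covariance `Q`
#' (optionally plus a differential-correlation component
#' `epsilon f' f'^T`, the information-limiting structure tangent to the
#' tuning manifold). The true Fisher information is `f'^T Q^-1 f'` and is
#' returned alongside the data, serving as the independent oracle for the
#' locally optimal linear estimator.
#'
#' @param f Baseline mean vector (length = neurons).
#' @param fprime Tuning derivative vector.
#' @param Q Noise covariance matrix (without the differential component).
#' @param epsilon Differential-correlation coefficient; 0 for none.
#' @param stimuli Stimulus values (degrees), e.g. `c(-1, 1)`.
#' @param n_per_stim Trials per stimulus.
#' @param discretize Round and floor to integer counts.
#' @param seed Integer seed.
#' @return A list: `counts` (a [count_matrix] with stimulus labels) and
#'   `info_true` (deg^-2, computed from the full covariance
#'   `Q + epsilon f' f'^T`).
#' @export
generate_linear_gaussian_counts <- function(f, fprime, Q, epsilon = 0,
                                            stimuli = c(-1, 1),
                                            n_per_stim = 1000,
                                            discretize = TRUE, seed = NULL) {
  p <- length(f)
  stopifnot(length(fprime) == p, all(dim(Q) == p))
  Qfull <- Q + epsilon * tcrossprod(fprime)
  ch <- chol(Qfull)
  n_trials <- n_per_stim * length(stimuli)
  stim <- rep(stimuli, each = n_per_stim)
  with_seed(seed, {
    Z <- matrix(rnorm(n_trials * p), n_trials, p) %*% ch
    M <- outer(stim, fprime) + matrix(f, n_trials, p, byrow = TRUE)
    counts <- t(M + Z)
    if (discretize) counts <- pmax(round(counts), 0)
    cm <- new_count_matrix(counts, kind = "trial", T = NA_real_,
                           neurons = seq_len(p),
                           x = seq_len(p) - 1, y = rep(0, p), L = p,
                           stimulus = stim)
    list(counts = cm,
         info_true = drop(crossprod(fprime, solve(Qfull, fprime))))
  })
}
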