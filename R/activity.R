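# count_matrix: neurons x observations matrix with metadata
new_count_matrix <- function(m, kind, T, neurons, x = NULL, y = NULL,
                             L = NULL, stimulus = NULL) {
  structure(m, kind = kind, T = T, neurons = as.integer(neurons),
            x = x, y = y, L = L, stimulus = stimulus,
            class = c("count_matrix", "matrix", "array"))
}

#' Construct a count matrix
#'
#' Wraps a plain neurons x observations matrix of spike counts in the
#' `count_matrix` container used by the correlation and decoding analyses,
#' e.g. for externally recorded counts or printed example tables.
#'
#' @param m Numeric matrix, neurons in rows, observations (trials or
#'   windows) in columns.
#' @param kind `"trial"` or `"window"`.
#' @param T Window / count interval length (s); `NA` if not applicable.
#' @param neurons Neuron ids (default row numbers).
#' @param x,y Neuron positions (px), for distance-resolved analyses.
#' @param L Torus side (px) for the distance metric.
#' @param stimulus Optional per-observation stimulus labels.
#' @return A `count_matrix`.
#' @examples
#' cm <- count_matrix(rbind(c(1, 2, 3, 4, 5), c(1, 1, 0, 3, 3)))
#' @export
count_matrix <- function(m, kind = "trial", T = NA_real_,
                         neurons = seq_len(nrow(m)), x = NULL, y = NULL,
                         L = NULL, stimulus = NULL) {
  m <- as.matrix(m)
  if (any(m < 0)) abort("spike counts must be non-negative")
  if (!is.null(stimulus) && length(stimulus) != ncol(m))
    abort("`stimulus` must have one label per observation (column)")
  new_count_matrix(m, kind = kind, T = T, neurons = neurons, x = x, y = y,
                   L = L, stimulus = stimulus)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d neurons x %d %s observations (T = %g s)\n",
              nrow(x), ncol(x), attr(x, "kind"), attr(x, "T")))
  invisible(x)
}

#' Sliding-window spike counts
#'
#' Boxcar counts `r_i(t, T)` over half-open windows `[t, t + T)` advancing
#' by `stride`, starting at the warm-up time. Each spike contributes to
#' every window that covers it. Counts from multiple trials are concatenated
#' column-wise (windows nested within trials).
#'
#' @param spikes A `spike_data` object.
#' @param T Window length (s).
#' @param stride Window advance (s); `stride = T` gives disjoint windows.
#' @param neurons Neuron ids to include (default: all excitatory neurons if
#'   positions are known, else all).
#' @return A `count_matrix` (neurons x windows) carrying neuron positions
#'   and, for trial-labelled spike data, per-window stimulus labels.
#' @export
sliding_window_counts <- function(spikes, T, stride = T, neurons = NULL) {
  stopifnot_scalar(T, "T", positive = TRUE)
  stopifnot_scalar(stride, "stride", positive = TRUE)
  warmup <- attr(spikes, "warmup") %||% 0
  duration <- attr(spikes, "duration")
  if (duration - warmup < T)
    abort("window length T exceeds the usable duration after warm-up")
  pos <- attr(spikes, "positions")
  if (is.null(neurons)) {
    neurons <- if (!is.null(pos)) pos$id[pos$pop == "E"]
               else seq_len(attr(spikes, "n_neurons"))
  }
  starts <- seq(warmup, duration - T + 1e-9, by = stride)
  trials <- sort(unique(spikes$trial))
  stim <- attr(spikes, "stimulus")

  count_one <- function(tr) {
    sp <- spikes[spikes$trial == tr, ]
    nw <- length(starts)
    nn <- length(neurons)
    idx <- match(sp$neuron, neurons)
    keep <- !is.na(idx)
    ts <- sp$time[keep]; idx <- idx[keep]
    acc <- integer(nn * nw)
    if (length(ts)) {
      # window w covers spike t iff start_w <= t < start_w + T;
      # starts form an arithmetic sequence, so the covering windows are a
      # contiguous index range handled by constant offsets
      w_hi <- pmin(floor((ts - warmup) / stride) + 1, nw)
      w_lo <- pmax(ceiling((ts - warmup - T) / stride + 1e-12) + 1, 1)
      maxcov <- max(0, max(w_hi - w_lo))
      for (off in 0:maxcov) {
        w <- w_lo + off
        sel <- w <= w_hi & ts >= starts[pmin(w, nw)] &
               ts < starts[pmin(w, nw)] + T
        if (any(sel))
          acc <- acc + tabulate(idx[sel] + (w[sel] - 1L) * nn,
                                nbins = nn * nw)
      }
    }
    matrix(acc, nrow = nn, ncol = nw)
  }
  mats <- lapply(trials, count_one)
  out <- do.call(cbind, mats)
  labels <- if (!is.null(stim))
    rep(stim[match(trials, sort(unique(spikes$trial)))], each = length(starts))
  new_count_matrix(out, kind = "window", T = T, neurons = neurons,
                   x = if (!is.null(pos)) pos$x[match(neurons, pos$id)],
                   y = if (!is.null(pos)) pos$y[match(neurons, pos$id)],
                   L = attr(spikes, "L"), stimulus = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise spike-count noise correlations versus distance
#'
#' Pearson correlation `r_SC = Cov(r_i, r_j) / sqrt(Var(r_i) Var(r_j))` of
#' spike counts for neuron pairs, with pair distances measured on the torus.
#' Pairs containing a zero-variance neuron are excluded from averages (and
#' counted), never propagated as NaN.
#'
#' @param counts A [count_matrix] with at least two observations.
#' @param max_distance Keep only pairs at most this far apart (px); `NULL`
#'   for all.
#' @param n_pairs If not `NULL`, a random subsample of this many pairs
#'   (recommended for large populations).
#' @param bin_width Distance bin width (px) for the binned profile.
#' @param min_pairs_per_bin Bins with fewer pairs are dropped from the
#'   binned summary.
#' @param seed Seed for the pair subsample.
#' @return A `correlation_profile`: list with `pairs` (tibble `i`, `j`,
#'   `distance`, `r_sc`), `binned` (tibble `distance`, `mean_r_sc`,
#'   `n_pairs`), and `n_excluded`.
#' @export
pairwise_noise_correlation <- function(counts, max_distance = NULL,
                                       n_pairs = NULL, bin_width = 1,
                                       min_pairs_per_bin = 20, seed = NULL) {
  if (ncol(counts) < 2) abort("need at least 2 observations per neuron")
  m <- unclass(counts)
  x <- attr(counts, "x"); y <- attr(counts, "y"); L <- attr(counts, "L")
  n <- nrow(m)
  if (is.null(x)) { x <- rep(0, n); y <- rep(0, n); L <- 1 }

  pick <- with_seed(seed, {
    if (!is.null(n_pairs)) {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      keep <- i < j
      cbind(i[keep], j[keep])
    } else {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      cbind(idx[, 1], idx[, 2])
    }
  })
  d <- torus_distance_cpp(x[pick[, 1]], y[pick[, 1]],
                          x[pick[, 2]], y[pick[, 2]], L)
  if (!is.null(max_distance)) {
    keep <- d <= max_distance
    pick <- pick[keep, , drop = FALSE]; d <- d[keep]
  }

  v <- apply(m, 1, var)
  ok_neuron <- v > 0
  ok <- ok_neuron[pick[, 1]] & ok_neuron[pick[, 2]]
  n_excluded <- sum(!ok)
  pick <- pick[ok, , drop = FALSE]; d <- d[ok]

  if (nrow(pick) == 0) {
    warn("all pairs degenerate (zero count variance); empty profile")
    return(structure(list(
      pairs = tibble(i = integer(), j = integer(), distance = numeric(),
                     r_sc = numeric()),
      binned = tibble(distance = numeric(), mean_r_sc = numeric(),
                      n_pairs = integer()),
      n_excluded = n_excluded, T = attr(counts, "T")),
      class = "correlation_profile"))
  }

  z <- m[ok_neuron, , drop = FALSE]
  z <- (z - rowMeans(z)) / sqrt(apply(z, 1, var))
  remap <- cumsum(ok_neuron)
  r <- rowSums(z[remap[pick[, 1]], , drop = FALSE] *
               z[remap[pick[, 2]], , drop = FALSE]) / (ncol(m) - 1)

  pairs <- tibble(i = attr(counts, "neurons")[pick[, 1]],
                  j = attr(counts, "neurons")[pick[, 2]],
                  distance = d, r_sc = r)
  binned <- pairs |>
    mutate(bin = floor(.data$distance / bin_width)) |>
    group_by(.data$bin) |>
    summarise(distance = (.data$bin[1] + 0.5) * bin_width,
              mean_r_sc = mean(.data$r_sc), n_pairs = n(),
              .groups = "drop") |>
    filter(.data$n_pairs >= min_pairs_per_bin) |>
    arrange(.data$distance) |>
    dplyr::select("distance", "mean_r_sc", "n_pairs")
  structure(list(pairs = pairs, binned = binned, n_excluded = n_excluded,
                 T = attr(counts, "T")),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf(
    "<correlation_profile> %d pairs (%d excluded), mean r_SC = %.4f\n",
    nrow(x$pairs), x$n_excluded, mean(x$pairs$r_sc)))
  invisible(x)
}

#' @export
tidy.correlation_profile <- function(x, ...) x$binned

#' @export
glance.correlation_profile <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), n_excluded = x$n_excluded,
         mean_r_sc = mean(x$pairs$r_sc), T = x$T %||% NA_real_)
}

#' Mean near-pair noise correlation
#'
#' Average `r_SC` over pairs at most `max_distance` px apart (13.3 px
#' corresponds to 0.2 mm of cortex at 15 um/px), the summary used for the
#' operating-regime sweeps.
#'
#' @inheritParams pairwise_noise_correlation
#' @return A single number.
#' @export
mean_near_correlation <- function(counts, max_distance = 13.3,
                                  n_pairs = NULL, seed = NULL) {
  prof <- pairwise_noise_correlation(counts, max_distance = max_distance,
                                     n_pairs = n_pairs, seed = seed)
  mean(prof$pairs$r_sc)
}

#' Noise correlation as a function of integration window length
#'
#' Computes the mean near-pair `r_SC` for each window length `T`, using
#' sliding-window counts over a single long presentation (correlation
#' magnitude saturates with `T` once windows exceed the dwell time of the
#' activity pattern).
#'
#' @param spikes A `spike_data` object (single long presentation).
#' @param T_values Window lengths (s); the longest should not exceed a third
#'   of the usable duration for a reliable estimate.
#' @param stride Window advance; default `T / 2`.
#' @param max_distance Pair-distance cutoff (px).
#' @param n_pairs Random pair subsample size.
#' @param seed Seed for the pair subsample (the same pairs are used at every
#'   `T`).
#' @return A tibble `T`, `mean_r_sc`, `n_pairs`.
#' @export
correlation_vs_window <- function(spikes, T_values, stride = NULL,
                                  max_distance = 13.3, n_pairs = 2000,
                                  seed = NULL) {
  purrr::map_dfr(T_values, function(T) {
    cm <- sliding_window_counts(spikes, T = T,
                                stride = if (is.null(stride)) T / 2 else stride)
    prof <- pairwise_noise_correlation(cm, max_distance = max_distance,
                                       n_pairs = n_pairs, seed = seed)
    tibble(T = T, mean_r_sc = mean(prof$pairs$r_sc),
           n_pairs = nrow(prof$pairs))
  })
}

#' Spatial autocorrelation of population activity
#'
#' Samples short windows of activity, forms the excitatory spike-count grid
#' for each, and computes the mean-subtracted circular autocorrelation via
#' the 2D FFT, normalised to unit zero lag and averaged over samples (and
#' trials). Also returns the radially averaged power spectrum and its
#' dominant spatial frequency (peak excluding the DC bin, in cycles per
#' 100 px).
#'
#' @param spikes A `spike_data` with excitatory grid layout.
#' @param n_samples Number of sampled windows per trial.
#' @param window Sample window length (s).
#' @param seed Seed for the window sample times.
#' @return An `autocorr_map`: list with `acf` (L x L matrix, zero lag at
#'   `[1, 1]`), `radial` (tibble `lag`, `acf`), `spectrum` (tibble
#'   `freq_cycles_per_100px`, `power`), `dominant_frequency`, and
#'   `n_skipped` (zero-variance samples).
#' @export
spatial_autocorrelation <- function(spikes, n_samples = 100, window = 0.01,
                                    seed = NULL) {
  pos <- attr(spikes, "positions")
  L <- attr(spikes, "L")
  if (is.null(pos) || is.null(L))
    abort("spatial autocorrelation needs grid positions")
  warmup <- attr(spikes, "warmup") %||% 0
  duration <- attr(spikes, "duration")
  eid <- pos$id[pos$pop == "E"]
  ex <- pos$x[pos$pop == "E"]; ey <- pos$y[pos$pop == "E"]
  trials <- unique(spikes$trial)
  if (length(trials) == 0) trials <- 1L  # no spikes: every sample is skipped

  starts <- with_seed(seed,
    runif(n_samples * length(trials), warmup, duration - window))
  acc <- matrix(0, L, L); pow <- matrix(0, L, L); used <- 0L; skipped <- 0L
  k <- 0L
  for (tr in trials) {
    sp <- spikes[spikes$trial == tr, ]
    idx <- match(sp$neuron, eid)
    keep <- !is.na(idx)
    ts <- sp$time[keep]; idx <- idx[keep]
    gx <- ex[idx] + 1L; gy <- ey[idx] + 1L
    for (s in seq_len(n_samples)) {
      k <- k + 1L
      inw <- ts >= starts[k] & ts < starts[k] + window
      grid <- matrix(0, L, L)
      if (any(inw)) {
        tab <- table(factor(gx[inw] + (gy[inw] - 1L) * L,
                            levels = seq_len(L * L)))
        grid[] <- as.numeric(tab)
      }
      g0 <- grid - mean(grid)
      if (all(g0 == 0)) { skipped <- skipped + 1L; next }
      F <- fft(g0)
      P <- Mod(F)^2
      ac <- Re(fft(P, inverse = TRUE)) / (L * L)
      acc <- acc + ac / ac[1, 1]
      pow <- pow + P
      used <- used + 1L
    }
  }
  if (used == 0L) {
    return(structure(list(acf = matrix(NA_real_, L, L),
                          radial = tibble(lag = numeric(), acf = numeric()),
                          spectrum = tibble(freq_cycles_per_100px = numeric(),
                                            power = numeric()),
                          dominant_frequency = NA_real_,
                          n_skipped = skipped, L = L),
                     class = "autocorr_map"))
  }
  acf <- acc / used
  pow <- pow / used

  # radial averages on the lag torus / frequency grid
  lag1 <- pmin(0:(L - 1), L - (0:(L - 1)))
  lagr <- sqrt(outer(lag1^2, lag1^2, "+"))
  radial <- tibble(lag = as.vector(round(lagr)), acf = as.vector(acf)) |>
    group_by(.data$lag) |> summarise(acf = mean(.data$acf), .groups = "drop")

  freqr <- round(sqrt(outer(lag1^2, lag1^2, "+")))  # cycles per L px
  spec <- tibble(k = as.vector(freqr), power = as.vector(pow)) |>
    group_by(.data$k) |> summarise(power = mean(.data$power), .groups = "drop") |>
    filter(.data$k > 0, .data$k <= floor(L / 2)) |>
    mutate(freq_cycles_per_100px = .data$k * 100 / L)
  dom <- spec$freq_cycles_per_100px[which.max(spec$power)]
  structure(list(acf = acf, radial = radial,
                 spectrum = dplyr::select(spec, "freq_cycles_per_100px",
                                          "power"),
                 dominant_frequency = dom, n_skipped = skipped, L = L),
            class = "autocorr_map")
}

#' @export
print.autocorr_map <- function(x, ...) {
  cat(sprintf(
    "<autocorr_map> %d x %d lags, dominant frequency %.2f cycles/100 px (%d samples skipped)\n",
    x$L, x$L, x$dominant_frequency, x$n_skipped))
  invisible(x)
}

#' Contrast of a spatial autocorrelation map
#'
#' Root-mean-square of the normalised autocorrelation over non-zero lags
#' beyond a guard radius; spatially inhomogeneous (patterned) activity gives
#' large values, homogeneous activity values near zero.
#'
#' @param map An `autocorr_map`.
#' @param min_lag Ignore lags below this radius (px), which reflect single
#'   neuron autocovariance rather than pattern.
#' @return A single number.
#' @export
autocorr_contrast <- function(map, min_lag = 3) {
  L <- map$L
  lag1 <- pmin(0:(L - 1), L - (0:(L - 1)))
  lagr <- sqrt(outer(lag1^2, lag1^2, "+"))
  sqrt(mean(map$acf[lagr >= min_lag]^2))
}

#' Dominant spatial frequency of a correlation-distance profile
#'
#' Interpolates the binned mean `r_SC` versus distance profile onto a
#' regular grid and returns the peak of its Fourier amplitude spectrum
#' (excluding DC), in cycles per 100 px. Used to compare the oscillation of
#' noise correlations with the spatial autocorrelation of activity.
#'
#' @param profile A `correlation_profile`.
#' @param max_distance Use the profile up to this distance (px); defaults to
#'   the largest binned distance.
#' @return Frequency in cycles per 100 px.
#' @export
profile_spatial_frequency <- function(profile, max_distance = NULL) {
  b <- profile$binned
  if (is.null(max_distance)) max_distance <- max(b$distance)
  b <- b[b$distance <= max_distance, ]
  if (nrow(b) < 8) abort("profile too short for a frequency estimate")
  grid <- seq(min(b$distance), max(b$distance), length.out = 128)
  y <- stats::approx(b$distance, b$mean_r_sc, xout = grid)$y
  y <- y - mean(y)
  span <- max(b$distance) - min(b$distance)
  amp <- Mod(fft(y))[2:(64)]
  k <- which.max(amp)  # cycles per span
  k / span * 100
}

#' Activity-centre trajectory
#'
#' For consecutive sliding windows, computes the activity-weighted circular
#' mean of neuron positions on the torus (each axis via the resultant of the
#' angles `2 pi x / L`), tracking the centre of an activity bump over time.
#' Windows without spikes yield `NA` centres (gap markers); windows whose
#' resultant length is below `min_resultant` are flagged undefined (e.g. two
#' equal antipodal clusters).
#'
#' @param spikes A `spike_data` with positions.
#' @param region Optional logical mask or vector of neuron ids restricting
#'   the analysis to a region (e.g. around one pinwheel).
#' @param window Window length (s).
#' @param stride Window advance (s).
#' @param min_resultant Minimum mean resultant length for a defined centre.
#' @return A tibble `trial`, `t` (window start), `x`, `y` (px), `n_spikes`,
#'   `resultant`, `defined`.
#' @export
activity_center_trajectory <- function(spikes, region = NULL, window = 0.25,
                                       stride = window / 2,
                                       min_resultant = 0.05) {
  pos <- attr(spikes, "positions")
  L <- attr(spikes, "L")
  if (is.null(pos) || is.null(L)) abort("needs positions and grid size")
  ids <- pos$id[pos$pop == "E"]
  if (!is.null(region)) {
    ids <- if (is.logical(region)) ids[region] else intersect(ids, region)
    if (length(ids) == 0) abort("empty region mask")
  }
  warmup <- attr(spikes, "warmup") %||% 0
  duration <- attr(spikes, "duration")
  starts <- seq(warmup, duration - window, by = stride)
  px <- pos$x[match(ids, pos$id)]; py <- pos$y[match(ids, pos$id)]
  thx <- 2 * pi * px / L; thy <- 2 * pi * py / L

  purrr::map_dfr(unique(spikes$trial), function(tr) {
    sp <- spikes[spikes$trial == tr & spikes$neuron %in% ids, ]
    idx <- match(sp$neuron, ids)
    purrr::map_dfr(starts, function(t0) {
      inw <- sp$time >= t0 & sp$time < t0 + window
      nsp <- sum(inw)
      if (nsp == 0)
        return(tibble(trial = tr, t = t0, x = NA_real_, y = NA_real_,
                      n_spikes = 0L, resultant = NA_real_, defined = FALSE))
      w <- tabulate(idx[inw], nbins = length(ids))
      Cx <- sum(w * cos(thx)); Sx <- sum(w * sin(thx))
      Cy <- sum(w * cos(thy)); Sy <- sum(w * sin(thy))
      Rres <- min(sqrt(Cx^2 + Sx^2), sqrt(Cy^2 + Sy^2)) / sum(w)
      cx <- (atan2(Sx, Cx) / (2 * pi) * L) %% L
      cy <- (atan2(Sy, Cy) / (2 * pi) * L) %% L
      tibble(trial = tr, t = t0, x = cx, y = cy, n_spikes = nsp,
             resultant = Rres, defined = Rres >= min_resultant)
    })
  })
}

#' Mean speed of an activity-centre trajectory
#'
#' Torus displacement between consecutive defined centres divided by the
#' window stride, averaged per trial.
#'
#' @param traj Output of [activity_center_trajectory()].
#' @param L Torus side (px).
#' @return Mean speed in px/s.
#' @export
trajectory_speed <- function(traj, L) {
  sp <- traj |>
    group_by(.data$trial) |>
    summarise(speed = {
      ok <- .data$defined
      xs <- .data$x[ok]; ys <- .data$y[ok]; ts <- .data$t[ok]
      if (length(xs) < 2) NA_real_ else {
        d <- torus_distance_cpp(xs[-length(xs)], ys[-length(ys)],
                                xs[-1], ys[-1], L)
        mean(d / diff(ts))
      }
    }, .groups = "drop")
  mean(sp$speed, na.rm = TRUE)
}

#' Subset a count matrix to a sample of readout neurons
#'
#' Uniform sampling without replacement among the rows (used to draw readout
#' populations for the information analyses).
#'
#' @param counts A [count_matrix].
#' @param n Number of neurons to keep, or a vector of row indices.
#' @param seed Seed for the uniform sample.
#' @return A `count_matrix` with the subset of rows and matching metadata.
#' @export
sample_neurons <- function(counts, n, seed = NULL) {
  idx <- if (length(n) > 1) as.integer(n)
         else with_seed(seed, sample.int(nrow(counts), n))
  m <- unclass(counts)[idx, , drop = FALSE]
  new_count_matrix(m, kind = attr(counts, "kind"), T = attr(counts, "T"),
                   neurons = attr(counts, "neurons")[idx],
                   x = attr(counts, "x")[idx], y = attr(counts, "y")[idx],
                   L = attr(counts, "L"), stimulus = attr(counts, "stimulus"))
}
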