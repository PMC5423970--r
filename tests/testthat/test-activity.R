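test_that("sliding-window counts use half-open boxcar windows from the warm-up", {
  sp <- spike_data(tibble::tibble(trial = 1L, neuron = c(1L, 1L),
                                  time = c(1.2, 1.8)),
                   n_neurons = 2, duration = 2, warmup = 1)
  cm <- sliding_window_counts(sp, T = 1, stride = 1)
  expect_equal(dim(cm), c(2L, 1L))
  expect_equal(unclass(cm)[1, 1], 2)
  expect_equal(unclass(cm)[2, ], 0)  # empty train: all-zero row
  # disjoint windows partition the analysed span
  set.seed(1)
  sp2 <- spike_data(tibble::tibble(trial = 1L,
                                   neuron = sample(1:5, 200, TRUE),
                                   time = runif(200, 0, 4)),
                    n_neurons = 5, duration = 4, warmup = 1)
  cm2 <- sliding_window_counts(sp2, T = 0.5, stride = 0.5)
  expect_equal(sum(cm2), sum(sp2$time >= 1 & sp2$time < 4))
  expect_error(sliding_window_counts(sp, T = 2), "usable duration")
})

test_that("the Pearson coefficient matches the printed worked example", {
  cm <- count_matrix(rbind(c(1, 2, 3, 4, 5), c(1, 1, 0, 3, 3)))
  prof <- pairwise_noise_correlation(cm)
  expect_equal(prof$pairs$r_sc, 6 / sqrt(72), tolerance = 1e-12)
  # identical rows correlate perfectly; constant rows are excluded, not NaN
  cm2 <- count_matrix(rbind(c(1, 2, 3), c(1, 2, 3), c(2, 2, 2)))
  prof2 <- pairwise_noise_correlation(cm2)
  expect_equal(prof2$pairs$r_sc, 1)
  expect_equal(prof2$n_excluded, 2L)
  expect_false(any(is.na(prof2$pairs$r_sc)))
  cm3 <- count_matrix(rbind(c(2, 2, 2), c(5, 5, 5)))
  expect_warning(pairwise_noise_correlation(cm3), "degenerate")
})

test_that("spatial autocorrelation recovers a planted sinusoid at 2 cycles per 100 px", {
  L <- 50
  rate <- 10 + 8 * sin(2 * pi * (0:(L - 1)) / L)  # 1 cycle per 50 px
  lam <- as.vector(outer(rate, rep(1, L)))
  set.seed(2)
  nsl <- 200; dur <- 2
  sl <- lapply(seq_len(nsl), function(s) {
    k <- rpois(L * L, lam * dur / nsl)
    tibble::tibble(trial = 1L, neuron = rep.int(seq_len(L * L), k),
                   time = runif(sum(k), (s - 1) * dur / nsl, s * dur / nsl))
  })
  spd <- spike_data(dplyr::bind_rows(sl), n_neurons = L * L, duration = dur,
                    L = L,
                    positions = tibble::tibble(id = seq_len(L * L), pop = "E",
                                               x = rep(0:(L - 1), times = L),
                                               y = rep(0:(L - 1), each = L)))
  ac <- spatial_autocorrelation(spd, n_samples = 80, window = 0.01, seed = 3)
  expect_equal(ac$dominant_frequency, 2, tolerance = 1e-9)
  # unit zero lag and symmetry under lag negation
  expect_equal(ac$acf[1, 1], 1)
  flip <- ac$acf[c(1, L:2), c(1, L:2)]
  expect_equal(ac$acf, flip, tolerance = 1e-9)
})

test_that("a constant field yields a defined empty autocorrelation result", {
  L <- 8
  spd <- spike_data(tibble::tibble(trial = 1L, neuron = integer(),
                                   time = numeric()),
                    n_neurons = L * L, duration = 1, L = L,
                    positions = tibble::tibble(id = seq_len(L * L), pop = "E",
                                               x = rep(0:(L - 1), times = L),
                                               y = rep(0:(L - 1), each = L)))
  ac <- spatial_autocorrelation(spd, n_samples = 10, seed = 4)
  expect_equal(ac$n_skipped, 10L)
  expect_true(is.na(ac$dominant_frequency))
})

test_that("bump width is recovered from the autocorrelation against the field oracle", {
  spec <- bump_field_spec(L = 40, amplitude = 60, width = 5, n_bumps = 1,
                          baseline = 0.5, n_trials = 40, duration = 0.5)
  sp <- generate_bump_spikes(spec, seed = 5)
  ac <- spatial_autocorrelation(sp, n_samples = 3, window = 0.3, seed = 6)
  w_emp <- acf_half_lag(ac$radial)
  w_th <- acf_half_lag(field_radial_acf(spec))
  expect_lt(abs(w_emp - w_th) / w_th, 0.15)
})

test_that("activity centres track mass on the torus and flag degeneracies", {
  pos <- tibble::tibble(id = 1:3, pop = "E",
                        x = c(10, 0, 20), y = c(20, 0, 0))
  one <- spike_data(tibble::tibble(trial = 1L, neuron = rep(1L, 20),
                                   time = seq(0.01, 0.99, length.out = 20)),
                    n_neurons = 3, duration = 1, L = 40, positions = pos)
  tr <- activity_center_trajectory(one, window = 0.25, stride = 0.25)
  expect_true(all(abs(tr$x - 10) < 1e-6))
  expect_true(all(abs(tr$y - 20) < 1e-6))
  # two equal antipodal clusters: resultant collapses, centre undefined
  anti <- spike_data(tibble::tibble(trial = 1L,
                                    neuron = rep(c(2L, 3L), each = 20),
                                    time = rep(seq(0.01, 0.99, length.out = 20), 2)),
                     n_neurons = 3, duration = 1, L = 40, positions = pos)
  tr2 <- activity_center_trajectory(anti, window = 0.25, stride = 0.25)
  expect_false(any(tr2$defined))
  # windows without spikes are gap markers
  gap <- spike_data(tibble::tibble(trial = 1L, neuron = 1L, time = 0.1),
                    n_neurons = 3, duration = 1, L = 40, positions = pos)
  tr3 <- activity_center_trajectory(gap, window = 0.25, stride = 0.25)
  expect_true(any(!tr3$defined & tr3$n_spikes == 0))
})

test_that("planted drift speed is recovered from centre trajectories within 10 percent", {
  spec <- bump_field_spec(L = 40, amplitude = 60, width = 5, n_bumps = 1,
                          baseline = 0.5, n_trials = 5, duration = 2,
                          drift_speed = 15)
  sp <- generate_bump_spikes(spec, seed = 7)
  traj <- activity_center_trajectory(sp, window = 0.25, stride = 0.125)
  v <- trajectory_speed(traj, L = 40)
  expect_lt(abs(v - 15) / 15, 0.10)
})

test_that("correlation versus window length is flat for homogeneous Poisson data", {
  spec <- bump_field_spec(L = 16, amplitude = 0, baseline = 15, n_trials = 1,
                          duration = 20)
  sp <- generate_bump_spikes(spec, seed = 8)
  cv <- correlation_vs_window(sp, c(0.2, 0.5, 1, 2), n_pairs = 3000, seed = 9,
                              max_distance = Inf)
  expect_true(all(abs(cv$mean_r_sc) < 0.02))
})

test_that("doubling the stride changes only estimator variance, not the expected value", {
  spec <- bump_field_spec(L = 20, amplitude = 30, width = 4, n_bumps = 1,
                          baseline = 3, n_trials = 1, duration = 30,
                          drift_speed = 10)
  sp <- generate_bump_spikes(spec, seed = 10)
  r1 <- correlation_vs_window(sp, 1, stride = 0.5, n_pairs = 4000, seed = 11,
                              max_distance = 8)
  r2 <- correlation_vs_window(sp, 1, stride = 1, n_pairs = 4000, seed = 11,
                              max_distance = 8)
  expect_lt(abs(r1$mean_r_sc - r2$mean_r_sc), 0.1)
  expect_gt(r1$mean_r_sc, 0.2)  # drifting bump correlates nearby cells
})
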