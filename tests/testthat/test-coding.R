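test_that("OSI matches its closed-form values and stays in [0, 1]", {
  s <- seq(-90, 75, by = 15)
  flat <- tibble::tibble(neuron = 1, orientation = s, mean_count = 2)
  expect_equal(osi(flat)$mean_osi, 0, tolerance = 1e-12)
  single <- tibble::tibble(neuron = 1, orientation = s,
                           mean_count = as.numeric(s == -30))
  expect_equal(osi(single)$mean_osi, 1, tolerance = 1e-12)
  cosine <- tibble::tibble(neuron = 1, orientation = s,
                           mean_count = 1 + cos(2 * s * pi / 180))
  expect_equal(osi(cosine)$mean_osi, 0.5, tolerance = 1e-12)
  set.seed(1)
  many <- tibble::tibble(neuron = rep(1:40, each = 12),
                         orientation = rep(s, 40),
                         mean_count = runif(480, 0, 5))
  o <- osi(many)
  expect_true(all(o$per_neuron$osi >= 0 & o$per_neuron$osi <= 1))
  # all-zero neurons are excluded with a count
  zero <- tibble::tibble(neuron = rep(1:2, each = 12), orientation = rep(s, 2),
                         mean_count = rep(c(1, 0), each = 12))
  expect_equal(osi(zero)$n_excluded, 1L)
})

test_that("shuffling preserves per-neuron marginals exactly and kills correlations", {
  # printed example: totals per neuron are invariant
  tab <- count_matrix(rbind(c(1, 2, 3, 4, 5), c(1, 1, 0, 3, 3),
                            c(1, 2, 0, 5, 4)))
  sh <- shuffle_counts(tab, seed = 2)
  expect_equal(rowSums(sh), c(15, 8, 12))
  for (i in 1:3) expect_equal(sort(sh[i, ]), sort(unclass(tab)[i, ]))
  # single-observation input is returned unchanged
  one <- count_matrix(cbind(c(3, 1)))
  expect_equal(unclass(shuffle_counts(one, seed = 3)), unclass(one))
  # correlations destroyed in expectation on strongly correlated counts
  cm <- generate_correlated_counts(30, 1500, mean = 20, variance = 25,
                                   rho = function(d) 0.5 * exp(-d / 20),
                                   seed = 4)
  sh2 <- shuffle_counts(cm, seed = 5)
  r <- pairwise_noise_correlation(sh2)$pairs$r_sc
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
  # shuffling respects stimulus classes: tuning (class means) unchanged
  stim <- rep(c(-1, 1), each = 20)
  cm2 <- count_matrix(matrix(rpois(200, 5), 5, 40), stimulus = stim)
  sh3 <- shuffle_counts(cm2, seed = 6)
  expect_equal(rowMeans(sh3[, stim == -1]), rowMeans(unclass(cm2)[, stim == -1]))
})

test_that("Fisher information from estimates follows the printed formula", {
  # worked example: means -0.8 and 0.9, variances 0.25 -> 2.89 deg^-2
  mk <- function(m) m + c(-0.5, 0.5) * sqrt(2 * 0.25)
  est2 <- tibble::tibble(stimulus = rep(c(-1, 1), each = 2),
                         s_hat = c(mk(-0.8), mk(0.9)))
  expect_equal(fisher_from_estimates(est2), 2.89, tolerance = 1e-12)
  # equal means carry no information
  est3 <- tibble::tibble(stimulus = rep(c(-1, 1), each = 3),
                         s_hat = rep(c(0.1, 0.2, 0.3), 2))
  expect_equal(fisher_from_estimates(est3), 0)
  # affine recalibration of the estimates leaves the value unchanged
  est4 <- est2; est4$s_hat <- 3 * est4$s_hat + 7
  expect_equal(fisher_from_estimates(est4), fisher_from_estimates(est2))
  # degenerate zero-variance estimates are flagged infinite
  est5 <- tibble::tibble(stimulus = rep(c(-1, 1), each = 2),
                         s_hat = rep(c(-1, 1), each = 2))
  expect_true(is.infinite(fisher_from_estimates(est5)))
  expect_true(attr(fisher_from_estimates(est5), "degenerate"))
})

test_that("the linear decoder handles noiseless, null, and oracle fixtures", {
  set.seed(7)
  p <- 12
  f <- runif(p, 5, 15); fp <- rnorm(p, 0, 1.5)
  # noiseless separable counts decode perfectly
  fx0 <- generate_linear_gaussian_counts(f, fp, diag(1e-8, p),
                                         n_per_stim = 120,
                                         discretize = FALSE, seed = 8)
  fit0 <- train_lole(fx0$counts, decoder_spec(), seed = 9)
  expect_lt(fit0$mse_test, 1e-3)
  # permuted labels carry no information
  fx1 <- generate_linear_gaussian_counts(f, fp, diag(4, p),
                                         n_per_stim = 400, seed = 10)
  stim <- attr(fx1$counts, "stimulus")
  attr(fx1$counts, "stimulus") <- sample(stim)
  fit1 <- train_lole(fx1$counts, decoder_spec(), seed = 11)
  I_null <- fisher_from_estimates(fit1)
  expect_lt(I_null, 0.15 * fx1$info_true)
  # refuses under-determined problems
  tiny <- generate_linear_gaussian_counts(f, fp, diag(4, p), n_per_stim = 8,
                                          seed = 12)
  expect_error(train_lole(tiny$counts, decoder_spec(), seed = 13),
               "presentations")
})

test_that("information suite orders raw, shuffled and diagonal decoders on planted fixtures", {
  set.seed(14)
  p <- 40
  f <- runif(p, 10, 30); fp <- rnorm(p, 0, 2)
  A <- matrix(rnorm(p * p, 0, 0.4), p, p)
  Q <- crossprod(A) + diag(4, p)
  # differential correlations (noise along f') degrade information
  fx <- generate_linear_gaussian_counts(f, fp, Q, epsilon = 0.05,
                                        n_per_stim = 1500, seed = 15)
  info <- estimate_information_suite(fx$counts, decoder_spec(), seed = 16)
  expect_lt(info$I_lole, info$I_shuff)
  expect_lte(info$I_diag, info$I_lole * 1.05)
  expect_false(info$bound_violated)
})

test_that("the SVR control stays within its hyperparameter grids and near linear performance", {
  set.seed(17)
  p <- 10
  f <- runif(p, 10, 20); fp <- rnorm(p, 0, 1.5)
  fx <- generate_linear_gaussian_counts(f, fp, diag(6, p), n_per_stim = 150,
                                        seed = 18)
  spec <- decoder_spec()
  split <- mexhat:::split_trials(attr(fx$counts, "stimulus"), spec, seed = 19)
  fit <- train_lole(fx$counts, spec, split = split, seed = 20)
  ctl <- svr_control(fx$counts, spec, split = split, seed = 21)
  expect_true(ctl$best_C %in% c(0.01, 0.1, 1, 10))
  expect_true(ctl$best_gamma %in% c(1e-4, 1e-3, 1e-2, 0.1))
  # linearity is optimal here: SVR no better than linear minus tolerance
  expect_gte(ctl$mse_test, fit$mse_test - 0.25 * fit$mse_test)
  # noiseless linear fixture: both decoders near zero error
  fx0 <- generate_linear_gaussian_counts(f, fp, diag(1e-8, p),
                                         n_per_stim = 120,
                                         discretize = FALSE, seed = 22)
  split0 <- mexhat:::split_trials(attr(fx0$counts, "stimulus"), spec, seed = 23)
  ctl0 <- svr_control(fx0$counts, spec, split = split0, seed = 24)
  expect_lt(ctl0$mse_test, 0.05)
})
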