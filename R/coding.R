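#' Orientation selectivity index
#'
#' Vector-strength measure of tuning sharpness over orientation (period 180
#' degrees): `OSI = |sum <r(s)> exp(2 i s)| / sum <r(s)>`, ranging from 0
#' (untuned) to 1 (response at a single orientation). The standard protocol
#' uses twelve evenly spaced orientations with mean counts over 10
#' presentations each; neurons with all-zero tuning are excluded and
#' counted.
#'
#' @param tuning Tibble with columns `neuron`, `orientation` (degrees),
#'   `mean_count` (as produced by [simulate_tuning()] or
#'   [tuning_from_counts()]).
#' @return A list of class `osi_result`: `per_neuron` (tibble `neuron`,
#'   `osi`), `mean_osi` (population mean), `n_excluded`.
#' @examples
#' s <- seq(-90, 75, by = 15)
#' tun <- tibble::tibble(neuron = 1, orientation = s,
#'                       mean_count = 1 + cos(2 * s * pi / 180))
#' osi(tun)$mean_osi  # 0.5
#' @export
osi <- function(tuning) {
  stopifnot(all(c("neuron", "orientation", "mean_count") %in% names(tuning)))
  if (any(tuning$mean_count < 0)) abort("mean counts must be non-negative")
  per <- tuning |>
    group_by(.data$neuron) |>
    summarise(
      total = sum(.data$mean_count),
      osi = {
        th <- 2 * .data$orientation * pi / 180
        sqrt(sum(.data$mean_count * cos(th))^2 +
             sum(.data$mean_count * sin(th))^2) / sum(.data$mean_count)
      },
      .groups = "drop")
  excluded <- per$total == 0
  per <- per[!excluded, c("neuron", "osi")]
  structure(list(per_neuron = per, mean_osi = mean(per$osi),
                 n_excluded = sum(excluded)),
            class = "osi_result")
}

#' @export
print.osi_result <- function(x, ...) {
  cat(sprintf("<osi_result> %d neurons, mean OSI = %.3f (%d excluded)\n",
              nrow(x$per_neuron), x$mean_osi, x$n_excluded))
  invisible(x)
}

#' @export
tidy.osi_result <- function(x, ...) x$per_neuron

#' Shuffle spike counts across presentations
#'
#' Permutes each neuron's counts independently across presentations of the
#' same stimulus. Per-neuron marginals (count multisets per stimulus) are
#' preserved exactly; cross-neuron correlations are destroyed in
#' expectation. This is the surrogate used for the shuffled information
#' `I_shuff` and the diagonal decoder.
#'
#' @param counts A [count_matrix]; if it carries stimulus labels, shuffling
#'   is done within each stimulus class (anything else would destroy
#'   tuning).
#' @param seed Integer seed.
#' @return A `count_matrix` of the same shape and metadata.
#' @export
shuffle_counts <- function(counts, seed = NULL) {
  m <- unclass(counts)
  stim <- attr(counts, "stimulus")
  groups <- if (is.null(stim)) list(seq_len(ncol(m)))
            else split(seq_len(ncol(m)), stim)
  out <- m
  with_seed(seed, {
    for (g in groups) {
      if (length(g) < 2) next
      for (i in seq_len(nrow(m)))
        out[i, g] <- m[i, g[sample.int(length(g))]]
    }
  })
  attributes(out) <- attributes(counts)
  out
}

#' Decoder specification for the locally optimal linear estimator
#'
#' @param train_frac,val_frac Fractions of presentations used for training
#'   and validation (0.6/0.2 in most experiments; 0.8/0.1 at 7,000
#'   presentations); the remainder is the test set.
#' @param patience Early stopping: training stops once the validation error
#'   has failed to improve for this many consecutive epochs.
#' @param max_epochs Hard cap on epochs.
#' @param learning_rate Step size as a fraction of the inverse Lipschitz
#'   constant of the squared-error gradient.
#' @return A `decoder_spec` list.
#' @export
decoder_spec <- function(train_frac = 0.6, val_frac = 0.2, patience = 500,
                         max_epochs = 10000, learning_rate = 0.9) {
  if (train_frac + val_frac >= 1)
    abort("train_frac + val_frac must leave room for a test set")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate),
            class = "decoder_spec")
}

# stratified split of observation indices into train/val/test
split_trials <- function(stimulus, spec, seed = NULL) {
  with_seed(seed, {
    tr <- integer(0); va <- integer(0); te <- integer(0)
    for (s in unique(stimulus)) {
      idx <- sample(which(stimulus == s))
      n <- length(idx)
      n_tr <- floor(spec$train_frac * n)
      n_va <- floor(spec$val_frac * n)
      tr <- c(tr, idx[seq_len(n_tr)])
      va <- c(va, idx[n_tr + seq_len(n_va)])
      te <- c(te, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
    list(train = tr, val = va, test = te)
  })
}

#' Train the locally optimal linear estimator (LOLE)
#'
#' Fits `s_hat = w^T r + w_0` by gradient descent on the squared decoding
#' error, stopping when the validation error has not improved for
#' `patience` consecutive epochs. Requires at least as many presentations
#' per stimulus as readout neurons (fewer would leave the fit
#' under-determined relative to its parameters).
#'
#' @param counts A [count_matrix] with per-observation stimulus labels
#'   (two stimulus values, e.g. -1 and +1 degree).
#' @param spec A [decoder_spec()].
#' @param split Optional precomputed split (list `train`, `val`, `test` of
#'   column indices); by default a stratified random split per `spec`.
#' @param seed Integer seed for the split and epoch order.
#' @return A `lole_fit`: weights `w`, bias `w0`, per-split MSEs, test-set
#'   estimates `s_hat` with labels, and the split.
#' @export
train_lole <- function(counts, spec = decoder_spec(), split = NULL,
                       seed = NULL) {
  stim <- attr(counts, "stimulus")
  if (is.null(stim)) abort("`counts` needs stimulus labels")
  m <- unclass(counts)
  n_per <- min(table(stim))
  if (n_per < nrow(m))
    abort(sprintf(paste0(
      "need at least as many presentations per stimulus (%d) as readout ",
      "neurons (%d); subsample neurons or add presentations"),
      n_per, nrow(m)))
  seeds <- child_seeds(seed, 2)
  if (is.null(split)) split <- split_trials(stim, spec, seed = seeds[[1]])

  X <- t(m)  # observations x neurons
  y <- stim
  # standardise features on the training set
  mu <- colMeans(X[split$train, , drop = FALSE])
  sdv <- apply(X[split$train, , drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xtr <- Xs[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- Xs[split$val, , drop = FALSE]; yva <- y[split$val]

  p <- ncol(Xtr); ntr <- nrow(Xtr)
  G <- crossprod(Xtr) / ntr          # p x p
  gy <- crossprod(Xtr, ytr) / ntr
  ybar <- mean(ytr)
  # Lipschitz constant of the gradient via power iteration on G
  v <- with_seed(seeds[[2]], rnorm(p))
  for (k in 1:50) { v <- G %*% v; v <- v / sqrt(sum(v^2)) }
  Lip <- drop(crossprod(v, G %*% v)) + 1e-12
  eta <- spec$learning_rate / Lip

  w <- numeric(p); w0 <- ybar
  best <- list(w = w, w0 = w0, err = Inf); stall <- 0L
  for (ep in seq_len(spec$max_epochs)) {
    grad_w <- G %*% w + w0 * colMeans(Xtr) - gy
    grad_0 <- w0 + drop(colMeans(Xtr) %*% w) - ybar
    w <- w - eta * drop(grad_w)
    w0 <- w0 - eta * grad_0
    verr <- mean((drop(Xva %*% w) + w0 - yva)^2)
    if (verr < best$err - 1e-12) {
      best <- list(w = w, w0 = w0, err = verr); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= spec$patience) break
    }
  }
  w <- best$w; w0 <- best$w0
  pred <- function(idx) drop(Xs[idx, , drop = FALSE] %*% w) + w0
  shat_te <- pred(split$test)
  structure(list(
    w = w / sdv, w0 = w0 - sum(w * mu / sdv),
    spec = spec, split = split, epochs = ep,
    mse_train = mean((pred(split$train) - y[split$train])^2),
    mse_val = best$err,
    mse_test = mean((shat_te - y[split$test])^2),
    estimates = tibble(stimulus = y[split$test], s_hat = shat_te)
  ), class = "lole_fit")
}

#' @export
print.lole_fit <- function(x, ...) {
  cat(sprintf(
    "<lole_fit> %d weights, %d epochs, MSE train/val/test = %.4g/%.4g/%.4g\n",
    length(x$w), x$epochs, x$mse_train, x$mse_val, x$mse_test))
  invisible(x)
}

#' @export
tidy.lole_fit <- function(x, ...) {
  tibble(term = c("(bias)", paste0("w", seq_along(x$w))),
         estimate = c(x$w0, x$w))
}

#' @export
glance.lole_fit <- function(x, ...) {
  tibble(mse_train = x$mse_train, mse_val = x$mse_val,
         mse_test = x$mse_test, epochs = x$epochs,
         n_neurons = length(x$w))
}

# apply a fitted decoder to new observations of a count matrix
predict_lole <- function(fit, counts, idx = NULL) {
  m <- unclass(counts)
  if (is.null(idx)) idx <- seq_len(ncol(m))
  drop(crossprod(m[, idx, drop = FALSE], fit$w)) + fit$w0
}

#' Fisher information from held-out decoder estimates
#'
#' `I_LOLE = ((<s_hat_2> - <s_hat_1>) / (s_2 - s_1))^2 /
#'  (0.5 (Var(s_hat_2) + Var(s_hat_1)))`, a lower bound on the Fisher
#' information, in deg^-2 for stimuli in degrees. Returns `Inf` with a flag
#' if both estimate variances vanish (perfectly decodable data).
#'
#' @param estimates Tibble with columns `stimulus` and `s_hat` (held-out
#'   estimates), or a `lole_fit`.
#' @param s1,s2 The two stimulus values (defaults: the sorted unique labels).
#' @return Fisher information (deg^-2), attribute `degenerate` when both
#'   variances were zero.
#' @examples
#' est <- tibble::tibble(stimulus = rep(c(-1, 1), each = 2),
#'                       s_hat = c(-1.3, -0.3, 0.4, 1.4))
#' fisher_from_estimates(est)
#' @export
fisher_from_estimates <- function(estimates, s1 = NULL, s2 = NULL) {
  if (inherits(estimates, "lole_fit")) estimates <- estimates$estimates
  labs <- sort(unique(estimates$stimulus))
  if (is.null(s1)) s1 <- labs[1]
  if (is.null(s2)) s2 <- labs[2]
  e1 <- estimates$s_hat[estimates$stimulus == s1]
  e2 <- estimates$s_hat[estimates$stimulus == s2]
  if (length(e1) < 2 || length(e2) < 2)
    abort("need at least 2 test estimates per stimulus")
  vbar <- 0.5 * (var(e1) + var(e2))
  num <- ((mean(e2) - mean(e1)) / (s2 - s1))^2
  if (vbar == 0)
    return(structure(Inf, degenerate = TRUE))
  num / vbar
}

#' Full information suite: raw, shuffled, and diagonal decoders
#'
#' Computes the information triple: `I_LOLE` (decoder trained and tested on
#' the recorded, correlated data), `I_shuff` (trained and tested on
#' trial-shuffled data with all correlations removed), and `I_diag` (the
#' correlation-blind decoder: trained on shuffled data, applied to the
#' original test data). `I_LOLE < I_shuff` indicates correlations degrade
#' coding; `I_diag < I_LOLE` indicates correlations themselves carry
#' information; `I_diag <= I_LOLE` up to estimation noise always (flagged
#' if violated).
#'
#' @inheritParams train_lole
#' @param svr Also run the nonlinear SVR control (slower).
#' @return An `info_estimate`: `I_lole`, `I_shuff`, `I_diag` (deg^-2),
#'   `mse_linear`, optionally `mse_svr`, `n_neurons`, `n_trials_per_stim`,
#'   `bound_violated` flag, and the underlying fits.
#' @export
estimate_information_suite <- function(counts, spec = decoder_spec(),
                                       seed = NULL, svr = FALSE) {
  seeds <- child_seeds(seed, 4)
  stim <- attr(counts, "stimulus")
  split <- split_trials(stim, spec, seed = seeds[[1]])
  shuffled <- shuffle_counts(counts, seed = seeds[[2]])

  fit_raw <- train_lole(counts, spec, split = split, seed = seeds[[3]])
  fit_shf <- train_lole(shuffled, spec, split = split, seed = seeds[[4]])

  I_lole <- fisher_from_estimates(fit_raw)
  I_shuff <- fisher_from_estimates(fit_shf)
  # diagonal decoder: shuffle-trained weights applied to the original data
  shat_diag <- predict_lole(fit_shf, counts, idx = split$test)
  est_diag <- tibble(stimulus = stim[split$test], s_hat = shat_diag)
  I_diag <- fisher_from_estimates(est_diag)

  mse_svr <- if (svr) svr_control(counts, spec, split = split,
                                  seed = seeds[[1]])$mse_test else NA_real_
  structure(list(
    I_lole = I_lole, I_shuff = I_shuff, I_diag = I_diag,
    mse_linear = fit_raw$mse_test, mse_svr = mse_svr,
    n_neurons = nrow(counts),
    n_trials_per_stim = as.integer(min(table(stim))),
    bound_violated = is.finite(I_diag) && is.finite(I_lole) &&
      I_diag > I_lole * 1.05,
    fit = fit_raw, fit_shuffled = fit_shf
  ), class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf(
    "<info_estimate> I_LOLE = %.4g, I_shuff = %.4g, I_diag = %.4g deg^-2\n",
    x$I_lole, x$I_shuff, x$I_diag))
  cat(sprintf("  %d neurons, %d presentations per stimulus, linear MSE %.4g\n",
              x$n_neurons, x$n_trials_per_stim, x$mse_linear))
  if (x$bound_violated)
    cat("  warning: I_diag exceeded I_LOLE beyond estimation noise\n")
  invisible(x)
}

#' @export
tidy.info_estimate <- function(x, ...) {
  tibble(measure = c("I_LOLE", "I_shuff", "I_diag"),
         information = c(x$I_lole, x$I_shuff, x$I_diag))
}

#' @export
glance.info_estimate <- function(x, ...) {
  tibble(I_lole = x$I_lole, I_shuff = x$I_shuff, I_diag = x$I_diag,
         mse_linear = x$mse_linear, mse_svr = x$mse_svr,
         n_neurons = x$n_neurons,
         n_trials_per_stim = x$n_trials_per_stim)
}

#' Nonlinear support-vector-regression control
#'
#' Sanity check that the linear decoder is adequate: an RBF-kernel SVR with
#' counts standardised to zero mean and unit variance, hyperparameters
#' selected by 5-fold cross-validation on the training set over
#' `C in {0.01, 0.1, 1, 10}` and `gamma in {1e-4, 1e-3, 1e-2, 0.1}`,
#' evaluated on the test set. On linearly decodable data its test MSE is
#' expected to be no better than the linear decoder's.
#'
#' @inheritParams train_lole
#' @param C_grid,gamma_grid Hyperparameter grids.
#' @param n_folds Cross-validation folds.
#' @return A list: `mse_test`, `best_C`, `best_gamma`, `cv` (tibble of the
#'   grid with CV errors), and the fitted `model`.
#' @export
svr_control <- function(counts, spec = decoder_spec(), split = NULL,
                        C_grid = c(0.01, 0.1, 1, 10),
                        gamma_grid = c(1e-4, 1e-3, 1e-2, 0.1),
                        n_folds = 5, seed = NULL) {
  stim <- attr(counts, "stimulus")
  if (is.null(stim)) abort("`counts` needs stimulus labels")
  seeds <- child_seeds(seed, 2)
  if (is.null(split)) split <- split_trials(stim, spec, seed = seeds[[1]])
  X <- t(unclass(counts)); y <- stim
  # drop constant features, then standardise on the training set
  sdv <- apply(X[split$train, , drop = FALSE], 2, sd)
  keep <- sdv > 0
  X <- X[, keep, drop = FALSE]
  mu <- colMeans(X[split$train, , drop = FALSE])
  sdv <- sdv[keep]
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xtr <- Xs[split$train, , drop = FALSE]; ytr <- y[split$train]

  folds <- with_seed(seeds[[2]],
    sample(rep_len(seq_len(n_folds), length(ytr))))
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  cv_err <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(n_folds), function(f) {
      fit <- e1071::svm(Xtr[folds != f, , drop = FALSE], ytr[folds != f],
                        type = "eps-regression", kernel = "radial",
                        cost = grid$C[g], gamma = grid$gamma[g],
                        scale = FALSE)
      mean((predict(fit, Xtr[folds == f, , drop = FALSE]) -
              ytr[folds == f])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(cv_err)
  model <- e1071::svm(Xtr, ytr, type = "eps-regression", kernel = "radial",
                      cost = grid$C[best], gamma = grid$gamma[best],
                      scale = FALSE)
  mse_test <- mean((predict(model, Xs[split$test, , drop = FALSE]) -
                      y[split$test])^2)
  list(mse_test = mse_test, best_C = grid$C[best],
       best_gamma = grid$gamma[best],
       cv = as_tibble(cbind(grid, cv_mse = cv_err)), model = model)
}
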