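# Shared fixtures, built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# small 10x10 topology for structural tests
fx_topo_small <- function() {
  fx_get("topo_small", function()
    build_topology(grid_spec(10), kernel_spec(3, 4, K_E = 20, K_I = 10),
                   seed = 1))
}

# 16x16 network for control simulations
fx_topo16 <- function() {
  fx_get("topo16", function()
    build_topology(grid_spec(16), kernel_spec(3, 4, K_E = 40, K_I = 10),
                   seed = 2))
}

# all-recurrence-off synapses
syn_zero <- function() synapse_params(0, 0, 0, 0)

# study operating point: g_IE as printed, g_EE calibrated to sit just below
# the measured self-sustained boundary (the regime where the marginal phase
# and its noise correlations live)
op_synapse <- function() synapse_params(g_EE = 0.58, g_IE = 0.6)
op_afferent <- function() afferent_config("homogeneous", nu_max = 15)

kernel_for <- function(profile, K_E = 400, K_I = 200) {
  switch(profile,
         mexican = kernel_spec(10, 15, K_E, K_I),
         inverse = kernel_spec(15, 10, K_E, K_I),
         balanced = kernel_spec(10, 10, K_E, K_I))
}

fx_marginal_topo <- function(profile = "mexican", seed = 101) {
  fx_get(paste0("mtopo_", profile, "_", seed), function()
    build_topology(grid_spec(50), kernel_for(profile), seed = seed))
}

# 50x50 marginal-phase simulation, shared across acceptance blocks
fx_marginal_run <- function(profile = "mexican", seed = 101, duration = 9) {
  fx_get(paste0("marg_", profile, "_", seed), function()
    run_simulation(fx_marginal_topo(profile, seed), synapse = op_synapse(),
                   afferent = op_afferent(), duration = duration,
                   seed = seed + 200))
}

fx_not_self_sustained <- function(profile, seed) {
  fx_get(paste0("ss_", profile, "_", seed), function()
    !isTRUE(classify_self_sustained(fx_marginal_topo(profile, seed),
                                    synapse = op_synapse(),
                                    afferent = op_afferent(),
                                    seed = seed + 400)))
}

# helper: radial-acf width functional (lag at which the radial
# autocorrelation falls to half its lag-1 value, by linear interpolation);
# shot noise inflates the zero lag, so lag 1 is the reference
acf_half_lag <- function(radial) {
  ref <- radial$acf[radial$lag == 1] / 2
  above <- which(radial$acf >= ref & radial$lag >= 1)
  k <- max(above)
  l0 <- radial$lag[k]; l1 <- radial$lag[k + 1]
  a0 <- radial$acf[k]; a1 <- radial$acf[k + 1]
  l0 + (a0 - ref) / (a0 - a1) * (l1 - l0)
}

# closed-form field autocorrelation for a bump spec (phase-averaged
# rate-mixing covariance equals the spatial autocovariance of the field)
field_radial_acf <- function(spec) {
  m <- as.integer(sqrt(spec$n_bumps))
  cx <- (seq_len(m) - 0.5) * spec$L / m
  ctr <- expand.grid(x = cx, y = cx)
  f <- mexhat:::bump_rate_field(spec, ctr$x, ctr$y)
  g0 <- f - mean(f)
  P <- Mod(stats::fft(g0))^2
  acf0 <- Re(stats::fft(P, inverse = TRUE)) / length(f)
  acf0 <- acf0 / acf0[1, 1]
  lag1 <- pmin(0:(spec$L - 1), spec$L - (0:(spec$L - 1)))
  lagr <- round(sqrt(outer(lag1^2, lag1^2, "+")))
  tibble::tibble(lag = as.numeric(names(tapply(acf0, lagr, mean))),
                 acf = as.numeric(tapply(acf0, lagr, mean)))
}

first_zero_crossing <- function(d, v) d[which(v < 0)[1]]
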