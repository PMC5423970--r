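#' AEIF neuron parameters
#'
#' Adaptive exponential integrate-and-fire parameters per population.
#' Adaptation is moderate for excitatory cells (`a_E` = 2 nS sub-threshold
#' coupling, `b_E` = 50 pA spike-triggered increment) and ten times weaker
#' for inhibitory cells (`a_I` = 0.2 nS, `b_I` = 5 pA). The remaining
#' constants are standard regular-spiking values with the resting potential
#' at -65 mV; all are exposed here. Units: pF, nS, mV, ms, pA.
#'
#' @param C Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param E_L Leak reversal / resting potential (mV).
#' @param V_T Exponential spike threshold (mV).
#' @param Delta_T Slope factor (mV).
#' @param a_E,a_I Sub-threshold adaptation coupling (nS).
#' @param b_E,b_I Spike-triggered adaptation increment (pA).
#' @param tau_w Adaptation time constant (ms).
#' @param V_reset Post-spike reset voltage (mV).
#' @param V_cut Spike detection cutoff (mV).
#' @param t_ref Absolute refractory period (ms).
#' @param C_I,g_L_I,V_T_I Optional overrides for the inhibitory population
#'   (fast-spiking membranes: smaller capacitance, larger leak); `NULL`
#'   inherits the excitatory value.
#' @return A `neuron_params` list.
#' @export
neuron_params <- function(C = 280, g_L = 14, E_L = -65, V_T = -50,
                          Delta_T = 2, a_E = 2.0, b_E = 50,
                          a_I = 0.2, b_I = 5, tau_w = 150,
                          V_reset = -60, V_cut = -30, t_ref = 2,
                          C_I = NULL, g_L_I = NULL, V_T_I = NULL) {
  prm <- list(C = C, g_L = g_L, E_L = E_L, V_T = V_T, Delta_T = Delta_T,
              a_E = a_E, b_E = b_E, a_I = a_I, b_I = b_I, tau_w = tau_w,
              V_reset = V_reset, V_cut = V_cut, t_ref = t_ref,
              C_I = C_I %||% C, g_L_I = g_L_I %||% g_L,
              V_T_I = V_T_I %||% V_T)
  for (nm in c("C", "g_L", "tau_w", "Delta_T", "C_I", "g_L_I"))
    stopifnot_scalar(prm[[nm]], nm, positive = TRUE)
  structure(prm, class = "neuron_params")
}

# 11 x 2 matrix consumed by the C++ core (column 1 = E, column 2 = I)
neuron_param_matrix <- function(p) {
  matrix(c(p$C, p$g_L, p$E_L, p$V_T, p$Delta_T, p$a_E, p$b_E, p$tau_w,
           p$V_reset, p$V_cut, p$t_ref,
           p$C_I, p$g_L_I, p$E_L, p$V_T_I, p$Delta_T, p$a_I, p$b_I, p$tau_w,
           p$V_reset, p$V_cut, p$t_ref),
         nrow = 11, ncol = 2)
}

#' Synaptic parameters
#'
#' Conductance-based synapses: AMPA and GABA_A as instantaneously rising,
#' exponentially decaying conductances; NMDA as a bi-exponential normalised
#' to unit peak. Excitatory connections split into a fixed 70% AMPA / 30%
#' NMDA ratio (`g_AMPA = 0.7 g`, `g_NMDA = 0.3 g` exactly). Strength
#' naming: first subscript is the target population, second the source, so
#' `g_EE` is E-to-E and `g_IE` is E-to-I. Inhibitory strengths are fixed at
#' `g_II = g_EI = 5 nS`.
#'
#' @param g_EE,g_IE Excitatory maximum conductances (nS), explored 0-1.2.
#' @param g_EI,g_II Inhibitory maximum conductances (nS).
#' @param frac_ampa AMPA fraction of each excitatory connection.
#' @param tau_ampa,tau_gaba Decay time constants (ms).
#' @param tau_nmda_rise,tau_nmda_decay NMDA bi-exponential constants (ms).
#' @param E_ex,E_in Excitatory and inhibitory reversal potentials (mV).
#' @return A `synapse_params` list.
#' @export
synapse_params <- function(g_EE = 0.4, g_IE = 0.6, g_EI = 5.0, g_II = 5.0,
                           frac_ampa = 0.7, tau_ampa = 5, tau_gaba = 10,
                           tau_nmda_rise = 2, tau_nmda_decay = 100,
                           E_ex = 0, E_in = -80) {
  if (any(c(g_EE, g_IE, g_EI, g_II) < 0))
    abort("conductances must be non-negative")
  if (tau_nmda_rise >= tau_nmda_decay)
    abort("NMDA rise time must be shorter than its decay time")
  structure(list(g_EE = g_EE, g_IE = g_IE, g_EI = g_EI, g_II = g_II,
                 frac_ampa = frac_ampa, tau_ampa = tau_ampa,
                 tau_gaba = tau_gaba, tau_nmda_rise = tau_nmda_rise,
                 tau_nmda_decay = tau_nmda_decay, E_ex = E_ex, E_in = E_in),
            class = "synapse_params")
}

#' Afferent input configuration
#'
#' Every neuron receives `K_A` independent Poisson spike trains targeting
#' AMPA receptors (realised as one equivalent Poisson process of rate
#' `K_A * nu` per neuron, which is statistically identical). In
#' `"homogeneous"` mode (blank stimulus) all neurons share the rate
#' `nu_max`; in `"tuned"` mode (orientation stimulus) the per-neuron rate
#' follows a circular Gaussian tuning curve of the angular distance between
#' the stimulus and the neuron's preferred orientation (see
#' [afferent_rate()]); `"off"` silences the afferents.
#'
#' @param mode `"homogeneous"`, `"tuned"`, or `"off"`.
#' @param nu_max Peak afferent rate per train (Hz).
#' @param nu_base Baseline rate (Hz), defaults to `nu_max / 10`.
#' @param sigma_aff Tuning width (degrees).
#' @param stimulus Stimulus orientation in degrees, `[-90, 90)`.
#' @param K_A Number of afferent trains per neuron.
#' @param g_aff Synaptic weight of one afferent event onto excitatory
#'   targets (nS); calibrated so that homogeneous 15 Hz input drives sparse
#'   irregular firing (a few Hz) in the uncoupled network.
#' @param g_aff_I Afferent event weight onto inhibitory targets (nS);
#'   defaults to `g_aff`.
#' @return An `afferent_config` list.
#' @export
afferent_config <- function(mode = c("homogeneous", "tuned", "off"),
                            nu_max = 15, nu_base = nu_max / 10,
                            sigma_aff = 27.5, stimulus = 0,
                            K_A = 100, g_aff = 0.6, g_aff_I = g_aff) {
  mode <- match.arg(mode)
  if (nu_max < nu_base || nu_base < 0)
    abort("need nu_max >= nu_base >= 0")
  structure(list(mode = mode, nu_max = nu_max, nu_base = nu_base,
                 sigma_aff = sigma_aff, stimulus = stimulus,
                 K_A = as.integer(K_A), g_aff = g_aff, g_aff_I = g_aff_I),
            class = "afferent_config")
}

#' Afferent tuning curve
#'
#' Circular Gaussian tuning of the afferent rate:
#' `nu(s) = (nu_max - nu_base) exp(-ds^2 / (2 sigma_aff^2)) + nu_base`,
#' where `ds` is the stimulus-to-preferred-orientation difference wrapped to
#' `[-90, 90)` (orientation has period 180 degrees).
#'
#' @param s Stimulus orientation (degrees).
#' @param s_po Preferred orientation(s) (degrees).
#' @param cfg An [afferent_config()].
#' @return Afferent rate(s) in Hz per train, in `[nu_base, nu_max]`.
#' @examples
#' cfg <- afferent_config("tuned", nu_max = 30, nu_base = 3)
#' afferent_rate(0, 0, cfg)      # 30
#' afferent_rate(0, 27.5, cfg)   # 3 + 27 * exp(-1/2)
#' @export
afferent_rate <- function(s, s_po, cfg) {
  ds <- wrap_orientation(s - s_po)
  (cfg$nu_max - cfg$nu_base) * exp(-ds^2 / (2 * cfg$sigma_aff^2)) + cfg$nu_base
}

# per-neuron total afferent rate in Hz (K_A trains superposed)
afferent_rate_vector <- function(topology, afferent) {
  n <- nrow(topology$positions)
  nu <- switch(afferent$mode,
    off = rep(0, n),
    homogeneous = rep(afferent$nu_max, n),
    tuned = {
      po <- topology$positions$po
      if (is.null(po))
        abort("tuned afferents need a topology with an orientation map")
      afferent_rate(afferent$stimulus, po, afferent)
    })
  nu * afferent$K_A
}

#' Simulate the spiking network
#'
#' Fixed-step integration (forward Euler for membrane and adaptation, exact
#' exponential decay for conductances, default dt = 0.05 ms) of the AEIF
#' network with conductance-based AMPA/NMDA/GABA_A synapses and independent
#' Poisson afferents. Spikes trigger reset, the adaptation increment, and
#' delayed conductance increments at all targets. Fully reproducible given
#' `seed`.
#'
#' @param topology A `network_topology` from [build_topology()].
#' @param neuron A [neuron_params()].
#' @param synapse A [synapse_params()].
#' @param afferent An [afferent_config()].
#' @param duration Simulated time (s).
#' @param dt Integration step (ms).
#' @param warmup Warm-up period (s) excluded from analyses downstream
#'   (attached as metadata; spikes are still returned).
#' @param seed Integer seed.
#' @param I_ext Constant injected current (pA), scalar or per neuron.
#' @param stim_end Time (s) after which afferents are switched off
#'   (`Inf` = never).
#' @param init_V Optional initial membrane voltages (mV, length n);
#'   default uniform in `[E_L, V_T]`.
#' @return A `spike_data` tibble with columns `trial`, `neuron`, `time` (s)
#'   and metadata attributes (`n_neurons`, `duration`, `warmup`, `L`,
#'   `positions`).
#' @export
run_simulation <- function(topology, neuron = neuron_params(),
                           synapse = synapse_params(),
                           afferent = afferent_config(),
                           duration = 2, dt = 0.05, warmup = 1,
                           seed = NULL, I_ext = 0, stim_end = Inf,
                           init_V = NULL) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  n <- nrow(topology$positions)
  nE <- sum(topology$positions$pop == "E")
  # delays below dt are floored at one integration step; a dt beyond the
  # longest delay would destroy event ordering altogether
  if (dt > max(topology$delay_ms))
    abort("dt exceeds the largest synaptic delay; reduce dt")
  csr <- topology_csr(topology, dt)
  rates <- afferent_rate_vector(topology, afferent)
  gaff <- if (isTRUE(all.equal(afferent$g_aff_I, afferent$g_aff)))
    afferent$g_aff
  else
    ifelse(topology$positions$pop == "E", afferent$g_aff, afferent$g_aff_I)
  res <- with_seed(seed,
    run_net_cpp(n, nE, csr$ptr, csr$tgt, csr$delay,
                neuron_param_matrix(neuron), unclass(synapse),
                rates, gaff, stim_end,
                as.numeric(I_ext), duration, dt,
                if (is.null(init_V)) numeric(0) else as.numeric(init_V)))
  out <- new_spike_data(
    tibble(trial = 1L, neuron = res$neuron, time = res$time),
    n_neurons = n, duration = duration, warmup = warmup,
    L = topology$grid$n_side, positions = topology$positions
  )
  attr(out, "V_final") <- res$V_final
  out
}

# CSR-by-source representation with delays quantised to dt (floored at 1 step)
topology_csr <- function(topology, dt) {
  key <- paste0("csr_", format(dt, digits = 12))
  cached <- attr(topology, key, exact = TRUE)
  if (!is.null(cached)) return(cached)
  ord <- order(topology$source)
  src <- topology$source[ord]
  tgt <- topology$target[ord] - 1L
  delay <- pmax(1L, as.integer(round(topology$delay_ms[ord] / dt)))
  n <- nrow(topology$positions)
  ptr <- c(0L, cumsum(tabulate(src, nbins = n)))
  list(ptr = as.integer(ptr), tgt = tgt, delay = delay)
}

# spike_data constructor
new_spike_data <- function(df, n_neurons, duration, warmup = 1, L = NULL,
                           positions = NULL, stimulus = NULL) {
  structure(
    as_tibble(df),
    n_neurons = as.integer(n_neurons), duration = duration,
    warmup = warmup, L = L, positions = positions, stimulus = stimulus,
    class = c("spike_data", class(as_tibble(df)))
  )
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf(
    "<spike_data> %d spikes, %d neurons, %d trial(s), %.3g s each (warmup %.3g s)\n",
    nrow(x), attr(x, "n_neurons"), length(unique(x$trial)),
    attr(x, "duration"), attr(x, "warmup")))
  NextMethod()
}

#' Peak EPSP amplitude of a single connection
#'
#' Delivers one presynaptic spike to a neuron at rest (-65 mV) and returns
#' the peak voltage deflection. Excitatory connections split 70/30 into
#' AMPA/NMDA as in the network. Amplitudes grow monotonically with `g` and
#' stay small (at most about 1.5 mV at the top of the explored 0-1.2 nS
#' range).
#'
#' @param g Maximum conductance of the connection (nS).
#' @param type `"excitatory"` or `"inhibitory"`.
#' @param neuron,synapse Parameter objects.
#' @param dt Integration step (ms).
#' @return Peak absolute deflection from rest in mV (positive for EPSPs,
#'   reported as positive magnitude for IPSPs too).
#' @examples
#' epsp_amplitude(1.2)
#' @export
epsp_amplitude <- function(g, type = c("excitatory", "inhibitory"),
                           neuron = neuron_params(),
                           synapse = synapse_params(), dt = 0.05) {
  type <- match.arg(type)
  prm <- as.numeric(neuron_param_matrix(neuron)[, 1])
  # settle to the true resting point first (exp term slightly lifts E_L)
  settle <- single_neuron_cpp(prm, unclass(synapse), 0, 0, 0, -1, 0,
                              500, dt, neuron$E_L)
  v_rest <- settle$V[length(settle$V)]
  base <- single_neuron_cpp(prm, unclass(synapse), 0, 0, 0, -1, 0,
                            400, dt, v_rest)
  vapply(g, function(gi) {
    wa <- if (type == "excitatory") synapse$frac_ampa * gi else 0
    wn <- if (type == "excitatory") (1 - synapse$frac_ampa) * gi else 0
    wg <- if (type == "inhibitory") gi else 0
    out <- single_neuron_cpp(prm, unclass(synapse), wa, wn, wg,
                             10, 0, 400, dt, v_rest)
    max(abs(out$V - base$V))
  }, numeric(1))
}

#' Classify a network as self-sustained
#'
#' Stimulates for `stim_dur` seconds, switches the afferents off, waits
#' `gap` seconds, then counts spikes in the following `probe` seconds. Any
#' spike classifies the network as self-sustained (able to maintain activity
#' without external drive); such networks are excluded from all analyses.
#'
#' @inheritParams run_simulation
#' @param stim_dur,gap,probe Phase durations in seconds.
#' @return Logical flag, with attribute `probe_spikes`.
#' @export
classify_self_sustained <- function(topology, neuron = neuron_params(),
                                    synapse = synapse_params(),
                                    afferent = afferent_config(),
                                    stim_dur = 1, gap = 1, probe = 1,
                                    dt = 0.05, seed = NULL) {
  sp <- run_simulation(topology, neuron, synapse, afferent,
                       duration = stim_dur + gap + probe, dt = dt,
                       warmup = 0, seed = seed, stim_end = stim_dur)
  n_probe <- sum(sp$time > stim_dur + gap)
  structure(n_probe > 0, probe_spikes = n_probe)
}

#' Simulate repeated stimulus presentations into a count matrix
#'
#' Produces the trial-structured spike counts used by the information
#' analyses. Two drivers are available: `method = "trials"` runs one
#' independent simulation per presentation (fresh initial state and
#' afferent noise, 1 s warm-up each, matching the repeated-presentation
#' protocol); `method = "windows"` runs one long presentation per stimulus
#' and takes disjoint `count_window` slices after the warm-up as
#' presentations (far cheaper; the same long-presentation device the sliding
#' window correlation analyses use).
#'
#' @inheritParams run_simulation
#' @param stimuli Vector of stimulus orientations (degrees); afferents run
#'   in tuned mode.
#' @param n_per_stim Presentations per stimulus.
#' @param count_window Count window per presentation (s).
#' @param method `"windows"` or `"trials"`.
#' @param neurons Optional neuron ids to keep (default all excitatory).
#' @return A [count_matrix] (neurons x presentations) with per-observation
#'   stimulus labels.
#' @export
simulate_trials <- function(topology, stimuli, n_per_stim,
                            neuron = neuron_params(),
                            synapse = synapse_params(),
                            afferent = afferent_config("tuned"),
                            count_window = 3, warmup = 1, dt = 0.05,
                            method = c("windows", "trials"),
                            neurons = NULL, seed = NULL) {
  method <- match.arg(method)
  posE <- topology$positions[topology$positions$pop == "E", ]
  if (is.null(neurons)) neurons <- posE$id
  seeds <- child_seeds(seed, length(stimuli) * max(1L, n_per_stim))
  blocks <- list(); labels <- numeric(0); k <- 0L
  for (s in stimuli) {
    aff <- afferent
    aff$stimulus <- s
    if (method == "windows") {
      k <- k + 1L
      sp <- run_simulation(topology, neuron, synapse, aff,
                           duration = warmup + n_per_stim * count_window,
                           dt = dt, warmup = warmup, seed = seeds[[k]])
      cm <- sliding_window_counts(sp, T = count_window,
                                  stride = count_window, neurons = neurons)
      cm <- cm[, seq_len(min(ncol(cm), n_per_stim)), drop = FALSE]
      blocks[[length(blocks) + 1L]] <- unclass(cm)
      labels <- c(labels, rep(s, ncol(cm)))
    } else {
      for (r in seq_len(n_per_stim)) {
        k <- k + 1L
        sp <- run_simulation(topology, neuron, synapse, aff,
                             duration = warmup + count_window, dt = dt,
                             warmup = warmup, seed = seeds[[k]])
        cm <- sliding_window_counts(sp, T = count_window,
                                    stride = count_window, neurons = neurons)
        blocks[[length(blocks) + 1L]] <- unclass(cm)[, 1, drop = FALSE]
        labels <- c(labels, s)
      }
    }
  }
  counts <- do.call(cbind, blocks)
  new_count_matrix(counts, kind = if (method == "windows") "window" else "trial",
                   T = count_window, neurons = neurons,
                   x = posE$x[match(neurons, posE$id)],
                   y = posE$y[match(neurons, posE$id)],
                   L = topology$grid$n_side, stimulus = labels)
}

#' Orientation tuning curves from simulations
#'
#' Presents each of the given orientations `n_per_stim` times and averages
#' excitatory spike counts, yielding the tuning table consumed by [osi()].
#' The default stimulus set is the twelve evenly spaced orientations
#' -90, -75, ..., 75 degrees with 10 presentations each.
#'
#' @inheritParams simulate_trials
#' @param orientations Stimulus orientations (degrees).
#' @return A tibble `neuron`, `orientation`, `mean_count`.
#' @export
simulate_tuning <- function(topology, orientations = seq(-90, 75, by = 15),
                            n_per_stim = 10,
                            neuron = neuron_params(),
                            synapse = synapse_params(),
                            afferent = afferent_config("tuned"),
                            count_window = 1, warmup = 1, dt = 0.05,
                            method = c("windows", "trials"), seed = NULL) {
  cm <- simulate_trials(topology, orientations, n_per_stim, neuron, synapse,
                        afferent, count_window, warmup, dt,
                        method = match.arg(method), seed = seed)
  tuning_from_counts(cm)
}

#' Average a labelled count matrix into tuning curves
#'
#' @param counts A [count_matrix] with per-observation stimulus labels.
#' @return A tibble `neuron`, `orientation`, `mean_count`.
#' @export
tuning_from_counts <- function(counts) {
  stim <- attr(counts, "stimulus")
  if (is.null(stim)) abort("`counts` has no stimulus labels")
  neurons <- attr(counts, "neurons")
  m <- unclass(counts)
  out <- lapply(sort(unique(stim)), function(s)
    tibble(neuron = neurons, orientation = s,
           mean_count = rowMeans(m[, stim == s, drop = FALSE])))
  dplyr::bind_rows(out)
}

#' Construct spike data from a table of spike times
#'
#' Builds the `spike_data` container used throughout the analyses from a
#' plain table, e.g. for externally generated or hand-constructed spike
#' trains.
#'
#' @param df Data frame with columns `trial`, `neuron`, `time` (s).
#' @param n_neurons Total number of neurons.
#' @param duration Duration of each trial (s).
#' @param warmup Warm-up period (s) excluded by the analyses.
#' @param L Torus side (px), if the neurons sit on a grid.
#' @param positions Optional positions tibble (`id`, `pop`, `x`, `y`).
#' @return A `spike_data` object.
#' @export
spike_data <- function(df, n_neurons, duration, warmup = 0, L = NULL,
                       positions = NULL) {
  stopifnot(all(c("trial", "neuron", "time") %in% names(df)))
  if (any(df$time < 0 | df$time > duration))
    abort("spike times must lie within [0, duration]")
  new_spike_data(df[order(df$trial, df$neuron, df$time), ],
                 n_neurons = n_neurons, duration = duration,
                 warmup = warmup, L = L, positions = positions)
}
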