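# mexhat

Spiking-network simulations and analyses of how **Mexican-hat lateral
connectivity** shapes **noise correlations** and **stimulus encoding** in a
model of primary visual cortex.

Nearby cortical neurons fluctuate together across repeated presentations of
the same stimulus. `mexhat` implements, end to end, the recurrent-origin
hypothesis for these noise correlations: a two-dimensional sheet of adaptive
exponential integrate-and-fire (AEIF) neurons with conductance-based
AMPA/NMDA/GABA_A synapses, whose recurrent connections are drawn from
Gaussian kernels over torus distance,

    p(i <- j)  ∝  exp( -d_ij² / 2σ_Y² ),   Y ∈ {E, I},  no self-connections,

with fixed in-degrees K_E = 400 and K_I = 200. When σ_E < σ_I (a *Mexican
hat*), homogeneous activity destabilises into moving bumps that induce
distance-dependent spike-count correlations

    r_SC = Cov(r_i, r_j) / √(Var r_i · Var r_j);

when σ_E ≥ σ_I they do not. The package contains the full analysis chain:
sliding-window counts, r_SC versus distance and window length, FFT spatial
autocorrelation, activity-centre trajectories, orientation selectivity
(OSI, vector strength over 12 orientations), and Fisher information from a
locally optimal linear estimator ŝ = wᵀr + w₀,

    I_LOLE = ((⟨ŝ₂⟩ − ⟨ŝ₁⟩)/(s₂ − s₁))² / (½(Var ŝ₁ + Var ŝ₂)),

with trial-shuffled (I_shuff) and diagonal (I_diag) controls and an SVR
nonlinearity check. A surrogate module plants known bump fields, drifts,
correlation functions and linear-Gaussian tuning (true information
f′ᵀQ⁻¹f′) so that every estimator is validated against a closed form.

## Worked example

Build a Mexican-hat network, simulate a blank stimulus, and measure the
distance dependence of noise correlations:

```r
library(mexhat)

topo <- build_topology(grid_spec(50), kernel_spec(sigma_E = 10, sigma_I = 15),
                       seed = 101)
syn  <- synapse_params(g_EE = 0.58, g_IE = 0.6)  # just below self-sustained
aff  <- afferent_config("homogeneous", nu_max = 15)

classify_self_sustained(topo, synapse = syn, afferent = aff, seed = 1)
#> [1] FALSE
#> attr(,"probe_spikes")
#> [1] 0

sp <- run_simulation(topo, synapse = syn, afferent = aff,
                     duration = 16, seed = 301)
cm <- sliding_window_counts(sp, T = 1, stride = 0.5)
prof <- pairwise_noise_correlation(cm, max_distance = 13.3,
                                   n_pairs = 20000, seed = 1)
prof
#> <correlation_profile> 2187 pairs (0 excluded), mean r_SC = 0.1867
```

Near pairs (≤ 13.3 px ≙ 0.2 mm) are strongly correlated; the same
measurement on an inverse-hat network (`kernel_spec(15, 10)`) at identical
strengths gives a mean r_SC of about 0.02. The spatial scale of the
correlations matches the activity pattern:

```r
ac <- spatial_autocorrelation(sp, n_samples = 60, seed = 2)
ac$dominant_frequency   # cycles per 100 px
#> [1] 2
autoplot(ac)            # bump-lattice autocorrelation
autoplot(prof)          # damped oscillation of r_SC with distance
```

Tuned input, orientation selectivity, and the information triple:

```r
tun <- simulate_tuning(topo, synapse = syn,
                       afferent = afferent_config("tuned", nu_max = 30),
                       n_per_stim = 2, count_window = 1, seed = 3)
osi(tun)
#> <osi_result> 2494 neurons, mean OSI = 0.848 (6 excluded)

cmi <- simulate_trials(topo, stimuli = c(-1, 1), n_per_stim = 70,
                       synapse = syn,
                       afferent = afferent_config("tuned", nu_max = 30),
                       count_window = 1.5, seed = 4)
tri <- sapply(1:4, function(k) {      # average over readout samples
  info <- estimate_information_suite(sample_neurons(cmi, 32, seed = k),
                                     decoder_spec(), seed = 10 + k)
  tidy(info)$information
})
tibble::tibble(measure = c("I_LOLE", "I_shuff", "I_diag"),
               information = rowMeans(tri))
#> # A tibble: 3 × 2
#>   measure information
#>   <chr>         <dbl>
#> 1 I_LOLE        0.624
#> 2 I_shuff       0.798
#> 3 I_diag        0.578
```

`I_shuff > I_LOLE`: removing the correlations by shuffling increases the
recoverable information, i.e. the recurrently generated correlations are
information-limiting (differential) noise. Single readout draws are noisy
at this scale; the information comparison is meaningful on averages over
readout samples (and, at full size, over network realisations).

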