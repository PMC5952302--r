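# crstim

A simulation testbed for **desynchronizing multichannel neurostimulation**
and the design of **sham (inactive) stimulation protocols**.

Several brain disorders involve abnormally strong neuronal
synchronization. Coordinated reset (CR) stimulation delivers
phase-shifted stimuli to distinct sub-populations of a synchronized
network to desynchronize it and — through spike-timing-dependent
plasticity (STDP) — to unlearn the connectivity that sustains the
synchrony ("anti-kindling"). Testing such therapies clinically requires
a sham protocol that shares the stimulation's perceptual structure but
lacks its specific neural effect. `crstim` implements the full
computational pipeline for comparing candidate protocols.

## What is inside

* **Model** — a ring of *N* Hodgkin–Huxley neurons,
  *C V̇ᵢ = Iᵢ − g_Na m³h(V−V_Na) − g_K n⁴(V−V_K) − g_l(V−V_l) + Sᵢ + Fᵢ*,
  coupled all-to-all through a Mexican-hat template
  *M_ij = (1 − d_ij²/σ₁²) exp(−d_ij²/2σ₂²)* (short-range excitation,
  long-range inhibition), with weight magnitudes *c_ij ∈ [0,1]* under an
  asymmetric event-based STDP rule
  (*Δc = β₁ e^{−Δt/γ₁τ}* for Δt ≥ 0, *β₂ (Δt/τ) e^{Δt/γ₂τ}* for Δt < 0).
* **Stimulation** — seven protocols sharing 16 ms ON/OFF cycles
  (3 ON : 2 OFF), four sites, alpha-function conductances and a
  quadratic spatial profile: purely periodic (PPMS), correlated-noise
  (CMNS, the sham candidate), uncorrelated-noise (UMNS), rapidly
  varying / fixed / slowly varying sequence CR, and a no-stimulation
  control.
* **Engine** — a compiled adaptive Dormand–Prince RK5(4) integrator
  (rel. tol. 1e−5, max step 0.25 ms) with interpolated spike detection,
  event-based plasticity, restarts at stimulation onsets, and full
  bit-reproducibility from seeds.
* **Analysis** — average signed connectivity *C_av* and its components,
  sorted connectivity matrices with across-sample median/IQR, linear
  inter-spike phases and Kuramoto order parameters (network and
  subpopulation level), acute stimulation/after-effects, stimulus-locked
  cross-trial phase distributions, resetting indices *E_k(Δt)*, spike
  count histograms, and exact one-sided rank-sum comparisons.

Everything user-facing takes and returns data frames, so results chain
with the pipe; `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
helpers are provided.

## A worked example

A reduced-scale experiment (20 neurons, 2 sites, 2/6/12/12 s periods —
same physics, smaller ring) comparing rapidly-varying-sequence CR with
the no-stimulation control for the same initial network:

```r
library(crstim)

ex  <- run_experiment(smoke_config("rvs_cr",  sample_id = 1))
ex0 <- run_experiment(smoke_config("no_stim", sample_id = 1))

dplyr::bind_rows(glance(ex), glance(ex0))[
  , c("protocol", "c_av_0", "c_av_on", "r_av_on", "r_av_off")]
#> # A tibble: 2 x 5
#>   protocol c_av_0 c_av_on r_av_on r_av_off
#>   <chr>     <dbl>   <dbl>   <dbl>    <dbl>
#> 1 rvs_cr   0.0671 -0.0622   0.400    0.805
#> 2 no_stim  0.0671  0.112    0.833    0.844
```

Both runs start from a bit-identical settled network (`c_av_0` agrees
exactly). During stimulation, CR pushes the average signed weight
negative (anti-kindling: excitation weakened, inhibition strengthened)
and halves the order parameter, while the control stays on its
synchronized attractor. On this small ring the network re-synchronizes
after stimulation ends (`r_av_off ≈ 0.81`); the long-lasting
after-effects of the full-scale system need the 200-neuron, 128 s
configuration (`experiment_config()`).

Mechanism-level analysis, e.g. the resetting index around the onsets of
site 2:

```r
map <- subpopulation_map(ex$config$net)
ct  <- cross_trial(ex$raster, ex$schedule,
                   neurons = map$neuron[map$site == 2], site = 2)
plot_resetting_index(resetting_index(ct))
```

Non-periodic protocols (CMNS, UMNS, RVS CR) show near-zero pre-onset
*E₂* that jumps after the stimulus — a phase reset; periodic ones
(PPMS, fixed CR, SVS CR) keep *E₂* elevated throughout — entrainment.

A command-line wrapper for shell use is installed at
`inst/cli/crstim.R` (`run`, `schedule`, `batch` subcommands).

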