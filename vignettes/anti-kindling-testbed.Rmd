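---
title: "A plastic Hodgkin-Huxley ring as a testbed for desynchronizing and sham multichannel stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A plastic Hodgkin-Huxley ring as a testbed for desynchronizing and sham multichannel stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Several brain disorders (Parkinson's disease, tinnitus, epilepsy) are
accompanied by abnormally strong neuronal synchronization. Coordinated
reset (CR) stimulation delivers phase-shifted stimuli to several
sub-populations of a synchronized network in order to desynchronize it,
and — in the presence of spike-timing-dependent plasticity (STDP) — to
*unlearn* the pathological connectivity that sustains the synchrony
("anti-kindling"). Evaluating such a therapy in a clinical trial
requires a *sham* protocol: a stimulation pattern that feels like the
treatment but lacks its specific neural effect. `crstim` implements a
computational testbed for exactly this question: a plastic spiking
network in which seven stimulation conditions can be compared — purely
periodic multichannel stimulation (PPMS), correlated and uncorrelated
noisy multichannel stimulation (CMNS, UMNS), three CR variants (rapidly
varying, fixed, and slowly varying sequences), and a no-stimulation
control.

## The model

The network is a one-dimensional ring of `N` Hodgkin-Huxley neurons.
Neuron `i` obeys

$$C \dot V_i = I_i - g_{Na} m_i^3 h_i (V_i - V_{Na})
  - g_K n_i^4 (V_i - V_K) - g_l (V_i - V_l) + S_i + F_i,$$

with the classical gate kinetics
$\dot x = \alpha_x(V)(1-x) - \beta_x(V)x$ for $x \in \{m, h, n\}$ and a
sigmoidal synaptic activation
$\dot s = 0.5\,(1-s)/(1+e^{-(V+5)/12}) - 2s$. The constant injected
currents $I_i$ are drawn uniformly from $[I_0 - \Delta_I, I_0 +
\Delta_I]$ with $I_0 = 11\,\mu A/cm^2$, which makes every neuron an
intrinsic oscillator with a firing period close to 14 ms.

Coupling is all-to-all with a distance-dependent *Mexican-hat* template

$$M_{ij} = \left(1 - d_{ij}^2/\sigma_1^2\right)
  e^{-d_{ij}^2 / (2\sigma_2^2)},\qquad
  d_{ij} = d\,\min(|i-j|,\, N - |i-j|),\ d = d_0/(N-1),$$

so short-range connections (ring distance below $\sigma_1 = 3.5$) are
excitatory and long-range connections are inhibitory. The postsynaptic
current is the ensemble average
$S_i = N^{-1}\sum_j (V_{r,j} - V_i)\, c_{ij} |M_{ij}|\, s_j$, with the
excitatory (20 mV) or inhibitory (-40 mV) reversal potential selected by
the sign of $M_{ij}$. The weight matrix `c` stores *magnitudes* in
$[0,1]$; synapse type lives entirely in the template's sign. We fix
$c_{ii} = 0$ and exclude the diagonal from plasticity and from synapse
counts: self-synapses are dynamically and biologically spurious in this
model, while all averaging denominators keep their defining form.

## Plasticity

Weights are updated event-wise at every detected spike. A spike of
neuron `i` at time $t$ is paired with each partner's most recent spike
(nearest-spike pairing; the update is applied once per event, which
matches an event-based implementation with a single last-spike store).
The pairing with time difference $\Delta t = t_{post} - t_{pre}$ changes
the weight by $\delta\,\Delta c$ on excitatory and $-\delta\,\Delta c$
on inhibitory synapses, with the asymmetric window

$$\Delta c = \begin{cases}
  \beta_1 e^{-\Delta t/(\gamma_1\tau)}, & \Delta t \ge 0\\[2pt]
  \beta_2 \frac{\Delta t}{\tau} e^{\Delta t/(\gamma_2\tau)}, & \Delta t < 0
\end{cases}$$

($\beta_1 = 1$, $\beta_2 = 16$, $\gamma_1 = 0.12$, $\gamma_2 = 0.15$,
$\tau = 14$ ms, $\delta = 0.002$), clipped to $[0, 1]$. Coincident
spikes take the potentiation branch; simultaneous events within one
integrator step are applied in chronological order of their
interpolated crossing times (ties by ascending neuron index), so the
result does not depend on detection order. With these parameters the
network is multistable: strongly coupled synchronized states coexist
with weakly coupled desynchronized ones, which is precisely what makes
long-lasting anti-kindling possible.

## Stimulation

All active protocols share one skeleton: 16 ms cycles in blocks of
three ON-cycles followed by two OFF-cycles; during an ON-cycle each of
the `Ns = 4` equidistant sites (neurons 25, 75, 125, 175 at full scale)
is activated exactly once. Over a 128 s stimulation period this yields
8,000 cycles, 4,800 of them ON, hence 4,800 onsets per site and 1,600
per within-block rank. An onset renders an alpha-function conductance
$(\Delta t/\tau_\alpha) e^{-\Delta t/\tau_\alpha}$ with time-to-peak
$\tau_\alpha = T_s/(6 N_s)$, truncated $T_s/2$ after the onset; two
onsets closer than $2 T_s/N_s = 8$ ms sum over the overlap (at 8 ms the
alpha function has decayed to 0.02% of its peak, so the truncation is
numerically invisible). The induced current is
$F_i = (V_r - V_i)\, K \sum_k D(i, x_k)\, G_k(t)$ with the quadratic
spatial profile $D = 1/(1 + d^2 (i - x_k)^2/\sigma_d^2)$.

The protocols differ *only* in how the within-cycle onset times are
drawn (uniform draws on the half-open cycle `[0, Ts)`):
one shared offset reused forever (PPMS), a fresh shared offset per
cycle (CMNS — the sham candidate), independent offsets per site (UMNS),
or the equidistant CR offsets $\{0, 4, 8, 12\}$ ms assigned by a site
permutation that changes every cycle (RVS), never (fixed), or every 100
cycles (SVS).

**Spatial decay rate.** $\sigma_d$ is the one stimulation constant the
model does not pin down numerically. We make it a required
configuration parameter with default 1.0 chain-length units: with that value the attenuation at
the midpoint between adjacent sites is about 0.39 at full scale, so
each stimulus acts predominantly on one subpopulation — the regime CR
stimulation assumes. The default was fixed once, on that geometric
argument.

## The experiment timeline and numerics

A run chains four periods: 2 s settling (the only period without STDP),
60 s STDP-only (the network falls onto its strongly coupled,
synchronized attractor), 128 s stimulation, 128 s follow-up. Time zero
is the first stimulus delivery. Initialization draws
$V_i \sim U[-65, 5]$ mV, gates and synaptic variables uniform on $[0,1]$, and
weights from a Gaussian(0.5, 0.01) clipped to $[0,1]$.

The coupled system is integrated with an adaptive Dormand-Prince
RK5(4) core (relative tolerance $10^{-5}$, absolute $10^{-6}$) with a
maximum step of 0.25 ms so that ~1 ms action potentials and the
sub-millisecond alpha conductance stay resolved even where the error
controller would take long steps. Integration is stopped and restarted
at every stimulation onset, because the conductance waveform has a kink
there; whether the original implementation did the same is not
documented, so this is our own numerical policy. Spikes are detected as
upward crossings of 0 mV with linear interpolation between accepted
steps and a 2 ms lockout — the model's action potentials peak far above
0 mV and the intrinsic period is 14 ms, so the rule is unambiguous.
STDP updates are applied at the interpolated crossing times, keeping
the pairing resolution well below 0.05 ms. Within-step weight changes
invalidate the integrator's reused end-point derivative, which is
therefore recomputed after any plasticity event.

Randomness is confined to R: the initialization stream depends only on
(base seed, sample id) — so one sample crossed with different protocols
starts from a bit-identical state at $t = 0$ — while the schedule
stream additionally depends on the protocol. The compiled core is fully
deterministic, and identical configurations reproduce rasters and
weight snapshots bit-for-bit.

## Metrics

* **Connectivity:** $C_{av} = N^{-2}\sum_{ij} \mathrm{sign}(M_{ij})
  c_{ij}$, with excitatory and inhibitory components normalized by the
  squared synapse counts $N_{EE}^{-2}$, $N_{II}^{-2}$ as defined for
  this model. Those components are therefore *relative scales* rather
  than per-synapse means; every use here compares them across protocols
  or time under the same constant normalization, which the choice of
  denominator cannot affect.
* **Sorted connectivity matrices:** per neuron pair the stronger weight
  goes to the (min, max) triangle and the weaker to the mirror
  position, then everything is signed by the template. Medians and IQRs
  across samples (linearly interpolated order statistics, `quantile`
  type 7 — fixed so golden values are stable) separate unidirectional
  from bidirectional coupling motifs.
* **Synchronization:** linear inter-spike phases
  $\varphi_j(t) = 2\pi (t - t_{j,m})/(t_{j,m+1} - t_{j,m})$ reduced by
  the Kuramoto order parameter, at the network level and per
  subpopulation (the 49 neurons nearest each site; the four neurons
  equidistant to two sites are excluded). Neurons without bracketing
  spikes at a query time have no defined phase and are excluded with
  renormalization — the phase definition simply does not extend beyond
  the first and last spike. Reported `R_av` values average the
  preceding 5 s of 1 ms samples.
* **Acute effects:** $1 - \bar R^{on}_k/\bar R^{pre}_k$ and
  $1 - \bar R^{off}_k/\bar R^{pre}_k$ per subpopulation (positive =
  desynchronizing).
* **Stimulus-locked dynamics:** the subpopulation mean phase collected
  in a ±32 ms window around every onset of the site (1 ms lag grid,
  matching the metric sampling), optionally split by rank within the
  ON-block, and reduced to the resetting index
  $E_k(\Delta t) = |L^{-1}\sum_n e^{i\Phi_k(t^n_k + \Delta t)}|$.
  Entrainment shows up as elevated $E$ before onsets; a phase reset as
  low pre-onset $E$ rising after the stimulus.
* **Statistics:** exact one-sided Wilcoxon rank-sum tests at
  $\alpha = 0.05$ across samples.

## Reduced-scale testing and what it can show

The full-scale conditions (200 neurons, 11 samples, 318 s per run)
produce the full protocol contrasts but cost hours of CPU per protocol
grid. The package therefore ships a reduced preset
(`smoke_config()`: 20 neurons, 2 sites at neurons 5 and 15, periods
2/6/12/12 s, all physical constants unchanged) that we use for
continuous verification; the methods and code paths are identical at
both scales, only `N` and durations differ.

What the reduced scale preserves: the intrinsic ~14 ms firing period;
development of a synchronized, strongly coupled attractor during the
STDP-only period (for most samples — the model is multistable and an
occasional sample settles on a weaker attractor, at either scale); the
stability of that attractor under the no-stimulation control; and the
acute directional contrasts — sequential CR suppresses both the average
signed weight and the order parameter relative to the control, while
the correlated-noise sham candidate desynchronizes far less and keeps
connectivity near or above the control level. What it does *not*
preserve quantitatively: full-scale effect sizes, long-lasting
after-effects (the small
ring re-synchronizes within the shortened follow-up period), and
significance at the 11-sample design. Tests therefore assert exact and
closed-form quantities exactly, oracle equivalences to $10^{-12}$, and
reduced-scale dynamics only directionally on medians.

## Known limitations

* Phases, and hence order parameters, are undefined before a neuron's
  first and after its last recorded spike; windows straddling the
  record edge silently renormalize over fewer neurons.
* The Eq.-level normalization of the excitatory/inhibitory weight
  averages (squared synapse counts) is kept as defined; absolute values
  of those two components should not be read as mean weights.
* The spatial profile uses the plain index difference of its defining
  formula, not the ring distance; for the default `sigma_d` the
  difference is negligible because the profile has decayed to ~0 at
  distances where wrap-around would matter.
* No conduction delays, synaptic noise, or alternative neuron models;
  single-process execution (a batch is a loop over independent runs).
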