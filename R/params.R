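#' Network parameters for the Hodgkin-Huxley ring
#'
#' Bundles every fixed constant of the neuronal network: classical
#' Hodgkin-Huxley membrane constants, the synaptic reversal potentials of
#' excitatory and inhibitory coupling, the distribution of the constant
#' injected currents, and the ring geometry (chain length, Mexican-hat
#' widths, stimulation-site placement). Defaults give the full-scale
#' configuration: a ring of 200 neurons with strong short-range excitation
#' and weak long-range inhibition, driven into tonic firing by injected
#' currents near 11 uA/cm2, with four equidistant stimulation sites at
#' neurons 25, 75, 125 and 175.
#'
#' @param N Number of neurons on the ring.
#' @param C Membrane capacitance (uF/cm2).
#' @param g_Na,g_K,g_l Maximal sodium, potassium and leak conductances
#'   (mS/cm2).
#' @param V_Na,V_K,V_l Sodium, potassium and leak reversal potentials (mV).
#' @param V_r_exc,V_r_inh Reversal potentials of excitatory and inhibitory
#'   synaptic coupling (mV).
#' @param I0 Mean constant injected current (uA/cm2).
#' @param delta_I Half-width of the uniform injected-current distribution
#'   (uA/cm2).
#' @param d0 Length of the neuronal chain (dimensionless ring length).
#' @param sigma1,sigma2 Widths of the Mexican-hat coupling template:
#'   `sigma1` sets the excitatory/inhibitory zero crossing, `sigma2` the
#'   Gaussian envelope.
#' @param Ns Number of stimulation sites; must divide `N`.
#' @param site_indices 1-based neuron indices of the stimulation sites.
#'   Default places `Ns` equidistant sites centred in each subpopulation
#'   (25, 75, 125, 175 for `N = 200`, `Ns = 4`).
#'
#' @return An object of class `network_params` (a named list).
#' @examples
#' p <- network_params()
#' p$site_indices
#' @export
network_params <- function(N = 200, C = 1,
                           g_Na = 120, g_K = 36, g_l = 0.3,
                           V_Na = 50, V_K = -77, V_l = -54.4,
                           V_r_exc = 20, V_r_inh = -40,
                           I0 = 11.0, delta_I = 0.45,
                           d0 = 10, sigma1 = 3.5, sigma2 = 2.0,
                           Ns = 4, site_indices = NULL) {
  if (N < 2 || N != round(N)) abort("`N` must be an integer >= 2")
  if (Ns < 1 || N %% Ns != 0)
    abort("`N` must be divisible by `Ns` (equidistant sites on the ring)")
  if (any(c(C, g_Na, g_K, g_l) <= 0))
    abort("capacitance and conductances must be strictly positive")
  if (is.null(site_indices)) {
    spacing <- N / Ns
    site_indices <- as.integer(round(spacing / 2) + spacing * (seq_len(Ns) - 1))
  }
  site_indices <- as.integer(site_indices)
  if (length(site_indices) != Ns ||
      any(site_indices < 1L | site_indices > N))
    abort("`site_indices` must be Ns valid 1-based neuron indices")
  if (Ns > 1) {
    gaps <- diff(c(site_indices, site_indices[1] + N))
    if (length(unique(gaps)) != 1L)
      abort("stimulation sites must be equidistant on the ring")
  }
  structure(
    list(N = as.integer(N), C = C, g_Na = g_Na, g_K = g_K, g_l = g_l,
         V_Na = V_Na, V_K = V_K, V_l = V_l,
         V_r_exc = V_r_exc, V_r_inh = V_r_inh,
         I0 = I0, delta_I = delta_I, d0 = d0,
         sigma1 = sigma1, sigma2 = sigma2,
         Ns = as.integer(Ns), site_indices = site_indices),
    class = "network_params")
}

#' Spike-timing-dependent plasticity parameters
#'
#' The asymmetric STDP window: potentiation decays exponentially for
#' post-after-pre pairs (time constant `gamma1 * tau`), depression follows
#' an alpha-shaped window for pre-after-post pairs (time constant
#' `gamma2 * tau`), and every pairing moves the weight by `delta` times the
#' window value. Weights are hard-clipped to `[c_min, c_max]`.
#'
#' @param beta1 Amplitude of the potentiation branch.
#' @param beta2 Amplitude of the depression branch.
#' @param gamma1,gamma2 Relative time constants of the two branches.
#' @param tau STDP reference time scale (ms).
#' @param delta Learning rate applied per spike pairing.
#' @param c_min,c_max Hard bounds of the synaptic weight magnitude.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(beta1 = 1, beta2 = 16, gamma1 = 0.12, gamma2 = 0.15,
                        tau = 14, delta = 0.002, c_min = 0, c_max = 1) {
  if (any(c(beta1, beta2, gamma1, gamma2, tau, delta) <= 0))
    abort("all STDP rate parameters must be strictly positive")
  if (c_min >= c_max) abort("`c_min` must be below `c_max`")
  structure(
    list(beta1 = beta1, beta2 = beta2, gamma1 = gamma1, gamma2 = gamma2,
         tau = tau, delta = delta, c_min = c_min, c_max = c_max),
    class = "stdp_params")
}

#' Stimulation-pattern parameters
#'
#' Describes the shared temporal skeleton of all active protocols:
#' 16 ms stimulation cycles grouped into blocks of three ON-cycles followed
#' by two OFF-cycles, each site activated exactly once per ON-cycle; a
#' normalized alpha-function conductance with time-to-peak
#' `Ts / (6 * Ns)` rendered at each onset; and a quadratic spatial decay
#' profile of rate `sigma_d` around each site.
#'
#' @param Ts Cycle duration (ms).
#' @param Ns Number of stimulation sites.
#' @param on_per_block,off_per_block ON- and OFF-cycles per block.
#' @param stim_on_duration Length of the stimulation period (s).
#' @param K Stimulation intensity (dimensionless gain).
#' @param sigma_d Spatial decay rate of the stimulation current, in chain
#'   length units; the
#'   default 1.0 keeps each stimulus predominantly local to one
#'   subpopulation (attenuation ~0.39 halfway between adjacent sites at
#'   the full scale).
#' @param svs_repeats Number of consecutive ON-cycles a slowly-varying
#'   sequence is repeated before a new sequence is drawn.
#' @return An object of class `stim_params`. Derived fields: `tau_alpha`
#'   (alpha-function time-to-peak, ms) and `overlap_window` (`2 Ts / Ns`,
#'   ms), the interval within which two onsets' conductances sum.
#' @export
stim_params <- function(Ts = 16, Ns = 4, on_per_block = 3, off_per_block = 2,
                        stim_on_duration = 128, K = 0.25, sigma_d = 1.0,
                        svs_repeats = 100) {
  if (Ts <= 0 || Ns < 1) abort("`Ts` must be positive and `Ns` >= 1")
  n_cycles <- stim_on_duration * 1000 / Ts
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    abort("stimulation cycles must tile the stim-on period exactly")
  n_cycles <- round(n_cycles)
  block <- on_per_block + off_per_block
  if (n_cycles %% block != 0)
    abort("ON/OFF blocks must tile the stim-on period exactly")
  structure(
    list(Ts = Ts, Ns = as.integer(Ns),
         on_per_block = as.integer(on_per_block),
         off_per_block = as.integer(off_per_block),
         stim_on_duration = stim_on_duration, K = K, sigma_d = sigma_d,
         svs_repeats = as.integer(svs_repeats),
         tau_alpha = Ts / (6 * Ns), overlap_window = 2 * Ts / Ns,
         n_cycles = as.integer(n_cycles)),
    class = "stim_params")
}

#' Experiment configuration
#'
#' One simulation run chains four periods: a settling period without STDP,
#' an STDP-only period during which the network develops strong
#' connectivity and synchrony, a stimulation period, and a stimulation-free
#' follow-up period. Time zero is defined as the delivery of the first
#' stimulation signal, so the settling and STDP-only periods run at
#' negative times.
#'
#' @param protocol One of `"no_stim"`, `"ppms"`, `"cmns"`, `"umns"`,
#'   `"rvs_cr"`, `"fixed_cr"`, `"svs_cr"`.
#' @param K Stimulation intensity.
#' @param sample_id Which of the independent initial-network samples to
#'   run (the full design uses 1..11).
#' @param periods Named durations in seconds:
#'   `init`, `stdp_only`, `stim_on`, `stim_off`.
#' @param net A [network_params()] object.
#' @param stdp A [stdp_params()] object.
#' @param stim A [stim_params()] object; its `Ns` must match `net$Ns` and
#'   its `stim_on_duration` is forced to `periods["stim_on"]`.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param hmax Maximum integrator step (ms); keeps ~1 ms action potentials
#'   and the sub-millisecond alpha-function resolved.
#' @param lockout Spike-detection refractory lockout (ms).
#' @param metric_dt Sampling interval of the metric time series (ms).
#' @param base_seed Base seed from which the per-sample initialization
#'   stream and the per-(sample, protocol) schedule stream are derived.
#' @return An object of class `experiment_config`.
#' @examples
#' cfg <- experiment_config("rvs_cr", K = 0.25, sample_id = 1)
#' cfg$periods
#' @export
experiment_config <- function(protocol = "no_stim", K = 0.25, sample_id = 1,
                              periods = c(init = 2, stdp_only = 60,
                                          stim_on = 128, stim_off = 128),
                              net = network_params(),
                              stdp = stdp_params(),
                              stim = NULL,
                              rtol = 1e-5, atol = 1e-6, hmax = 0.25,
                              lockout = 2, metric_dt = 1,
                              base_seed = 0) {
  protocol <- match.arg(protocol, PROTOCOLS)
  need <- c("init", "stdp_only", "stim_on", "stim_off")
  if (!all(need %in% names(periods))) {
    if (length(periods) == 4 && is.null(names(periods)))
      names(periods) <- need
    else abort("`periods` must name init, stdp_only, stim_on, stim_off")
  }
  if (is.null(stim))
    stim <- stim_params(Ns = net$Ns, K = K,
                        stim_on_duration = periods[["stim_on"]])
  else {
    if (stim$Ns != net$Ns) abort("`stim$Ns` must match `net$Ns`")
    stim <- stim_params(Ts = stim$Ts, Ns = stim$Ns,
                        on_per_block = stim$on_per_block,
                        off_per_block = stim$off_per_block,
                        stim_on_duration = periods[["stim_on"]],
                        K = K, sigma_d = stim$sigma_d,
                        svs_repeats = stim$svs_repeats)
  }
  structure(
    list(protocol = protocol, K = K, sample_id = as.integer(sample_id),
         periods = periods[need], net = net, stdp = stdp, stim = stim,
         rtol = rtol, atol = atol, hmax = hmax, lockout = lockout,
         metric_dt = metric_dt, base_seed = as.integer(base_seed)),
    class = "experiment_config")
}

#' Reduced-scale configuration for fast exploration and testing
#'
#' A down-scaled ring (20 neurons, 2 stimulation sites at neurons 5 and 15)
#' with shortened periods (2 / 6 / 12 / 12 s). All physical constants,
#' cycle structure and metric definitions are unchanged; only the network
#' size and simulated durations shrink.
#'
#' @inheritParams experiment_config
#' @param periods Period durations (s), defaulting to the reduced preset.
#' @return An `experiment_config` object.
#' @export
smoke_config <- function(protocol = "no_stim", K = 0.25, sample_id = 1,
                         periods = c(init = 2, stdp_only = 6,
                                     stim_on = 12, stim_off = 12),
                         base_seed = 0) {
  net <- network_params(N = 20, Ns = 2)
  experiment_config(protocol = protocol, K = K, sample_id = sample_id,
                    periods = periods, net = net, base_seed = base_seed)
}

#' @export
print.network_params <- function(x, ...) {
  cat("Hodgkin-Huxley ring network parameters\n")
  cat(sprintf("  N = %d neurons, chain length d0 = %g (lattice d = %.5f)\n",
              x$N, x$d0, x$d0 / (x$N - 1)))
  cat(sprintf("  Mexican hat: sigma1 = %g, sigma2 = %g\n",
              x$sigma1, x$sigma2))
  cat(sprintf("  %d stimulation sites at neurons %s\n",
              x$Ns, paste(x$site_indices, collapse = ", ")))
  invisible(x)
}

#' Serialize parameters to a flat YAML file
#'
#' @param params A `network_params`, `stdp_params` or `stim_params` object.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  lst <- unclass(params)
  lst$.class <- class(params)[1]
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read parameters back from a YAML file written by [write_params_yaml()]
#'
#' @param path File to read.
#' @return A parameter object of the class recorded in the file.
#' @export
read_params_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class
  lst$.class <- NULL
  ctor <- switch(cls,
                 network_params = network_params,
                 stdp_params = stdp_params,
                 stim_params = stim_params,
                 abort(paste0("unknown parameter class: ", cls)))
  keep <- intersect(names(lst), names(formals(ctor)))
  do.call(ctor, lst[keep])
}
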