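#' Draw a fresh random initial network state
#'
#' Builds one "sample": constant injected currents uniform on
#' `[I0 - delta_I, I0 + delta_I]`, membrane potentials uniform on
#' `[-65, 5]` mV, gate and synaptic variables uniform on `[0, 1]`, and
#' synaptic weight magnitudes Gaussian with mean 0.5 and standard
#' deviation 0.01, clipped to `[c_min, c_max]`. Self-connections are
#' fixed at zero and no neuron has a spike history yet. The draw order is
#' part of the determinism contract: I, V, m, h, n, s, then the weight
#' matrix column-major.
#'
#' @param seed Integer seed; identical seeds give identical states.
#' @param params A [network_params()] object.
#' @param stdp An [stdp_params()] object (for the weight bounds).
#' @return A `network_state`: list with `V`, `m`, `h`, `n`, `s`, `I`
#'   (length-N numerics), `c` (N x N weight magnitudes), `last_spike`
#'   (length-N, `NA` = never spiked) and `t` (current time, ms).
#' @examples
#' st <- initialize_network(1, network_params(N = 20, Ns = 2))
#' range(st$I)
#' @export
initialize_network <- function(seed, params = network_params(),
                               stdp = stdp_params()) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  withr::local_seed(seed)
  I <- runif(N, params$I0 - params$delta_I, params$I0 + params$delta_I)
  V <- runif(N, -65, 5)
  m <- runif(N)
  h <- runif(N)
  n <- runif(N)
  s <- runif(N)
  c_mat <- matrix(pmin(stdp$c_max, pmax(stdp$c_min, rnorm(N * N, 0.5, 0.01))),
                  N, N)
  diag(c_mat) <- 0
  structure(
    list(V = V, m = m, h = h, n = n, s = s, I = I, c = c_mat,
         last_spike = rep(NA_real_, N), t = 0),
    class = "network_state")
}

#' Detect spikes in a sampled voltage trace
#'
#' A spike is an upward crossing of the 0 mV threshold, timed by linear
#' interpolation between samples; a refractory lockout suppresses double
#' detections of one action potential.
#'
#' @param time Sample times, ms (ascending).
#' @param V Voltage samples, mV (same length as `time`).
#' @param threshold Crossing threshold, mV.
#' @param lockout Refractory lockout, ms.
#' @return Numeric vector of spike times, ms.
#' @examples
#' tt <- seq(0, 30, by = 0.1)
#' detect_spikes(tt, 40 * sin(2 * pi * tt / 14) - 20)
#' @export
detect_spikes <- function(time, V, threshold = 0, lockout = 2) {
  stopifnot(length(time) == length(V), !is.unsorted(time))
  below <- V[-length(V)] < threshold
  above <- V[-1] >= threshold
  idx <- which(below & above)
  if (length(idx) == 0) return(numeric(0))
  frac <- (threshold - V[idx]) / (V[idx + 1] - V[idx])
  cand <- time[idx] + frac * (time[idx + 1] - time[idx])
  keep <- numeric(0)
  last <- -Inf
  for (ts in cand) {
    if (ts - last >= lockout) {
      keep <- c(keep, ts)
      last <- ts
    }
  }
  keep
}

net_const_list <- function(cfg) {
  net <- cfg$net
  M <- mexican_hat_matrix(net)
  sgn <- sign(M)
  diag(sgn) <- 0 # self-connections carry no synapse
  list(C = net$C, g_Na = net$g_Na, g_K = net$g_K, g_l = net$g_l,
       V_Na = net$V_Na, V_K = net$V_K, V_l = net$V_l,
       V_r_exc = net$V_r_exc, V_r_inh = net$V_r_inh,
       abs_M = abs(M), sign_M = matrix(as.integer(sgn), net$N, net$N),
       M = M)
}

#' Integrate one simulation period
#'
#' Advances a network state by `duration` seconds with the compiled
#' adaptive Runge-Kutta (4,5) core: relative tolerance as configured
#' (default 1e-5), maximum step 0.25 ms, integration restarted at every
#' stimulation onset so the conductance kinks are resolved, spikes
#' detected as interpolated 0 mV upward crossings with a 2 ms lockout,
#' and (when enabled) the event-based STDP update applied at each
#' detected spike in chronological order. Connectivity metrics are
#' sampled every `metric_dt` ms.
#'
#' @param state A `network_state`.
#' @param duration Period length, seconds.
#' @param stdp_enabled Apply plasticity at detected spikes?
#' @param schedule Onset schedule tibble (absolute times, ms) or `NULL`
#'   for no stimulation.
#' @param cfg An [experiment_config()] object.
#' @return A list with elements `state` (the advanced `network_state`),
#'   `raster` (tibble `neuron`, `time_ms`), `metrics` (tibble `time_ms`,
#'   `c_av`, `c_ee`, `c_ii`) and `stats` (integrator counters).
#' @export
run_period <- function(state, duration, stdp_enabled, schedule = NULL,
                       cfg = experiment_config()) {
  stopifnot(inherits(state, "network_state"),
            inherits(cfg, "experiment_config"))
  nets <- net_const_list(cfg)
  if (is.null(schedule) || nrow(schedule) == 0) {
    onset_times <- numeric(0)
    onset_sites <- integer(0)
  } else {
    ord <- order(schedule$onset_ms)
    onset_times <- schedule$onset_ms[ord]
    onset_sites <- as.integer(schedule$site[ord])
  }
  prof <- site_profile_matrix(cfg$net, cfg$stim)
  res <- sim_period_cpp(
    unclass(state), nets, unclass(cfg$stdp),
    duration_ms = duration * 1000, stdp_enabled = stdp_enabled,
    onset_times = onset_times, onset_sites = onset_sites,
    site_profile = prof, K = cfg$K,
    Ts = cfg$stim$Ts, tau_alpha = cfg$stim$tau_alpha,
    rtol = cfg$rtol, atol = cfg$atol, hmax = cfg$hmax,
    metric_dt = cfg$metric_dt, lockout_ms = cfg$lockout)
  new_state <- structure(res$state, class = "network_state")
  list(
    state = new_state,
    raster = tibble::tibble(neuron = res$raster_neuron,
                            time_ms = res$raster_time),
    metrics = tibble::tibble(time_ms = res$metric_time,
                             c_av = res$c_av, c_ee = res$c_ee,
                             c_ii = res$c_ii),
    stats = list(n_steps = res$n_steps, n_rejected = res$n_rejected,
                 n_spikes = res$n_spikes, n_EE = res$n_EE,
                 n_II = res$n_II))
}

derive_seeds <- function(cfg) {
  pid <- protocol_id(cfg$protocol)
  base <- as.numeric(cfg$base_seed)
  init <- (base * 1009 + cfg$sample_id * 9973) %% 2147483647
  sched <- (base * 1013 + cfg$sample_id * 9973 + pid * 104729) %% 2147483647
  list(init = as.integer(init) + 1L, schedule = as.integer(sched) + 1L)
}

#' Run one complete four-period experiment
#'
#' Chains the four periods of a run: settling (no STDP), STDP-only
#' (the network converges to its synchronized strongly-coupled
#' attractor), stimulation-on (the protocol is delivered), and
#' stimulation-off. Time zero is the first stimulus delivery, so the
#' settling and STDP-only periods run at negative times. Weight-matrix
#' snapshots are taken at the start of stimulation, the end of
#' stimulation, and the end of the follow-up period. The initialization
#' stream depends only on (`base_seed`, `sample_id`), so the same sample
#' crossed with different protocols starts from an identical state at
#' `t = 0`; the schedule stream additionally depends on the protocol.
#'
#' @param cfg An [experiment_config()] object.
#' @return A `cr_experiment` object: list with `raster` (tibble
#'   `neuron`, `time_ms`, spanning the STDP-only period onward),
#'   `metrics` (tibble of 1 ms connectivity samples), `snapshots` (named
#'   list of weight-magnitude matrices at `t0`, `stim_end`, `off_end`),
#'   `schedule`, `template` (signed Mexican-hat matrix), `config`, and
#'   integrator `stats`.
#' @examples
#' \donttest{
#' ex <- run_experiment(smoke_config("cmns", sample_id = 1))
#' glance(ex)
#' }
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  seeds <- derive_seeds(cfg)
  state <- initialize_network(seeds$init, cfg$net, cfg$stdp)
  pre_ms <- (cfg$periods[["init"]] + cfg$periods[["stdp_only"]]) * 1000
  state$t <- -pre_ms

  p_init <- run_period(state, cfg$periods[["init"]], stdp_enabled = FALSE,
                       schedule = NULL, cfg = cfg)
  p_stdp <- run_period(p_init$state, cfg$periods[["stdp_only"]],
                       stdp_enabled = TRUE, schedule = NULL, cfg = cfg)
  snap_t0 <- p_stdp$state$c

  schedule <- build_schedule(cfg$protocol, cfg$stim, seed = seeds$schedule)
  p_on <- run_period(p_stdp$state, cfg$periods[["stim_on"]],
                     stdp_enabled = TRUE, schedule = schedule, cfg = cfg)
  snap_on <- p_on$state$c
  p_off <- run_period(p_on$state, cfg$periods[["stim_off"]],
                      stdp_enabled = TRUE, schedule = NULL, cfg = cfg)
  snap_off <- p_off$state$c

  raster <- dplyr::bind_rows(p_stdp$raster, p_on$raster, p_off$raster)
  metrics <- dplyr::bind_rows(p_stdp$metrics, p_on$metrics, p_off$metrics)
  nets <- net_const_list(cfg)

  structure(
    list(raster = raster, metrics = metrics,
         snapshots = list(t0 = snap_t0, stim_end = snap_on,
                          off_end = snap_off),
         schedule = schedule, template = nets$M, config = cfg,
         final_state = p_off$state,
         stats = list(init = p_init$stats, stdp_only = p_stdp$stats,
                      stim_on = p_on$stats, stim_off = p_off$stats),
         seeds = seeds),
    class = "cr_experiment")
}

#' @export
print.cr_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cr_experiment> protocol = %s, K = %g, sample = %d\n",
              cfg$protocol, cfg$K, cfg$sample_id))
  cat(sprintf("  N = %d neurons, periods (s): %s\n", cfg$net$N,
              paste(sprintf("%s=%g", names(cfg$periods), cfg$periods),
                    collapse = ", ")))
  cat(sprintf("  %d spikes recorded, %d onsets delivered\n",
              nrow(x$raster), nrow(x$schedule)))
  invisible(x)
}
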