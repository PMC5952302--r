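#' Raw STDP weight change for one spike pairing
#'
#' The asymmetric plasticity window as a function of the post-minus-pre
#' spike-time difference `dt`: exponential potentiation
#' `beta1 * exp(-dt / (gamma1 tau))` for `dt >= 0`, alpha-shaped depression
#' `beta2 * (dt / tau) * exp(dt / (gamma2 tau))` (negative) for `dt < 0`.
#' Coincident spikes (`dt = 0`) take the potentiation branch.
#'
#' @param dt Post-minus-pre spike-time difference(s), ms.
#' @param p An [stdp_params()] object.
#' @return Raw weight change(s), dimensionless; scaled by the learning
#'   rate and signed by synapse type when applied to a weight.
#' @examples
#' stdp_delta(c(0, 1.68, -2.1))
#' @export
stdp_delta <- function(dt, p = stdp_params()) {
  stopifnot(inherits(p, "stdp_params"))
  ifelse(dt >= 0,
         p$beta1 * exp(-dt / (p$gamma1 * p$tau)),
         p$beta2 * (dt / p$tau) * exp(dt / (p$gamma2 * p$tau)))
}

#' Apply the event-based STDP update for one spike
#'
#' When a neuron spikes, every synapse it shares with a partner that has
#' spiked before is updated once against that partner's most recent spike:
#' the incoming weight (partner presynaptic) with the post-after-pre
#' branch, the outgoing weight (partner postsynaptic) with the
#' pre-after-post branch. Excitatory weights move by `+delta * dc`,
#' inhibitory weights by `-delta * dc`, and results are clipped to the
#' weight bounds. Partners with no spike history and self-connections are
#' skipped, and the neuron's own last-spike record is advanced to
#' `t_spike`.
#'
#' @param neuron 1-based index of the spiking neuron.
#' @param t_spike Spike time, ms. Must not precede the neuron's recorded
#'   last spike.
#' @param state A `network_state`.
#' @param M Signed template matrix.
#' @param p An [stdp_params()] object.
#' @return The updated `network_state`.
#' @export
apply_spike <- function(neuron, t_spike, state, M, p = stdp_params()) {
  stopifnot(inherits(p, "stdp_params"))
  ls_own <- state$last_spike[neuron]
  if (!is.na(ls_own) && t_spike < ls_own)
    abort("`t_spike` precedes the neuron's recorded last spike")
  partners <- which(!is.na(state$last_spike))
  partners <- setdiff(partners, neuron)
  for (j in partners) {
    lj <- state$last_spike[j]
    sgn_in <- sign(M[neuron, j])
    if (sgn_in != 0) {
      dc <- stdp_delta(t_spike - lj, p)
      w <- state$c[neuron, j] + sgn_in * p$delta * dc
      state$c[neuron, j] <- min(p$c_max, max(p$c_min, w))
    }
    sgn_out <- sign(M[j, neuron])
    if (sgn_out != 0) {
      dc <- stdp_delta(lj - t_spike, p)
      w <- state$c[j, neuron] + sgn_out * p$delta * dc
      state$c[j, neuron] <- min(p$c_max, max(p$c_min, w))
    }
  }
  state$last_spike[neuron] <- t_spike
  state
}

#' Apply a batch of spike events in chronological order
#'
#' Sorts the events by time (ties broken by ascending neuron index, with
#' coincident spikes taking the potentiation branch) and applies
#' [apply_spike()] sequentially, so each event pairs against the spike
#' history as of its own time. The outcome is therefore independent of
#' the order in which the events are supplied.
#'
#' @param events A data frame with columns `neuron` and `time_ms`.
#' @param state A `network_state`.
#' @param M Signed template matrix.
#' @param p An [stdp_params()] object.
#' @return The updated `network_state`.
#' @export
apply_spike_events <- function(events, state, M, p = stdp_params()) {
  stopifnot(is.data.frame(events),
            all(c("neuron", "time_ms") %in% names(events)))
  events <- events[order(events$time_ms, events$neuron), , drop = FALSE]
  for (q in seq_len(nrow(events)))
    state <- apply_spike(events$neuron[q], events$time_ms[q], state, M, p)
  state
}
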