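#' Voltage-dependent Hodgkin-Huxley rate constants
#'
#' Evaluates the six opening/closing rates of the gating variables
#' m, h and n at membrane potential `V`. The two removable 0/0
#' singularities (alpha_m at -40 mV, alpha_n at -55 mV) are replaced by
#' their analytic limits inside a small epsilon window, so the returned
#' rates are finite and continuous everywhere.
#'
#' @param V Membrane potential(s), mV. Must be finite.
#' @return A tibble with one row per element of `V` and columns
#'   `alpha_m`, `beta_m`, `alpha_h`, `beta_h`, `alpha_n`, `beta_n`
#'   (all rates in 1/ms).
#' @examples
#' rate_constants(c(-65, -40, 0))
#' @export
rate_constants <- function(V) {
  if (!is.numeric(V) || length(V) == 0 || any(!is.finite(V)))
    abort("`V` must be finite numeric")
  ratio <- function(u) ifelse(abs(u) < 1e-7, 1, u / (1 - exp(-u)))
  tibble::tibble(
    alpha_m = ratio(0.1 * V + 4),
    beta_m = 4 * exp((-V - 65) / 18),
    alpha_h = 0.07 * exp((-V - 65) / 20),
    beta_h = 1 / (1 + exp(-0.1 * V - 3.5)),
    alpha_n = 0.1 * ratio(0.1 * V + 5.5),
    beta_n = 0.125 * exp((-V - 65) / 80))
}

#' Mexican-hat coupling template
#'
#' Distance-dependent signed template that fixes both the type and the
#' maximal strength of every connection on the ring: positive (excitatory)
#' for ring distances below `sigma1`, negative (inhibitory) beyond. The
#' ring distance between neurons `i` and `j` is
#' `d * min(|i - j|, N - |i - j|)` with lattice spacing
#' `d = d0 / (N - 1)`.
#'
#' @param i,j 1-based neuron indices (vectors are recycled).
#' @param params A [network_params()] object.
#' @return Numeric template value(s) `M_ij`, symmetric in `(i, j)` with
#'   `M_ii = 1`.
#' @examples
#' p <- network_params()
#' mexican_hat(1, 2, p)
#' @export
mexican_hat <- function(i, j, params) {
  stopifnot(inherits(params, "network_params"))
  if (any(i < 1 | i > params$N | j < 1 | j > params$N) ||
      any(i != round(i)) || any(j != round(j)))
    abort("neuron indices must lie in 1..N")
  d <- params$d0 / (params$N - 1)
  dij <- d * pmin(abs(i - j), params$N - abs(i - j))
  (1 - dij^2 / params$sigma1^2) * exp(-dij^2 / (2 * params$sigma2^2))
}

#' Full Mexican-hat template matrix
#'
#' @param params A [network_params()] object.
#' @return The `N x N` signed template matrix `M`.
#' @export
mexican_hat_matrix <- function(params) {
  stopifnot(inherits(params, "network_params"))
  idx <- seq_len(params$N)
  outer(idx, idx, function(i, j) mexican_hat(i, j, params))
}

#' Synaptic coupling current received by one neuron
#'
#' The ensemble-averaged postsynaptic current
#' `S_i = N^-1 sum_j (V_r,j - V_i) c_ij |M_ij| s_j`, where the reversal
#' potential `V_r,j` is the excitatory one where the template `M_ij` is
#' positive and the inhibitory one where it is negative. The weight matrix
#' carries magnitudes only; the synapse type lives entirely in the sign of
#' the template.
#'
#' @param i 1-based index of the receiving neuron.
#' @param state A `network_state` (see [initialize_network()]).
#' @param M Signed template matrix from [mexican_hat_matrix()].
#' @param params A [network_params()] object.
#' @return Coupling current `S_i` in uA/cm2.
#' @export
coupling_current <- function(i, state, M, params) {
  stopifnot(inherits(params, "network_params"))
  if (i < 1 || i > params$N) abort("`i` must lie in 1..N")
  Vr <- ifelse(M[i, ] > 0, params$V_r_exc, params$V_r_inh)
  sum((Vr - state$V[i]) * state$c[i, ] * abs(M[i, ]) * state$s) / params$N
}

#' Time derivatives of the full network state
#'
#' Plain-R reference implementation of the coupled membrane, gating and
#' synaptic dynamics: the current-balance equation with sodium, potassium
#' and leak currents plus coupling and stimulation input, first-order gate
#' kinetics `x' = alpha(V)(1 - x) - beta(V) x`, and the sigmoidal synaptic
#' activation `s' = 0.5 (1 - s) / (1 + exp(-(V + 5)/12)) - 2 s`. The
#' compiled integration core mirrors this routine; the two are held
#' together by tests.
#'
#' @param state A `network_state`.
#' @param S Coupling currents, uA/cm2 (length N).
#' @param F_current Stimulation currents, uA/cm2 (length N).
#' @param params A [network_params()] object.
#' @return A tibble with columns `dV` (mV/ms) and `dm`, `dh`, `dn`, `ds`
#'   (1/ms).
#' @export
hh_derivatives <- function(state, S, F_current, params) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  if (length(S) != N || length(F_current) != N)
    abort("`S` and `F_current` must have length N")
  V <- state$V
  r <- rate_constants(V)
  INa <- params$g_Na * state$m^3 * state$h * (V - params$V_Na)
  IK <- params$g_K * state$n^4 * (V - params$V_K)
  Il <- params$g_l * (V - params$V_l)
  tibble::tibble(
    dV = (state$I - INa - IK - Il + S + F_current) / params$C,
    dm = r$alpha_m * (1 - state$m) - r$beta_m * state$m,
    dh = r$alpha_h * (1 - state$h) - r$beta_h * state$h,
    dn = r$alpha_n * (1 - state$n) - r$beta_n * state$n,
    ds = 0.5 * (1 - state$s) / (1 + exp(-(V + 5) / 12)) - 2 * state$s)
}
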