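#' Build the stimulation onset schedule for a protocol
#'
#' All active protocols share the same skeleton: cycles of `Ts` ms in
#' repeating blocks of `on_per_block` ON-cycles followed by
#' `off_per_block` OFF-cycles, and each site activated exactly once per
#' ON-cycle. They differ only in how the within-cycle onset times are
#' drawn:
#'
#' * `ppms` - one uniform offset drawn once and reused every ON-cycle;
#'   all sites simultaneous (purely periodic multichannel stimulation).
#' * `cmns` - a fresh uniform offset per ON-cycle, shared by all sites
#'   (correlated multichannel noisy stimulation; the sham candidate).
#' * `umns` - an independent uniform offset per site per ON-cycle
#'   (uncorrelated multichannel noisy stimulation).
#' * `rvs_cr` - per ON-cycle a fresh random permutation of the sites
#'   assigned to the equidistant offsets `0, Ts/Ns, 2 Ts/Ns, ...`
#'   (rapidly varying sequence coordinated reset).
#' * `fixed_cr` - one random permutation of the equidistant offsets held
#'   for the whole stimulation period.
#' * `svs_cr` - a random permutation redrawn after every
#'   `svs_repeats` ON-cycles (slowly varying sequences).
#' * `no_stim` - the empty schedule (control).
#'
#' Offsets are drawn on the half-open interval `[0, Ts)`, so every onset
#' lies strictly inside its ON-cycle.
#'
#' @param protocol Protocol tag (see above).
#' @param p A [stim_params()] object.
#' @param seed Integer seed for the schedule stream.
#' @return A tibble with one row per onset and columns `site` (1-based
#'   site index), `onset_ms` (absolute time from the start of the
#'   stimulation period), `cycle` (1-based index among ON-cycles),
#'   `rank` (position 1..`on_per_block` within its ON-block), and
#'   `protocol`. Rows are sorted by onset time. The `stim_params` and
#'   seed used are attached as attributes.
#' @examples
#' sched <- build_schedule("rvs_cr", stim_params(), seed = 1)
#' dplyr::count(sched, rank)
#' @export
build_schedule <- function(protocol, p = stim_params(), seed = 1) {
  protocol <- match.arg(protocol, PROTOCOLS)
  stopifnot(inherits(p, "stim_params"))
  empty <- tibble::tibble(site = integer(), onset_ms = numeric(),
                          cycle = integer(), rank = integer(),
                          protocol = character())
  if (protocol == "no_stim") {
    out <- empty
  } else {
    block <- p$on_per_block + p$off_per_block
    all_cycles <- seq_len(p$n_cycles)
    pos_in_block <- (all_cycles - 1) %% block + 1
    on_mask <- pos_in_block <= p$on_per_block
    on_cycles <- all_cycles[on_mask]
    n_on <- length(on_cycles)
    cycle_start <- (on_cycles - 1) * p$Ts
    rank <- pos_in_block[on_mask]
    Ns <- p$Ns
    slot <- p$Ts / Ns

    withr::local_seed(seed)
    # offsets[n, k]: within-cycle onset offset of site k in the n-th ON-cycle
    offsets <- switch(
      protocol,
      ppms = matrix(runif(1, 0, p$Ts), n_on, Ns),
      cmns = matrix(runif(n_on, 0, p$Ts), n_on, Ns),
      umns = matrix(runif(n_on * Ns, 0, p$Ts), n_on, Ns),
      rvs_cr = t(vapply(seq_len(n_on), function(q) {
        perm <- sample.int(Ns)
        (match(seq_len(Ns), perm) - 1) * slot
      }, numeric(Ns))),
      fixed_cr = {
        perm <- sample.int(Ns)
        matrix(rep((match(seq_len(Ns), perm) - 1) * slot, each = n_on),
               n_on, Ns)
      },
      svs_cr = {
        n_seq <- ceiling(n_on / p$svs_repeats)
        seq_offsets <- t(vapply(seq_len(n_seq), function(q) {
          perm <- sample.int(Ns)
          (match(seq_len(Ns), perm) - 1) * slot
        }, numeric(Ns)))
        seq_offsets[ceiling(seq_len(n_on) / p$svs_repeats), , drop = FALSE]
      })
    if (Ns == 1) offsets <- matrix(offsets, n_on, 1)

    out <- tibble::tibble(
      site = rep(seq_len(Ns), each = n_on),
      onset_ms = rep(cycle_start, Ns) + as.vector(offsets),
      cycle = rep(seq_len(n_on), Ns),
      rank = rep(rank, Ns),
      protocol = protocol)
    out <- dplyr::arrange(out, .data$onset_ms, .data$site)
  }
  attr(out, "stim_params") <- p
  attr(out, "seed") <- seed
  attr(out, "protocol") <- protocol
  out
}

#' Spatial attenuation of a stimulation site at a neuron
#'
#' Quadratic decay profile `D = 1 / (1 + d^2 (i - x_k)^2 / sigma_d^2)`
#' with `d` the lattice spacing; equals 1 at the site itself and 1/2 at
#' index distance `sigma_d / d`.
#'
#' @param i Neuron index (vectorized).
#' @param x_k Neuron index of the stimulation site.
#' @param p A [stim_params()] object (supplies `sigma_d`).
#' @param net A [network_params()] object (supplies the lattice spacing).
#' @return Attenuation value(s) in `(0, 1]`.
#' @export
spatial_profile <- function(i, x_k, p, net) {
  stopifnot(inherits(p, "stim_params"), inherits(net, "network_params"))
  if (any(i < 1 | i > net$N) || any(x_k < 1 | x_k > net$N))
    abort("indices must lie in 1..N")
  d <- net$d0 / (net$N - 1)
  1 / (1 + d^2 * (i - x_k)^2 / p$sigma_d^2)
}

site_profile_matrix <- function(net, p) {
  vapply(net$site_indices,
         function(x) spatial_profile(seq_len(net$N), x, p, net),
         numeric(net$N))
}

#' Normalized stimulation conductance of one site
#'
#' Renders a site's ordered onset times into the alpha-function
#' conductance `(dt / tau) exp(-dt / tau)` with time-to-peak
#' `tau = Ts / (6 Ns)`. Each onset's contribution is truncated `Ts / 2`
#' after it; when two onsets fall within `2 Ts / Ns` of each other their
#' alpha-functions sum over the overlap (at that separation the older
#' contribution is already down to 0.02% of its peak).
#'
#' @param t Query time(s), ms.
#' @param site_onsets Ordered (ascending) onset times of one site, ms.
#' @param p A [stim_params()] object.
#' @return Conductance value(s), `>= 0`.
#' @examples
#' p <- stim_params()
#' conductance(p$tau_alpha, 0, p) # peak value exp(-1)
#' @export
conductance <- function(t, site_onsets, p) {
  stopifnot(inherits(p, "stim_params"))
  if (is.unsorted(site_onsets)) abort("`site_onsets` must be sorted ascending")
  if (length(site_onsets) == 0) return(rep(0, length(t)))
  cutoff <- p$Ts / 2
  idx <- findInterval(t, site_onsets)
  g <- numeric(length(t))
  for (back in 0:1) {
    sel <- idx - back
    ok <- sel >= 1
    dt <- ifelse(ok, t - site_onsets[pmax(sel, 1)], -1)
    act <- ok & dt >= 0 & dt <= cutoff
    u <- dt[act] / p$tau_alpha
    g[act] <- g[act] + u * exp(-u)
  }
  g
}

#' Total stimulation current induced in one neuron
#'
#' `F_i = (V_r - V_i) * K * sum_k D(i, x_k) G_k(t)` with the excitatory
#' reversal potential as driving force: each stimulus acts as a brief
#' excitatory postsynaptic conductance scaled by the intensity `K` and
#' attenuated with distance from its site.
#'
#' @param i Neuron index.
#' @param t Query time, ms (scalar).
#' @param state A `network_state` supplying `V[i]` at time `t`.
#' @param schedule Onset schedule tibble from [build_schedule()].
#' @param p A [stim_params()] object.
#' @param net A [network_params()] object.
#' @return Stimulation current, uA/cm2.
#' @export
stim_current <- function(i, t, state, schedule, p, net) {
  stopifnot(length(t) == 1)
  if (nrow(schedule) == 0 || p$K == 0) return(0)
  acc <- 0
  for (k in seq_len(net$Ns)) {
    ons <- sort(schedule$onset_ms[schedule$site == k])
    gk <- conductance(t, ons, p)
    if (gk > 0)
      acc <- acc + spatial_profile(i, net$site_indices[k], p, net) * gk
  }
  (net$V_r_exc - state$V[i]) * p$K * acc
}

#' Write / read an onset schedule as tab-separated text
#'
#' @param schedule Schedule tibble from [build_schedule()].
#' @param path File path.
#' @return `path` (write) or the schedule tibble (read).
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(
    schedule[, c("site", "onset_ms", "cycle", "rank")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  tibble::as_tibble(df)
}
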