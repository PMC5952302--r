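#' Signed weight matrix
#'
#' Multiplies each weight magnitude by the sign of the Mexican-hat
#' template, so excitatory synapses appear as positive values in `[0, 1]`
#' and inhibitory synapses as negative values in `[-1, 0]`.
#'
#' @param c Weight-magnitude matrix.
#' @param M Signed template matrix.
#' @return Signed N x N matrix.
#' @export
signed_weights <- function(c, M) {
  stopifnot(all(dim(c) == dim(M)))
  sign(M) * c
}

#' Network-level connectivity summaries
#'
#' The average signed synaptic weight `C_av = N^-2 sum sign(M_ij) c_ij`
#' and its excitatory / inhibitory components, normalized as defined for
#' this model by the squared synapse counts `N_EE^-2` and `N_II^-2`
#' (so `c_EE` and `c_II` are relative scales, not per-synapse means;
#' every comparison across protocols or time uses the same constant
#' normalization). Self-connections carry no synapse and are excluded
#' from sums and counts.
#'
#' @param c Weight-magnitude matrix.
#' @param M Signed template matrix.
#' @return A one-row tibble with columns `c_av`, `c_ee`, `c_ii`, `n_ee`,
#'   `n_ii`.
#' @export
mean_weights <- function(c, M) {
  stopifnot(all(dim(c) == dim(M)))
  N <- nrow(c)
  sgn <- sign(M)
  diag(sgn) <- 0
  exc <- sgn > 0
  inh <- sgn < 0
  n_ee <- sum(exc)
  n_ii <- sum(inh)
  tibble::tibble(
    c_av = sum(sgn * c) / N^2,
    c_ee = if (n_ee > 0) sum(c[exc]) / n_ee^2 else 0,
    c_ii = if (n_ii > 0) sum(c[inh]) / n_ii^2 else 0,
    n_ee = n_ee, n_ii = n_ii)
}

#' Sorted connectivity matrix
#'
#' For every unordered neuron pair the larger of the two directed weights
#' is placed at `(min(i, j), max(i, j))` and the smaller at
#' `(max(i, j), min(i, j))`, then the result is multiplied elementwise by
#' the template sign. Across samples this separates bidirectionally
#' strong, bidirectionally weak and unidirectional coupling motifs, which
#' the raw matrices mix.
#'
#' @param c Weight-magnitude matrix (square).
#' @param M Signed template matrix.
#' @return The sorted signed matrix.
#' @export
sort_connectivity <- function(c, M) {
  stopifnot(nrow(c) == ncol(c), all(dim(c) == dim(M)))
  ct <- t(c)
  out <- c
  upper <- upper.tri(c) # rows i < cols j -> (min, max) positions
  lower <- lower.tri(c)
  out[upper] <- pmax(c[upper], ct[upper])
  out[lower] <- pmin(c[lower], ct[lower])
  sign(M) * out
}

#' Elementwise median and IQR of a stack of matrices
#'
#' @param matrices List of equally-shaped matrices (one per sample).
#' @return List with elements `median` and `iqr` (both matrices). The
#'   IQR uses linearly interpolated order statistics
#'   (`quantile(type = 7)`).
#' @export
median_iqr_stack <- function(matrices) {
  if (length(matrices) < 2) abort("need at least 2 matrices")
  dims <- dim(matrices[[1]])
  if (!all(vapply(matrices, function(m) all(dim(m) == dims), logical(1))))
    abort("all matrices must have the same shape")
  arr <- array(unlist(matrices), dim = c(dims, length(matrices)))
  med <- apply(arr, c(1, 2), median)
  iqr <- apply(arr, c(1, 2), function(v) {
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  })
  list(median = med, iqr = iqr)
}

#' Linear inter-spike phase of one neuron
#'
#' The phase grows linearly from 0 to 2*pi between consecutive spikes:
#' `phi(t) = 2 pi (t - t_m) / (t_{m+1} - t_m)` for `t` in
#' `[t_m, t_{m+1})`. Outside the first/last spike the phase is undefined
#' and returned as `NA`.
#'
#' @param spike_times Sorted spike times of one neuron, ms.
#' @param t Query time(s), ms.
#' @return Phase value(s) in `[0, 2 pi)`, `NA` where undefined.
#' @export
linear_phase <- function(spike_times, t) {
  if (is.unsorted(spike_times)) abort("`spike_times` must be sorted")
  n <- length(spike_times)
  if (n < 2) return(rep(NA_real_, length(t)))
  m <- findInterval(t, spike_times)
  ok <- m >= 1 & m < n
  phi <- rep(NA_real_, length(t))
  mm <- m[ok]
  phi[ok] <- 2 * pi * (t[ok] - spike_times[mm]) /
    (spike_times[mm + 1] - spike_times[mm])
  phi
}

#' Kuramoto order parameter of a set of phases
#'
#' `R e^{i Phi} = mean(e^{i phi_j})` over the neurons whose phase is
#' defined; `R = 1` is perfect in-phase synchrony, `R = 0` none.
#' Undefined (`NA`) phases are excluded with renormalization by the
#' count of defined phases.
#'
#' @param phases Numeric phases, radians; `NA` = undefined.
#' @return A list with `R`, `Phi` (circular mean, in `[0, 2 pi)`) and
#'   `n_defined`. If no phase is defined, `R` and `Phi` are `NA`.
#' @examples
#' order_parameter(c(0, 0, pi))$R # 1/3
#' @export
order_parameter <- function(phases) {
  phases <- phases[!is.na(phases)]
  if (length(phases) == 0)
    return(list(R = NA_real_, Phi = NA_real_, n_defined = 0L))
  z <- mean(exp(1i * phases))
  list(R = Mod(z), Phi = Arg(z) %% (2 * pi), n_defined = length(phases))
}

#' Order-parameter time series from a spike raster
#'
#' Evaluates each neuron's linear inter-spike phase at the query times
#' and reduces them to the Kuramoto order parameter, either over the
#' whole network or over a subset of neurons (a subpopulation).
#'
#' @param raster Tibble with columns `neuron`, `time_ms`.
#' @param times Query times, ms.
#' @param neurons Neuron indices to include (default: all in `raster`).
#' @return Tibble with columns `time_ms`, `R`, `Phi`, `n_defined`.
#' @export
r_series <- function(raster, times, neurons = NULL) {
  if (is.null(neurons)) neurons <- sort(unique(raster$neuron))
  spk <- split(raster$time_ms, factor(raster$neuron, levels = neurons))
  zsum <- complex(real = rep(0, length(times)),
                  imaginary = rep(0, length(times)))
  ndef <- integer(length(times))
  for (st in spk) {
    phi <- linear_phase(sort(st), times)
    ok <- !is.na(phi)
    zsum[ok] <- zsum[ok] + exp(1i * phi[ok])
    ndef <- ndef + ok
  }
  z <- ifelse(ndef > 0, zsum / ndef, NA_complex_)
  tibble::tibble(time_ms = times, R = Mod(z), Phi = Arg(z) %% (2 * pi),
                 n_defined = ndef)
}

#' Trailing 5 s average of the order parameter
#'
#' @param r_tbl Tibble from [r_series()] with 1 ms samples.
#' @param t_ms Query time, ms.
#' @param window_ms Averaging window (default 5 s), taken over
#'   `(t_ms - window_ms, t_ms]`.
#' @return The windowed mean of `R`.
#' @export
r_av <- function(r_tbl, t_ms, window_ms = 5000) {
  sel <- r_tbl$time_ms > t_ms - window_ms & r_tbl$time_ms <= t_ms
  if (!any(sel) ||
      min(r_tbl$time_ms) > t_ms - window_ms + 1e-9)
    abort("insufficient history for the averaging window")
  mean(r_tbl$R[sel], na.rm = TRUE)
}

#' Acute stimulation effect and after-effect
#'
#' Relative drop of a (sub)population's trailing-averaged order
#' parameter at the end of stimulation (`stim_effect = 1 - on/pre`) and
#' at the end of the follow-up period (`after_effect = 1 - off/pre`)
#' versus the pre-stimulation baseline. Positive values mean
#' desynchronization, negative values a synchronizing effect.
#'
#' @param r_pre,r_on,r_off Trailing 5 s means of the order parameter
#'   before stimulation, at stimulation end, and at follow-up end.
#' @return A tibble with columns `stim_effect` and `after_effect`.
#' @export
acute_effects <- function(r_pre, r_on, r_off) {
  if (any(r_pre <= 0)) abort("`r_pre` must be strictly positive")
  tibble::tibble(stim_effect = 1 - r_on / r_pre,
                 after_effect = 1 - r_off / r_pre)
}

#' Subpopulation membership around each stimulation site
#'
#' Assigns every neuron to the stimulation site nearest on the ring and
#' drops the boundary neurons that are equidistant to two sites, so each
#' of the `Ns` subpopulations contains `N / Ns - 1` members (49 at full
#' scale, e.g. neurons 51-99 around site 75).
#'
#' @param net A [network_params()] object.
#' @return Tibble with columns `site` (1-based site number) and `neuron`.
#' @export
subpopulation_map <- function(net) {
  stopifnot(inherits(net, "network_params"))
  N <- net$N
  purrr::map_dfr(seq_len(N), function(i) {
    dist <- pmin(abs(i - net$site_indices),
                 N - abs(i - net$site_indices))
    nearest <- which(dist == min(dist))
    if (length(nearest) > 1) return(NULL) # boundary neuron, excluded
    tibble::tibble(site = nearest, neuron = i)
  })
}

#' Stimulus-locked cross-trial phase distribution of a subpopulation
#'
#' Collects the subpopulation mean phase `Phi_k` at lags
#' `-window .. +window` ms (1 ms grid) around every onset delivered to
#' one site, optionally restricted to one rank within the ON-blocks.
#' Onsets whose window exceeds the raster record are skipped and the
#' trial count reduced accordingly.
#'
#' @param raster Spike raster tibble (`neuron`, `time_ms`).
#' @param schedule Onset schedule from [build_schedule()].
#' @param neurons Member neurons of the subpopulation (from
#'   [subpopulation_map()]).
#' @param site Site index whose onsets to lock to.
#' @param window Half-width of the lag window, ms.
#' @param dt Lag grid spacing, ms.
#' @param rank_filter Optional rank (1..on_per_block) to restrict to.
#' @return A `cross_trial` tibble with columns `delta_t`, `onset_n`,
#'   `phi` (`NA` where no member phase is defined); the number of
#'   retained onsets is attached as attribute `L`.
#' @export
cross_trial <- function(raster, schedule, neurons, site,
                        window = 32, dt = 1, rank_filter = NULL) {
  ons <- schedule[schedule$site == site, , drop = FALSE]
  if (!is.null(rank_filter))
    ons <- ons[ons$rank %in% rank_filter, , drop = FALSE]
  lo <- min(raster$time_ms)
  hi <- max(raster$time_ms)
  keep <- ons$onset_ms - window >= lo & ons$onset_ms + window <= hi
  ons <- ons[keep, , drop = FALSE]
  L <- nrow(ons)
  deltas <- seq(-window, window, by = dt)
  times <- as.vector(outer(ons$onset_ms, deltas, `+`))
  rsub <- raster[raster$neuron %in% neurons, , drop = FALSE]
  rs <- r_series(rsub, times, neurons = neurons)
  out <- tibble::tibble(
    delta_t = rep(deltas, each = L),
    onset_n = rep(seq_len(L), length(deltas)),
    phi = rs$Phi)
  attr(out, "L") <- L
  class(out) <- c("cross_trial", class(out))
  out
}

#' Resetting index from a cross-trial distribution
#'
#' `E_k(dt) = |L^-1 sum_n exp(i Phi_k(t_k^n + dt))|`: the resultant
#' length of the subpopulation phase across stimulus repetitions at each
#' lag. Values near 1 indicate stimulus-locked phase, values near 0 a
#' uniform phase distribution across trials.
#'
#' @param dist A `cross_trial` tibble from [cross_trial()].
#' @return Tibble with columns `delta_t`, `E`, `L` (trials with a
#'   defined phase at that lag).
#' @export
resetting_index <- function(dist) {
  stopifnot(all(c("delta_t", "phi") %in% names(dist)))
  dist |>
    dplyr::group_by(.data$delta_t) |>
    dplyr::summarise(
      E = {
        ph <- .data$phi[!is.na(.data$phi)]
        if (length(ph) == 0) NA_real_ else Mod(mean(exp(1i * ph)))
      },
      L = sum(!is.na(.data$phi)),
      .groups = "drop")
}

#' One-sided exact rank-sum comparison of two samples
#'
#' Exact Mann-Whitney / Wilcoxon rank-sum test. `side = "less"` tests
#' whether the first sample's distribution is shifted below the second's
#' (the "left-sided" usage for testing decreases of a metric under one
#' protocol versus another).
#'
#' @param A,B Numeric sample vectors.
#' @param side `"less"` or `"greater"`.
#' @param alpha Significance level.
#' @return A one-row tibble: `statistic` (Mann-Whitney U of `A`),
#'   `p_value`, `significant`, `side`, `alpha`, `median_a`, `median_b`,
#'   `n_a`, `n_b`.
#' @examples
#' rank_sum_compare(c(1, 2, 3), c(4, 5, 6), side = "less")
#' @export
rank_sum_compare <- function(A, B, side = c("less", "greater"),
                             alpha = 0.05) {
  side <- match.arg(side)
  if (length(A) < 1 || length(B) < 1) abort("both samples must be non-empty")
  if (length(unique(c(A, B))) == 1L) {
    warn("all observations tied; reporting p = 1")
    p <- 1
    stat <- length(A) * length(B) / 2
  } else {
    ht <- suppressWarnings(
      wilcox.test(A, B, alternative = side, exact = TRUE))
    p <- ht$p.value
    stat <- unname(ht$statistic)
  }
  tibble::tibble(statistic = stat, p_value = p,
                 significant = p < alpha, side = side, alpha = alpha,
                 median_a = median(A), median_b = median(B),
                 n_a = length(A), n_b = length(B))
}

#' Population spike counts per time bin
#'
#' Histogram of spikes across all neurons in 1 ms bins, as used to
#' visualize how many neurons fire within each millisecond at the end of
#' the stimulation period.
#'
#' @param raster Spike raster tibble (`neuron`, `time_ms`).
#' @param window Length-2 interval `[lo, hi)`, ms.
#' @param bin Bin width, ms.
#' @return Tibble with columns `bin_start` and `count`.
#' @export
spike_counts <- function(raster, window, bin = 1) {
  stopifnot(length(window) == 2, window[2] > window[1])
  edges <- seq(window[1], window[2], by = bin)
  tt <- raster$time_ms[raster$time_ms >= window[1] &
                         raster$time_ms < window[2]]
  idx <- findInterval(tt, edges)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  tibble::tibble(bin_start = edges[-length(edges)], count = counts)
}

#' Subpopulation synchronization summary of an experiment
#'
#' Computes, for every subpopulation, the trailing 5 s averaged order
#' parameter before stimulation, at stimulation end and at follow-up
#' end, together with the acute stimulation effect and after-effect.
#'
#' @param ex A `cr_experiment` from [run_experiment()].
#' @param window_ms Trailing averaging window, ms (clipped to the
#'   shortest period if needed).
#' @return Tibble with one row per subpopulation: `site`, `r_pre`,
#'   `r_on`, `r_off`, `stim_effect`, `after_effect`.
#' @export
subpop_effects <- function(ex, window_ms = 5000) {
  stopifnot(inherits(ex, "cr_experiment"))
  cfg <- ex$config
  t_on <- cfg$periods[["stim_on"]] * 1000
  t_off <- t_on + cfg$periods[["stim_off"]] * 1000
  window_ms <- min(window_ms, cfg$periods[["stdp_only"]] * 1000,
                   t_on, t_off - t_on)
  map <- subpopulation_map(cfg$net)
  purrr::map_dfr(sort(unique(map$site)), function(k) {
    members <- map$neuron[map$site == k]
    pre_t <- seq(-window_ms + cfg$metric_dt, 0, by = cfg$metric_dt)
    on_t <- seq(t_on - window_ms + cfg$metric_dt, t_on, by = cfg$metric_dt)
    off_t <- seq(t_off - window_ms + cfg$metric_dt, t_off,
                 by = cfg$metric_dt)
    rsub <- ex$raster[ex$raster$neuron %in% members, , drop = FALSE]
    rp <- mean(r_series(rsub, pre_t, members)$R, na.rm = TRUE)
    ro <- mean(r_series(rsub, on_t, members)$R, na.rm = TRUE)
    rf <- mean(r_series(rsub, off_t, members)$R, na.rm = TRUE)
    eff <- acute_effects(rp, ro, rf)
    tibble::tibble(site = k, r_pre = rp, r_on = ro, r_off = rf,
                   stim_effect = eff$stim_effect,
                   after_effect = eff$after_effect)
  })
}
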