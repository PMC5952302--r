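test_that("connectivity summaries match the brute-force oracle", {
  p <- toy_params(N = 6, Ns = 2)
  M <- mexican_hat_matrix(p)
  for (seed in 1:5) {
    st <- toy_state(N = 6, seed = seed)
    got <- mean_weights(st$c, M)
    want <- oracle_mean_weights(st$c, M)
    expect_equal(got$c_av, want$c_av, tolerance = 1e-12)
    expect_equal(got$c_ee, want$c_ee, tolerance = 1e-12)
    expect_equal(got$c_ii, want$c_ii, tolerance = 1e-12)
    expect_equal(got$n_ee, want$n_ee)
    expect_equal(got$n_ii, want$n_ii)
  }
  # degenerate and saturated cases
  z <- matrix(0, 6, 6)
  expect_equal(as.numeric(mean_weights(z, M)[, 1:3]), c(0, 0, 0))
  o <- matrix(1, 6, 6); diag(o) <- 0
  w <- mean_weights(o, M)
  expect_equal(w$c_av, (w$n_ee - w$n_ii) / 36, tolerance = 1e-12)
  # C_av always within the sign-count bounds
  for (seed in 1:3) {
    st <- toy_state(N = 6, seed = seed)
    w <- mean_weights(st$c, M)
    expect_gte(w$c_av, -w$n_ii / 36)
    expect_lte(w$c_av, w$n_ee / 36)
  }
})

test_that("sorted connectivity puts the stronger weight in the upper triangle", {
  p <- toy_params(N = 6, Ns = 2)
  M <- mexican_hat_matrix(p)
  for (seed in 1:5) {
    st <- toy_state(N = 6, seed = seed)
    srt <- sort_connectivity(st$c, M)
    for (i in 1:6) for (j in 1:6) {
      if (i == j) next
      lo <- min(i, j); hi <- max(i, j)
      expect_equal(abs(srt[lo, hi]), max(st$c[i, j], st$c[j, i]),
                   tolerance = 1e-12)
      expect_equal(abs(srt[hi, lo]), min(st$c[i, j], st$c[j, i]),
                   tolerance = 1e-12)
      expect_equal(sign(srt[i, j]), sign(M[i, j]))
      # construction invariant: |upper| >= |mirror lower|
      expect_gte(abs(srt[lo, hi]), abs(srt[hi, lo]))
    }
  }
  # explicit pair and tie behaviour
  cm <- matrix(0, 3, 3); cm[1, 2] <- 0.9; cm[2, 1] <- 0.1
  Mx <- matrix(1, 3, 3)
  srt <- sort_connectivity(cm, Mx)
  expect_equal(srt[1, 2], 0.9)
  expect_equal(srt[2, 1], 0.1)
  cm[1, 2] <- cm[2, 1] <- 0.4
  srt <- sort_connectivity(cm, Mx)
  expect_equal(srt[1, 2], 0.4)
  expect_equal(srt[2, 1], 0.4)
  # symmetric input is returned signed but otherwise unchanged
  cs <- (cm + t(cm)) / 2
  expect_equal(sort_connectivity(cs, Mx), sign(Mx) * cs)
})

test_that("elementwise median/IQR stack follows the fixed quartile rule", {
  mats <- lapply(1:11, function(v) matrix(v, 2, 2))
  res <- median_iqr_stack(mats)
  expect_equal(res$median, matrix(6, 2, 2))
  q <- quantile(1:11, c(0.25, 0.75), type = 7)
  expect_equal(res$iqr, matrix(unname(q[2] - q[1]), 2, 2))
  # identical matrices: IQR is zero, sign preserved in the median
  neg <- lapply(1:5, function(q) matrix(-0.3, 2, 2))
  res <- median_iqr_stack(neg)
  expect_equal(res$iqr, matrix(0, 2, 2))
  expect_equal(res$median, matrix(-0.3, 2, 2))
  expect_error(median_iqr_stack(mats[1]), "at least 2")
  expect_error(median_iqr_stack(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "shape")
})

test_that("linear phase interpolates between spikes and flags outside", {
  spikes <- c(0, 14, 28)
  expect_equal(linear_phase(spikes, 0), 0)
  expect_equal(linear_phase(spikes, 7), pi)
  expect_equal(linear_phase(spikes, 21), pi)
  expect_equal(linear_phase(spikes, 27.9999), 2 * pi, tolerance = 1e-3)
  expect_true(is.na(linear_phase(spikes, -1)))
  expect_true(is.na(linear_phase(spikes, 28))) # no bracketing interval
  expect_true(all(is.na(linear_phase(c(5), c(1, 10)))))
})

test_that("order parameter reduces phases as the Kuramoto mean", {
  expect_equal(order_parameter(rep(1.3, 7))$R, 1, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 2, pi, 3 * pi / 2))$R, 0,
               tolerance = 1e-12)
  op <- order_parameter(c(0, 0, pi))
  expect_equal(op$R, 1 / 3, tolerance = 1e-12)
  expect_equal(op$n_defined, 3L)
  # undefined phases are excluded with renormalization
  op2 <- order_parameter(c(0, 0, pi, NA, NA))
  expect_equal(op2$R, 1 / 3, tolerance = 1e-12)
  expect_equal(op2$n_defined, 3L)
  op3 <- order_parameter(c(NA_real_, NA_real_))
  expect_true(is.na(op3$R))
})

test_that("trailing average of the order parameter uses a 5 s window", {
  tt <- seq(1, 10000)
  r_tbl <- tibble::tibble(time_ms = tt, R = 0.7)
  expect_equal(r_av(r_tbl, 10000), 0.7)
  r_tbl$R <- rep(c(0, 1), length.out = length(tt))
  expect_equal(r_av(r_tbl, 10000), 0.5, tolerance = 1e-3)
  ramp <- tibble::tibble(time_ms = tt,
                         R = pmin(1, pmax(0, (tt - 5000) / 5000)))
  expect_equal(r_av(ramp, 10000), 0.5, tolerance = 1e-3)
  expect_error(r_av(r_tbl, 4000), "insufficient")
})

test_that("acute effects report relative desynchronization", {
  eff <- acute_effects(0.9, 0.9, 0.99)
  expect_equal(eff$stim_effect, 0)
  expect_equal(eff$after_effect, -0.1, tolerance = 1e-12)
  expect_equal(acute_effects(0.5, 0, 0.25)$stim_effect, 1)
  expect_error(acute_effects(0, 0.5, 0.5), "positive")
})

test_that("subpopulations hold N/Ns - 1 members and exclude boundaries", {
  map <- subpopulation_map(network_params())
  counts <- dplyr::count(map, site)
  expect_equal(counts$n, rep(49L, 4))
  expect_equal(sort(map$neuron[map$site == 2]), 51:99)
  expect_false(any(c(50, 100, 150, 200) %in% map$neuron))
  # reduced ring: 9 members per site, boundaries 10 and 20 excluded
  map2 <- subpopulation_map(network_params(N = 20, Ns = 2))
  expect_equal(dplyr::count(map2, site)$n, rep(9L, 2))
  expect_false(any(c(10, 20) %in% map2$neuron))
})

test_that("resetting index matches its defining resultant length", {
  d <- tibble::tibble(delta_t = rep(0, 4), onset_n = 1:4,
                      phi = rep(0.7, 4))
  expect_equal(resetting_index(d)$E, 1, tolerance = 1e-12)
  d$phi <- c(0, pi / 2, pi, 3 * pi / 2)
  expect_equal(resetting_index(d)$E, 0, tolerance = 1e-12)
  # uniform random phases: E concentrates near sqrt(pi)/(2 sqrt(L))
  withr::local_seed(1)
  L <- 400
  reps <- vapply(1:200, function(q) {
    d <- tibble::tibble(delta_t = 0, onset_n = 1:L,
                        phi = runif(L, 0, 2 * pi))
    resetting_index(d)$E
  }, numeric(1))
  expect_equal(mean(reps), sqrt(pi) / (2 * sqrt(L)), tolerance = 0.1)
})

test_that("cross-trial distribution locks phases to onsets", {
  # two-neuron 'subpopulation' firing strictly periodically at 14 ms
  spikes <- seq(0, 2000, by = 14)
  raster <- tibble::tibble(
    neuron = rep(1:2, each = length(spikes)),
    time_ms = c(spikes, spikes + 0.5))
  p <- stim_params(Ns = 2, stim_on_duration = 1.6) # 100 cycles
  sched <- build_schedule("fixed_cr", p, seed = 4)
  ct <- cross_trial(raster, sched, neurons = 1:2, site = 1, window = 16)
  expect_true(all(ct$phi >= 0 & ct$phi < 2 * pi, na.rm = TRUE))
  # periodic spiking + periodic onsets: perfect stimulus locking
  ri <- resetting_index(ct)
  # rank filter keeps exactly a third of the onsets
  ct1 <- cross_trial(raster, sched, neurons = 1:2, site = 1, window = 16,
                     rank_filter = 1)
  expect_equal(attr(ct1, "L") * 3, attr(ct, "L"), tolerance = 0.1)
  expect_true(all(ri$L <= attr(ct, "L")))
})

test_that("exact rank-sum comparison agrees with exhaustive enumeration", {
  A <- c(1, 2, 3); B <- c(4, 5, 6)
  res <- rank_sum_compare(A, B, side = "less")
  expect_equal(res$p_value, 0.05, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_ranksum_p(A, B, "less"),
               tolerance = 1e-12)
  # random fixtures against the enumeration oracle
  withr::local_seed(3)
  for (q in 1:5) {
    A <- round(runif(5), 6); B <- round(runif(6) + 0.2, 6)
    for (side in c("less", "greater")) {
      res <- rank_sum_compare(A, B, side = side)
      expect_equal(res$p_value, oracle_ranksum_p(A, B, side),
                   tolerance = 1e-9)
    }
  }
  # identical samples are never a significant shift
  expect_gte(rank_sum_compare(c(1, 2, 3), c(1, 2, 3), "less")$p_value, 0.5)
  # fully tied data degenerates to p = 1 with a warning
  expect_warning(res <- rank_sum_compare(rep(1, 4), rep(1, 4)), "tied")
  expect_equal(res$p_value, 1)
})

test_that("spike counts histogram conserves events", {
  raster <- tibble::tibble(neuron = c(1, 2, 3, 1, 2),
                           time_ms = c(10.2, 10.7, 10.9, 55.1, 99.5))
  sc <- spike_counts(raster, c(0, 100))
  expect_equal(sum(sc$count), 5)
  expect_equal(sc$count[sc$bin_start == 10], 3)
  empty <- spike_counts(raster[0, ], c(0, 100))
  expect_true(all(empty$count == 0))
})
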