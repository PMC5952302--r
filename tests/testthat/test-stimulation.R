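test_that("full-length schedules have the published combinatorics", {
  p <- stim_params() # 128 s of 16 ms cycles, 3 ON : 2 OFF
  expect_equal(p$n_cycles, 8000L)
  for (proto in c("ppms", "cmns", "umns", "rvs_cr", "fixed_cr", "svs_cr")) {
    sched <- build_schedule(proto, p, seed = 11)
    counts <- dplyr::count(sched, site)
    expect_equal(nrow(sched), 4800 * p$Ns)
    expect_true(all(counts$n == 4800))
    ranks <- dplyr::count(sched, site, rank)
    expect_true(all(ranks$n == 1600))
    # every onset inside its own ON-cycle [start, start + Ts)
    cyc_on <- sched$cycle # index among ON-cycles
    block <- p$on_per_block + p$off_per_block
    abs_cycle <- (cyc_on - 1) %/% p$on_per_block * block +
      (cyc_on - 1) %% p$on_per_block
    start <- abs_cycle * p$Ts
    expect_true(all(sched$onset_ms >= start & sched$onset_ms < start + p$Ts))
  }
  expect_equal(nrow(build_schedule("no_stim", p, 1)), 0)
  expect_error(build_schedule("bogus", p, 1))
})

test_that("protocol-specific onset structure is as designed", {
  p <- stim_params()
  wide <- function(s) tidyr::pivot_wider(s[, c("site", "cycle", "onset_ms")],
                                         names_from = "site",
                                         values_from = "onset_ms")
  # PPMS: same within-cycle offset everywhere, all sites simultaneous
  s <- build_schedule("ppms", p, seed = 3)
  w <- wide(s)
  expect_true(all(abs(w$`1` - w$`2`) < 1e-12))
  offs <- s$onset_ms %% p$Ts
  expect_lt(diff(range(offs)), 1e-9)
  # CMNS: sites simultaneous, offsets vary across cycles
  s <- build_schedule("cmns", p, seed = 3)
  w <- wide(s)
  expect_true(all(abs(w$`1` - w$`4`) < 1e-12))
  expect_gt(diff(range(s$onset_ms %% p$Ts)), 1)
  # UMNS: per-cycle offsets essentially uncorrelated between sites
  s <- build_schedule("umns", p, seed = 3)
  w <- wide(s)
  o <- sapply(as.character(1:4), function(k) w[[k]] %% p$Ts)
  for (a in 1:3) for (b in (a + 1):4)
    expect_lt(abs(cor(o[, a], o[, b])), 0.05)
  # RVS CR: each cycle uses exactly the offsets {0, 4, 8, 12}
  s <- build_schedule("rvs_cr", p, seed = 3)
  offs <- split(round(s$onset_ms %% p$Ts, 9), s$cycle)
  expect_true(all(vapply(offs, function(x) setequal(x, c(0, 4, 8, 12)),
                         logical(1))))
  # and the sequence actually varies (positive sequence entropy)
  seqs <- vapply(split(s[order(s$onset_ms), ]$site, s[order(s$onset_ms), ]$cycle),
                 paste, collapse = "", character(1))
  expect_gt(length(unique(seqs)), 1)
  # fixed CR: one sequence throughout
  s <- build_schedule("fixed_cr", p, seed = 3)
  seqs <- vapply(split(s[order(s$onset_ms), ]$site, s[order(s$onset_ms), ]$cycle),
                 paste, collapse = "", character(1))
  expect_equal(length(unique(seqs)), 1L)
  # SVS CR: sequence changes exactly at 100-cycle boundaries
  s <- build_schedule("svs_cr", p, seed = 3)
  seqs <- vapply(split(s[order(s$onset_ms), ]$site, s[order(s$onset_ms), ]$cycle),
                 paste, collapse = "", character(1))
  runs <- rle(seqs)
  expect_true(all(runs$lengths %% 100 == 0 | cumsum(runs$lengths) == 4800))
  expect_gt(length(runs$values), 1)
})

test_that("fixed CR onsets are periodic over the 5-cycle block structure", {
  p <- stim_params()
  s <- build_schedule("fixed_cr", p, seed = 5)
  one <- sort(s$onset_ms[s$site == 1])
  # onsets of rank-1 cycles repeat with an 80 ms block period
  r1 <- sort(s$onset_ms[s$site == 1 & s$rank == 1])
  expect_equal(diff(r1), rep(80, length(r1) - 1), tolerance = 1e-9)
  expect_true(all(diff(one) %in% c(16, 48)))
})

test_that("schedules are reproducible and half-open in the cycle", {
  p <- stim_params()
  s1 <- build_schedule("umns", p, seed = 9)
  s2 <- build_schedule("umns", p, seed = 9)
  expect_identical(s1$onset_ms, s2$onset_ms)
  s3 <- build_schedule("umns", p, seed = 10)
  expect_false(identical(s1$onset_ms, s3$onset_ms))
})

test_that("alpha-function conductance has the published calibration", {
  p <- stim_params()
  expect_equal(p$tau_alpha, 16 / 24)
  # peak value exp(-1) at one time-to-peak after the onset
  expect_equal(conductance(p$tau_alpha, 0, p), exp(-1), tolerance = 1e-12)
  # zero before the onset and marginal at the 8 ms overlap window
  expect_equal(conductance(-0.1, 0, p), 0)
  ratio <- conductance(8, 0, p) / conductance(p$tau_alpha, 0, p)
  expect_equal(100 * ratio, 0.02, tolerance = 0.01) # percent of peak
  # truncation: zero beyond Ts/2 after the onset
  expect_equal(conductance(8.0001, 0, p), 0)
  # two onsets within the overlap window sum
  g <- conductance(6.5, c(0, 6), p)
  expect_equal(g, conductance(6.5, 0, p) + conductance(0.5, 0, p),
               tolerance = 1e-12)
  # nonnegative everywhere
  tt <- seq(-5, 40, by = 0.01)
  expect_true(all(conductance(tt, c(0, 6, 20), p) >= 0))
  expect_error(conductance(1, c(5, 2), p), "sorted")
})

test_that("spatial profile decays quadratically and symmetrically", {
  net <- network_params()
  p <- stim_params(sigma_d = 1)
  expect_equal(spatial_profile(25, 25, p, net), 1)
  # half attenuation where lattice distance equals sigma_d
  d <- net$d0 / (net$N - 1)
  i_half <- 25 + round(1 / d)
  expect_equal(spatial_profile(i_half, 25, p, net), 0.5, tolerance = 0.01)
  expect_equal(spatial_profile(20, 25, p, net),
               spatial_profile(30, 25, p, net))
})

test_that("stimulation current vanishes in the degenerate cases", {
  net <- network_params(N = 20, Ns = 2)
  p <- stim_params(Ns = 2, K = 0.25)
  st <- toy_state(N = 20)
  sched <- build_schedule("rvs_cr", p, seed = 1)
  # control schedule
  expect_equal(stim_current(3, 10, st,
                            build_schedule("no_stim", p, 1), p, net), 0)
  # zero intensity
  p0 <- stim_params(Ns = 2, K = 0)
  expect_equal(stim_current(3, 10, st, sched, p0, net), 0)
  # vanishing driving force at the reversal potential
  st$V[] <- net$V_r_exc
  expect_equal(stim_current(3, 10, st, sched, p, net), 0)
})

test_that("schedule TSV round-trips exactly", {
  p <- stim_params(stim_on_duration = 0.4) # 25 cycles
  s <- build_schedule("rvs_cr", p, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(s, f)
  s2 <- read_schedule(f)
  expect_equal(s2$onset_ms, s$onset_ms, tolerance = 1e-12)
  expect_equal(s2$site, s$site)
  expect_equal(s2$rank, s$rank)
})
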