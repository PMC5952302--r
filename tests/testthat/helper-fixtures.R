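# Small deterministic fixtures used across test files.

toy_params <- function(N = 10, Ns = 2, ...) {
  network_params(N = N, Ns = Ns, ...)
}

# A random valid network state for oracle tests (not a dynamical fixture).
toy_state <- function(N = 10, seed = 42, with_history = FALSE) {
  withr::local_seed(seed)
  st <- list(
    V = runif(N, -80, 40),
    m = runif(N), h = runif(N), n = runif(N), s = runif(N),
    I = runif(N, 10.55, 11.45),
    c = {
      cm <- matrix(runif(N * N), N, N)
      diag(cm) <- 0
      cm
    },
    last_spike = if (with_history) sort(runif(N, 0, 50)) else
      rep(NA_real_, N),
    t = 0)
  structure(st, class = "network_state")
}

# Brute-force coupling current straight from its defining sum.
oracle_coupling <- function(i, state, M, params) {
  acc <- 0
  for (j in seq_len(params$N)) {
    Vr <- if (M[i, j] > 0) params$V_r_exc else params$V_r_inh
    acc <- acc + (Vr - state$V[i]) * state$c[i, j] * abs(M[i, j]) * state$s[j]
  }
  acc / params$N
}

# Brute-force connectivity summaries (double loop, diagonal excluded).
oracle_mean_weights <- function(c, M) {
  N <- nrow(c)
  s_all <- 0; s_ee <- 0; s_ii <- 0; n_ee <- 0; n_ii <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    sg <- sign(M[i, j])
    s_all <- s_all + sg * c[i, j]
    if (sg > 0) { s_ee <- s_ee + c[i, j]; n_ee <- n_ee + 1 }
    if (sg < 0) { s_ii <- s_ii + c[i, j]; n_ii <- n_ii + 1 }
  }
  list(c_av = s_all / N^2, c_ee = s_ee / n_ee^2, c_ii = s_ii / n_ii^2,
       n_ee = n_ee, n_ii = n_ii)
}

# Exhaustive one-sided rank-sum p-value by enumerating group assignments.
oracle_ranksum_p <- function(A, B, side = "less") {
  pooled <- c(A, B)
  nA <- length(A)
  idx <- utils::combn(length(pooled), nA)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(A, B)
  us <- apply(idx, 2, function(sel) u_of(pooled[sel], pooled[-sel]))
  if (side == "less") mean(us <= u_obs) else mean(us >= u_obs)
}
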