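# Independent oracles used to check the package's estimators. These are
# deliberately simple re-derivations (closed forms, exhaustive enumeration,
# exhaustive grid search) that share no code with the implementation.

# Closed-form Kelvin-Voigt interface length.
kv_length <- function(t, L0, D, tau) {
  ifelse(t <= 0, L0, L0 + D * (1 - exp(-t / tau)))
}

# Exhaustive grid search for the least-squares (D, tau) on a post-ablation
# increment series: evaluates the rss on an n x n lattice and returns the
# smallest value found.
grid_oracle <- function(tt, dL, D_max, tau_lo, tau_hi, n = 200L) {
  Ds <- seq(0, D_max, length.out = n)
  taus <- seq(tau_lo, tau_hi, length.out = n)
  best <- Inf
  for (tau in taus) {
    f <- 1 - exp(-tt / tau)
    resid <- matrix(dL, nrow = n, ncol = length(tt), byrow = TRUE) -
      outer(Ds, f)
    r <- rowSums(resid^2)
    if (min(r) < best) best <- min(r)
  }
  best
}

# Brute-force two-sided Mann-Whitney p by full enumeration of all
# choose(n1 + n2, n1) group labelings.
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- combn(length(pool), n1, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# A noiseless Kelvin-Voigt interface-length series built without the
# package's simulator.
kv_series <- function(L0, D, tau, dt = 4, n_pre = 1, n_post = 9) {
  t <- (seq_len(n_pre + n_post) - n_pre) * dt
  data.frame(t = t, L = kv_length(t, L0, D, tau))
}
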