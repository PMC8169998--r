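# Shared fixtures: small noiseless parameter sets and brute-force oracles.

quiet_params <- function(seed = 1, ...) {
  gait_params(marker_noise_sd = 0, mos_sd = 0, seed = seed, ...)
}

# short perturbation schedule within the protocol's 30-90 s gap band but at
# its lower end, to keep test sessions compact
short_schedule <- function(seed = 1) {
  set.seed(seed)
  perturbation_schedule(gap_range = c(30, 36), warmup = 30)
}

# brute-force Mann-Whitney two-sided p by enumerating all group labelings
enum_mw_p <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  labelings <- utils::combn(length(r), n)
  u_all <- apply(labelings, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# brute-force Wilcoxon signed-rank two-sided p over all sign patterns
enum_wsr_p <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  v_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# independent recovery-step oracle: the count equals the index of the last
# out-of-band post step (0 when all eight are in band)
scan_recovery <- function(post, base, tol = 0.05) {
  out <- which(abs(post - base) > tol)
  if (length(out) == 0) 0L else max(out)
}
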