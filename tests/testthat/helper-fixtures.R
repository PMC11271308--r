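# shared in-code fixtures for the test suite

# random monotone pupariation curve on a random observation grid
random_curve <- function(n_seeded = 20) {
  k <- sample(4:12, 1)
  times <- cumsum(runif(k, 2, 10))
  cum <- sort(sample(0:n_seeded, k, replace = TRUE))
  pup_curve(times, cum, n_seeded)
}

# dense-resampling oracle for the P50 statistic: resample the piecewise
# linear curve at 0.01 h and take the first time at or above 0.5
p50_oracle <- function(curve, step = 0.01) {
  if (max(curve$cum_fraction) < 0.5) return(NA_real_)
  tt <- unique(c(seq(min(curve$obs_times), max(curve$obs_times), by = step),
                 max(curve$obs_times)))
  ff <- approx(curve$obs_times, curve$cum_fraction, xout = tt)$y
  tt[which(ff >= 0.5)[1]]
}

# exhaustive hypergeometric enumeration oracle for the two-sided
# Fisher's exact p of table rbind(c(a, b), c(cc, d))
fisher_oracle <- function(a, b, cc, d) {
  m <- a + cc; n_ <- b + d; k <- a + b
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# response table with prescribed direction calls (for counting ops)
make_responses <- function(n_up, n_down, n_none, genotype = "g",
                           prefix = "s") {
  n <- n_up + n_down + n_none
  out <- data.frame(
    site_id = sprintf("%s%05d", prefix, seq_len(n)),
    protein_id = sprintf("p%05d", seq_len(n)),
    fold_change = c(rep(1.5, n_up), rep(0.6, n_down), rep(1.0, n_none)),
    direction = c(rep("up", n_up), rep("down", n_down), rep("none", n_none)),
    p = rep(NA_real_, n))
  attr(out, "genotype") <- genotype
  out
}
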