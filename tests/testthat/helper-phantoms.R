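# Shared fixtures: small synthetic phantoms built in code.

# quick triangular indentation history (times s, depths nm)
triangle_history <- function(dmax = 500, tm = 0.01, n_per_phase = 100) {
  t <- seq(0, 2 * tm, length.out = 2 * n_per_phase + 1)
  delta <- ifelse(t <= tm, dmax * t / tm, dmax * (2 * tm - t) / tm)
  list(t = t, delta = pmax(delta, 0), i_tm = n_per_phase + 1)
}

# a modest single-curve spec used across tests (fast to simulate)
quick_spec <- function(...) {
  args <- modifyList(list(rate_hz = 100000, trigger_nN = 1), list(...))
  do.call(curve_spec, args)
}

# random smooth indentation history for oracle cross-checks: monotone
# power-shaped loading and unloading with random exponents, depth and
# turnaround, emulating piezo ramps seen through cantilever compliance
random_history <- function(seed, n = 160) {
  set.seed(seed)
  t <- seq(0, 0.02, length.out = n)
  i_tm <- round(runif(1, 0.35, 0.65) * n)
  dmax <- runif(1, 100, 600)
  q_up <- runif(1, 0.8, 1.5)
  q_dn <- runif(1, 0.8, 1.5)
  tm <- t[i_tm]
  delta <- numeric(n)
  delta[1:i_tm] <- dmax * (t[1:i_tm] / tm)^q_up
  delta[(i_tm + 1):n] <- dmax * ((t[n] - t[(i_tm + 1):n]) / (t[n] - tm))^q_dn
  delta[1] <- 0
  list(t = t, delta = pmax(delta, 0), i_tm = i_tm,
       alpha = runif(1, 0.05, 0.35), E1 = runif(1, 500, 8000))
}
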