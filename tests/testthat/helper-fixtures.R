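# Shared fixture helpers. All randomness is seeded through trimodal_config().

ref_config <- function(n = 2000, seed = 1, shape = 2, rate = 0.01,
                       correlation = diag(3)) {
  trimodal_config(shape = shape,
                  rates = c(A = rate, V = rate, S = rate),
                  n = n, seed = seed, correlation = correlation)
}

condition_rt <- function(data, cond) data$rt_ms[data$condition == cond]

# Exact CDFs of minima of independent Erlang channels, for analytic checks.
race_min_cdf <- function(t, shape, rates) {
  1 - Reduce(`*`, lapply(rates, function(r) pgamma(t, shape, rate = r,
                                                   lower.tail = FALSE)))
}

# Tiny discrete trivariate joint for brute-force bound verification: support
# points and a full probability table over them.
toy_joint <- function() {
  support <- c(10, 20, 30, 40)
  grid <- expand.grid(A = support, V = support, S = support)
  set.seed(404)
  p <- runif(nrow(grid))
  grid$p <- p / sum(p)
  grid
}

# Exact condition CDFs of a toy joint on a time grid (P(min <= t) from the
# enumerated joint probabilities). cols: subset of c("A","V","S").
toy_cdf <- function(joint, cols, times) {
  m <- do.call(pmin, joint[cols])
  vapply(times, function(t) sum(joint$p[m <= t]), numeric(1))
}
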