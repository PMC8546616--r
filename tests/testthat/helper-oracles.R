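# Independent numerical oracle for the exponential-phase frequency dynamics:
# integrates dp/dt = -r p [mu + s (1 - p - mu)] with a high-accuracy solver.
ode_frequency <- function(p0, r, s, mu, times) {
  f <- function(t, y, parms) list(-r * y * (mu + s * (1 - y - mu)))
  sol <- deSolve::ode(y = p0, times = c(0, times), func = f, parms = NULL,
                      rtol = 1e-12, atol = 1e-14)
  unname(sol[-1, 2])
}

# deterministic logistic growth closed form (single type, no mutation)
logistic_growth <- function(N0, r, K, t) {
  K * N0 * exp(r * t) / (K + N0 * (exp(r * t) - 1))
}

# quick counts-table constructor
counts_table <- function(time_h, x, n = 100L, replicate = "r1") {
  tibble::tibble(replicate = replicate, time_h = time_h,
                 n_sampled = as.integer(n), x_engineered = as.integer(x))
}

# deterministic pseudo-exact dataset: x = round(n * p(t)) on Eq-(4) dynamics
pseudo_exact_counts <- function(params, times, n = 1e6, p0 = 1) {
  p <- frequency_trajectory(p0, params, times)
  counts_table(times, round(n * p), n = n)
}
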