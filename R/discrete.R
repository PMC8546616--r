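#' One serial-transfer cycle of the discrete mutation-selection recursion
#'
#' Per-cycle analogue of the continuous frequency dynamics, for protocols
#' where within-culture growth is unknown but consistent across cultures.
#' With per-cycle loss probability `U` and per-cycle selection coefficient
#' `S`, engineered individuals contribute relative weight `(1 - S)` of which
#' a fraction `U` of offspring lose the transgene, giving
#' \deqn{p' = \frac{p (1-S)(1-U)}{p (1-S) + (1-p)}.}
#' This is the standard discrete mutation-selection recursion with loss
#' applied to engineered offspring; it is a reconstruction of the per-
#' transfer estimator and for small parameters one cycle matches the
#' continuous closed form with `U = 1 - exp(-r T mu)` and `S = r T s`.
#'
#' @param p Transgene frequency at the start of the cycle, in `[0, 1]`.
#'   Vectorised.
#' @param U Per-cycle loss probability, in `[0, 1)`.
#' @param S Per-cycle selection coefficient, in `[0, 1)`.
#'
#' @return The frequency after one cycle, in `[0, 1]`, `<= p`.
#' @examples
#' discrete_frequency_step(1, U = 0.01, S = 0)   # pure culture: 1 - U
#' @export
discrete_frequency_step <- function(p, U, S) {
  stopifnot(all(p >= 0 & p <= 1), U >= 0, U < 1, S >= 0, S < 1)
  w <- p * (1 - S) + (1 - p)
  out <- ifelse(w > 0, p * (1 - S) * (1 - U) / w, 0)
  pmin(pmax(out, 0), 1)
}

# frequency after 0..n_cycles cycles, starting from p0
discrete_trajectory <- function(p0, U, S, n_cycles) {
  p <- numeric(n_cycles + 1)
  p[1] <- p0
  for (j in seq_len(n_cycles)) p[j + 1] <- discrete_frequency_step(p[j], U, S)
  p
}

# half-life in cycles, by iteration with log-linear interpolation
discrete_half_life <- function(U, S, p0 = 1, max_cycles = 1e6) {
  if (U == 0 && S == 0) stop("transgene is never lost when both U and S are zero")
  if (p0 <= 0.5) return(0)
  p <- p0
  for (j in seq_len(max_cycles)) {
    p_next <- discrete_frequency_step(p, U, S)
    if (p_next <= 0.5) {
      if (p_next == p) return(Inf)
      return(j - 1 + (p - 0.5) / (p - p_next))
    }
    p <- p_next
  }
  Inf
}

#' Per-transfer (discrete-time) maximum-likelihood estimation
#'
#' Fits the discrete recursion of [discrete_frequency_step()] to serial-
#' transfer counts: the frequency at cycle `j` is obtained by iterating the
#' recursion from `p0`, and counts are binomial as in
#' [neg_log_likelihood()]. No growth rate is needed — only that transfers
#' are equally spaced, so sampling times map onto integer cycle indices.
#' Estimates `(U, S)` are per transfer cycle and live on a different scale
#' from the per-hour continuous estimates; the two should not be compared
#' numerically, though the relative importance of mutation versus selection
#' is expected to agree.
#'
#' @param data A counts tibble; sampling times must be equally spaced within
#'   and across replicates (irregular rows are reported by replicate and
#'   time).
#' @param p0 Initial-frequency policy, as in [fit_mle()].
#' @param compute_ci If `TRUE`, add profile-likelihood intervals.
#'
#' @return A `transloss_fit` with `engine = "discrete"`; `mu_hat`/`s_hat`
#'   hold `U`/`S`, and `t50_hat` is in transfer cycles.
#' @examples
#' counts <- simulate_experiment(model_params(0.1, 0.05, 0.01),
#'                               transfer_design(duration = 480, seed = 7))
#' fit_mle_discrete(counts)
#' @export
fit_mle_discrete <- function(data, p0 = c("pooled", "pure", "estimate"),
                             compute_ci = FALSE) {
  data <- validate_counts(data)
  t0 <- min(data$time_h)
  steps <- sort(unique(data$time_h)) - t0
  if (length(steps) < 3) {
    stop("need at least two sampling times after the first sample")
  }
  cycle_T <- steps[2]
  cycles <- (data$time_h - t0) / cycle_T
  bad <- abs(cycles - round(cycles)) > 1e-8
  if (any(bad)) {
    off <- data[bad, ]
    stop("transfer times are not equally spaced; offending rows: ",
         paste(sprintf("(%s, t=%g)", off$replicate, off$time_h),
               collapse = ", "))
  }
  cycles <- as.integer(round(cycles))
  max_cycle <- max(cycles)

  p0_info <- resolve_p0(data, p0)
  p_fun <- function(U, S, p0v) {
    discrete_trajectory(p0v, U, S, max_cycle)[cycles + 1]
  }
  raw <- fit_binomial_mle(data, p_fun, p0_info)
  flags <- boundary_flags(raw$rate, raw$coef, raw$rate_bounds, raw$coef_hi,
                          data)
  structure(
    list(
      engine = "discrete",
      mu_hat = raw$rate, s_hat = raw$coef,
      nll = raw$nll, converged = raw$converged,
      ci_mu = c(NA_real_, NA_real_), ci_s = c(NA_real_, NA_real_),
      ci_flags = character(),
      r_assumed = NA_real_, p0_used = raw$p0, p0_policy = p0_info$policy,
      t50_hat = discrete_half_life(raw$rate, raw$coef),
      boundary_flags = flags,
      rate_bounds = raw$rate_bounds, coef_hi = raw$coef_hi,
      objective = raw$objective,
      n_obs = nrow(data),
      cycle_interval = cycle_T,
      data = data
    ),
    class = "transloss_fit"
  ) -> fit
  if (compute_ci) fit <- profile_confidence_intervals(fit)
  fit
}
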