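#' Negative log-likelihood of serial-transfer counts
#'
#' Under the exponential-phase model, the transgene frequency at sampling
#' time `t` is `p(t)` from [frequency_trajectory()], and each genotyping
#' count `x` out of `n` is binomial. Replicates are independent lineages
#' sharing `(mu, s, r, p0)`, so they contribute additively:
#' \deqn{-\log L = -\sum_j \log {n_j \choose x_j}
#'   p(t_j)^{x_j} (1 - p(t_j))^{n_j - x_j}.}
#' Binomial terms are evaluated in log space (log-gamma coefficients), so
#' large `n` does not overflow. The value is `Inf` when an observation is
#' impossible under the parameters (e.g. `x < n` at a time where `p(t) = 1`
#' exactly).
#'
#' @param mu Per-replication loss rate, in `[0, 1)`.
#' @param s Selection coefficient, in `[0, 1)`.
#' @param r Assumed per-hour growth rate (not estimated from these data).
#' @param p0 Initial transgene frequency (treated as known here; see
#'   [fit_mle()] for the policies that choose it).
#' @param data A counts tibble with columns `replicate`, `time_h`,
#'   `n_sampled`, `x_engineered` (as produced by [simulate_experiment()] or
#'   [read_counts()]).
#'
#' @return The negative log-likelihood (non-negative, possibly `Inf`).
#' @examples
#' counts <- simulate_experiment(model_params(0.1, 0.05, 0.01),
#'                               transfer_design(duration = 240, seed = 1))
#' neg_log_likelihood(0.01, 0.05, r = 0.1, p0 = 1, data = counts)
#' @export
neg_log_likelihood <- function(mu, s, r, p0, data) {
  data <- validate_counts(data)
  p <- frequency_trajectory(p0, model_params(r = r, s = s, mu = mu, K = 1),
                            data$time_h)
  -sum(stats::dbinom(data$x_engineered, data$n_sampled, p, log = TRUE))
}

# ---- shared fitting machinery (continuous and discrete engines) ----------

# resolve the p0 policy against the data; returns list(value, estimated)
resolve_p0 <- function(data, p0) {
  if (is.numeric(p0)) {
    stopifnot(p0 > 0, p0 <= 1)
    return(list(value = p0, estimated = FALSE, policy = "fixed"))
  }
  p0 <- match.arg(p0, c("pooled", "pure", "estimate"))
  if (p0 == "pure") return(list(value = 1, estimated = FALSE, policy = "pure"))
  if (p0 == "estimate") {
    return(list(value = NA_real_, estimated = TRUE, policy = "estimate"))
  }
  t0 <- min(data$time_h)
  first <- data[data$time_h == t0, ]
  list(value = sum(first$x_engineered) / sum(first$n_sampled),
       estimated = FALSE, policy = "pooled")
}

# negative log-likelihood with probabilities clamped into the open interval,
# so the optimiser always sees a finite surface
clamped_nll <- function(p, x, n) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-12)
  v <- -sum(stats::dbinom(x, n, p, log = TRUE))
  if (!is.finite(v)) 1e12 else v
}

# Minimise a binomial NLL over (rate, coefficient[, p0]) on
# [rate_lo, rate_hi] x [0, coef_hi], rate optimised on log10 scale.
# p_fun(rate, coef, p0) returns the per-row success probability.
fit_binomial_mle <- function(data, p_fun, p0_info,
                             rate_bounds = c(1e-9, 0.5), coef_hi = 0.95) {
  x <- data$x_engineered
  n <- data$n_sampled
  obj <- function(theta) {
    p0v <- if (p0_info$estimated) theta[3] else p0_info$value
    clamped_nll(p_fun(10^theta[1], theta[2], p0v), x, n)
  }
  lb <- c(log10(rate_bounds[1]), 0)
  ub <- c(log10(rate_bounds[2]), coef_hi)
  starts <- tidyr::expand_grid(
    lrate = seq(-7, -1, length.out = 5),
    coef = seq(0.005, 0.5, length.out = 5)
  )
  if (p0_info$estimated) {
    t0 <- min(data$time_h)
    first <- data[data$time_h == t0, ]
    p0_start <- max(sum(first$x_engineered) / sum(first$n_sampled), 1e-6)
    lb <- c(lb, 1e-6); ub <- c(ub, 1)
    starts$p0 <- p0_start
  }
  best <- NULL
  best_clean <- Inf   # best value among starts that reported convergence
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) best_clean <- min(best_clean, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimiser starts failed")
  # a line-search hiccup on the winning start is benign if a cleanly
  # converged start reached the same minimum
  converged <- best$convergence == 0 || best_clean <= best$value + 1e-6
  # report the honest (unclamped) NLL at the optimum
  p0v <- if (p0_info$estimated) best$par[3] else p0_info$value
  honest <- -sum(stats::dbinom(x, n, p_fun(10^best$par[1], best$par[2], p0v),
                               log = TRUE))
  if (is.finite(honest)) best$value <- honest
  list(
    rate = 10^best$par[1],
    coef = best$par[2],
    p0 = if (p0_info$estimated) best$par[3] else p0_info$value,
    nll = best$value,
    converged = converged,
    message = best$message,
    rate_bounds = rate_bounds,
    coef_hi = coef_hi,
    objective = obj
  )
}

boundary_flags <- function(rate, coef, rate_bounds, coef_hi, data) {
  flags <- character()
  if (rate <= rate_bounds[1] * (1 + 1e-6)) flags <- c(flags, "mu_at_lower_bound")
  if (rate >= rate_bounds[2] * (1 - 1e-9)) flags <- c(flags, "mu_at_upper_bound")
  if (coef <= 1e-10) flags <- c(flags, "s_at_lower_bound")
  if (coef >= coef_hi * (1 - 1e-9)) flags <- c(flags, "s_at_upper_bound")
  if (all(data$x_engineered == data$n_sampled)) {
    flags <- c(flags, "s_unidentifiable")
  }
  flags
}

#' Maximum-likelihood estimation of mutation and selection
#'
#' Jointly estimates the per-replication transgene loss rate `mu` and the
#' selection coefficient `s` from serial-transfer genotyping counts by
#' minimising [neg_log_likelihood()]. The growth rate `r` is assumed known
#' (it is not identifiable from frequency data alone); a misassigned `r`
#' biases both estimates, in the direction opposite to the error in `r`.
#'
#' Optimisation runs in transformed coordinates (`log10(mu)`, `s`) with
#' box constraints `mu` in `[1e-9, 0.5]`, `s` in `[0, 0.95]`, from a 5 x 5
#' multistart grid, so the result is deterministic given the data. Estimates
#' pinned at a bound are flagged; data carrying no loss signal (every sample
#' fully engineered) yield `mu` at its lower bound with an
#' `s_unidentifiable` flag.
#'
#' The initial frequency `p0` can be taken as the pooled time-0 sample
#' frequency (`"pooled"`, the default), fixed at 1 (`"pure"`), supplied as a
#' number, or estimated as a third free parameter (`"estimate"`).
#'
#' @param data A counts tibble (see [simulate_experiment()] /
#'   [read_counts()]), pooled over replicates; needs at least two sampling
#'   times after time 0.
#' @param r Assumed per-hour growth rate.
#' @param p0 Initial-frequency policy: `"pooled"`, `"pure"`, `"estimate"`,
#'   or a number in `(0, 1]`.
#' @param compute_ci If `TRUE`, run [profile_confidence_intervals()] on the
#'   result (slower).
#'
#' @return A `transloss_fit` object; see [tidy.transloss_fit()] and
#'   [glance.transloss_fit()] for tidy accessors. Key fields: `mu_hat`,
#'   `s_hat`, `nll`, `converged`, `ci_mu`, `ci_s`, `t50_hat`,
#'   `boundary_flags`.
#' @examples
#' counts <- simulate_experiment(model_params(0.1, 0.05, 0.01),
#'                               transfer_design(duration = 480, seed = 7))
#' fit <- fit_mle(counts, r = 0.1)
#' glance(fit)
#' @export
fit_mle <- function(data, r, p0 = c("pooled", "pure", "estimate"),
                    compute_ci = FALSE) {
  data <- validate_counts(data)
  stopifnot(r > 0)
  if (length(unique(data$time_h[data$time_h > min(data$time_h)])) < 2) {
    stop("need at least two distinct sampling times after the first sample")
  }
  p0_info <- resolve_p0(data, p0)
  p_fun <- function(mu, s, p0v) {
    frequency_trajectory(p0v, model_params(r = r, s = s, mu = mu, K = 1),
                         data$time_h)
  }
  raw <- fit_binomial_mle(data, p_fun, p0_info)
  flags <- boundary_flags(raw$rate, raw$coef, raw$rate_bounds, raw$coef_hi,
                          data)
  t50 <- half_life(model_params(r = r, s = raw$coef, mu = raw$rate, K = 1))
  fit <- structure(
    list(
      engine = "continuous",
      mu_hat = raw$rate, s_hat = raw$coef,
      nll = raw$nll, converged = raw$converged,
      ci_mu = c(NA_real_, NA_real_), ci_s = c(NA_real_, NA_real_),
      ci_flags = character(),
      r_assumed = r, p0_used = raw$p0, p0_policy = p0_info$policy,
      t50_hat = t50,
      boundary_flags = flags,
      rate_bounds = raw$rate_bounds, coef_hi = raw$coef_hi,
      objective = raw$objective,
      n_obs = nrow(data),
      data = data
    ),
    class = "transloss_fit"
  )
  if (compute_ci) fit <- profile_confidence_intervals(fit)
  fit
}

#' @export
print.transloss_fit <- function(x, ...) {
  lab <- if (x$engine == "continuous") c("mu (per replication)", "s (per hour scale)")
         else c("U (per transfer)", "S (per transfer)")
  cat("<transloss_fit>", x$engine, "engine,", x$n_obs, "observations\n")
  fmt_ci <- function(ci) {
    if (all(is.na(ci))) "" else sprintf(" (95%% CI %.4g-%.4g)", ci[1], ci[2])
  }
  cat(sprintf("  %s: %.4g%s\n", lab[1], x$mu_hat, fmt_ci(x$ci_mu)))
  cat(sprintf("  %s: %.4g%s\n", lab[2], x$s_hat, fmt_ci(x$ci_s)))
  cat(sprintf("  NLL %.4f | t50 %.4g %s | p0 %.4g (%s)\n", x$nll, x$t50_hat,
              if (x$engine == "continuous") "h" else "cycles",
              x$p0_used, x$p0_policy))
  if (length(x$boundary_flags)) {
    cat("  flags:", paste(x$boundary_flags, collapse = ", "), "\n")
  }
  if (!x$converged) cat("  warning: optimiser did not report convergence\n")
  invisible(x)
}

#' Profile-likelihood confidence intervals for a fit
#'
#' For each parameter in turn, the other is re-optimised at every fixed
#' value, and the approximate 95% interval is the set of values whose
#' profile negative log-likelihood lies within `qchisq(0.95, 1) / 2 = 1.92`
#' of the minimum. Endpoints are located by root finding; endpoints that
#' run into the parameter bounds are clipped there and flagged
#' (`ci_*_at_bound`), which also covers likelihood directions that are
#' effectively flat.
#'
#' @param fit A converged `transloss_fit` from [fit_mle()] or
#'   [fit_mle_discrete()].
#' @param level Confidence level (default 0.95).
#'
#' @return The fit, with `ci_mu`, `ci_s` and `ci_flags` filled in.
#' @export
profile_confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "transloss_fit"))
  obj <- fit$objective
  cut <- fit$nll + stats::qchisq(level, df = 1) / 2
  l_lo <- log10(fit$rate_bounds[1]); l_hi <- log10(fit$rate_bounds[2])
  l_hat <- log10(fit$mu_hat)
  flags <- character()

  prof_mu <- function(l) {
    stats::optimize(function(s) obj(c(l, s)), c(0, fit$coef_hi),
                    tol = 1e-9)$objective
  }
  prof_s <- function(s) {
    stats::optimize(function(l) obj(c(l, s)), c(l_lo, l_hi),
                    tol = 1e-9)$objective
  }
  endpoint <- function(prof, at_hat, bound, side) {
    h <- function(v) prof(v) - cut
    hb <- h(bound)
    if (!is.finite(hb) || hb <= 0) {
      flags <<- c(flags, paste0("ci_", side, "_at_bound"))
      return(bound)
    }
    if (abs(at_hat - bound) < 1e-12) return(bound)
    stats::uniroot(h, sort(c(at_hat, bound)), tol = 1e-8)$root
  }

  ci_mu_lo <- endpoint(prof_mu, l_hat, l_lo, "mu_lower")
  ci_mu_hi <- endpoint(prof_mu, l_hat, l_hi, "mu_upper")
  ci_s_lo <- endpoint(prof_s, fit$s_hat, 0, "s_lower")
  ci_s_hi <- endpoint(prof_s, fit$s_hat, fit$coef_hi, "s_upper")

  fit$ci_mu <- c(10^ci_mu_lo, 10^ci_mu_hi)
  fit$ci_s <- c(ci_s_lo, ci_s_hi)
  fit$ci_flags <- flags
  fit$ci_level <- level
  fit
}

#' Negative log-likelihood over a parameter grid
#'
#' Exhaustively evaluates the likelihood surface over a grid that is
#' log-spaced in `mu` and linear in `s` — the tidy input for a contour plot
#' and a direct way to inspect ridges and parameter correlation.
#'
#' @param data A counts tibble.
#' @param r Assumed per-hour growth rate.
#' @param mu_range Length-2 range for `mu` (log-spaced grid).
#' @param s_range Length-2 range for `s` (linear grid).
#' @param n_mu,n_s Number of grid points per axis.
#' @param p0 Initial-frequency policy (see [fit_mle()]).
#'
#' @return A tibble with columns `mu`, `s`, `nll` (`n_mu * n_s` rows).
#' @export
likelihood_surface <- function(data, r, mu_range = c(1e-5, 0.1),
                               s_range = c(0, 0.3), n_mu = 50, n_s = 40,
                               p0 = "pooled") {
  data <- validate_counts(data)
  p0v <- resolve_p0(data, p0)
  if (p0v$estimated) stop("likelihood_surface needs a fixed p0 policy")
  grid <- tidyr::expand_grid(
    mu = exp(seq(log(mu_range[1]), log(mu_range[2]), length.out = n_mu)),
    s = seq(s_range[1], s_range[2], length.out = n_s)
  )
  grid$nll <- purrr::map2_dbl(grid$mu, grid$s, function(m, sv) {
    neg_log_likelihood(m, sv, r = r, p0 = p0v$value, data = data)
  })
  grid
}

#' Model-fit envelope: expected sampling spread at the fitted parameters
#'
#' At each sampling time, the central `level` interval of
#' `Binomial(n, p_hat(t)) / n`, where `p_hat(t)` is the fitted frequency
#' curve. Observed frequencies falling outside this band indicate model
#' violations (e.g. multiple mutation classes). Uses equal-tail binomial
#' quantiles, so the band collapses to a point where `p_hat` is 0 or 1.
#'
#' @param fit A `transloss_fit` from [fit_mle()].
#' @param times Sampling times (hours); defaults to the fit's data times.
#' @param n Genotyped sample size per time; defaults to the median sample
#'   size at each time in the fit's data.
#' @param level Envelope coverage (default 0.95).
#'
#' @return A tibble with columns `time_h`, `n`, `p_hat`, `lower`, `upper`.
#' @export
fit_envelope <- function(fit, times = NULL, n = NULL, level = 0.95) {
  stopifnot(inherits(fit, "transloss_fit"))
  if (fit$engine != "continuous") {
    stop("fit_envelope expects a continuous-time fit")
  }
  if (is.null(times)) {
    byt <- dplyr::summarise(dplyr::group_by(fit$data, .data$time_h),
                            n = round(stats::median(.data$n_sampled)),
                            .groups = "drop")
    times <- byt$time_h
    if (is.null(n)) n <- byt$n
  }
  if (is.null(n)) n <- 100
  n <- as.integer(rep_len(n, length(times)))
  p_hat <- frequency_trajectory(
    fit$p0_used,
    model_params(r = fit$r_assumed, s = fit$s_hat, mu = fit$mu_hat, K = 1),
    times
  )
  alpha <- (1 - level) / 2
  tibble::tibble(
    time_h = times, n = n, p_hat = p_hat,
    lower = stats::qbinom(alpha, n, p_hat) / n,
    upper = stats::qbinom(1 - alpha, n, p_hat) / n
  )
}

# ---- broom-style accessors ------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mutation-selection fit
#'
#' @param x A `transloss_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `conf.low`,
#'   `conf.high` (profile-likelihood bounds if computed).
#' @export
tidy.transloss_fit <- function(x, ...) {
  terms <- if (x$engine == "continuous") c("mu", "s") else c("U", "S")
  tibble::tibble(
    term = terms,
    estimate = c(x$mu_hat, x$s_hat),
    conf.low = c(x$ci_mu[1], x$ci_s[1]),
    conf.high = c(x$ci_mu[2], x$ci_s[2])
  )
}

#' One-row summary of a mutation-selection fit
#'
#' @param x A `transloss_fit`.
#' @param ... Unused.
#' @return A one-row tibble: estimates, `nll`, `converged`, `t50_hat`,
#'   `r_assumed`, `p0_used`, `n_obs`, and comma-joined boundary flags.
#' @export
glance.transloss_fit <- function(x, ...) {
  tibble::tibble(
    engine = x$engine,
    mu_hat = x$mu_hat, s_hat = x$s_hat,
    nll = x$nll, converged = x$converged,
    t50_hat = x$t50_hat,
    r_assumed = x$r_assumed, p0_used = x$p0_used,
    n_obs = x$n_obs,
    flags = paste(x$boundary_flags, collapse = ",")
  )
}
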