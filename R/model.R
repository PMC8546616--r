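#' Evolutionary and growth parameters of a serial-transfer culture
#'
#' Bundles the four parameters of the two-type logistic growth model:
#' the wild-type per-capita growth rate `r` (per hour), the selection
#' coefficient `s` against transgene carriers (their growth rate is
#' `r(1-s)`), the per-replication probability `mu` that an engineered
#' parent produces a transgene-free (revertant) offspring, and the carrying
#' capacity `K` of the culture. Back mutation is assumed absent.
#'
#' @param r Per-capita growth rate of the wild type, per hour. Positive.
#' @param s Selection coefficient against the transgene, in `[0, 1)`.
#' @param mu Per-replication probability of transgene loss, in `[0, 1)`.
#' @param K Carrying capacity (individuals). Positive.
#'
#' @return An object of class `model_params`: a named list with elements
#'   `r`, `s`, `mu`, `K`.
#' @examples
#' model_params(r = 0.1, s = 0.05, mu = 1e-3)
#' @export
model_params <- function(r, s, mu, K = 2e6) {
  stopifnot(
    is.numeric(r), length(r) == 1, is.finite(r), r > 0,
    is.numeric(s), length(s) == 1, is.finite(s), s >= 0, s < 1,
    is.numeric(mu), length(mu) == 1, is.finite(mu), mu >= 0, mu < 1,
    is.numeric(K), length(K) == 1, K > 0
  )
  structure(list(r = r, s = s, mu = mu, K = K), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> r =", x$r, "/h, s =", x$s, ", mu =", x$mu,
      ", K =", format(x$K, big.mark = ","), "\n")
  invisible(x)
}

#' Counts of engineered and revertant individuals at a time point
#'
#' @param N_E Number of engineered (transgene-carrying) individuals, >= 0.
#' @param N_R Number of revertant (transgene-free) individuals, >= 0.
#' @param t Time in hours, >= 0.
#'
#' @return An object of class `population_state`.
#' @examples
#' population_state(N_E = 1e4, N_R = 0)
#' @export
population_state <- function(N_E, N_R, t = 0) {
  stopifnot(
    is.numeric(N_E), length(N_E) == 1, N_E >= 0,
    is.numeric(N_R), length(N_R) == 1, N_R >= 0,
    is.numeric(t), length(t) == 1, t >= 0
  )
  structure(list(N_E = N_E, N_R = N_R, t = t), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> N_E =", x$N_E, ", N_R =", x$N_R,
      ", t =", x$t, "h (frequency",
      if (x$N_E + x$N_R > 0) signif(x$N_E / (x$N_E + x$N_R), 4) else NA,
      ")\n")
  invisible(x)
}

#' Right-hand side of the two-type logistic growth model
#'
#' Time derivatives of the engineered and revertant population sizes under
#' density-dependent (logistic) growth with one-way mutation:
#' \deqn{dN_E/dt = r(1-s)\,N_E\,(1 - N/K)\,(1-\mu)}
#' \deqn{dN_R/dt = r\,N_R\,(1 - N/K) + r(1-s)\,N_E\,(1 - N/K)\,\mu}
#' with \eqn{N = N_E + N_R}. Mutation redirects a fraction \eqn{\mu} of
#' engineered births into the revertant class; there is no back mutation, so
#' an all-revertant culture stays all-revertant. The logistic factor is not
#' clamped here: for `N > K` both derivatives are negative, so a
#' deterministic trajectory relaxes back towards `K`.
#'
#' @param state A [population_state()].
#' @param params A [model_params()].
#'
#' @return Named numeric vector `c(dN_E, dN_R)`, per hour.
#' @examples
#' full_ode_rhs(population_state(1000, 0), model_params(0.1, 0.1, 0.01))
#' @export
full_ode_rhs <- function(state, params) {
  f <- 1 - (state$N_E + state$N_R) / params$K
  gE <- params$r * (1 - params$s) * state$N_E * f
  c(
    dN_E = gE * (1 - params$mu),
    dN_R = params$r * state$N_R * f + gE * params$mu
  )
}

#' Numerically integrate the two-type logistic growth model
#'
#' Solves the full density-dependent system (see [full_ode_rhs()]) with
#' `deSolve::ode()` (lsoda). Used where the closed-form exponential-phase
#' frequency solution does not apply, i.e. when the culture approaches its
#' carrying capacity.
#'
#' @param initial A [population_state()] giving the starting counts; its `t`
#'   is the starting time.
#' @param params A [model_params()].
#' @param t_end End time in hours, greater than `initial$t`.
#' @param n_steps Number of output time points (the solver's internal step
#'   control is independent of this).
#' @param rtol,atol Relative and absolute solver tolerances.
#'
#' @return A tibble with columns `t`, `N_E`, `N_R`, and `frequency`
#'   (`N_E / (N_E + N_R)`).
#' @examples
#' tr <- integrate_full_model(population_state(1e4, 0),
#'                            model_params(0.1, 0.1, 0.01), t_end = 48)
#' tail(tr)
#' @export
integrate_full_model <- function(initial, params, t_end, n_steps = 200,
                                 rtol = 1e-8, atol = 1e-8) {
  stopifnot(t_end > initial$t)
  times <- seq(initial$t, t_end, length.out = n_steps + 1)
  deriv <- function(t, y, p) {
    st <- list(N_E = y[[1]], N_R = y[[2]])
    list(unname(full_ode_rhs(st, p)))
  }
  sol <- deSolve::ode(
    y = c(N_E = initial$N_E, N_R = initial$N_R),
    times = times, func = deriv, parms = params,
    rtol = rtol, atol = atol
  )
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[[1]] < 0) {
    stop("ODE integration failed (lsoda istate = ", diag[[1]], ")")
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "t"
  out$N_E <- pmax(out$N_E, 0)
  out$N_R <- pmax(out$N_R, 0)
  out$frequency <- ifelse(out$N_E + out$N_R > 0,
                          out$N_E / (out$N_E + out$N_R), NA_real_)
  out
}

#' Instantaneous rate of change of the transgene frequency
#'
#' During exponential growth (population far below `K`) the frequency
#' `p = N_E / (N_E + N_R)` of the engineered type obeys
#' \deqn{dp/dt = -r\,p\,[\mu + s(1 - p - \mu)].}
#' The rate is non-positive for all `p` in `[0, 1]` whenever `s, mu >= 0`:
#' the transgene can only be lost.
#'
#' @param p Transgene frequency, in `[0, 1]`. Vectorised.
#' @param params A [model_params()] (`K` is irrelevant here).
#'
#' @return `dp/dt`, per hour.
#' @export
frequency_ode_rhs <- function(p, params) {
  stopifnot(all(p >= 0 & p <= 1))
  -params$r * p * (params$mu + params$s * (1 - p - params$mu))
}

#' Closed-form transgene frequency trajectory
#'
#' The exponential-phase frequency dynamics admit the closed form
#' \deqn{p(t) = \frac{p_0\,a\,e^{-r a t}}
#'   {\mu + s\left[1 - \mu - p_0\,(1 - e^{-r a t})\right]},
#'   \quad a = s(1-\mu) + \mu,}
#' valid while the population is large enough for drift to be negligible yet
#' well below carrying capacity. `p(0) = p0`, and `p(t)` is non-increasing.
#'
#' Degenerate cases: with `s = mu = 0` the formula is 0/0 and the continuous
#' limit `p0` is returned. With `mu = 0` an algebraically equivalent form is
#' used that stays exact when the exponential underflows (a pure culture then
#' remains at frequency 1 forever). Underflow at very large `t` returns 0,
#' never a negative value.
#'
#' @param p0 Initial transgene frequency, in `[0, 1]`.
#' @param params A [model_params()] (`K` is irrelevant here).
#' @param t Time in hours, >= 0. Vectorised.
#'
#' @return Frequency in `[0, 1]`, same length as `t`.
#' @examples
#' frequency_trajectory(1, model_params(0.1, 0.05, 1e-3), t = c(0, 24, 240))
#' @export
frequency_trajectory <- function(p0, params, t) {
  stopifnot(p0 >= 0, p0 <= 1, all(t >= 0))
  s <- params$s
  mu <- params$mu
  if (s == 0 && mu == 0) {
    return(rep(p0, length(t)))
  }
  a <- s * (1 - mu) + mu
  e <- exp(-params$r * a * t)
  if (mu == 0) {
    # p = p0 e / (1 - p0 (1 - e)); exact at e -> 0 when p0 = 1
    p <- p0 * e / ((1 - p0) + p0 * e)
    p[(1 - p0) + p0 * e == 0] <- 1
  } else {
    p <- p0 * a * e / (mu + s * (1 - mu - p0 * (1 - e)))
  }
  pmin(pmax(p, 0), 1)
}

#' Evolutionary half-life of a transgene
#'
#' Time (hours) until half of the population has lost transgene function.
#' Starting from a pure engineered culture (`p0 = 1`) the half-life has the
#' closed form
#' \deqn{t_{50} = \frac{\ln\!\left(\frac{\mu(1-s)}{\mu(1-s)+s(1-\mu)+\mu}\right)}
#'   {-r\,[s(1-\mu)+\mu]}.}
#' With no fitness cost (`s = 0`) this reduces to `ln(2) / (r mu)`, roughly
#' `0.7 / (r mu)`. For a general starting frequency the half-life is found by
#' root-bracketing on [frequency_trajectory()]; a start already at or below
#' one half returns 0 so that grid evaluations never abort.
#'
#' @param params A [model_params()]; `s` and `mu` must not both be zero.
#' @param p0 Initial transgene frequency (default 1, a pure culture).
#'
#' @return Half-life in hours.
#' @examples
#' half_life(model_params(r = 0.1, s = 0, mu = 0.1))    # ln 2 / (r mu) = 69.3 h
#' half_life(model_params(r = 0.2878, s = 0.057, mu = 0.015))
#' @export
half_life <- function(params, p0 = 1) {
  s <- params$s
  mu <- params$mu
  if (s == 0 && mu == 0) {
    stop("transgene is never lost when both s and mu are zero")
  }
  if (p0 <= 0.5) {
    return(0)
  }
  a <- s * (1 - mu) + mu
  if (p0 == 1) {
    return(log(mu * (1 - s) / (mu * (1 - s) + a)) / (-params$r * a))
  }
  # impure start: bracket the root of p(t) = 1/2
  f <- function(t) frequency_trajectory(p0, params, t) - 0.5
  upper <- 1 / (params$r * a)
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-10 * upper)$root
}

#' Parameters and target for a re-engineering gain calculation
#'
#' Describes a proposed improvement to an engineered construct: the current
#' loss rate `mu*` and cost `s*` (in `base`) would be divided by the factors
#' `k_mu` and `k_s`.
#'
#' @param base A [model_params()] holding the current `r`, `s*`, `mu*`.
#' @param k_mu Mutation reduction factor, >= 1.
#' @param k_s Selection reduction factor, >= 1.
#'
#' @return An object of class `half_life_gain_request`.
#' @export
half_life_gain_request <- function(base, k_mu = 1, k_s = 1) {
  stopifnot(inherits(base, "model_params"), k_mu >= 1, k_s >= 1)
  if (base$s == 0 && base$mu == 0) {
    stop("base parameters must have s > 0 or mu > 0")
  }
  structure(list(base = base, k_mu = k_mu, k_s = k_s),
            class = "half_life_gain_request")
}

#' Half-life gain from reducing mutation and/or selection
#'
#' Ratio of the transgene half-life after dividing the loss rate by `k_mu`
#' and the selection coefficient by `k_s`, relative to the current half-life:
#' `t50(mu*/k_mu, s*/k_s, r) / t50(mu*, s*, r)`. The ratio is >= 1 and
#' non-decreasing in both factors. Contour maps of this ratio show whether
#' re-engineering effort is better spent on the mutation rate (vertical
#' isoclines) or on the fitness cost (horizontal isoclines).
#'
#' @param req A [half_life_gain_request()], or a [model_params()] if `k_mu`
#'   and `k_s` are given directly.
#' @param k_mu,k_s Reduction factors (used when `req` is a `model_params`).
#'
#' @return The half-life ratio (dimensionless, >= 1).
#' @examples
#' half_life_gain(model_params(r = 0.1, s = 0.1, mu = 1e-4), k_mu = 10)
#' @export
half_life_gain <- function(req, k_mu = 1, k_s = 1) {
  if (inherits(req, "model_params")) {
    req <- half_life_gain_request(req, k_mu = k_mu, k_s = k_s)
  }
  stopifnot(inherits(req, "half_life_gain_request"))
  b <- req$base
  improved <- model_params(r = b$r, s = b$s / req$k_s, mu = b$mu / req$k_mu,
                           K = b$K)
  half_life(improved) / half_life(b)
}

#' Half-life gain over a lattice of reduction factors
#'
#' Evaluates [half_life_gain()] on a log-spaced `(k_mu, k_s)` lattice, the
#' tidy input for a contour plot of attainable longevity gains.
#'
#' @param base A [model_params()] holding the current `r`, `s*`, `mu*`.
#' @param k_max Largest reduction factor on each axis (default 100).
#' @param n Grid points per axis (default 50).
#'
#' @return A tibble with columns `k_mu`, `k_s`, `ratio` (`n^2` rows).
#' @examples
#' g <- half_life_gain_grid(model_params(0.1, 0.1, 1e-4), k_max = 10, n = 5)
#' @export
half_life_gain_grid <- function(base, k_max = 100, n = 50) {
  stopifnot(inherits(base, "model_params"), k_max >= 1, n >= 2)
  ks <- exp(seq(0, log(k_max), length.out = n))
  grid <- tidyr::expand_grid(k_mu = ks, k_s = ks)
  t50_base <- half_life(base)
  grid$ratio <- purrr::map2_dbl(grid$k_mu, grid$k_s, function(km, kc) {
    half_life(model_params(r = base$r, s = base$s / kc, mu = base$mu / km,
                           K = base$K)) / t50_base
  })
  grid
}
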