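#' Serial-transfer experiment protocol
#'
#' Describes how a serial passage experiment is run: cultures grow for
#' `transfer_interval` hours, then `beta` individuals are drawn at random to
#' found the next culture and `n` of those founders are genotyped for the
#' transgene. This repeats for `duration` hours, in `replicates` independent
#' lineages.
#'
#' @param transfer_interval Hours between transfers (default 24).
#' @param beta Bottleneck: number of individuals transferred (default 10000).
#' @param n Number of individuals genotyped at each transfer, `n <= beta`
#'   (default 100).
#' @param replicates Number of replicate lineages (default 3).
#' @param duration Total experiment length in hours (default 3600, i.e. 150
#'   days).
#' @param initial_size Founding population size (default `beta`).
#' @param initial_revertants Number of transgene-free individuals in the
#'   founding population (default 0, a pure culture). Used to study impure
#'   initial cultures.
#' @param truncation_freq Optional threshold in (0, 1): a replicate stops
#'   once its *sampled* transgene frequency `x/n` first reaches or falls
#'   below this value (the triggering sample is retained). `NULL` disables
#'   truncation.
#' @param seed Optional integer master seed; each replicate gets an
#'   independent stream derived from it.
#'
#' @return An object of class `transfer_design`.
#' @examples
#' transfer_design()                        # the default 24-h protocol
#' transfer_design(transfer_interval = 72)  # saturating cultures
#' @export
transfer_design <- function(transfer_interval = 24, beta = 10000, n = 100,
                            replicates = 3, duration = 3600,
                            initial_size = beta, initial_revertants = 0,
                            truncation_freq = NULL, seed = NULL) {
  stopifnot(
    transfer_interval > 0, duration > 0,
    beta >= 1, beta == round(beta),
    n >= 1, n == round(n),
    replicates >= 1, replicates == round(replicates),
    initial_size >= 1, initial_size == round(initial_size),
    initial_revertants >= 0, initial_revertants <= initial_size
  )
  if (n > beta) {
    stop("genotyped sample size n (", n, ") cannot exceed the bottleneck beta (",
         beta, ")")
  }
  if (!is.null(truncation_freq)) {
    stopifnot(truncation_freq > 0, truncation_freq < 1)
  }
  structure(
    list(
      transfer_interval = transfer_interval, beta = beta, n = n,
      replicates = replicates, duration = duration,
      initial_size = initial_size, initial_revertants = initial_revertants,
      truncation_freq = truncation_freq, seed = seed
    ),
    class = "transfer_design"
  )
}

#' @export
print.transfer_design <- function(x, ...) {
  cat("<transfer_design> T =", x$transfer_interval, "h, beta =", x$beta,
      ", n =", x$n, ", replicates =", x$replicates,
      ", duration =", x$duration, "h\n")
  if (x$initial_revertants > 0) {
    cat("  founding culture:", x$initial_size, "individuals incl.",
        x$initial_revertants, "revertants\n")
  }
  if (!is.null(x$truncation_freq)) {
    cat("  truncated once sampled frequency <=", x$truncation_freq, "\n")
  }
  invisible(x)
}

# Exact stochastic simulation (Gillespie) of the three birth reactions.
# Used for small populations where tau-leaping would be inaccurate.
ssa_step_loop <- function(N_E, N_R, params, t, t_end, switch_above = Inf) {
  r <- params$r; s <- params$s; mu <- params$mu; K <- params$K
  repeat {
    if (N_E + N_R >= switch_above) break
    f <- max(0, 1 - (N_E + N_R) / K)
    aE <- r * (1 - s) * N_E * f
    aR <- r * N_R * f
    a0 <- aE + aR
    if (a0 <= 0) {
      t <- t_end
      break
    }
    t <- t + stats::rexp(1, a0)
    if (t >= t_end) {
      t <- t_end
      break
    }
    if (stats::runif(1) < aE / a0) {
      # engineered parent: offspring reverts with probability mu
      if (stats::runif(1) < mu) N_R <- N_R + 1 else N_E <- N_E + 1
    } else {
      N_R <- N_R + 1
    }
  }
  list(N_E = N_E, N_R = N_R, t = t)
}

#' Stochastic growth of one culture
#'
#' Simulates the birth process implied by the two-type logistic model for
#' `t_grow` hours. Three reactions fire: an engineered birth
#' (propensity `r(1-s) N_E max(0, 1-N/K) (1-mu)`), a mutational birth in
#' which an engineered parent produces a revertant offspring (same, with
#' `mu` in place of `1-mu`), and a revertant birth
#' (`r*N_R*max(0, 1-N/K)`). Mutation is a redirected birth, never a
#' conversion of a living individual, and there are no deaths.
#'
#' Simulation uses midpoint tau-leaping with Poisson event counts
#' (propensities re-evaluated at the expected mid-leap state, which removes
#' the first-order frequency bias of a plain leap); the leap is capped so
#' that expected events change both the population and its headroom below
#' `K` by at most 5%. Populations below 1000 individuals are advanced by the exact
#' Gillespie algorithm instead. Any overshoot of `K` simply zeroes the
#' propensities (individuals are never removed).
#'
#' Uses R's global random number generator; seed with [set.seed()] (or let
#' [simulate_experiment()] manage streams).
#'
#' @param state A [population_state()] with integer-valued counts.
#' @param params A [model_params()].
#' @param t_grow Growth time in hours.
#' @param eps Tau-leap accuracy parameter (max relative propensity change
#'   per leap; default 0.05).
#' @param ssa_threshold Population size below which exact simulation is used.
#' @param tau_max Hard cap on the leap length, hours.
#'
#' @return A [population_state()] at time `state$t + t_grow`.
#' @examples
#' set.seed(1)
#' simulate_culture_growth(population_state(1e4, 0),
#'                         model_params(0.1, 0.1, 0.01), t_grow = 24)
#' @export
simulate_culture_growth <- function(state, params, t_grow, eps = 0.05,
                                    ssa_threshold = 1000, tau_max = 0.5) {
  stopifnot(state$N_E == round(state$N_E), state$N_R == round(state$N_R),
            t_grow >= 0)
  N_E <- state$N_E; N_R <- state$N_R
  t <- state$t; t_end <- state$t + t_grow
  r <- params$r; s <- params$s; mu <- params$mu; K <- params$K

  while (t < t_end) {
    if (N_E + N_R == 0) break
    if (N_E + N_R < ssa_threshold) {
      st <- ssa_step_loop(N_E, N_R, params, t, t_end,
                          switch_above = ssa_threshold)
      N_E <- st$N_E; N_R <- st$N_R; t <- st$t
      next
    }
    N <- N_E + N_R
    f <- max(0, 1 - N / K)
    aE <- r * (1 - s) * N_E * f     # engineered parents (both offspring types)
    aR <- r * N_R * f
    B <- aE + aR                    # total birth rate
    if (B <= 0) break               # at/above carrying capacity
    tau <- min(tau_max, t_end - t, eps * N / B, eps * (K - N) / B)
    # midpoint rule: re-evaluate propensities at the expected mid-leap state,
    # removing the O(tau) bias a plain leap leaves in the type frequencies
    NEm <- N_E + aE * (1 - mu) * tau / 2
    NRm <- N_R + (aR + aE * mu) * tau / 2
    fm <- max(0, 1 - (NEm + NRm) / K)
    aEm <- r * (1 - s) * NEm * fm
    births_EE <- stats::rpois(1, aEm * (1 - mu) * tau)
    births_ER <- stats::rpois(1, aEm * mu * tau)
    births_RR <- stats::rpois(1, r * NRm * fm * tau)
    N_E <- N_E + births_EE
    N_R <- N_R + births_ER + births_RR
    t <- t + tau
  }
  population_state(N_E, N_R, t_end)
}

#' Bottleneck transfer and genotyping sample
#'
#' Draws `beta` founders for the next culture without replacement from the
#' current culture (hypergeometric sampling over engineered vs revertant
#' individuals), then genotypes `n` of those founders, again without
#' replacement. If `beta` meets or exceeds the whole population, the entire
#' culture transfers.
#'
#' @param culture A [population_state()] with integer counts.
#' @param beta Bottleneck size (positive integer).
#' @param n Genotyped sample size, `n <= beta`.
#'
#' @return A list with `founders` (a [population_state()]) and `sample`
#'   (list with `n`, the realised sample size, and `x`, the number of
#'   engineered individuals in it).
#' @examples
#' set.seed(1)
#' bottleneck_and_sample(population_state(9e5, 1e5), beta = 1e4, n = 100)
#' @export
bottleneck_and_sample <- function(culture, beta, n) {
  stopifnot(culture$N_E == round(culture$N_E),
            culture$N_R == round(culture$N_R))
  if (n > beta) {
    stop("genotyped sample size n (", n, ") cannot exceed the bottleneck beta (",
         beta, ")")
  }
  total <- culture$N_E + culture$N_R
  if (beta >= total) {
    fE <- culture$N_E
    fR <- culture$N_R
  } else {
    fE <- stats::rhyper(1, m = culture$N_E, n = culture$N_R, k = beta)
    fR <- beta - fE
  }
  n_eff <- min(n, fE + fR)
  x <- if (n_eff == 0) 0L else stats::rhyper(1, m = fE, n = fR, k = n_eff)
  list(
    founders = population_state(fE, fR, culture$t),
    sample = list(n = n_eff, x = x)
  )
}

#' Simulate a serial-transfer experiment
#'
#' Runs the full protocol described by a [transfer_design()] under the model
#' of [model_params()]: each replicate is founded with
#' `initial_size - initial_revertants` engineered and `initial_revertants`
#' revertant individuals, a time-0 genotyping sample of `n` is drawn from
#' the founding culture, and then grow/bottleneck/sample cycles repeat every
#' `transfer_interval` hours until `duration` is reached or the sampled
#' transgene frequency drops to `truncation_freq` (the triggering sample is
#' kept). Replicates use independent random streams spawned from the master
#' seed, so a fixed seed reproduces the counts exactly.
#'
#' @param params A [model_params()].
#' @param design A [transfer_design()].
#'
#' @return A tibble of genotyping counts with columns `replicate`, `time_h`,
#'   `n_sampled`, `x_engineered` — the format consumed by [fit_mle()] and
#'   written by [write_counts()]. Metadata (the design, the master seed, the
#'   per-replicate seeds and truncation flags) is attached as the `"meta"`
#'   attribute.
#' @examples
#' counts <- simulate_experiment(
#'   model_params(r = 0.1, s = 0.1, mu = 0.01),
#'   transfer_design(duration = 240, seed = 42)
#' )
#' head(counts)
#' @export
simulate_experiment <- function(params, design) {
  stopifnot(inherits(params, "model_params"),
            inherits(design, "transfer_design"))
  master <- design$seed
  if (is.null(master)) {
    master <- stats::runif(1, 0, .Machine$integer.max)
  }
  set.seed(as.integer(master %% .Machine$integer.max))
  rep_seeds <- sample.int(.Machine$integer.max, design$replicates)

  one_replicate <- function(idx) {
    set.seed(rep_seeds[idx])
    state <- population_state(design$initial_size - design$initial_revertants,
                              design$initial_revertants, t = 0)
    # time-0 genotyping sample from the founding culture itself
    x0 <- if (state$N_R == 0) design$n else
      stats::rhyper(1, m = state$N_E, n = state$N_R,
                    k = min(design$n, state$N_E + state$N_R))
    rows <- list(tibble::tibble(time_h = 0,
                                n_sampled = min(design$n, state$N_E + state$N_R),
                                x_engineered = x0))
    truncated <- FALSE
    t <- 0
    while (t + design$transfer_interval <= design$duration) {
      state <- simulate_culture_growth(state, params, design$transfer_interval)
      t <- t + design$transfer_interval
      bs <- bottleneck_and_sample(state, design$beta, design$n)
      rows[[length(rows) + 1]] <- tibble::tibble(
        time_h = t, n_sampled = bs$sample$n, x_engineered = bs$sample$x
      )
      state <- bs$founders
      if (!is.null(design$truncation_freq) &&
          bs$sample$x / bs$sample$n <= design$truncation_freq) {
        truncated <- TRUE
        break
      }
    }
    out <- dplyr::bind_rows(rows)
    out$replicate <- paste0("r", idx)
    attr(out, "truncated") <- truncated
    out
  }

  reps <- purrr::map(seq_len(design$replicates), one_replicate)
  counts <- dplyr::bind_rows(reps)
  counts <- dplyr::select(counts, "replicate", "time_h", "n_sampled",
                          "x_engineered")
  attr(counts, "meta") <- list(
    design = design,
    params = params,
    seed = master,
    replicate_seeds = rep_seeds,
    truncated = purrr::map_lgl(reps, ~ attr(.x, "truncated"))
  )
  counts
}
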