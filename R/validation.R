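#' Draw true parameter values for a recovery study
#'
#' Samples the ground-truth parameters used to benchmark the estimator:
#' `s` uniform on `[0.005, 0.2]`, and `mu` from a Gamma distribution with
#' shape 10 whose mode grows geometrically across datasets as
#' `1.5^i x 1e-5` for dataset index `i` (so scale = mode / 9), sweeping the
#' loss rate over several orders of magnitude. Draws above `mu_cap` are
#' capped there and flagged: for large indices the literal mode exceeds 1,
#' which is not a probability, and the cap keeps `mu` inside the estimable
#' range while preserving the broad sweep.
#'
#' @param count Number of datasets (default 50).
#' @param mu_cap Upper cap applied to `mu` draws (default 0.1).
#' @param mode_base Geometric growth factor of the Gamma mode (default 1.5).
#' @param mode_scale Baseline mode at index 1 divided by `mode_base`
#'   (default 1e-5).
#' @param shape Gamma shape (default 10).
#'
#' @return A tibble with columns `dataset`, `s_true`, `mu_true`,
#'   `mu_capped`. Uses R's global RNG; call [set.seed()] for
#'   reproducibility.
#' @examples
#' set.seed(1)
#' draw_true_parameters(5)
#' @export
draw_true_parameters <- function(count = 50, mu_cap = 0.1, mode_base = 1.5,
                                 mode_scale = 1e-5, shape = 10) {
  stopifnot(count >= 1, mu_cap > 0, shape > 1)
  idx <- seq_len(count)
  mode <- mode_base^idx * mode_scale
  mu_raw <- stats::rgamma(count, shape = shape, scale = mode / (shape - 1))
  tibble::tibble(
    dataset = idx,
    s_true = stats::runif(count, 0.005, 0.2),
    mu_true = pmin(mu_raw, mu_cap),
    mu_capped = mu_raw > mu_cap
  )
}

#' Simulate-and-re-estimate parameter recovery study
#'
#' The validation loop for the estimator: draw true `(s, mu)` pairs
#' ([draw_true_parameters()]), simulate a serial-transfer experiment for
#' each ([simulate_experiment()]), re-estimate with [fit_mle()] assuming
#' `r_assumed`, and regress estimates on truth by ordinary least squares.
#' With frequent transfers (cultures staying in exponential growth) the
#' regression slopes sit near 1; long transfer intervals that let cultures
#' saturate at carrying capacity depress both slopes (evolution slows while
#' the estimator assumes it did not), and a misassigned `r` biases
#' estimates in the opposite direction to the error.
#'
#' @param design A [transfer_design()] (its `seed` is ignored; per-dataset
#'   seeds are spawned from `seed`).
#' @param r_true True per-hour growth rate used to simulate.
#' @param r_assumed Growth rate handed to the estimator (default `r_true`).
#' @param K Carrying capacity used to simulate (default 2e6).
#' @param count Number of simulated datasets (default 50).
#' @param seed Master seed for the whole study.
#'
#' @return A `recovery_report`: list with `results` (one row per dataset:
#'   truths, estimates, flags), `fit_mu` and `fit_s` (the `lm` objects for
#'   estimate-on-truth), and `settings`. `tidy()` returns the rows,
#'   `glance()` the regression summaries, `autoplot()` the scatter with 1:1
#'   and fitted lines.
#' @examples
#' \donttest{
#' rep24 <- recovery_study(transfer_design(), r_true = 0.1, count = 10,
#'                         seed = 1)
#' glance(rep24)
#' }
#' @export
recovery_study <- function(design, r_true, r_assumed = r_true, K = 2e6,
                           count = 50, seed = NULL) {
  stopifnot(inherits(design, "transfer_design"), r_true > 0, r_assumed > 0)
  if (!is.null(seed)) set.seed(seed)
  truths <- draw_true_parameters(count)
  dataset_seeds <- sample.int(.Machine$integer.max, count)

  one <- function(i) {
    params <- model_params(r = r_true, s = truths$s_true[i],
                           mu = truths$mu_true[i], K = K)
    des <- design
    des$seed <- dataset_seeds[i]
    counts <- simulate_experiment(params, des)
    fit <- tryCatch(fit_mle(counts, r = r_assumed), error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(
        dataset = i, s_true = truths$s_true[i], mu_true = truths$mu_true[i],
        mu_capped = truths$mu_capped[i], mu_hat = NA_real_, s_hat = NA_real_,
        converged = FALSE, flags = paste("fit_error:", conditionMessage(fit)),
        seed = dataset_seeds[i]
      ))
    }
    tibble::tibble(
      dataset = i, s_true = truths$s_true[i], mu_true = truths$mu_true[i],
      mu_capped = truths$mu_capped[i], mu_hat = fit$mu_hat, s_hat = fit$s_hat,
      converged = fit$converged,
      flags = paste(fit$boundary_flags, collapse = ","),
      seed = dataset_seeds[i]
    )
  }
  results <- purrr::map_dfr(seq_len(count), one)

  ok <- results[!is.na(results$mu_hat), ]
  fit_mu <- stats::lm(mu_hat ~ mu_true, data = ok)
  fit_s <- stats::lm(s_hat ~ s_true, data = ok)
  structure(
    list(
      results = results, fit_mu = fit_mu, fit_s = fit_s,
      settings = list(design = design, r_true = r_true,
                      r_assumed = r_assumed, K = K, count = count,
                      seed = seed, n_failed = count - nrow(ok))
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  g <- glance(x)
  cat("<recovery_report>", x$settings$count, "simulated datasets (",
      x$settings$n_failed, "fit failures )\n")
  cat(sprintf("  mu: estimate = %.4g + %.3f * truth (slope 95%% CI %.3f-%.3f)\n",
              g$intercept_mu, g$slope_mu, g$slope_mu_low, g$slope_mu_high))
  cat(sprintf("  s:  estimate = %.4g + %.3f * truth (slope 95%% CI %.3f-%.3f)\n",
              g$intercept_s, g$slope_s, g$slope_s_low, g$slope_s_high))
  invisible(x)
}

#' @rdname recovery_study
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @export
tidy.recovery_report <- function(x, ...) x$results

#' @rdname recovery_study
#' @export
glance.recovery_report <- function(x, ...) {
  ci_mu <- stats::confint(x$fit_mu)["mu_true", ]
  ci_s <- stats::confint(x$fit_s)["s_true", ]
  tibble::tibble(
    slope_mu = stats::coef(x$fit_mu)[["mu_true"]],
    intercept_mu = stats::coef(x$fit_mu)[["(Intercept)"]],
    slope_mu_low = ci_mu[[1]], slope_mu_high = ci_mu[[2]],
    slope_s = stats::coef(x$fit_s)[["s_true"]],
    intercept_s = stats::coef(x$fit_s)[["(Intercept)"]],
    slope_s_low = ci_s[[1]], slope_s_high = ci_s[[2]],
    n_datasets = x$settings$count,
    n_failed = x$settings$n_failed
  )
}
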