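#' Chance-performance baselines for the heading task
#'
#' Monte-Carlo (and closed-form) estimates of the mean absolute heading
#' error a subject would produce under three response strategies, used to
#' bound the worst plausible behavioral performance:
#' * `baseline_always_center()`: always report straight ahead — closed form
#'   `mean(|h|)`, 60/7 = 8.57 deg on the seven experimental headings;
#' * `baseline_uniform()`: report uniformly at random over the response
#'   ruler `(-R, R)` — converges to `(R^2 + mean(h^2)) / (2R)`;
#' * `baseline_gaussian()`: report from a Gaussian centered straight ahead
#'   with SD `sigma` — converges to the folded-normal mean averaged over
#'   headings.
#'
#' @param headings Vector of true headings, degrees (default the seven
#'   experimental values).
#' @return Mean absolute error in degrees (scalar).
#' @name baselines
#' @examples
#' baseline_always_center()                     # 8.571
#' baseline_uniform(R = 24, n_draws = 1e5, seed = 1)
#' baseline_gaussian(sigma = 2, n_draws = 1e5, seed = 1)
NULL

check_headings <- function(headings) {
  if (length(headings) == 0) {
    abort("`headings` must be nonempty.", class = "headingflow_invalid_baseline")
  }
}

#' @rdname baselines
#' @export
baseline_always_center <- function(headings = experiment_levels()$headings_deg) {
  check_headings(headings)
  mean(abs(headings))
}

#' @rdname baselines
#' @param R Half-range of the response ruler, degrees (> 0).
#' @param n_draws Monte-Carlo sample size per heading.
#' @param seed Integer seed.
#' @param discrete_ruler If `TRUE`, responses are snapped to the 1
#'   deg-spaced ruler values before scoring (the display offered integer
#'   ruler labels); default `FALSE` keeps the continuous closed-form limit.
#' @export
baseline_uniform <- function(headings = experiment_levels()$headings_deg,
                             R = 24, n_draws = 1e5, seed = 1,
                             discrete_ruler = FALSE) {
  check_headings(headings)
  if (!(is.numeric(R) && R > 0)) {
    abort("`R` must be positive.", class = "headingflow_invalid_baseline")
  }
  stop_if_not(n_draws >= 1, "`n_draws` must be >= 1.")
  with_seed(seed, {
    mean(vapply(headings, function(h) {
      x <- runif(n_draws, -R, R)
      if (discrete_ruler) x <- round(x)
      mean(abs(x - h))
    }, numeric(1)))
  })
}

#' @rdname baselines
#' @export
baseline_uniform_closed_form <- function(headings = experiment_levels()$headings_deg,
                                         R = 24) {
  check_headings(headings)
  stop_if_not(R > 0, "`R` must be positive.")
  # E|X - h| for X ~ U(-R, R), |h| <= R
  mean((R^2 + headings^2) / (2 * R))
}

#' @rdname baselines
#' @param sigma SD of the center-biased Gaussian response profile, degrees
#'   (default 2).
#' @export
baseline_gaussian <- function(headings = experiment_levels()$headings_deg,
                              sigma = 2, n_draws = 1e5, seed = 1,
                              discrete_ruler = FALSE) {
  check_headings(headings)
  if (!(is.numeric(sigma) && sigma > 0)) {
    abort("`sigma` must be positive.", class = "headingflow_invalid_baseline")
  }
  stop_if_not(n_draws >= 1, "`n_draws` must be >= 1.")
  with_seed(seed, {
    mean(vapply(headings, function(h) {
      x <- rnorm(n_draws, 0, sigma)
      if (discrete_ruler) x <- round(x)
      mean(abs(x - h))
    }, numeric(1)))
  })
}

#' @rdname baselines
#' @export
baseline_gaussian_closed_form <- function(headings = experiment_levels()$headings_deg,
                                          sigma = 2) {
  check_headings(headings)
  stop_if_not(sigma > 0, "`sigma` must be positive.")
  # folded-normal mean of N(-h, sigma)
  mean(sigma * sqrt(2 / pi) * exp(-headings^2 / (2 * sigma^2)) +
         abs(headings) * (1 - 2 * stats::pnorm(-abs(headings) / sigma)))
}

#' Compare all three baseline strategies
#'
#' @inheritParams baselines
#' @param R Uniform half-range, degrees.
#' @param sigma Gaussian SD, degrees.
#' @param n_draws Monte-Carlo draws per heading and strategy.
#' @param seed Integer seed.
#' @return Tibble with one row per strategy: `strategy`,
#'   `mean_error_deg` (Monte-Carlo), `closed_form_deg`.
#' @export
baseline_table <- function(headings = experiment_levels()$headings_deg,
                           R = 24, sigma = 2, n_draws = 1e5, seed = 1) {
  tibble(
    strategy = c("uniform", "gaussian_center", "always_center"),
    mean_error_deg = c(
      baseline_uniform(headings, R, n_draws, seed),
      baseline_gaussian(headings, sigma, n_draws, derive_seed(seed, 1L)),
      baseline_always_center(headings)
    ),
    closed_form_deg = c(
      baseline_uniform_closed_form(headings, R),
      baseline_gaussian_closed_form(headings, sigma),
      baseline_always_center(headings)
    )
  )
}
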