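test_that("heading regression recovers veridical and biased mappings", {
  h <- rep(c(-15, -10, -5, 0, 5, 10, 15), each = 10)
  fit <- fit_heading_regression(tibble::tibble(true_heading = h, response = h))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$flagged)
  g <- glance(fit)
  expect_equal(g$slope, 1)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  # sampling-distribution oracle: OLS slope SE with sigma = 2 at n = 350
  # is sigma / (sqrt(n) * sd(h)) ~ 0.011, so +-0.05 is ~4.5 SE
  set.seed(12)
  h350 <- rep(c(-15, -10, -5, 0, 5, 10, 15), each = 50)
  resp <- 1 + 0.5 * h350 + rnorm(350, 0, 2)
  fit2 <- fit_heading_regression(tibble::tibble(true_heading = h350,
                                                response = resp))
  expect_equal(fit2$slope, 0.5, tolerance = 0.05)
  expect_equal(fit2$intercept, 1, tolerance = 0.4)
  expect_error(
    fit_heading_regression(tibble::tibble(true_heading = rep(0, 10),
                                          response = rnorm(10))),
    class = "headingflow_degenerate_design"
  )
})

test_that("regression on anti-symmetric responses has zero intercept", {
  h <- rep(c(-15, -10, -5, 0, 5, 10, 15), each = 4)
  resp <- 0.4 * h + 0.01 * h^3 / 100  # odd function of heading
  fit <- fit_heading_regression(tibble::tibble(true_heading = h,
                                               response = resp))
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
})

test_that("heading error matches the hand-computed accuracy statistic", {
  lv <- experiment_levels()
  # all-zero responses on the balanced seven-heading design: 60/7 deg
  tr <- tibble::tibble(true_heading = rep(lv$headings_deg, times = 50),
                       response = 0)
  he <- heading_error(tr)
  expect_equal(he$mean_abs_error, 60 / 7)
  expect_equal(he$n, 350)
  # perfect responses: zero error
  tr2 <- tibble::tibble(true_heading = rep(lv$headings_deg, 5),
                        response = rep(lv$headings_deg, 5))
  expect_equal(heading_error(tr2)$mean_abs_error, 0)
  expect_error(heading_error(tr2[0, ]), class = "headingflow_empty_trials")
})

test_that("precision profile recovers a known dispersion structure", {
  tr <- tibble::tibble(true_heading = rep(c(-10, 0, 10), each = 4),
                       response = rep(c(-10, 0, 10), each = 4))
  pr <- precision_by_heading(tr)
  expect_equal(pr$sd_deg, rep(0, 3))
  # heteroscedastic generator sigma(h) = 1 + 0.2 |h|
  set.seed(77)
  hs <- rep(c(-15, -10, -5, 0, 5, 10, 15), each = 400)
  tr2 <- tibble::tibble(
    true_heading = hs,
    response = hs + rnorm(length(hs), 0, 1 + 0.2 * abs(hs))
  )
  pr2 <- precision_by_heading(tr2)
  truth <- 1 + 0.2 * abs(pr2$true_heading)
  # sampling SE of an SD at n=400 is sigma/sqrt(2n) ~ 3.5% of sigma
  expect_equal(pr2$sd_deg, truth, tolerance = 0.15)
  # dispersion grows monotonically with eccentricity on each side
  right <- pr2$sd_deg[pr2$true_heading >= 0]
  expect_true(all(diff(right) > 0))
  expect_warning(
    precision_by_heading(
      tibble::tibble(true_heading = c(0, 0, 5), response = c(1, 2, 3))
    ),
    "Omitting"
  )
})

test_that("BH step-up matches a literal execution of the procedure", {
  # the textbook case: {0.001, 0.02, 0.04, 0.9} at alpha .05 rejects 2
  res <- bh_adjust(c(0.001, 0.02, 0.04, 0.9), alpha = 0.05)
  expect_identical(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  # exhaustive comparison with the independent oracle on a p-grid
  grid_p <- seq(0.005, 1, by = 0.005)
  set.seed(5)
  for (len in 2:5) {
    for (rep in 1:40) {
      p <- sample(grid_p, len, replace = TRUE)
      expect_identical(bh_adjust(p, 0.05)$significant, bh_oracle(p, 0.05))
    }
  }
})

test_that("group comparison flags shifted cells and spares identical ones", {
  lv <- experiment_levels()
  base <- tidyr::crossing(duration = lv$durations_ms, n_dots = lv$n_dots,
                          true_heading = lv$headings_deg, rep = 1:8)
  set.seed(42)
  a <- dplyr::mutate(base, response = true_heading + rnorm(dplyr::n(), 0, 2))
  # identical samples: all p = 1, no rejections
  same <- compare_conditions(a, a)
  expect_equal(nrow(same), 16)
  expect_false(any(same$significant))
  # 3 deg extra error in group b: power > 0.99 at this n
  b <- dplyr::mutate(base, response = true_heading +
                       rnorm(dplyr::n(), 0, 2) + 3 * sample(c(-1, 1), dplyr::n(), TRUE))
  shifted <- compare_conditions(a, b)
  expect_true(all(shifted$significant))
  expect_error(
    compare_conditions(a, b[b$duration != 200, ],
                       cells = tibble::tibble(duration = 200, n_dots = 2)),
    class = "headingflow_empty_cell"
  )
})

test_that("stereo-improvement criterion counts significant densities", {
  mono <- tibble::tibble(n_dots = c(2, 10, 50, 100),
                         mean_abs_error = c(8, 7, 6, 5))
  stereo <- tibble::tibble(n_dots = c(2, 10, 50, 100),
                           mean_abs_error = c(7, 6, 5, 4))
  expect_true(stereo_improvement(mono, stereo,
                                 c(0.01, 0.02, 0.03, 0.2))$improved)
  expect_false(stereo_improvement(mono, stereo,
                                  c(0.01, 0.02, 0.2, 0.2))$improved)
  expect_true(stereo_improvement(mono, stereo,
                                 c(0.01, 0.01, 0.01, 0.01))$improved)
  # significance without a lower stereo error does not count
  worse <- dplyr::mutate(stereo, mean_abs_error = mono$mean_abs_error + 1)
  expect_false(stereo_improvement(mono, worse,
                                  c(0.01, 0.01, 0.01, 0.01))$improved)
  expect_error(stereo_improvement(mono[1:3, ], stereo[1:3, ], c(0.1, 0.1, 0.1)),
               class = "headingflow_invalid_densities")
})

test_that("ANOVA/Tukey plumbing reproduces textbook results on a toy design", {
  # balanced one-way design with known group means and unit variance
  set.seed(8)
  d <- tibble::tibble(
    duration = rep(c(200, 500, 1000, 2000), each = 60),
    true_heading = 0,
    response = rnorm(240, rep(c(4, 4, 2, 2), each = 60), 1)
  )
  eff <- duration_effect(d)
  expect_equal(eff$anova$df, 3)
  expect_lt(eff$anova$p.value, 1e-6)
  # cross-check the F statistic against stats::oneway.test equal-var form
  ow <- stats::oneway.test(abs(response) ~ factor(duration), data = d,
                           var.equal = TRUE)
  expect_equal(eff$anova$statistic, unname(ow$statistic), tolerance = 1e-8)
  tk <- eff$tukey
  gap <- tk$p.adj[tk$contrast == "1000-500"]
  expect_lt(gap, 0.001)
  expect_gt(tk$p.adj[tk$contrast == "500-200"], 0.2)
})
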