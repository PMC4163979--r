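#' Fit the perceived-vs-true heading regression
#'
#' Ordinary least squares of reported heading on true heading within one
#' condition cell. A slope of 1 with intercept 0 is veridical perception;
#' the slope quantifies sensitivity to heading variation, the intercept a
#' straight-ahead bias. Fits with R^2 <= 0.5 are flagged (not dropped).
#'
#' @param trials Tibble of trial records with columns `true_heading` and
#'   `response` (degrees).
#' @return Object of class `heading_fit` wrapping the `lm` fit.
#' @export
#' @examples
#' tr <- tibble::tibble(true_heading = rep(c(-10, 0, 10), each = 5),
#'                      response = rep(c(-10, 0, 10), each = 5))
#' glance(fit_heading_regression(tr))  # slope 1, intercept 0, R^2 = 1
fit_heading_regression <- function(trials) {
  if (length(unique(trials$true_heading)) < 2) {
    abort("Need >= 2 distinct true headings to fit a regression.",
          class = "headingflow_degenerate_design")
  }
  fit <- lm(response ~ true_heading, data = trials)
  r2 <- summary(fit)$r.squared
  structure(
    list(fit = fit,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r2,
         flagged = r2 <= 0.5,
         n = nrow(trials)),
    class = "heading_fit"
  )
}

#' @export
print.heading_fit <- function(x, ...) {
  cat(sprintf(
    "<heading_fit> slope %.3f, intercept %.3f deg, R^2 %.3f%s (n = %d)\n",
    x$slope, x$intercept, x$r_squared,
    if (x$flagged) " [flagged: R^2 <= 0.5]" else "", x$n
  ))
  invisible(x)
}

#' @rdname fit_heading_regression
#' @param x A `heading_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.heading_fit <- function(x, ...) {
  out <- as_tibble(summary(x$fit)$coefficients, rownames = "term")
  names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
  out$term <- c("intercept", "slope")
  out
}

#' @rdname fit_heading_regression
#' @exportS3Method generics::glance
glance.heading_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, flagged = x$flagged, n = x$n)
}

#' Heading accuracy of a set of trials
#'
#' Accuracy is the arithmetic mean of the absolute deviation of the
#' perceived from the true heading, with its standard error. One condition
#' cell of a 10-subject cohort has n = 350 (7 headings x 5 repetitions x 10
#' subjects).
#'
#' @param trials Tibble with columns `true_heading`, `response` (degrees).
#' @return One-row tibble: `mean_abs_error`, `standard_error`, `n`.
#' @export
heading_error <- function(trials) {
  if (nrow(trials) == 0) {
    abort("No trials supplied.", class = "headingflow_empty_trials")
  }
  dev <- abs(trials$response - trials$true_heading)
  tibble(
    mean_abs_error = mean(dev),
    standard_error = if (length(dev) > 1) sd(dev) / sqrt(length(dev)) else NA_real_,
    n = length(dev)
  )
}

#' Per-heading response precision
#'
#' Dispersion of the reported headings at each true heading. Both the
#' standard deviation and the standard error of the mean are returned (the
#' two dispersion conventions used for precision in this paradigm).
#' Headings with fewer than two trials are omitted with a warning.
#'
#' @param trials Tibble with columns `true_heading`, `response`.
#' @return Tibble per heading: `true_heading`, `sd_deg`, `sem_deg`, `n`.
#' @export
precision_by_heading <- function(trials) {
  if (nrow(trials) == 0) {
    abort("No trials supplied.", class = "headingflow_empty_trials")
  }
  counts <- dplyr::count(trials, .data$true_heading)
  thin <- counts$true_heading[counts$n < 2]
  if (length(thin) > 0) {
    warn(sprintf("Omitting headings with < 2 trials: %s",
                 paste(thin, collapse = ", ")))
  }
  trials |>
    dplyr::group_by(true_heading = .data$true_heading) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      sd_deg = sd(.data$response),
      sem_deg = sd(.data$response) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

# two-sided Mann-Whitney U; exact enumeration for small tie-free samples,
# tie-corrected normal approximation otherwise
mann_whitney_p <- function(a, b, exact_below = 20) {
  exact <- length(a) < exact_below && length(b) < exact_below &&
    !any(duplicated(c(a, b)))
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg step-up decisions
#'
#' @param p Vector of raw p-values (one family).
#' @param alpha Target false-discovery rate.
#' @return Tibble: `p`, `p_adj`, `significant`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  tibble(p = p, p_adj = p.adjust(p, method = "BH"),
         significant = p.adjust(p, method = "BH") <= alpha)
}

#' Compare two groups cell-by-cell (Mann-Whitney + FDR)
#'
#' For every duration x dot-count condition cell, compares the absolute
#' heading errors of the two groups with a two-sided Mann-Whitney U test,
#' then applies the Benjamini-Hochberg step-up correction across the cells
#' of the family.
#'
#' @param group_a,group_b Trial tibbles (columns `duration`, `n_dots`,
#'   `true_heading`, `response`).
#' @param cells Optional tibble of `duration`, `n_dots` cells to test;
#'   defaults to all cells present in both groups.
#' @param alpha FDR level (default 0.05).
#' @return Tibble per cell: `duration`, `n_dots`, `statistic` (median error
#'   difference a - b), `p`, `p_adj`, `significant`.
#' @export
compare_conditions <- function(group_a, group_b, cells = NULL, alpha = 0.05) {
  if (is.null(cells)) {
    cells <- dplyr::intersect(
      dplyr::distinct(group_a[, c("duration", "n_dots")]),
      dplyr::distinct(group_b[, c("duration", "n_dots")])
    )
  }
  cells <- dplyr::arrange(cells, .data$duration, .data$n_dots)
  res <- purrr::pmap_dfr(cells, function(duration, n_dots) {
    a <- group_a[group_a$duration == duration & group_a$n_dots == n_dots, ]
    b <- group_b[group_b$duration == duration & group_b$n_dots == n_dots, ]
    if (nrow(a) == 0 || nrow(b) == 0) {
      abort(sprintf("Empty cell (duration %s, n_dots %s) in one group.",
                    duration, n_dots),
            class = "headingflow_empty_cell")
    }
    ea <- abs(a$response - a$true_heading)
    eb <- abs(b$response - b$true_heading)
    tibble(duration = duration, n_dots = n_dots,
           statistic = median(ea) - median(eb),
           p = mann_whitney_p(ea, eb))
  })
  adj <- bh_adjust(res$p, alpha)
  res$p_adj <- adj$p_adj
  res$significant <- adj$significant
  res
}

#' Stereo-improvement criterion
#'
#' Stereoscopic presentation counts as improving performance at a given
#' presentation time if the stereo condition's heading error is
#' significantly lower than the mono condition's for at least 3 of the 4
#' dot densities.
#'
#' @param mono,stereo Tibbles with one row per dot density: columns
#'   `n_dots`, `mean_abs_error` (from [heading_error()] per cell).
#' @param p_values Per-density (FDR-adjusted) p-values, same order.
#' @param alpha Significance level.
#' @return One-row tibble: `n_improved`, `improved` (logical).
#' @export
stereo_improvement <- function(mono, stereo, p_values, alpha = 0.05) {
  if (nrow(mono) != 4 || nrow(stereo) != 4 || length(p_values) != 4) {
    abort("Exactly 4 dot densities are required.",
          class = "headingflow_invalid_densities")
  }
  stopifnot(all(mono$n_dots == stereo$n_dots))
  better <- stereo$mean_abs_error < mono$mean_abs_error & p_values <= alpha
  tibble(n_improved = sum(better), improved = sum(better) >= 3)
}

#' Within-group effect of presentation time (ANOVA + Tukey)
#'
#' Standard one-way ANOVA of absolute heading error on presentation time,
#' followed by Tukey honest-significant-difference post-hoc contrasts —
#' the plumbing used for duration effects within a group.
#'
#' @param trials Trial tibble (columns `duration`, `true_heading`,
#'   `response`).
#' @return List with `anova` (tibble: `df`, `statistic`, `p.value`) and
#'   `tukey` (tibble of pairwise contrasts).
#' @export
duration_effect <- function(trials) {
  d <- tibble(
    err = abs(trials$response - trials$true_heading),
    duration = factor(trials$duration)
  )
  fit <- aov(err ~ duration, data = d)
  an <- summary(fit)[[1]]
  tk <- as.data.frame(TukeyHSD(fit)$duration)
  list(
    anova = tibble(df = an[1, "Df"], statistic = an[1, "F value"],
                   p.value = an[1, "Pr(>F)"]),
    tukey = as_tibble(tk, rownames = "contrast") |>
      setNames(c("contrast", "estimate", "conf.low", "conf.high", "p.adj"))
  )
}

#' Slope-distribution comparison between groups
#'
#' Fits the heading regression in every duration x dot-count cell of each
#' group and compares the two slope distributions with a two-sample t-test
#' across the 16 cells (df = 15 per group).
#'
#' @param group_a,group_b Trial tibbles.
#' @return List with `fits` (per-cell tibble of slopes/intercepts by group)
#'   and `slope_test`, `intercept_test` (one-row tibbles).
#' @export
compare_regressions <- function(group_a, group_b) {
  per_cell <- function(trials, label) {
    trials |>
      dplyr::group_by(.data$duration, .data$n_dots) |>
      dplyr::group_modify(~ glance(fit_heading_regression(.x))) |>
      dplyr::ungroup() |>
      dplyr::mutate(group = label)
  }
  fits <- dplyr::bind_rows(per_cell(group_a, "a"), per_cell(group_b, "b"))
  tt <- function(var) {
    ht <- stats::t.test(fits[[var]][fits$group == "a"],
                        fits[[var]][fits$group == "b"])
    tibble(estimate = unname(diff(rev(ht$estimate))),
           statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  list(fits = fits, slope_test = tt("slope"), intercept_test = tt("intercept"))
}

#' Full per-condition summary of a trial table
#'
#' Applies [heading_error()] and [fit_heading_regression()] to every
#' group x experiment x duration x dot-count cell.
#'
#' @param trials Trial tibble (columns `group`, `experiment`, `duration`,
#'   `n_dots`, `true_heading`, `response`).
#' @return Tibble with one row per cell: error and regression summaries.
#' @export
condition_summary <- function(trials) {
  trials |>
    dplyr::group_by(.data$group, .data$experiment, .data$duration,
                    .data$n_dots) |>
    dplyr::group_modify(function(d, key) {
      fit <- glance(fit_heading_regression(d))
      dplyr::bind_cols(heading_error(d),
                       fit[, c("slope", "intercept", "r.squared", "flagged")])
    }) |>
    dplyr::ungroup()
}
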