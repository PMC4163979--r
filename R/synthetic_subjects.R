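#' Parameters of a synthetic behavioral cohort
#'
#' The generative model is deliberately minimal: reported heading is a
#' linear function of true heading (`response = b + a h`) plus
#' heteroscedastic Gaussian noise whose SD grows with eccentricity,
#' `sigma(h) = (sigma0 + sigma1 |h|) * duration_factor * density_factor`,
#' clipped to the response-ruler span. It reproduces the three qualitative
#' signatures of the behavioral data — compressive slope (a < 1),
#' dispersion growing away from straight ahead, and group/condition error
#' offsets — without claiming subject-level realism.
#'
#' @param group Group label (`"test"` or `"control"`).
#' @param slope,intercept Linear response mapping (unitless; degrees).
#' @param sigma0 Baseline response SD, degrees.
#' @param sigma1 Eccentricity gain of the SD, degrees per degree.
#' @param duration_factor Named multiplicative error factors per duration.
#' @param density_factor Named multiplicative error factors per dot count.
#' @param n_subjects Cohort size (default 10).
#' @param subject_cv Between-subject coefficient of variation of slope and
#'   intercept (default 0.1).
#' @param ruler_span Response clipping half-range, degrees (default 24,
#'   consistent with the uniform-baseline ruler).
#' @param seed Integer seed.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(group = "control",
                          slope = 0.55, intercept = 0.5,
                          sigma0 = 2, sigma1 = 0.15,
                          duration_factor = c(`200` = 1.3, `500` = 1.15,
                                              `1000` = 1.05, `2000` = 1),
                          density_factor = c(`2` = 1.5, `10` = 1.2,
                                             `50` = 1.05, `100` = 1),
                          n_subjects = 10, subject_cv = 0.1,
                          ruler_span = 24, seed = 1) {
  stop_if_not(sigma0 >= 0, "`sigma0` must be >= 0.")
  stop_if_not(sigma1 >= 0, "`sigma1` must be >= 0.")
  stop_if_not(n_subjects >= 1, "`n_subjects` must be >= 1.")
  structure(
    list(group = group, slope = slope, intercept = intercept,
         sigma0 = sigma0, sigma1 = sigma1,
         duration_factor = duration_factor, density_factor = density_factor,
         n_subjects = n_subjects, subject_cv = subject_cv,
         ruler_span = ruler_span, seed = seed),
    class = "cohort_params"
  )
}

#' Default cohort parameterizations
#'
#' `"control"`: younger adults (steeper slope, lower noise); `"test"`:
#' older adults (compressed slope, higher noise); `"static_target"`:
#' stationary-square localization control task (veridical slope, small
#' noise whose folded-normal mean error is about 1.7 deg).
#'
#' @param which One of `"control"`, `"test"`, `"static_target"`.
#' @param seed Integer seed.
#' @return A [cohort_params()] object.
#' @export
default_cohort <- function(which = c("control", "test", "static_target"),
                           seed = 1) {
  which <- match.arg(which)
  switch(which,
    control = cohort_params(group = "control", slope = 0.55, intercept = 0.5,
                            sigma0 = 2, sigma1 = 0.15, seed = seed),
    test = cohort_params(group = "test", slope = 0.3, intercept = 0.5,
                         sigma0 = 4, sigma1 = 0.25, seed = seed),
    static_target = cohort_params(group = "control", slope = 1, intercept = 0,
                                  sigma0 = 1.7 / sqrt(2 / pi), sigma1 = 0,
                                  duration_factor = c(`200` = 1, `500` = 1,
                                                      `1000` = 1, `2000` = 1),
                                  density_factor = c(`2` = 1, `10` = 1,
                                                     `50` = 1, `100` = 1),
                                  seed = seed)
  )
}

#' Build the factorial trial scaffold
#'
#' Full method-of-constant-stimuli design: 4 durations x 4 dot counts x 7
#' headings x 5 repetitions = 560 trials per subject per experiment, with
#' trial order randomized independently per subject.
#'
#' @param experiments Character vector of experiment labels.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed for the per-subject trial shuffles.
#' @return Tibble: `subject_id`, `experiment`, `trial`, `duration`,
#'   `n_dots`, `true_heading` (no responses yet).
#' @export
#' @examples
#' nrow(generate_design("coherent_mono", 1))  # 560
generate_design <- function(experiments = "coherent_mono", n_subjects = 10,
                            seed = 1) {
  stop_if_not(n_subjects >= 1, "`n_subjects` must be >= 1.")
  lv <- experiment_levels()
  base <- tidyr::crossing(
    duration = lv$durations_ms,
    n_dots = lv$n_dots,
    true_heading = lv$headings_deg,
    repetition = seq_len(lv$repetitions)
  )
  with_seed(seed, {
    tidyr::crossing(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                    experiment = experiments) |>
      dplyr::group_by(.data$subject_id, .data$experiment) |>
      dplyr::group_modify(function(d, key) {
        sh <- base[sample.int(nrow(base)), ]
        sh$trial <- seq_len(nrow(sh))
        sh
      }) |>
      dplyr::ungroup() |>
      dplyr::select("subject_id", "experiment", "trial", "duration",
                    "n_dots", "true_heading")
  })
}

#' Generate synthetic responses for a design
#'
#' Fills a [generate_design()] scaffold with responses from the
#' [cohort_params()] generative model. Subject-level slopes and intercepts
#' vary around the cohort values with coefficient of variation
#' `subject_cv`; all draws are reproducible from the params seed.
#'
#' @param params A [cohort_params()] object.
#' @param design A design scaffold; defaults to a fresh one for
#'   `params$n_subjects` subjects.
#' @return Trial tibble with added `group` and `response` columns.
#' @export
generate_cohort <- function(params, design = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(design)) {
    design <- generate_design(n_subjects = params$n_subjects,
                              seed = derive_seed(params$seed, 1L))
  }
  subjects <- unique(design$subject_id)
  with_seed(derive_seed(params$seed, 2L), {
    subj <- tibble(
      subject_id = subjects,
      subj_slope = rnorm(length(subjects), params$slope,
                         params$subject_cv * abs(params$slope)),
      subj_intercept = rnorm(length(subjects), params$intercept,
                             params$subject_cv * max(abs(params$intercept), 0.5))
    )
    out <- dplyr::left_join(design, subj, by = "subject_id")
    dfac <- params$duration_factor[as.character(out$duration)]
    nfac <- params$density_factor[as.character(out$n_dots)]
    dfac[is.na(dfac)] <- 1
    nfac[is.na(nfac)] <- 1
    sigma <- (params$sigma0 + params$sigma1 * abs(out$true_heading)) *
      as.numeric(dfac) * as.numeric(nfac)
    resp <- out$subj_intercept + out$subj_slope * out$true_heading +
      rnorm(nrow(out), 0, sigma)
    out$response <- pmin(pmax(resp, -params$ruler_span), params$ruler_span)
    out$group <- params$group
    dplyr::select(out, "subject_id", "group", "experiment", "trial",
                  "duration", "n_dots", "true_heading", "response")
  })
}

#' Write / read trial tables as plain CSV
#'
#' Column layout: `subject_id`, `group`, `experiment`, `duration_ms`,
#' `n_dots`, `true_heading_deg`, `response_deg`.
#'
#' @param trials Trial tibble as returned by [generate_cohort()].
#' @param path File path.
#' @return `write_trials_csv()` returns `trials` invisibly;
#'   `read_trials_csv()` returns a trial tibble in internal column naming.
#' @export
write_trials_csv <- function(trials, path) {
  out <- tibble(
    subject_id = trials$subject_id,
    group = trials$group,
    experiment = trials$experiment,
    duration_ms = trials$duration,
    n_dots = trials$n_dots,
    true_heading_deg = trials$true_heading,
    response_deg = trials$response
  )
  readr::write_csv(out, path)
  invisible(trials)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "group", "experiment", "duration_ms", "n_dots",
            "true_heading_deg", "response_deg")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Trial CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "headingflow_parse_error")
  }
  tibble(
    subject_id = as.character(raw$subject_id),
    group = as.character(raw$group),
    experiment = as.character(raw$experiment),
    duration = raw$duration_ms,
    n_dots = raw$n_dots,
    true_heading = raw$true_heading_deg,
    response = raw$response_deg
  )
}
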