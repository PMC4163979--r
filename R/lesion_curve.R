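#' Heading-error curve under increasing simulated cell loss
#'
#' For every deactivation probability in `p_values`, presents noise-free
#' translational 100-dot flow at the seven experimental headings (full
#' 2000 ms trials, temporally integrated at the MT stage), draws `n_seeds`
#' independent lesion masks (and dot clouds) per heading, decodes heading,
#' and records the absolute azimuthal error. Lesion masks are coupled across
#' `p_values` by common random numbers (a unit deactivated at probability p
#' stays deactivated at every p' > p), which removes Monte-Carlo wiggle from
#' the monotone trend.
#'
#' @param layer A [build_mst_layer()] object (its own lesion mask is
#'   ignored; masks are drawn here).
#' @param population The matching [build_mt_population()].
#' @param p_values Deactivation probabilities in \[0, 1).
#' @param n_seeds Lesion/stimulus draws per heading (>= 1).
#' @param headings_deg Heading azimuths; default the seven experimental ones.
#' @param n_dots Dots per stimulus (default 100, noise-free).
#' @param duration_ms Trial duration (default 2000 ms).
#' @param frame_stride Every `frame_stride`-th frame enters the temporal
#'   average (default 10, i.e. 12 flow samples of a 2000 ms trial).
#' @param frustum Viewing frustum.
#' @param seed Master seed.
#' @param readout Passed to the decoder; see [estimate_heading()].
#' @return Tibble with one row per (p, seed, heading): columns `p`, `seed`,
#'   `heading_deg`, `estimate_deg`, `abs_error_deg`.
#' @seealso [lesion_error_summary()] to aggregate, [autoplot.lesion_curve()].
#' @export
lesion_error_curve <- function(layer, population,
                               p_values = seq(0, 0.10, by = 0.01),
                               n_seeds = 100,
                               headings_deg = experiment_levels()$headings_deg,
                               n_dots = 100,
                               duration_ms = 2000,
                               frame_stride = 10,
                               frustum = build_frustum(),
                               seed = 1,
                               readout = "centroid") {
  if (length(p_values) == 0) {
    abort("`p_values` must be nonempty.", class = "headingflow_invalid_lesion")
  }
  if (any(p_values < 0 | p_values >= 1)) {
    abort("`p_values` must lie in [0, 1).", class = "headingflow_invalid_lesion")
  }
  stop_if_not(n_seeds >= 1, "`n_seeds` must be >= 1.")
  n_units <- length(layer$active)
  rows <- vector("list", length(headings_deg) * n_seeds)
  r <- 0L
  for (hi in seq_along(headings_deg)) {
    h <- headings_deg[hi]
    for (k in seq_len(n_seeds)) {
      sk <- derive_seed(seed, hi * 100003L + k)
      cfg <- stimulus_config(duration_ms = duration_ms, n_dots = n_dots,
                             heading_deg = h)
      fl <- simulate_trial(cfg, frustum, sk)
      fl <- fl[fl$frame %% frame_stride == 1L, ]
      drive <- mst_drive(layer, population, fl)
      u_les <- with_seed(sk + 1L, runif(n_units))
      est <- vapply(p_values, function(p) {
        out <- population_output(layer, drive, active = u_les >= p)
        decode_from_output(layer, out, readout)[["az"]]
      }, numeric(1))
      r <- r + 1L
      rows[[r]] <- tibble(
        p = p_values, seed = k, heading_deg = h,
        estimate_deg = est, abs_error_deg = abs(est - h)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lesion_curve", class(out))
  out
}

#' Summarize a lesion error curve
#'
#' @param curve Output of [lesion_error_curve()].
#' @param conf Confidence level for the normal-approximation interval.
#' @return Tibble per `p`: `mean_error_deg`, `sem_deg`, `ci_lo`, `ci_hi`,
#'   `n`.
#' @export
lesion_error_summary <- function(curve, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  out <- curve |>
    dplyr::group_by(.data$p) |>
    dplyr::summarise(
      mean_error_deg = mean(.data$abs_error_deg),
      sem_deg = sd(.data$abs_error_deg) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_lo = .data$mean_error_deg - z * .data$sem_deg,
      ci_hi = .data$mean_error_deg + z * .data$sem_deg
    )
  out
}

#' Match a behavioral error level to a cell-loss range
#'
#' Interpolates the summarized lesion curve to report which deactivation
#' probabilities bracket a given behavioral heading error.
#'
#' @param summary Output of [lesion_error_summary()].
#' @param behavioral_error_deg Observed mean heading error, degrees.
#' @return One-row tibble: `behavioral_error_deg`, `p_matched` (linear
#'   interpolation), `p_lo`, `p_hi` (bracketing grid values).
#' @export
match_cell_loss <- function(summary, behavioral_error_deg) {
  s <- dplyr::arrange(summary, .data$p)
  e <- s$mean_error_deg
  if (behavioral_error_deg <= min(e)) {
    p_m <- s$p[which.min(e)]
    return(tibble(behavioral_error_deg = behavioral_error_deg,
                  p_matched = p_m, p_lo = p_m, p_hi = p_m))
  }
  if (behavioral_error_deg >= max(e)) {
    p_m <- s$p[which.max(e)]
    return(tibble(behavioral_error_deg = behavioral_error_deg,
                  p_matched = p_m, p_lo = p_m, p_hi = p_m))
  }
  p_m <- stats::approx(e, s$p, xout = behavioral_error_deg, ties = mean)$y
  below <- s$p[e <= behavioral_error_deg]
  above <- s$p[e >= behavioral_error_deg]
  tibble(
    behavioral_error_deg = behavioral_error_deg,
    p_matched = p_m,
    p_lo = max(below),
    p_hi = min(above)
  )
}
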