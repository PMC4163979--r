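#' Canonical stimulus levels of the behavioral design
#'
#' Presentation times, dot counts and heading directions used throughout:
#' 4 durations x 4 dot densities x 7 headings (method of constant stimuli,
#' 5 repetitions per cell).
#'
#' @return Named list with `durations_ms`, `n_dots`, `headings_deg`,
#'   `repetitions`.
#' @export
experiment_levels <- function() {
  list(
    durations_ms = c(200, 500, 1000, 2000),
    n_dots       = c(2, 10, 50, 100),
    headings_deg = c(-15, -10, -5, 0, 5, 10, 15),
    repetitions  = 5
  )
}

#' Build a viewing frustum
#'
#' The display geometry is a non-symmetric pinhole frustum: near/far clipping
#' planes plus half-angles derived from the headset's diagonal field of view
#' and the panel aspect ratio via planar-screen trigonometry
#' (`tan(d/2)^2 = tan(h)^2 + tan(v)^2` with `tan(h)/tan(v) = aspect`).
#'
#' @param near Near clipping distance in meters (default 0.023).
#' @param far Far clipping distance in meters (default 20).
#' @param diagonal_fov Diagonal field of view in degrees (default 60).
#' @param aspect Horizontal:vertical aspect ratio (default 1280/1024).
#' @return Object of class `frustum`: near/far distances (m), horizontal and
#'   vertical half-angles (deg) and their tangents.
#' @export
#' @examples
#' fr <- build_frustum()
#' fr$half_az_deg  # about 24.3 degrees
build_frustum <- function(near = 0.023, far = 20, diagonal_fov = 60,
                          aspect = 1280 / 1024) {
  if (!(is.numeric(near) && is.numeric(far) && near > 0 && far > near)) {
    abort("`near` and `far` must satisfy 0 < near < far.",
          class = "headingflow_invalid_geometry")
  }
  if (!(diagonal_fov > 0 && diagonal_fov < 180)) {
    abort("`diagonal_fov` must be in (0, 180) degrees.",
          class = "headingflow_invalid_geometry")
  }
  td <- tan(deg2rad(diagonal_fov / 2))
  tv <- td / sqrt(1 + aspect^2)
  th <- aspect * tv
  structure(
    list(
      near = near, far = far,
      half_az_deg = rad2deg(atan(th)),
      half_el_deg = rad2deg(atan(tv)),
      tan_half_az = th, tan_half_el = tv
    ),
    class = "frustum"
  )
}

#' @export
print.frustum <- function(x, ...) {
  cat(sprintf(
    "<frustum> near %.3f m, far %.1f m, half-angles %.1f x %.1f deg\n",
    x$near, x$far, x$half_az_deg, x$half_el_deg
  ))
  invisible(x)
}

#' Stimulus configuration
#'
#' Parameters of one translational optic-flow trial. Defaults reproduce the
#' canonical experimental values; `coherence` is the fraction of dots whose
#' motion is consistent with the simulated self-motion (1 for fully coherent
#' displays, 0.15 for the noise condition, implying a signal-to-noise ratio
#' `coherence / (1 - coherence)`).
#'
#' @param duration_ms Presentation time in ms.
#' @param n_dots Number of visible dots.
#' @param heading_deg Heading azimuth in degrees (FOE on the horizontal
#'   meridian).
#' @param speed Simulated observer speed, m/s.
#' @param frame_rate Display frame rate, Hz.
#' @param coherence Fraction in \[0, 1\].
#' @param stereo Logical; stereoscopic (off-axis) presentation.
#' @param dot_size_range Dot size range in degrees (display property only).
#' @param depth_distribution How dot depths are drawn: `"uniform_z"`
#'   (default; reproduces the reported mean dot speed of a few deg/s at
#'   1 m/s), `"uniform_invz"` (uniform screen density of inverse depth) or
#'   `"uniform_volume"` (uniform in the 3-D frustum volume).
#' @return Object of class `stimulus_config` (a named list); `$snr` holds the
#'   implied signal-to-noise ratio.
#' @export
#' @examples
#' cfg <- stimulus_config(duration_ms = 2000, n_dots = 100, heading_deg = 10)
#' stimulus_config(coherence = 0.15)$snr   # 0.1765
stimulus_config <- function(duration_ms = 2000, n_dots = 100, heading_deg = 0,
                            speed = 1.0, frame_rate = 60, coherence = 1.0,
                            stereo = FALSE, dot_size_range = c(0.2, 10),
                            depth_distribution = c("uniform_z", "uniform_invz",
                                                   "uniform_volume")) {
  depth_distribution <- match.arg(depth_distribution)
  stop_if_not(duration_ms > 0, "`duration_ms` must be positive.")
  stop_if_not(n_dots >= 0, "`n_dots` must be non-negative.")
  stop_if_not(speed > 0, "`speed` must be positive.")
  stop_if_not(frame_rate > 0, "`frame_rate` must be positive.")
  if (!(is.numeric(coherence) && coherence >= 0 && coherence <= 1)) {
    abort("`coherence` must lie in [0, 1].",
          class = "headingflow_invalid_coherence")
  }
  structure(
    list(
      duration_ms = duration_ms, n_dots = n_dots, heading_deg = heading_deg,
      speed = speed, frame_rate = frame_rate, coherence = coherence,
      stereo = isTRUE(stereo), dot_size_range = dot_size_range,
      depth_distribution = depth_distribution,
      snr = if (coherence < 1) coherence / (1 - coherence) else Inf
    ),
    class = "stimulus_config"
  )
}

sample_depths <- function(n, frustum, distribution) {
  switch(distribution,
    uniform_z    = runif(n, frustum$near, frustum$far),
    uniform_invz = 1 / runif(n, 1 / frustum$far, 1 / frustum$near),
    uniform_volume = {
      # density proportional to z^2 between the clipping planes
      u <- runif(n)
      (u * frustum$far^3 + (1 - u) * frustum$near^3)^(1 / 3)
    }
  )
}

sample_positions <- function(n, frustum, distribution) {
  z <- sample_depths(n, frustum, distribution)
  tibble(
    x = runif(n, -frustum$tan_half_az, frustum$tan_half_az) * z,
    y = runif(n, -frustum$tan_half_el, frustum$tan_half_el) * z,
    z = z
  )
}

#' Sample a random dot cloud inside a frustum
#'
#' Dots are placed uniformly in screen position with depth drawn according to
#' `depth_distribution`, so the screen density is uniform regardless of depth.
#'
#' @param n Number of dots (>= 0).
#' @param frustum A [build_frustum()] object.
#' @param seed Integer seed; identical seeds give identical clouds.
#' @param depth_distribution See [stimulus_config()].
#' @return Tibble with columns `dot_id`, `x`, `y`, `z` (meters, camera
#'   coordinates: x right, y up, z forward).
#' @export
sample_dot_cloud <- function(n, frustum, seed,
                             depth_distribution = "uniform_z") {
  stop_if_not(is.numeric(n) && n >= 0, "`n` must be non-negative.")
  n <- as.integer(n)
  with_seed(seed, {
    pos <- sample_positions(n, frustum, depth_distribution)
    dplyr::bind_cols(tibble(dot_id = seq_len(n)), pos)
  })
}

in_frustum <- function(pos, frustum) {
  pos$z >= frustum$near & pos$z <= frustum$far &
    abs(pos$x / pos$z) <= frustum$tan_half_az &
    abs(pos$y / pos$z) <= frustum$tan_half_el
}

#' Analytic optic flow at an image point
#'
#' Pinhole flow for pure observer translation: with normalized image
#' coordinates `(x, y)` (tangent of azimuth/elevation) and translation
#' `T = (tx, ty, tz)`, the image velocity is `u = (x tz - tx)/Z`,
#' `v = (y tz - ty)/Z` (rad/s), reported in degree-equivalents per second.
#' The flow vanishes exactly at the focus of expansion `x = tx/tz`,
#' `y = ty/tz`.
#'
#' @param az_deg,el_deg Image position, degrees of visual angle.
#' @param depth Dot depth Z in meters (> 0).
#' @param translation Length-3 translation vector, m/s (see
#'   [heading_vector()]).
#' @return Tibble with `u_degps`, `v_degps`.
#' @export
#' @examples
#' # 0.1 rad off-axis at 1 m, forward motion at 1 m/s: u = 0.1 rad/s = 5.73 deg/s
#' analytic_flow_at(rad2deg(atan(0.1)), 0, 1, c(0, 0, 1))
analytic_flow_at <- function(az_deg, el_deg, depth, translation) {
  if (any(depth <= 0)) {
    abort("`depth` must be positive.", class = "headingflow_invalid_depth")
  }
  x <- tan(deg2rad(az_deg))
  y <- tan(deg2rad(el_deg))
  tibble(
    u_degps = rad2deg((x * translation[3] - translation[1]) / depth),
    v_degps = rad2deg((y * translation[3] - translation[2]) / depth)
  )
}

flow_from_positions <- function(pos, translation) {
  x <- pos$x / pos$z
  y <- pos$y / pos$z
  tibble(
    dot_id = pos$dot_id %||% seq_len(nrow(pos)),
    az_deg = rad2deg(atan(x)),
    el_deg = rad2deg(atan(y)),
    u_degps = rad2deg((x * translation[3] - translation[1]) / pos$z),
    v_degps = rad2deg((y * translation[3] - translation[2]) / pos$z),
    is_signal = TRUE
  )
}

#' Instantaneous flow field of a dot cloud
#'
#' @param cloud A [sample_dot_cloud()] tibble.
#' @param translation Length-3 translation vector, m/s.
#' @return Flow-field tibble: `dot_id`, `az_deg`, `el_deg`, `u_degps`,
#'   `v_degps`, `is_signal`.
#' @export
flow_field <- function(cloud, translation) {
  flow_from_positions(cloud, translation)
}

#' Replace a fraction of flow vectors by direction noise
#'
#' Each dot is independently marked as noise with probability
#' `1 - coherence`; noise dots receive a uniformly random motion direction
#' with magnitude resampled from the signal dots' speed distribution (so only
#' direction information is destroyed). Signal dots keep their radial flow.
#'
#' @param flow A flow-field tibble.
#' @param coherence Fraction in \[0, 1\]; 1 returns the input unchanged.
#' @param seed Integer seed.
#' @return Flow-field tibble with updated velocities and `is_signal`.
#' @export
apply_coherence <- function(flow, coherence, seed) {
  if (!(is.numeric(coherence) && coherence >= 0 && coherence <= 1)) {
    abort("`coherence` must lie in [0, 1].",
          class = "headingflow_invalid_coherence")
  }
  if (coherence == 1 || nrow(flow) == 0) {
    flow$is_signal <- rep(TRUE, nrow(flow))
    return(flow)
  }
  with_seed(seed, {
    n <- nrow(flow)
    noise <- runif(n) < (1 - coherence)
    speeds <- sqrt(flow$u_degps^2 + flow$v_degps^2)
    pool <- speeds[!noise]
    if (length(pool) == 0) pool <- speeds
    k <- sum(noise)
    if (k > 0) {
      theta <- runif(k, 0, 2 * pi)
      mag <- sample(pool, k, replace = TRUE)
      flow$u_degps[noise] <- mag * cos(theta)
      flow$v_degps[noise] <- mag * sin(theta)
    }
    flow$is_signal <- !noise
    flow
  })
}

#' Simulate a full stimulus trial frame-by-frame
#'
#' Dots are advected by the observer translation at the display frame rate;
#' flow is evaluated at each frame's temporal midpoint. Dots leaving the
#' frustum (or crossing the near plane) are respawned at a new random
#' in-frustum location so the dot count stays constant. If
#' `config$coherence < 1`, per-frame direction noise is applied as in
#' [apply_coherence()] (noise dots are redrawn every frame).
#'
#' @param config A [stimulus_config()].
#' @param frustum A [build_frustum()] object.
#' @param seed Integer seed; the full frame sequence is reproducible.
#' @return Tibble with columns `frame`, `dot_id`, `az_deg`, `el_deg`,
#'   `u_degps`, `v_degps`, `is_signal`.
#' @export
#' @examples
#' fr <- build_frustum()
#' cfg <- stimulus_config(duration_ms = 200, n_dots = 10)
#' nrow(simulate_trial(cfg, fr, seed = 1))  # 12 frames x 10 dots
simulate_trial <- function(config, frustum, seed) {
  stopifnot(inherits(config, "stimulus_config"))
  n_frames <- round(config$duration_ms * config$frame_rate / 1000)
  dt <- 1 / config$frame_rate
  tr <- heading_vector(config$heading_deg, 0, config$speed)
  with_seed(seed, {
    pos <- sample_positions(config$n_dots, frustum, config$depth_distribution)
    pos$dot_id <- seq_len(config$n_dots)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      mid <- pos
      mid$x <- pos$x - tr[1] * dt / 2
      mid$y <- pos$y - tr[2] * dt / 2
      mid$z <- pos$z - tr[3] * dt / 2
      fl <- flow_from_positions(mid, tr)
      if (config$coherence < 1 && nrow(fl) > 0) {
        n <- nrow(fl)
        noise <- runif(n) < (1 - config$coherence)
        speeds <- sqrt(fl$u_degps^2 + fl$v_degps^2)
        pool <- speeds[!noise]
        if (length(pool) == 0) pool <- speeds
        k <- sum(noise)
        if (k > 0) {
          theta <- runif(k, 0, 2 * pi)
          mag <- sample(pool, k, replace = TRUE)
          fl$u_degps[noise] <- mag * cos(theta)
          fl$v_degps[noise] <- mag * sin(theta)
        }
        fl$is_signal <- !noise
      }
      frames[[f]] <- dplyr::bind_cols(tibble(frame = f), fl)
      # advect a full frame step, then respawn exited dots
      pos$x <- pos$x - tr[1] * dt
      pos$y <- pos$y - tr[2] * dt
      pos$z <- pos$z - tr[3] * dt
      out <- !in_frustum(pos, frustum)
      if (any(out)) {
        repl <- sample_positions(sum(out), frustum, config$depth_distribution)
        pos$x[out] <- repl$x
        pos$y[out] <- repl$y
        pos$z[out] <- repl$z
      }
    }
    dplyr::bind_rows(frames)
  })
}

#' Stereo viewing geometry
#'
#' @param eye_separation Interocular distance in meters (default 0.063).
#' @param zero_parallax_distance Distance of the zero-parallax plane in
#'   meters.
#' @return Object of class `stereo_geometry`.
#' @export
stereo_geometry <- function(eye_separation = 0.063,
                            zero_parallax_distance = 1) {
  stop_if_not(eye_separation >= 0, "`eye_separation` must be >= 0.")
  stop_if_not(zero_parallax_distance > 0,
              "`zero_parallax_distance` must be positive.")
  structure(
    list(eye_separation = eye_separation,
         zero_parallax_distance = zero_parallax_distance),
    class = "stereo_geometry"
  )
}

#' Off-axis stereoscopic projection of a dot cloud
#'
#' Parallel-axis asymmetric-frustum projection: the two cameras keep parallel
#' view vectors and each frustum is sheared so that points on the
#' zero-parallax plane coincide in the two images. Disparity is purely
#' horizontal; points nearer than the zero-parallax plane have crossed
#' (negative) disparity, farther points uncrossed (positive).
#'
#' @param cloud A [sample_dot_cloud()] tibble.
#' @param geom A [stereo_geometry()] object.
#' @param frustum A [build_frustum()] object (carried for provenance).
#' @return Tibble with per-dot screen coordinates of both eyes
#'   (`x_left`, `x_right`, shared `y`, normalized units) and
#'   `disparity_deg = atan(x_right) - atan(x_left)` in degrees.
#' @export
stereo_project <- function(cloud, geom, frustum) {
  s <- geom$eye_separation
  d0 <- geom$zero_parallax_distance
  # eye at (e, 0, 0), screen shear +e/d0 maps the z = d0 plane to itself
  project_eye <- function(e) (cloud$x - e) / cloud$z + e / d0
  xl <- project_eye(-s / 2)
  xr <- project_eye(+s / 2)
  tibble(
    dot_id = cloud$dot_id,
    x_left = xl,
    x_right = xr,
    y = cloud$y / cloud$z,
    disparity_deg = rad2deg(atan(xr) - atan(xl))
  )
}

#' Write / read a flow field as plain CSV
#'
#' Columns: `frame`, `dot_id`, `az_deg`, `el_deg`, `u_degps`, `v_degps`,
#' `is_signal`.
#'
#' @param flow Flow-field tibble (a `frame` column is added if absent).
#' @param path File path.
#' @return `write_flow_csv()` returns `flow` invisibly; `read_flow_csv()`
#'   returns the tibble.
#' @export
write_flow_csv <- function(flow, path) {
  if (!"frame" %in% names(flow)) flow <- dplyr::bind_cols(tibble(frame = 1L), flow)
  readr::write_csv(flow[, c("frame", "dot_id", "az_deg", "el_deg",
                            "u_degps", "v_degps", "is_signal")], path)
  invisible(flow)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    frame = readr::col_integer(),
                    dot_id = readr::col_integer(),
                    is_signal = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}
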