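#' Degree/radian conversion helpers
#'
#' @param x Numeric vector of angles.
#' @return Converted numeric vector.
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

#' Translation vector for a heading direction
#'
#' Converts a heading given as azimuth/elevation (degrees) into a 3-D camera
#' frame translation vector (x right, y up, z forward). Azimuth is positive
#' rightward, elevation positive upward.
#'
#' @param azimuth Heading azimuth in degrees.
#' @param elevation Heading elevation in degrees (default 0, the horizontal
#'   meridian used in the experiments).
#' @param speed Observer speed in m/s (default 1.0).
#' @return Numeric length-3 vector `c(tx, ty, tz)` in m/s.
#' @export
#' @examples
#' heading_vector(0)            # straight ahead: (0, 0, 1)
#' heading_vector(15)[1] > 0    # rightward heading has positive x
heading_vector <- function(azimuth, elevation = 0, speed = 1) {
  az <- deg2rad(azimuth)
  el <- deg2rad(elevation)
  speed * c(sin(az) * cos(el), sin(el), cos(az) * cos(el))
}

# seed helper: derive a distinct 31-bit stream seed from a base seed
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2017L %% 2147483647L + as.integer(k)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

stop_if_not <- function(cond, msg, class = "headingflow_error") {
  if (!isTRUE(cond)) abort(msg, class = class)
}
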