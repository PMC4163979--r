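#' Build the MT-like input layer
#'
#' The input layer consists of `n_sets` receptive-field locations placed
#' uniformly at random within `max_ecc` degrees of eccentricity; each
#' location carries `per_set` direction-tuned units with preferred directions
#' equally spaced around the circle (defaults: 300 sets x 4 units = 1200
#' units, preferred directions 0/90/180/270 deg). Direction tuning is a
#' rectified cosine scaled linearly by local speed, which makes the local
#' flow vector exactly reconstructable from a set's four responses
#' (`u = r0 - r180`, `v = r90 - r270`).
#'
#' @param n_sets Number of receptive-field locations (>= 1).
#' @param per_set Units per location (>= 2).
#' @param max_ecc Maximum eccentricity, degrees.
#' @param seed Integer seed.
#' @return Object of class `mt_population`: a tibble (`unit_id`, `set_id`,
#'   `az_deg`, `el_deg`, `pref_deg`) with the build parameters as attributes.
#' @export
#' @examples
#' mt <- build_mt_population(seed = 1)
#' nrow(mt)  # 1200
build_mt_population <- function(n_sets = 300, per_set = 4, max_ecc = 50,
                                seed = 1) {
  stop_if_not(n_sets >= 1, "`n_sets` must be >= 1.")
  if (per_set < 2) {
    abort("`per_set` must be >= 2: local flow is not reconstructable from fewer than two directions.",
          class = "headingflow_invalid_mt")
  }
  units <- with_seed(seed, {
    # uniform over the eccentricity disk in the (az, el) plane
    r <- max_ecc * sqrt(runif(n_sets))
    phi <- runif(n_sets, 0, 2 * pi)
    prefs <- seq(0, 360, length.out = per_set + 1)[seq_len(per_set)]
    tidyr::crossing(
      tibble(set_id = seq_len(n_sets),
             az_deg = r * cos(phi), el_deg = r * sin(phi)),
      tibble(pref_deg = prefs)
    )
  })
  units <- dplyr::arrange(units, .data$set_id, .data$pref_deg)
  units$unit_id <- seq_len(nrow(units))
  units <- units[, c("unit_id", "set_id", "az_deg", "el_deg", "pref_deg")]
  structure(as_tibble(units),
            class = c("mt_population", class(units)),
            n_sets = n_sets, per_set = per_set, max_ecc = max_ecc, seed = seed)
}

# nearest stimulus dot within match_radius (deg) for each RF location;
# returns per-set flow (u, v in deg/s), zero where no dot is in range
sample_flow_at_rfs <- function(population, flow, match_radius = 1) {
  sets <- dplyr::distinct(as_tibble(population)[, c("set_id", "az_deg", "el_deg")])
  n <- nrow(sets)
  u <- numeric(n); v <- numeric(n)
  if (nrow(flow) > 0) {
    d2 <- outer(sets$az_deg, flow$az_deg, "-")^2 +
      outer(sets$el_deg, flow$el_deg, "-")^2
    j <- max.col(-d2, ties.method = "first")
    ok <- d2[cbind(seq_len(n), j)] <= match_radius^2
    u[ok] <- flow$u_degps[j[ok]]
    v[ok] <- flow$v_degps[j[ok]]
  }
  tibble(set_id = sets$set_id, az_deg = sets$az_deg, el_deg = sets$el_deg,
         u_degps = u, v_degps = v)
}

#' Encode a flow field into MT population activity
#'
#' Each receptive field samples the flow of the nearest stimulus dot within
#' `match_radius` degrees (locations with no dot in range stay silent, which
#' reproduces the sparse-input regime of 2-dot displays). Unit response is
#' `speed * max(0, cos(flow_direction - preferred_direction))`. A small
#' radius keeps the positional mismatch between dot and receptive-field
#' center (which otherwise biases the decoded heading) below the grid
#' resolution.
#'
#' For a multi-frame flow tibble (a `frame` column with several values) the
#' sampled flow is averaged across frames before encoding — temporal
#' integration at the motion-measurement stage. Under pure translation the
#' flow direction at a fixed image location is stationary, so the average
#' remains a valid translational flow sample.
#'
#' @param population A [build_mt_population()] object.
#' @param flow Flow-field tibble (one or several frames).
#' @param match_radius Receptive-field match radius, degrees (default 1).
#' @return Numeric activity vector, one entry per MT unit (unit_id order).
#' @export
mt_encode <- function(population, flow, match_radius = 1) {
  if (is.null(flow) || nrow(flow) == 0) {
    abort("Empty flow field.", class = "headingflow_empty_flow")
  }
  rf <- sample_flow_at_rfs_avg(population, flow, match_radius)
  units <- as_tibble(population)
  idx <- match(units$set_id, rf$set_id)
  u <- rf$u_degps[idx]
  v <- rf$v_degps[idx]
  speed <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  resp <- speed * pmax(0, cos(theta - deg2rad(units$pref_deg)))
  resp[speed == 0] <- 0
  resp
}

# average the RF-sampled flow over the frames of a trial
sample_flow_at_rfs_avg <- function(population, flow, match_radius = 1) {
  if (!"frame" %in% names(flow) || length(unique(flow$frame)) == 1) {
    return(sample_flow_at_rfs(population, flow, match_radius))
  }
  per <- lapply(split(flow, flow$frame), function(fl) {
    sample_flow_at_rfs(population, fl, match_radius)
  })
  out <- per[[1]]
  out$u_degps <- Reduce(`+`, lapply(per, `[[`, "u_degps")) / length(per)
  out$v_degps <- Reduce(`+`, lapply(per, `[[`, "v_degps")) / length(per)
  out
}

# reconstruct the sampled flow (deg/s, one row per RF location) from an MT
# activity vector; requires per_set = 4 with prefs 0/90/180/270
reconstruct_flow <- function(population, activity) {
  units <- as_tibble(population)
  stopifnot(length(activity) == nrow(units))
  wide <- tibble(set_id = units$set_id, pref = units$pref_deg, r = activity)
  wide <- tidyr::pivot_wider(wide, names_from = "pref", values_from = "r",
                             names_prefix = "p")
  sets <- dplyr::distinct(units[, c("set_id", "az_deg", "el_deg")])
  wide <- dplyr::left_join(sets, wide, by = "set_id")
  tibble(
    set_id = wide$set_id, az_deg = wide$az_deg, el_deg = wide$el_deg,
    u_degps = wide$p0 - wide$p180,
    v_degps = wide$p90 - wide$p270
  )
}
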