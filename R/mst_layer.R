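#' Candidate-heading grid of the MST layer
#'
#' Each node of the grid carries one MST population encoding that heading.
#' The default spans +/-16 deg azimuth x +/-5 deg elevation at 1 deg spacing
#' (33 x 11 nodes): the seven experimental headings plus a 1-node margin so
#' the centroid readout has a full neighborhood at +/-15 deg. A centered
#' 20 x 20 grid can be requested for fidelity runs with the original model's
#' population count.
#'
#' @param az,el Numeric vectors of grid azimuths/elevations in degrees
#'   (regularly spaced).
#' @return Tibble `pop_id`, `az_deg`, `el_deg` with grid-shape attributes.
#' @export
heading_grid <- function(az = seq(-16, 16, by = 1), el = seq(-5, 5, by = 1)) {
  stop_if_not(length(az) >= 1 && length(el) >= 1, "Grid must be nonempty.")
  g <- tidyr::crossing(el_deg = sort(el), az_deg = sort(az))
  g <- g[, c("az_deg", "el_deg")]
  g$pop_id <- seq_len(nrow(g))
  structure(as_tibble(g[, c("pop_id", "az_deg", "el_deg")]),
            class = c("heading_grid", class(g)),
            az = sort(az), el = sort(el))
}

# translation/rotation flow design matrix at normalized image coords (x, y):
# 2m rows; m inverse-depth columns (A_i T) plus 3 rotation columns
flow_design_matrix <- function(x, y, translation) {
  m <- length(x)
  C <- matrix(0, 2 * m, m + 3)
  ax <- -translation[1] + x * translation[3]
  ay <- -translation[2] + y * translation[3]
  for (i in seq_len(m)) {
    C[2 * i - 1, i] <- ax[i]
    C[2 * i, i] <- ay[i]
  }
  C[seq(1, 2 * m, 2), m + 1:3] <-
    cbind(x * y, -(1 + x^2), y)
  C[seq(2, 2 * m, 2), m + 1:3] <-
    cbind(1 + y^2, -x * y, -x)
  C
}

# orthonormal basis of the orthogonal complement of col(C)
null_basis <- function(C) {
  qrC <- qr(C)
  Q <- qr.Q(qrC, complete = TRUE)
  r <- qrC$rank
  if (r >= nrow(C)) return(matrix(0, nrow(C), 0))
  Q[, (r + 1):nrow(C), drop = FALSE]
}

#' Build the MST-like output layer with fixed least-squares weights
#'
#' For every candidate heading `T` on the grid, each neuron pair's weight
#' vector is drawn from the orthogonal complement of the subspace of image
#' flow fields that translation `T` can generate over the pair's sampled
#' receptive-field locations (any depth assignment, rotation components
#' included). Consequently the pair's drive `w . v` vanishes exactly when the
#' stimulus heading equals `T`, for any scene layout — the subspace
#' least-squares criterion. Weights are fixed at construction; nothing is
#' learned.
#'
#' Each neuron of a pair carries opposite signs (+w / -w) and a saturating
#' (logistic) activation `g(bias +/- gain * w.v)`, so the summed pair
#' activity is maximal when the drive is zero: the population encoding the
#' true heading is the most active one. `gain` defaults to a calibration
#' that sets the median pair drive at the task's extreme heading offset
#' (15 deg, reference 100-dot 1 m/s integrated stimulus) to 1, which keeps
#' the population heading tuning broad across the tested range.
#'
#' @param population A [build_mt_population()] object supplying the
#'   receptive-field locations.
#' @param grid A [heading_grid()].
#' @param inputs_per_unit Receptive-field locations sampled per neuron pair
#'   (default 30).
#' @param pairs Neuron pairs per population (default 20, i.e. 40 units per
#'   population).
#' @param seed Integer seed for location sampling and weight directions.
#' @param bias Logistic bias `b` (default 2; units sit near saturation at
#'   zero drive).
#' @param gain Logistic gain; `NULL` (default) triggers the flow-statistics
#'   calibration described above.
#' @param frustum Frustum used for the calibration stimulus.
#' @param share_locations If `TRUE`, all pairs of a population share one
#'   location sample and their weight vectors form an orthonormal set — this
#'   makes the summed squared drive exactly the projection residual of the
#'   measured flow onto the complement of the heading subspace (used by the
#'   brute-force oracle tests).
#' @return Object of class `mst_layer`.
#' @export
build_mst_layer <- function(population, grid,
                            inputs_per_unit = 30, pairs = 20, seed = 1,
                            bias = 2, gain = NULL,
                            frustum = build_frustum(),
                            share_locations = FALSE) {
  units <- as_tibble(population)
  sets <- dplyr::distinct(units[, c("set_id", "az_deg", "el_deg")])
  sets <- dplyr::arrange(sets, .data$set_id)
  n_loc <- nrow(sets)
  if (inputs_per_unit > n_loc) {
    abort(sprintf("`inputs_per_unit` (%d) exceeds available RF locations (%d).",
                  inputs_per_unit, n_loc),
          class = "headingflow_invalid_mst")
  }
  xs <- tan(deg2rad(sets$az_deg))
  ys <- tan(deg2rad(sets$el_deg))
  n_pop <- nrow(grid)

  trip_i <- vector("list", n_pop)
  trip_j <- vector("list", n_pop)
  trip_x <- vector("list", n_pop)
  n_pairs_pop <- integer(n_pop)

  with_seed(seed, {
    for (k in seq_len(n_pop)) {
      tr <- heading_vector(grid$az_deg[k], grid$el_deg[k])
      if (share_locations) {
        S <- sort(sample.int(n_loc, inputs_per_unit))
        C <- flow_design_matrix(xs[S], ys[S], tr)
        NS <- null_basis(C)
        npk <- min(pairs, ncol(NS))
        # orthonormal random rotation of the null basis
        Wk <- qr.Q(qr(NS %*% matrix(rnorm(ncol(NS) * npk), ncol(NS), npk)))
        rows <- lapply(seq_len(npk), function(p) {
          list(j = as.vector(rbind(2L * S - 1L, 2L * S)), x = Wk[, p])
        })
      } else {
        npk <- pairs
        rows <- lapply(seq_len(pairs), function(p) {
          S <- sort(sample.int(n_loc, inputs_per_unit))
          C <- flow_design_matrix(xs[S], ys[S], tr)
          NS <- null_basis(C)
          if (ncol(NS) == 0) {
            abort("Flow subspace fills the whole measurement space; cannot build weights.",
                  class = "headingflow_invalid_mst")
          }
          w <- NS %*% rnorm(ncol(NS))
          w <- w / sqrt(sum(w^2))
          list(j = as.vector(rbind(2L * S - 1L, 2L * S)), x = as.vector(w))
        })
      }
      n_pairs_pop[k] <- length(rows)
      trip_j[[k]] <- unlist(lapply(rows, `[[`, "j"))
      trip_x[[k]] <- unlist(lapply(rows, `[[`, "x"))
    }
  })

  n_pairs <- sum(n_pairs_pop)
  pair_pop <- rep(seq_len(n_pop), n_pairs_pop)
  row_id <- rep(seq_len(n_pairs), each = 2L * inputs_per_unit)
  W <- sparseMatrix(
    i = row_id,
    j = unlist(trip_j),
    x = unlist(trip_x),
    dims = c(n_pairs, 2L * n_loc)
  )

  layer <- structure(
    list(
      W = W,
      pair_pop = pair_pop,
      grid = grid,
      sets = sets,
      inputs_per_unit = inputs_per_unit,
      pairs = pairs,
      bias = bias,
      gain = 1,
      active = rep(TRUE, 2L * n_pairs),
      lesion_p = 0,
      seed = seed,
      share_locations = share_locations
    ),
    class = "mst_layer"
  )

  if (is.null(gain)) {
    layer$gain <- calibrate_gain(layer, population, frustum,
                                 seed = derive_seed(seed, 7919L))
  } else {
    layer$gain <- gain
  }
  layer
}

#' @export
print.mst_layer <- function(x, ...) {
  cat(sprintf(
    "<mst_layer> %d populations x %d pairs = %d units; %d/%d active; gain %.3g, bias %.2g\n",
    nrow(x$grid), x$pairs, 2L * nrow(x$W), sum(x$active), 2L * nrow(x$W),
    x$gain, x$bias
  ))
  invisible(x)
}

# gain such that the median |pair drive| at the task's extreme heading
# offset (15 deg) is 1, measured on the same kind of input the decoder
# sees: a temporally integrated 2000 ms, 100-dot, 1 m/s straight-ahead
# reference trial. Anchoring the sigmoid scale to the full tested heading
# span keeps the population heading tuning broad (the hallmark of MST-like
# heading codes) while staying informative across the task range.
calibrate_gain <- function(layer, population, frustum, seed,
                           offset_deg = 15, n_dots = 100) {
  cfg <- stimulus_config(duration_ms = 2000, n_dots = n_dots, heading_deg = 0)
  fl <- simulate_trial(cfg, frustum, seed)
  fl <- fl[fl$frame %% 10L == 1L, ]
  s <- mst_drive(layer, population, fl)
  off <- layer$grid$pop_id[abs(abs(layer$grid$az_deg) - offset_deg) < 1e-9 &
                             layer$grid$el_deg == 0]
  if (length(off) == 0) off <- layer$grid$pop_id
  sref <- median(abs(s[layer$pair_pop %in% off]))
  if (!is.finite(sref) || sref <= 0) 1 else 1 / sref
}

# measured-flow vector in the layer's input coordinates (normalized
# tangent-plane rates, interleaved x/y per RF location)
mst_input_vector <- function(layer, population, flow, match_radius = 1) {
  act <- mt_encode(population, flow, match_radius)
  rec <- reconstruct_flow(population, act)
  rec <- rec[match(layer$sets$set_id, rec$set_id), ]
  v <- numeric(2L * nrow(rec))
  v[seq(1, length(v), 2)] <- deg2rad(rec$u_degps)
  v[seq(2, length(v), 2)] <- deg2rad(rec$v_degps)
  v
}

#' Pair drives and population statistics
#'
#' `mst_drive()` returns each neuron pair's drive `w . v` for a flow field;
#' `population_residual()` aggregates |drive| (or squared drive) per
#' population — the least-squares residual statistic that vanishes at the
#' true heading; `population_output()` applies the saturating pair
#' activation under the current lesion mask and sums per population.
#'
#' @param layer An [build_mst_layer()] object.
#' @param population The matching [build_mt_population()].
#' @param flow Flow-field tibble.
#' @param match_radius Receptive-field match radius in degrees.
#' @return `mst_drive()`: numeric vector (one per pair).
#' @export
mst_drive <- function(layer, population, flow, match_radius = 1) {
  v <- mst_input_vector(layer, population, flow, match_radius)
  as.numeric(layer$W %*% v)
}

#' @rdname mst_drive
#' @param drive Vector of pair drives from `mst_drive()`.
#' @param type `"abs"` (sum of |w.v|; the rectified pair sum) or `"sq"`
#'   (sum of squares; equals the subspace projection residual when the layer
#'   was built with `share_locations = TRUE`).
#' @return `population_residual()`: tibble `pop_id`, `az_deg`, `el_deg`,
#'   `residual`.
#' @export
population_residual <- function(layer, drive, type = c("abs", "sq")) {
  type <- match.arg(type)
  val <- if (type == "abs") abs(drive) else drive^2
  res <- as.numeric(rowsum(val, layer$pair_pop))
  out <- layer$grid
  out$residual <- res
  as_tibble(out)
}

#' @rdname mst_drive
#' @param active Logical activation mask, length `2 * n_pairs` (the +w
#'   neurons followed by the -w neurons); defaults to the layer's mask.
#' @return `population_output()`: tibble `pop_id`, `az_deg`, `el_deg`,
#'   `output` (summed unit activity).
#' @export
population_output <- function(layer, drive, active = layer$active) {
  n <- length(drive)
  o_plus <- stats::plogis(layer$bias + layer$gain * drive)
  o_minus <- stats::plogis(layer$bias - layer$gain * drive)
  o <- o_plus * active[seq_len(n)] + o_minus * active[n + seq_len(n)]
  out_v <- as.numeric(rowsum(o, layer$pair_pop))
  out <- layer$grid
  out$output <- out_v
  as_tibble(out)
}

#' Deactivate MST units at random (simulated cell loss)
#'
#' Each unit of the layer (both members of a pair independently) is silenced
#' with probability `p`; a silenced unit contributes exactly 0 to its
#' population's output while its partner stays active. This asymmetric loss
#' is what perturbs the population activity landscape and induces heading
#' errors.
#'
#' @param layer An `mst_layer`.
#' @param p Deactivation probability in \[0, 1\].
#' @param seed Integer seed; the mask is reproducible.
#' @return The layer with an updated `active` mask.
#' @export
lesion <- function(layer, p, seed = 1) {
  if (!(is.numeric(p) && p >= 0 && p <= 1)) {
    abort("`p` must lie in [0, 1].", class = "headingflow_invalid_lesion")
  }
  n <- length(layer$active)
  layer$active <- with_seed(seed, runif(n) >= p)
  layer$lesion_p <- p
  layer
}

decode_from_output <- function(layer, out_tbl,
                               readout = c("centroid", "argmax")) {
  readout <- match.arg(readout)
  U <- out_tbl$output
  k <- which.max(U)
  az0 <- out_tbl$az_deg[k]
  el0 <- out_tbl$el_deg[k]
  if (readout == "argmax") return(c(az = az0, el = el0))
  azs <- attr(layer$grid, "az")
  els <- attr(layer$grid, "el")
  daz <- if (length(azs) > 1) min(diff(azs)) else 1
  del <- if (length(els) > 1) min(diff(els)) else 1
  nb <- abs(out_tbl$az_deg - az0) <= daz + 1e-9 &
    abs(out_tbl$el_deg - el0) <= del + 1e-9
  w <- U[nb] - min(U)
  if (sum(w) <= 0) w <- rep(1, sum(nb))
  c(az = sum(out_tbl$az_deg[nb] * w) / sum(w),
    el = sum(out_tbl$el_deg[nb] * w) / sum(w))
}

#' Decode heading from a flow field
#'
#' Runs the flow through the MT layer, computes every MST population's
#' summed activity under the current lesion mask, and reads out heading as
#' the activity-weighted centroid of the 3x3 grid neighborhood around the
#' most active population (`readout = "argmax"` returns the raw winner).
#'
#' @inheritParams mst_drive
#' @param true_heading True heading azimuth in degrees (elevation 0), used
#'   to report the absolute azimuthal error.
#' @param readout `"centroid"` (default) or `"argmax"`.
#' @return One-row tibble: `az_deg`, `el_deg`, `true_heading_deg`,
#'   `abs_error_deg`, `low_support` (TRUE when fewer receptive fields than
#'   one unit's input count received stimulus flow), `n_active_rf`.
#' @export
#' @examples
#' \donttest{
#' mt <- build_mt_population(seed = 2)
#' net <- build_mst_layer(mt, heading_grid(), seed = 2)
#' fl <- flow_field(sample_dot_cloud(100, build_frustum(), 3),
#'                  heading_vector(10))
#' estimate_heading(net, mt, fl, true_heading = 10)
#' }
estimate_heading <- function(layer, population, flow, true_heading = 0,
                             readout = c("centroid", "argmax"),
                             match_radius = 1) {
  if (!any(layer$active)) {
    abort("All MST units are deactivated: degenerate readout.",
          class = "headingflow_degenerate_readout")
  }
  v <- mst_input_vector(layer, population, flow, match_radius)
  n_active_rf <- sum(v[seq(1, length(v), 2)] != 0 | v[seq(2, length(v), 2)] != 0)
  drive <- as.numeric(layer$W %*% v)
  out <- population_output(layer, drive)
  est <- decode_from_output(layer, out, readout)
  tibble(
    az_deg = unname(est["az"]),
    el_deg = unname(est["el"]),
    true_heading_deg = true_heading,
    abs_error_deg = abs(unname(est["az"]) - true_heading),
    low_support = n_active_rf < layer$inputs_per_unit,
    n_active_rf = n_active_rf
  )
}

# brute-force subspace least-squares oracle: projection residual of the
# measured flow onto the complement of each candidate heading's subspace
bruteforce_heading <- function(flow_v, x, y, grid) {
  res <- vapply(seq_len(nrow(grid)), function(k) {
    C <- flow_design_matrix(x, y, heading_vector(grid$az_deg[k], grid$el_deg[k]))
    r <- qr.resid(qr(C), flow_v)
    sum(r^2)
  }, numeric(1))
  out <- as_tibble(grid)
  out$residual <- res
  out
}
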