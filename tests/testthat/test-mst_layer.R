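test_that("layer dimensions follow the population-grid layout", {
  mt <- fix_mt()
  # original-model fidelity configuration: 20 x 20 grid, 20 pairs -> 16000
  g20 <- heading_grid(az = seq(-9.5, 9.5, by = 1), el = seq(-9.5, 9.5, by = 1))
  small <- build_mst_layer(mt, g20, inputs_per_unit = 10, pairs = 20,
                           seed = 3, gain = 1)
  expect_equal(nrow(g20), 400)
  expect_equal(2 * nrow(small$W), 16000)
  expect_error(build_mst_layer(mt, heading_grid(), inputs_per_unit = 301),
               class = "headingflow_invalid_mst")
})

test_that("pair drives vanish at the true heading for any scene depths", {
  net <- fix_layer()
  mt <- fix_mt()
  set.seed(17)
  draws <- 20
  probes <- net$grid[sample(nrow(net$grid), draws), ]
  for (k in seq_len(draws)) {
    tr <- heading_vector(probes$az_deg[k], probes$el_deg[k])
    fl <- flow_at_rfs(net, tr, n = 80, seed = 1000 + k)
    # infinitesimal match radius: only the receptive fields that carry a
    # dot are sampled, so the measured flow is positionally exact
    res <- population_residual(net, mst_drive(net, mt, fl, match_radius = 1e-6))
    at_true <- res$residual[res$az_deg == probes$az_deg[k] &
                              res$el_deg == probes$el_deg[k]]
    expect_lt(at_true, 1e-8)
  }
})

test_that("network heading matches the brute-force least-squares oracle", {
  # small shared-location instance: summed squared drive must equal the
  # projection residual computed independently via QR, and the argmin
  # headings must agree
  mt_small <- build_mt_population(n_sets = 10, max_ecc = 20, seed = 4)
  grid5 <- heading_grid(az = -2:2, el = -2:2)
  net <- build_mst_layer(mt_small, grid5, inputs_per_unit = 10, pairs = 30,
                         seed = 4, gain = 1, share_locations = TRUE)
  sets <- net$sets
  xs <- tan(deg2rad(sets$az_deg))
  ys <- tan(deg2rad(sets$el_deg))
  for (k in 1:5) {
    set.seed(40 + k)
    z <- runif(10, 1, 10)
    tr <- heading_vector(sample(-2:2, 1), sample(-2:2, 1))
    cloud <- tibble::tibble(dot_id = 1:10, x = xs * z, y = ys * z, z = z)
    # perturb the flow so no candidate fits perfectly
    fl <- flow_field(cloud, tr)
    fl$u_degps <- fl$u_degps + rnorm(10, 0, 0.2)
    fl$v_degps <- fl$v_degps + rnorm(10, 0, 0.2)
    v <- headingflow:::mst_input_vector(net, mt_small, fl)
    net_res <- population_residual(net, as.numeric(net$W %*% v), type = "sq")
    oracle <- headingflow:::bruteforce_heading(v, xs, ys, net$grid)
    expect_equal(net_res$residual, oracle$residual, tolerance = 1e-8)
    expect_equal(which.min(net_res$residual), which.min(oracle$residual))
  }
})

test_that("decoding is invariant to a global flow-speed scaling", {
  net <- fix_layer()
  mt <- fix_mt()
  fl <- flow_field(sample_dot_cloud(100, fix_frustum(), 21), heading_vector(10))
  fl2 <- fl
  fl2$u_degps <- 3 * fl$u_degps
  fl2$v_degps <- 3 * fl$v_degps
  r1 <- population_residual(net, mst_drive(net, mt, fl))
  r2 <- population_residual(net, mst_drive(net, mt, fl2))
  expect_equal(r2$residual, 3 * r1$residual, tolerance = 1e-9)
  expect_equal(which.min(r1$residual), which.min(r2$residual))
})

test_that("lesioning follows its binomial contract", {
  net <- fix_layer()
  mt <- fix_mt()
  n <- length(net$active)
  l0 <- lesion(net, 0, seed = 1)
  expect_true(all(l0$active))
  l1 <- lesion(net, 1, seed = 1)
  expect_false(any(l1$active))
  fl <- flow_field(sample_dot_cloud(50, fix_frustum(), 3), heading_vector(0))
  expect_error(estimate_heading(l1, mt, fl),
               class = "headingflow_degenerate_readout")
  expect_error(lesion(net, 1.5), class = "headingflow_invalid_lesion")
  # deactivated count within the binomial 99% interval
  l05 <- lesion(net, 0.05, seed = 7)
  k <- sum(!l05$active)
  bounds <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  expect_identical(lesion(net, 0.05, seed = 7)$active, l05$active)
})

test_that("unlesioned decoding hits all seven headings within grid spacing", {
  net <- fix_layer()
  mt <- fix_mt()
  fr <- fix_frustum()
  for (h in experiment_levels()$headings_deg) {
    cfg <- stimulus_config(duration_ms = 2000, n_dots = 100, heading_deg = h)
    fl <- simulate_trial(cfg, fr, seed = 500 + h)
    fl <- fl[fl$frame %% 10 == 1, ]
    est <- estimate_heading(net, mt, fl, true_heading = h)
    expect_lte(est$abs_error_deg, 1)
  }
})

test_that("sparse 2-dot stimuli are decoded but flagged low-support", {
  net <- fix_layer()
  mt <- fix_mt()
  fl <- flow_field(sample_dot_cloud(2, fix_frustum(), 8), heading_vector(0))
  est <- estimate_heading(net, mt, fl, true_heading = 0)
  expect_true(est$low_support)
  expect_true(is.finite(est$az_deg))
  expect_lte(est$n_active_rf, 2)
})
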