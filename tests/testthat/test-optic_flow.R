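test_that("frustum geometry follows planar-screen trigonometry", {
  fr <- build_frustum(near = 0.023, far = 20, diagonal_fov = 60,
                      aspect = 5 / 4)
  expect_equal(fr$near, 0.023)
  expect_equal(fr$far, 20)
  # independent derivation: tan(d/2)^2 = th^2 + tv^2, th/tv = 5/4
  tv <- tan(deg2rad(30)) / sqrt(1 + (5 / 4)^2)
  expect_equal(fr$half_az_deg, rad2deg(atan(5 / 4 * tv)))
  expect_equal(fr$half_az_deg, 24.3, tolerance = 0.01)
  expect_error(build_frustum(near = 20, far = 0.023),
               class = "headingflow_invalid_geometry")
  expect_error(build_frustum(diagonal_fov = 200),
               class = "headingflow_invalid_geometry")
})

test_that("dot clouds respect the frustum and the seed contract", {
  fr <- fix_frustum()
  for (dist in c("uniform_z", "uniform_invz", "uniform_volume")) {
    cloud <- sample_dot_cloud(100, fr, seed = 7, depth_distribution = dist)
    expect_equal(nrow(cloud), 100)
    expect_true(all(cloud$z >= fr$near & cloud$z <= fr$far))
    expect_true(all(abs(cloud$x / cloud$z) <= fr$tan_half_az + 1e-12))
    expect_true(all(abs(cloud$y / cloud$z) <= fr$tan_half_el + 1e-12))
  }
  expect_identical(sample_dot_cloud(50, fr, seed = 3),
                   sample_dot_cloud(50, fr, seed = 3))
  expect_equal(nrow(sample_dot_cloud(0, fr, seed = 1)), 0)
  expect_error(sample_dot_cloud(-1, fr, seed = 1))
})

test_that("analytic flow matches the pinhole closed form", {
  # x = 0.1 normalized, Z = 1 m, forward 1 m/s: u = 0.1 rad/s = 5.73 deg/s
  fl <- analytic_flow_at(rad2deg(atan(0.1)), 0, 1, c(0, 0, 1))
  expect_equal(fl$u_degps, rad2deg(0.1), tolerance = 1e-12)
  expect_equal(fl$u_degps, 5.73, tolerance = 1e-3)
  expect_equal(fl$v_degps, 0)
  # flow vanishes exactly at the FOE
  tr <- heading_vector(15)
  foe_az <- rad2deg(atan(tr[1] / tr[3]))
  expect_equal(foe_az, 15)
  at_foe <- analytic_flow_at(foe_az, 0, 2, tr)
  expect_equal(c(at_foe$u_degps, at_foe$v_degps), c(0, 0), tolerance = 1e-12)
  expect_error(analytic_flow_at(5, 0, -1, tr),
               class = "headingflow_invalid_depth")
})

test_that("flow fields expand radially from the FOE and scale with speed", {
  fr <- fix_frustum()
  cloud <- sample_dot_cloud(200, fr, seed = 11)
  for (h in c(-15, 0, 10)) {
    fl <- flow_field(cloud, heading_vector(h))
    # radial: (position - FOE) . velocity > 0 away from the FOE
    dx <- fl$az_deg - h
    dy <- fl$el_deg - 0
    proj <- dx * fl$u_degps + dy * fl$v_degps
    expect_true(all(proj[abs(dx) + abs(dy) > 0.5] > 0))
    # magnitude strictly positive off the FOE
    expect_true(all(sqrt(fl$u_degps^2 + fl$v_degps^2)
                    [abs(dx) + abs(dy) > 0.5] > 0))
  }
  f1 <- flow_field(cloud, heading_vector(5, speed = 1))
  f2 <- flow_field(cloud, heading_vector(5, speed = 2))
  expect_equal(f2$u_degps, 2 * f1$u_degps, tolerance = 1e-12)
  expect_equal(f2$v_degps, 2 * f1$v_degps, tolerance = 1e-12)
})

test_that("mean dot speed at 1 m/s is of the reported few-deg/s order", {
  fr <- fix_frustum()
  cloud <- sample_dot_cloud(2000, fr, seed = 5)
  fl <- flow_field(cloud, heading_vector(0))
  speed <- mean(sqrt(fl$u_degps^2 + fl$v_degps^2))
  expect_gt(speed, 1)
  expect_lt(speed, 8)
})

test_that("trial simulation produces the right frame counts deterministically", {
  fr <- fix_frustum()
  for (case in list(c(2000, 120), c(200, 12), c(500, 30), c(1000, 60))) {
    cfg <- stimulus_config(duration_ms = case[1], n_dots = 10)
    frames <- simulate_trial(cfg, fr, seed = 4)
    expect_equal(max(frames$frame), case[2])
    expect_equal(nrow(frames), case[2] * 10)
  }
  cfg <- stimulus_config(duration_ms = 500, n_dots = 25)
  expect_identical(simulate_trial(cfg, fr, seed = 9),
                   simulate_trial(cfg, fr, seed = 9))
  # dots stay inside the field of view throughout
  frames <- simulate_trial(stimulus_config(duration_ms = 2000, n_dots = 50),
                           fr, seed = 2)
  expect_true(all(abs(frames$az_deg) <= fr$half_az_deg + 0.5))
})

test_that("coherence noise hits the configured signal fraction", {
  fr <- fix_frustum()
  fl <- flow_field(sample_dot_cloud(200, fr, seed = 1), heading_vector(0))
  expect_identical(apply_coherence(fl, 1, seed = 1)$u_degps, fl$u_degps)
  expect_true(all(apply_coherence(fl, 1, seed = 1)$is_signal))
  expect_error(apply_coherence(fl, 1.2, seed = 1),
               class = "headingflow_invalid_coherence")
  expect_error(stimulus_config(coherence = -0.1),
               class = "headingflow_invalid_coherence")
  # signal fraction ~ Binomial(n, coherence) across seeds
  n_sig <- vapply(1:40, function(s) {
    sum(apply_coherence(fl, 0.15, seed = s)$is_signal)
  }, numeric(1))
  expect_equal(mean(n_sig) / 200, 0.15, tolerance = 0.03)
  # noise dots keep the speed statistics but lose direction
  noisy <- apply_coherence(fl, 0.15, seed = 3)
  expect_equal(median(sqrt(noisy$u_degps^2 + noisy$v_degps^2)),
               median(sqrt(fl$u_degps^2 + fl$v_degps^2)), tolerance = 0.5)
  # coherence 0: mean resultant direction vector shrinks toward 0
  ang <- atan2(noisy$v_degps[!noisy$is_signal], noisy$u_degps[!noisy$is_signal])
  all0 <- apply_coherence(fl, 0, seed = 5)
  ang0 <- atan2(all0$v_degps, all0$u_degps)
  res_len <- sqrt(mean(cos(ang0))^2 + mean(sin(ang0))^2)
  expect_lt(res_len, 3 / sqrt(length(ang0)))  # 3 SE of the uniform null
})

test_that("coherence 0.15 implies the reported signal-to-noise ratio", {
  cfg <- stimulus_config(coherence = 0.15)
  expect_equal(cfg$snr, 0.15 / 0.85)
  expect_lt(abs(cfg$snr - 0.177), 1e-3)
})

test_that("off-axis stereo projection has the textbook disparity geometry", {
  fr <- fix_frustum()
  cloud <- sample_dot_cloud(100, fr, seed = 6)
  # zero eye separation reproduces the monocular projection bit-exactly
  mono <- stereo_project(cloud, stereo_geometry(0, 1), fr)
  expect_identical(mono$x_left, mono$x_right)
  expect_identical(mono$x_left, cloud$x / cloud$z)
  geom <- stereo_geometry(0.063, 1)
  st <- stereo_project(cloud, geom, fr)
  # no vertical parallax by construction
  expect_equal(st$y, cloud$y / cloud$z)
  # independent ray-geometry oracle for the horizontal screen coordinates:
  # eye at (e,0,0) looking down +z through a screen sheared by e/d0
  oracle <- function(e) (cloud$x - e) / cloud$z + e / geom$zero_parallax_distance
  expect_equal(st$x_left, oracle(-0.0315), tolerance = 1e-12)
  expect_equal(st$x_right, oracle(0.0315), tolerance = 1e-12)
  # crossed (negative) disparity nearer than the zero-parallax plane,
  # uncrossed beyond it, zero on it
  near_pts <- cloud$z < 1
  expect_true(all(st$disparity_deg[near_pts] < 0))
  expect_true(all(st$disparity_deg[!near_pts & cloud$z > 1] > 0))
  on_plane <- cloud[1, ]
  on_plane$z <- 1
  on_plane$x <- 0.2
  st0 <- stereo_project(on_plane, geom, fr)
  expect_equal(st0$disparity_deg, 0, tolerance = 1e-12)
})

test_that("flow CSV round-trips", {
  fr <- fix_frustum()
  fl <- simulate_trial(stimulus_config(duration_ms = 200, n_dots = 5), fr, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(fl, path)
  back <- read_flow_csv(path)
  expect_equal(back$u_degps, fl$u_degps, tolerance = 1e-9)
  expect_equal(back$is_signal, fl$is_signal)
})
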