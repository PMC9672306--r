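test_that("place_and_measure reproduces explicit placement geometry", {
  # straight path of length 4R placed at (1.5R, 0) and aimed at the centre:
  # the full diameter chord 2R lies inside
  R <- 10
  spec <- medium_spec(R = R, d = 0.5 * R)
  path <- trajectory(c(0, 4 * R), c(0, 0))
  ev <- place_and_measure(path, spec, rotation = pi, source_angle = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$L_mm, 2 * R, tolerance = 1e-9)
  expect_equal(ev$entry_x_mm, R, tolerance = 1e-9)
  expect_equal(ev$entry_heading, pi, tolerance = 1e-9)

  # aimed tangentially past the disk: no events
  ev <- place_and_measure(path, spec, rotation = pi / 2, source_angle = 0)
  expect_equal(nrow(ev), 0)

  # deterministic: identical inputs give identical events
  a <- place_and_measure(path, spec, rotation = 2.1, source_angle = 0.3)
  b <- place_and_measure(path, spec, rotation = 2.1, source_angle = 0.3)
  expect_identical(a, b)

  # the source angle places the start on the source circle
  placed <- translate_rotate(path, spec$R_e * c(cos(1.2), sin(1.2)), 0)
  expect_equal(
    sqrt(placed$x_mm[1]^2 + placed$y_mm[1]^2), spec$R_e,
    tolerance = 1e-9
  )
})

test_that("mean_path_length averages entry events with bootstrap errors", {
  set.seed(71)
  # ballistic ensemble: long straight paths from the source circle
  rays <- dplyr::bind_rows(lapply(1:25, function(i) {
    trajectory(c(0, 4000), c(0, 0), id = sprintf("ray%02d", i))
  }))
  spec <- medium_spec(R = 100, d = 100)
  res <- mean_path_length(rays, spec, n_placements = 4000, seed = 72)
  expect_s3_class(res, "ip_mpl")
  expect_true(res$valid)
  expect_equal(res$ip_mm, pi * 50)
  expect_equal(res$ratio * res$ip_mm, res$mean_L_mm, tolerance = 1e-12)
  # isotropic rays from a circle sample chords uniformly in impact parameter,
  # mean chord pi*R/2 within Monte Carlo error (bootstrap SE is broad here)
  expect_lt(abs(res$mean_L_mm - pi * 50), 4 * res$se_L_mm + 1)

  # trajectories shorter than the gap never reach the disk: undefined result
  short <- trajectory(c(0, 10), c(0, 0))
  res0 <- mean_path_length(short, spec, n_placements = 50, seed = 73)
  expect_false(res0$valid)
  expect_equal(res0$n_entries, 0)
  expect_true(is.nan(res0$mean_L_mm))

  # the placements denominator rescales the mean by the entry fraction
  res_p <- mean_path_length(rays, spec,
    n_placements = 500, seed = 74,
    denominator = "placements"
  )
  expect_lt(res_p$mean_L_mm, pi * 50)
})

test_that("ip_sweep grids are complete, ordered and deterministic", {
  set.seed(75)
  walks <- generate_ensemble(step_model("exponential", 50), 150,
    n_walkers = 8, length_budget = 2000, seed = 76, source = "random"
  )
  cfg <- ip_config(
    mode = "replay", R_mm = c(60, 30), d_mm = c(40, 90),
    n_placements = 200, bootstrap_B = 50, seed = 77
  )
  tab <- ip_sweep(cfg, data = walks)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$d_mm, c(40, 40, 90, 90))
  expect_equal(tab$R_mm, c(30, 60, 30, 60))
  tab2 <- ip_sweep(cfg, data = walks)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  expect_error(ip_config(mode = "replay", R_mm = numeric(0)),
    class = "ipwalk_config_error"
  )
  expect_error(ip_sweep(cfg, data = NULL), class = "ipwalk_config_error")
})

test_that("entrance-angle profiles separate radial from Lambertian input", {
  # all-radial synthetic events: every entry aimed at the centre
  ang <- runif(500, 0, 2 * pi)
  events <- tibble::tibble(
    entry_x_mm = 100 * cos(ang),
    entry_y_mm = 100 * sin(ang),
    entry_heading = ang + pi
  )
  prof <- entrance_angle_profile(events, n_bins = 9)
  expect_s3_class(prof, "ip_angles")
  centre_bin <- which.max(prof$count)
  expect_equal(prof$theta_mid[centre_bin], 0, tolerance = 1e-9)
  expect_equal(sum(prof$count), 500)
  expect_equal(max(prof$count), 500)

  expect_error(
    entrance_angle_profile(events[0, ], n_bins = 9),
    class = "ipwalk_validation_error"
  )
  expect_error(entrance_angle_profile(events, n_bins = 1),
    class = "ipwalk_config_error"
  )

  # diffuse input after a deep gap is closer to Lambertian than the
  # boundary-launch isotropic case
  iso0 <- simulate_entrance_angles(
    R_mm = 100, d_mm = 0, launch = "isotropic",
    model = step_model("constant", 1e6), budget_mm = 1,
    n_walkers = 2e4, seed = 78
  )
  deep <- simulate_entrance_angles(
    R_mm = 100, d_mm = 100, launch = "isotropic",
    model = step_model("exponential", 50),
    n_walkers = 2e4, seed = 79
  )
  expect_lt(glance(deep)$chisq / glance(deep)$n_events,
            glance(iso0)$chisq / glance(iso0)$n_events)
})
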