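test_that("1D projection returns ordered coordinates", {
  tr <- trajectory(c(0, 1, 2), c(0, 5, 3))
  expect_equal(project_1d(tr, "x"), c(0, 1, 2))
  expect_equal(project_1d(tr, "y"), c(0, 5, 3))
  expect_equal(length(project_1d(tr, "x")), nrow(tr))
})

test_that("turn detection flags direction reversals and ignores plateaus", {
  expect_equal(detect_turns_1d(c(0, 1, 2, 1, 0)), 3L)
  expect_equal(detect_turns_1d(c(0, 1, 1, 2)), integer(0))
  expect_equal(detect_turns_1d(c(5, 5, 5)), integer(0))
  # plateau inside a reversal: direction carried across the flat stretch
  expect_equal(detect_turns_1d(c(0, 2, 2, 1)), 3L)

  # property: equals the brute-force sign-scan oracle on random +/-1 walks
  set.seed(101)
  for (i in 1:10) {
    steps <- sample(c(-1L, 0L, 1L), 1000, replace = TRUE)
    coords <- cumsum(c(0L, steps))
    expect_equal(detect_turns_1d(coords), brute_force_turns(coords))
  }
})

test_that("pooled 2D discretization is lossless on orthogonal-turn paths", {
  # L-shaped path: one turn, both projections flag it
  lshape <- trajectory(c(0, 10, 10), c(0, 0, 10))
  s <- steps_from_turns(lshape)
  expect_equal(attr(s, "turns"), 2L)
  expect_equal(s$step_mm, c(10, 10))

  # straight path: no turns, a single full-length step
  straight <- trajectory(c(0, 5, 10), c(0, 0, 0))
  s <- steps_from_turns(straight)
  expect_equal(s$step_mm, 10)

  # staircase of right angles recovers every generating segment exactly
  set.seed(103)
  seg <- runif(12, 5, 30)
  dirs <- rep(c(1, 2), 6) # alternate +x and +y
  x <- cumsum(c(0, ifelse(dirs == 1, seg, 0)))
  y <- cumsum(c(0, ifelse(dirs == 2, seg, 0)))
  s <- steps_from_turns(trajectory(x, y))
  expect_equal(s$step_mm, seg, tolerance = 1e-12)

  # per-axis view returns 1D displacements for both axes
  pa <- steps_from_turns(lshape, method = "per_axis")
  expect_setequal(unique(pa$axis), c("x", "y"))
})

test_that("isotropic turning is detected with probability about 3/4", {
  expect_equal(turn_detection_probability(), 0.75)
  set.seed(105)
  expect_lt(abs(turn_detection_probability(simulate = TRUE, n = 2e5) - 0.75), 0.005)

  # on real synthetic walks, the detected-turn fraction matches
  set.seed(106)
  lam <- launch_spec("isotropic", origin = c(0, 0))
  frac <- vapply(1:60, function(i) {
    w <- generate_walk(step_model("exponential", 50), lam, 100 * 50)
    length(attr(steps_from_turns(w), "turns")) / (nrow(w) - 2)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.75), 0.02)
})

test_that("corrected pooled estimator recovers the mean free path", {
  set.seed(107)
  walks <- generate_ensemble(step_model("exponential", 50), 200,
    n_walkers = 120, length_budget = 200 * 50, source = "random"
  )
  est <- estimate_mfp_trajset(walks)$pooled
  expect_lt(abs(est$mfp_mm - 50) / 50, 0.1)
  # uncorrected mean is inflated by merged steps (about 4/3)
  raw <- estimate_mfp_trajset(walks, corrected = FALSE)$pooled
  expect_gt(raw$mfp_mm, est$mfp_mm)
  expect_lt(abs(raw$mfp_mm / est$mfp_mm - 4 / 3), 1e-9)

  expect_error(estimate_mfp(tibble::tibble(step_mm = numeric(0))),
    class = "ipwalk_validation_error"
  )
})
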