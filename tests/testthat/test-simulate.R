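test_that("Monte Carlo kernel is seed-deterministic", {
  a <- simulate_ip(R_mm = c(40, 80), R_e_mm = 200, n_walkers = 2e3, seed = 81)
  b <- simulate_ip(R_mm = c(40, 80), R_e_mm = 200, n_walkers = 2e3, seed = 81)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_ip(R_mm = c(40, 80), R_e_mm = 200, n_walkers = 2e3, seed = 82)
  expect_false(identical(a$mean_L_mm, c$mean_L_mm))
})

test_that("kernel agrees with the slow R route (generate, place, clip)", {
  # same physical setting, independent code paths and seeds
  R <- 50
  d <- 50
  budget <- 5000
  set.seed(83)
  walks <- generate_ensemble(step_model("exponential", 50), R + d,
    n_walkers = 1200, length_budget = budget
  )
  ev <- clip_to_entry_events(walks, medium_spec(R = R, d = d))
  # cluster (per-walker) standard error for the event mean
  per_w <- ev |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(L = sum(L_mm), n = dplyr::n())
  m_r <- sum(per_w$L) / sum(per_w$n)
  se_r <- sqrt(sum((per_w$L - m_r * per_w$n)^2)) / sum(per_w$n)

  fast <- simulate_ip(
    R_mm = R, d_mm = d, n_walkers = 5e3,
    budget_mm = budget, seed = 84
  )
  # the R route truncates hard at the budget, the kernel completes the open
  # excursion; at this R the difference is far below the Monte Carlo spread
  expect_lt(
    abs(fast$mean_L_mm - m_r),
    3 * sqrt(fast$se_L_mm^2 + se_r^2) + 0.02 * fast$ip_mm
  )
})

test_that("ballistic Lambertian boundary launch reproduces the Cauchy chord", {
  r <- simulate_ip(
    R_mm = 100, d_mm = 0, launch = "lambertian",
    model = step_model("constant", 1e6), budget_mm = 1,
    n_walkers = 1e5, seed = 85
  )
  expect_lt(abs(r$mean_L_mm - pi * 50), 3 * r$se_L_mm)
  expect_equal(r$n_entries, 1e5)
})

test_that("undefined cells are flagged rather than silently zero", {
  # steps too short to bridge the gap within the budget
  r <- simulate_ip(
    R_mm = 10, d_mm = 500, model = step_model("constant", 1),
    budget_mm = 5, n_walkers = 100, seed = 86
  )
  expect_false(r$valid)
  expect_equal(r$n_entries, 0)
  expect_true(is.na(r$mean_L_mm))
})

test_that("budget convergence check reports agreement under the default", {
  conv <- check_budget_convergence(
    R_mm = 50, d_mm = 100,
    n_walkers = 2e4, seed = 87
  )
  expect_true(conv$converged)
  expect_lt(abs(conv$delta_mm), conv$se_comb_mm)
})

test_that("doubling the walker count shrinks the SE like 1/sqrt(n)", {
  r1 <- simulate_ip(R_mm = 50, d_mm = 100, n_walkers = 8e3, seed = 88)
  r2 <- simulate_ip(R_mm = 50, d_mm = 100, n_walkers = 32e3, seed = 89)
  # quadrupling n halves the SE; allow a generous band around 2
  expect_gt(r1$se_L_mm / r2$se_L_mm, 1.5)
  expect_lt(r1$se_L_mm / r2$se_L_mm, 2.7)
})
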