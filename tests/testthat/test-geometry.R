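test_that("segment_disk_overlap matches closed-form chord geometry", {
  # fully inside
  expect_equal(segment_disk_overlap(-0.5, 0, 0.5, 0, 1), 1)
  # full diameter passage
  expect_equal(segment_disk_overlap(-2, 0, 2, 0, 1), 2)
  # chord at offset h: 2 * sqrt(R^2 - h^2)
  expect_equal(segment_disk_overlap(-2, 0.5, 2, 0.5, 1), sqrt(3), tolerance = 1e-12)
  expect_equal(
    segment_disk_overlap(-2, 0.5, 2, 0.5, 1),
    sampled_disk_overlap(c(-2, 0.5), c(2, 0.5), 1),
    tolerance = 1e-4
  )
  # tangent line contributes nothing; fully outside likewise
  expect_equal(segment_disk_overlap(-2, 1, 2, 1, 1), 0)
  expect_equal(segment_disk_overlap(2, 2, 3, 5, 1), 0)
  # degenerate zero-length segment
  expect_equal(segment_disk_overlap(0.2, 0.1, 0.2, 0.1, 1), 0)
})

test_that("segment_disk_overlap is additive and rotation invariant", {
  set.seed(41)
  for (i in 1:20) {
    p0 <- runif(2, -3, 3)
    p1 <- runif(2, -3, 3)
    R <- runif(1, 0.5, 2)
    full <- segment_disk_overlap(p0[1], p0[2], p1[1], p1[2], R)
    # split at a random interior point
    s <- runif(1)
    pm <- p0 + s * (p1 - p0)
    expect_equal(
      segment_disk_overlap(p0[1], p0[2], pm[1], pm[2], R) +
        segment_disk_overlap(pm[1], pm[2], p1[1], p1[2], R),
      full,
      tolerance = 1e-9
    )
    # rotate both endpoints about the origin
    a <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    q0 <- rot %*% p0
    q1 <- rot %*% p1
    expect_equal(
      segment_disk_overlap(q0[1], q0[2], q1[1], q1[2], R), full,
      tolerance = 1e-9 * max(full, 1)
    )
  }
})

test_that("clip_to_entry_events counts each re-entry as a new event", {
  spec <- medium_spec(R = 1, d = 1)

  # two diameter passages
  path <- trajectory(c(-2, 2, -2), c(0, 0, 1e-4))
  ev <- clip_to_entry_events(path, spec)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$entry_idx, 1:2)
  expect_equal(ev$L_mm, c(2, 2), tolerance = 1e-6)
  expect_true(all(ev$exited))
  # entry points sit on the boundary and the sum matches the segment clip
  expect_equal(sqrt(ev$entry_x_mm^2 + ev$entry_y_mm^2), c(1, 1), tolerance = 1e-9)
  total <- sum(segment_disk_overlap(
    path$x_mm[-3], path$y_mm[-3], path$x_mm[-1], path$y_mm[-1], 1
  ))
  expect_equal(sum(ev$L_mm), total, tolerance = 1e-9)

  # path entirely outside
  expect_equal(nrow(clip_to_entry_events(trajectory(c(2, 3), c(2, 3)), spec)), 0)

  # a path starting inside opens an event at its first vertex
  ev <- clip_to_entry_events(trajectory(c(0, 2), c(0, 0)), spec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$L_mm, 1)
  expect_equal(c(ev$entry_x_mm, ev$entry_y_mm), c(0, 0))
  expect_true(ev$exited)

  # a path ending inside leaves the last event flagged as not exited
  ev <- clip_to_entry_events(trajectory(c(2, 0), c(0, 0)), spec)
  expect_false(ev$exited)
  expect_equal(ev$L_mm, 1)
})

test_that("event lengths agree with summed segment overlaps on random walks", {
  set.seed(43)
  for (i in 1:10) {
    tr <- random_path(60, scale = 1.5)
    R <- runif(1, 0.5, 3)
    ev <- clip_to_entry_events(tr, medium_spec(R = R, d = 1))
    n <- nrow(tr)
    total <- sum(segment_disk_overlap(
      tr$x_mm[-n], tr$y_mm[-n], tr$x_mm[-1], tr$y_mm[-1], R
    ))
    expect_equal(sum(ev$L_mm), total, tolerance = 1e-9)
  }
})

test_that("equal-area annuli follow the sqrt(k/n) closed form", {
  part <- equal_area_annuli(1, 2)
  expect_equal(c(part$r_inner_mm, 1), c(0, sqrt(0.5), 1), tolerance = 1e-12)

  part <- equal_area_annuli(200, 4)
  expect_equal(part$r_outer_mm, 200 * sqrt(1:4 / 4), tolerance = 1e-12)
  expect_equal(part$area_mm2, rep(pi * 200^2 / 4, 4), tolerance = 1e-12)

  expect_equal(nrow(equal_area_annuli(5, 1)), 1)
  expect_error(equal_area_annuli(5, 0), class = "ipwalk_config_error")
})

test_that("per-annulus lengths are exact and conserved under refinement", {
  # diameter of the unit disk split into two equal-area annuli
  tr <- trajectory(c(-1, 1), c(0, 0))
  lens <- path_length_per_annulus(tr, equal_area_annuli(1, 2))
  expect_equal(lens$length_mm, c(2 * sqrt(0.5), 2 - 2 * sqrt(0.5)), tolerance = 1e-12)

  # outside the outer disk: all zero
  far <- trajectory(c(5, 6), c(5, 5))
  expect_equal(path_length_per_annulus(far, equal_area_annuli(1, 3))$length_mm, rep(0, 3))

  # totals are independent of the annulus count and match the disk clip
  set.seed(47)
  tr <- random_path(80, scale = 2)
  totals <- vapply(
    c(1, 4, 13, 40),
    function(n) sum(path_length_per_annulus(tr, equal_area_annuli(2.5, n))$length_mm),
    numeric(1)
  )
  expect_equal(max(totals) - min(totals), 0, tolerance = 1e-9 * max(totals))
  n <- nrow(tr)
  expect_equal(
    totals[1],
    sum(segment_disk_overlap(tr$x_mm[-n], tr$y_mm[-n], tr$x_mm[-1], tr$y_mm[-1], 2.5)),
    tolerance = 1e-9
  )

  # dense-sampling oracle on one random path
  part <- equal_area_annuli(2, 5)
  lens <- path_length_per_annulus(tr, part)
  i0 <- seq_len(n - 1)
  oracle <- vapply(seq_len(5), function(k) {
    sum(vapply(i0, function(i) {
      sampled_disk_overlap(
        c(tr$x_mm[i], tr$y_mm[i]), c(tr$x_mm[i + 1], tr$y_mm[i + 1]),
        part$r_outer_mm[k],
        n = 4e4
      )
    }, numeric(1)))
  }, numeric(1))
  expect_equal(lens$length_mm, diff(c(0, oracle)), tolerance = 2e-3)
})

test_that("ip_mean reproduces the pi*S/P closed forms", {
  expect_equal(ip_mean(pi * 100^2, 2 * pi * 100), pi * 100 / 2, tolerance = 1e-12)
  expect_equal(ip_mean_disk(100), pi * 50)
  expect_equal(ip_mean(4, 8), pi / 2) # square of side 2: pi*a/4
  expect_equal(ip_mean(3, 3), pi) # S = P gives pi in any units
  expect_error(ip_mean(-1, 2), class = "ipwalk_domain_error")
  expect_error(ip_mean(1, 0), class = "ipwalk_domain_error")
})
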