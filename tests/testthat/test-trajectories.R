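test_that("trajectory construction and lengths follow polyline geometry", {
  # legs of 3 mm and 4 mm meeting at a right angle
  tr <- trajectory(c(0, 3, 3), c(0, 0, 4))
  expect_equal(total_length(tr), 7)

  # degenerate repeated points contribute zero length
  expect_equal(total_length(trajectory(c(0, 0), c(0, 0))), 0)
  expect_equal(total_length(trajectory(c(0, 1, 1, 2), c(0, 0, 0, 0))), 2)

  # random path equals the brute-force pairwise sum
  set.seed(11)
  tr <- random_path(100)
  brute <- sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2))
  expect_equal(total_length(tr), brute)

  expect_error(trajectory(c(0, NA), c(0, 1)), class = "ipwalk_validation_error")
  expect_error(total_length(dplyr::bind_rows(
    trajectory(c(0, 1), c(0, 0), id = "a"),
    trajectory(c(0, 1), c(0, 0), id = "b")
  )), class = "ipwalk_validation_error")
})

test_that("file round-trip preserves schema, order and coordinates", {
  set.seed(21)
  data <- dplyr::bind_rows(
    random_path(7, id = "a"),
    random_path(5, id = "b")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(data, path)
  back <- read_trajectories(path)
  expect_equal(as.data.frame(back), as.data.frame(data), tolerance = 1e-12)

  # tab dialect is auto-detected
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(data, path2, delim = "\t")
  expect_equal(read_trajectories(path2)$x_mm, data$x_mm, tolerance = 1e-12)

  # rows arrive ordered by point index even if stored shuffled
  shuffled <- data[sample(nrow(data)), ]
  write_trajectories(shuffled, path)
  expect_equal(read_trajectories(path)$point_idx, data$point_idx)
})

test_that("malformed trajectory files are rejected with informative classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("traj_id,x_mm,y_mm", "a,0,0"), path)
  expect_error(read_trajectories(path), class = "ipwalk_format_error")

  writeLines(c("traj_id,point_idx,x_mm,y_mm", "a,1,0,0", "a,2,NaN,1"), path)
  expect_error(read_trajectories(path), class = "ipwalk_validation_error")

  expect_error(read_trajectories(file.path(tempdir(), "absent.csv")),
    class = "ipwalk_format_error"
  )
})

test_that("translate_rotate is a rigid motion anchored at the new start", {
  tr <- trajectory(c(0, 1), c(0, 0))
  moved <- translate_rotate(tr, c(5, 0), 0)
  expect_equal(moved$x_mm, c(5, 6))
  expect_equal(moved$y_mm, c(0, 0))

  quarter <- translate_rotate(tr, c(0, 0), pi / 2)
  expect_equal(quarter$x_mm, c(0, 0), tolerance = 1e-12)
  expect_equal(quarter$y_mm, c(0, 1), tolerance = 1e-12)

  # distances between all vertex pairs are preserved for a random motion
  set.seed(31)
  tr <- random_path(40)
  out <- translate_rotate(tr, c(-17, 42), runif(1, 0, 2 * pi))
  expect_equal(traj_dist_matrix(out), traj_dist_matrix(tr), tolerance = 1e-9)
  expect_equal(out$x_mm[1], -17)
  expect_equal(out$y_mm[1], 42)
  expect_lt(
    abs(total_length(out) - total_length(tr)),
    1e-9 * total_length(tr)
  )

  # composing two rotations about the same start equals their sum
  a <- runif(1, 0, 2 * pi)
  b <- runif(1, 0, 2 * pi)
  two_step <- translate_rotate(translate_rotate(tr, c(1, 2), a), c(1, 2), b)
  one_step <- translate_rotate(tr, c(1, 2), a + b)
  expect_equal(two_step$x_mm, one_step$x_mm, tolerance = 1e-9)
  expect_equal(two_step$y_mm, one_step$y_mm, tolerance = 1e-9)
})
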