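# Independent oracles used across tests. These deliberately avoid the package
# implementations they are checked against.

# dense point-sampling estimate of the length of a segment inside a disk
sampled_disk_overlap <- function(p0, p1, R, n = 2e5) {
  t <- (seq_len(n) - 0.5) / n
  x <- p0[1] + t * (p1[1] - p0[1])
  y <- p0[2] + t * (p1[2] - p0[2])
  mean(x^2 + y^2 <= R^2) * sqrt(sum((p1 - p0)^2))
}

# brute-force scan for direction reversals in a 1D coordinate series
brute_force_turns <- function(coords) {
  d <- diff(coords)
  out <- integer(0)
  last <- 0
  for (i in seq_along(d)) {
    s <- sign(d[i])
    if (s != 0) {
      if (last != 0 && s == -last) out <- c(out, i)
      last <- s
    }
  }
  out
}

# pairwise distance matrix of a trajectory's vertices
traj_dist_matrix <- function(data) {
  as.matrix(dist(cbind(data$x_mm, data$y_mm)))
}

# a random jagged test path
random_path <- function(n, scale = 100, id = "rnd") {
  trajectory(cumsum(runif(n, -scale, scale)), cumsum(runif(n, -scale, scale)),
    id = id
  )
}
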