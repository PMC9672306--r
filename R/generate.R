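#' Default walk length budget
#'
#' Walks are terminated at the first step whose cumulative length reaches the
#' budget (that step is kept whole). The default is large relative to both
#' the step scale and the geometry so that truncation cannot bias the mean
#' path length: `max(100 * mfp, 20 * R_e)`. A convergence check is available
#' via [check_budget_convergence()].
#'
#' @param mfp mean free path in mm.
#' @param R_e source-circle radius in mm.
#' @return Budget in mm.
#' @export
default_length_budget <- function(mfp, R_e) {
  max(100 * mfp, 20 * R_e)
}

#' Generate one synthetic random walk
#'
#' The walk starts at `launch$origin` with a first heading drawn from the
#' launch mode; every subsequent heading is an independent uniform draw on
#' `[0, 2*pi)` (fully isotropic turning — the turning-angle distribution does
#' not affect the invariance property). Generation stops at the first step
#' whose cumulative length reaches `length_budget`; that step is kept whole,
#' so the total length is >= the budget.
#'
#' @param model a [step_model()].
#' @param launch a [launch_spec()].
#' @param length_budget total path length budget in mm (> 0).
#' @param id trajectory label.
#' @return A trajectory tibble (see [trajectory()]).
#' @export
generate_walk <- function(model, launch, length_budget, id = "walk_1") {
  stopifnot(inherits(model, "step_model"), inherits(launch, "launch_spec"))
  if (!is.numeric(length_budget) || length_budget <= 0) {
    abort("length_budget must be > 0", class = "ipwalk_config_error")
  }
  steps <- numeric(0)
  while (sum(steps) < length_budget) {
    need <- max(16, ceiling((length_budget - sum(steps)) / model$mfp * 1.5))
    steps <- c(steps, sample_steps(model, need))
  }
  k <- which(cumsum(steps) >= length_budget)[1]
  steps <- steps[seq_len(k)]
  headings <- c(sample_heading(launch, 1), runif(k - 1, 0, 2 * pi))
  x <- launch$origin[1] + cumsum(c(0, steps * cos(headings)))
  y <- launch$origin[2] + cumsum(c(0, steps * sin(headings)))
  trajectory(x, y, id = id)
}

#' Generate an ensemble of synthetic walkers on a source circle
#'
#' Launches `n_walkers` independent walks from the circle of radius
#' `launch_circle_radius`. By default every walker starts at the fixed point
#' `(radius, 0)`: with an isotropic (uniform) first heading this is
#' statistically equivalent, by circular symmetry, to a uniform random point
#' on the circle, and reduces variance. Set `source = "random"` to draw a
#' uniform source angle per walker.
#'
#' @param model a [step_model()].
#' @param launch_circle_radius source-circle radius `R_e` in mm.
#' @param mode launch heading mode, `"isotropic"` or `"lambertian"`.
#' @param n_walkers number of walkers (>= 1).
#' @param length_budget walk length budget in mm; default
#'   [default_length_budget()].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param source `"fixed"` (start at `(R_e, 0)`) or `"random"` (uniform
#'   angle on the circle).
#' @return A trajectory tibble with ids `walk_000001, ...`.
#' @export
generate_ensemble <- function(model, launch_circle_radius,
                              mode = c("isotropic", "lambertian"),
                              n_walkers, length_budget = NULL, seed = NULL,
                              source = c("fixed", "random")) {
  mode <- match.arg(mode)
  source <- match.arg(source)
  stopifnot(inherits(model, "step_model"), launch_circle_radius > 0)
  if (!is.numeric(n_walkers) || n_walkers < 1) {
    abort("n_walkers must be >= 1", class = "ipwalk_config_error")
  }
  n_walkers <- as.integer(n_walkers)
  length_budget <- length_budget %||%
    default_length_budget(model$mfp, launch_circle_radius)
  if (!is.null(seed)) set.seed(seed)

  alpha <- if (source == "random") runif(n_walkers, 0, 2 * pi) else rep(0, n_walkers)
  ox <- launch_circle_radius * cos(alpha)
  oy <- launch_circle_radius * sin(alpha)
  first_heading <- if (mode == "isotropic") {
    runif(n_walkers, 0, 2 * pi)
  } else {
    (alpha + pi) + asin(2 * runif(n_walkers) - 1)
  }

  # draw steps as walker x step matrices, chunked; top up rare long walkers
  m0 <- ceiling(length_budget / model$mfp + 10 * sqrt(length_budget / model$mfp)) + 2
  walks <- purrr::map(seq_len(n_walkers), function(w) {
    steps <- sample_steps(model, m0)
    while (sum(steps) < length_budget) {
      steps <- c(steps, sample_steps(model, m0))
    }
    k <- which(cumsum(steps) >= length_budget)[1]
    steps <- steps[seq_len(k)]
    headings <- c(first_heading[w], runif(k - 1, 0, 2 * pi))
    list(
      x = ox[w] + cumsum(c(0, steps * cos(headings))),
      y = oy[w] + cumsum(c(0, steps * sin(headings)))
    )
  })
  lens <- vapply(walks, function(p) length(p$x), integer(1))
  ids <- sprintf("walk_%06d", seq_len(n_walkers))
  tibble(
    traj_id = rep(ids, lens),
    point_idx = unlist(lapply(lens, seq_len), use.names = FALSE),
    x_mm = unlist(lapply(walks, `[[`, "x"), use.names = FALSE),
    y_mm = unlist(lapply(walks, `[[`, "y"), use.names = FALSE)
  )
}
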