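#' Step-length model for synthetic walkers
#'
#' Describes the distribution of single step lengths \eqn{\ell} of a random
#' walker. Supported families:
#' * `exponential` (Lambert-Beer): density `exp(-l/mfp)/mfp`, the one family
#'   for which the invariance property holds rigorously under Lambertian
#'   boundary input;
#' * `pareto`: heavy-tailed, density proportional to `l^-mu` for
#'   `l >= min_step`, mean `min_step * (mu - 1) / (mu - 2)` (finite only for
#'   `mu > 2`); samples are clamped at `1e4 * mfp` to keep walk budgets
#'   finite;
#' * `constant`: every step exactly `mfp` long.
#'
#' When `family = "pareto"` and `min_step` is not given, it is solved from
#' the target mean free path; `mu <= 2` is refused since the implied mean
#' would be infinite.
#'
#' @param family one of `"exponential"`, `"pareto"`, `"constant"`.
#' @param mfp mean free path (mean step length) in mm, > 0.
#' @param pareto_mu Pareto tail exponent (> 2 when matching a finite `mfp`).
#' @param min_step Pareto lower cutoff in mm; solved from `mfp` if omitted.
#' @return An object of class `step_model`.
#' @examples
#' step_model("exponential", mfp = 50)
#' step_model("pareto", mfp = 50, pareto_mu = 2.5)
#' @export
step_model <- function(family = c("exponential", "pareto", "constant"),
                       mfp = 50, pareto_mu = NULL, min_step = NULL) {
  family <- match.arg(family)
  if (!is.numeric(mfp) || length(mfp) != 1 || !is.finite(mfp) || mfp <= 0) {
    abort("mfp must be a single positive number", class = "ipwalk_config_error")
  }
  if (family == "pareto") {
    if (is.null(pareto_mu) || !is.finite(pareto_mu) || pareto_mu <= 1) {
      abort("pareto requires tail exponent pareto_mu > 1",
        class = "ipwalk_config_error"
      )
    }
    if (is.null(min_step)) {
      if (pareto_mu <= 2) {
        abort(
          "pareto with mu <= 2 has infinite mean: cannot match a finite mfp",
          class = "ipwalk_config_error"
        )
      }
      min_step <- mfp * (pareto_mu - 2) / (pareto_mu - 1)
    }
    if (min_step <= 0) {
      abort("min_step must be > 0", class = "ipwalk_config_error")
    }
  }
  structure(
    list(
      family = family, mfp = mfp,
      pareto_mu = if (family == "pareto") pareto_mu else NA_real_,
      min_step = if (family == "pareto") min_step else NA_real_,
      step_cap = 1e4 * mfp
    ),
    class = "step_model"
  )
}

#' @export
print.step_model <- function(x, ...) {
  extra <- if (x$family == "pareto") {
    sprintf(" (mu = %g, min_step = %.4g mm)", x$pareto_mu, x$min_step)
  } else {
    ""
  }
  cat(sprintf("<step_model> %s, mfp = %g mm%s\n", x$family, x$mfp, extra))
  invisible(x)
}

# encode for the C++ kernel
step_family_code <- function(model) {
  match(model$family, c("exponential", "pareto", "constant")) - 1L
}

#' Sample step lengths from a step model
#'
#' @param model a [step_model()].
#' @param n number of draws (>= 1).
#' @return Numeric vector of `n` strictly positive step lengths in mm.
#' @examples
#' set.seed(1)
#' mean(sample_steps(step_model("exponential", 50), 1e4))
#' @export
sample_steps <- function(model, n) {
  stopifnot(inherits(model, "step_model"), n >= 1)
  switch(model$family,
    exponential = rexp(n, rate = 1 / model$mfp),
    pareto = pmin(
      model$min_step * runif(n)^(-1 / (model$pareto_mu - 1)),
      model$step_cap
    ),
    constant = rep(model$mfp, n)
  )
}

#' Launch specification for a walker
#'
#' A walker is launched from `origin` (a point on a circle about `center`)
#' with a first heading drawn either isotropically (uniform on `[0, 2*pi)`)
#' or from a Lambertian profile about the inward normal: the angle `theta`
#' to the normal has density `cos(theta)/2` on `(-pi/2, pi/2)`, sampled as
#' `theta = asin(2u - 1)`.
#'
#' @param mode `"isotropic"` or `"lambertian"`.
#' @param origin numeric length-2 launch point in mm.
#' @param center numeric length-2 centre of the circle the origin sits on
#'   (default the origin of coordinates); defines the inward normal.
#' @return An object of class `launch_spec`.
#' @export
launch_spec <- function(mode = c("isotropic", "lambertian"),
                        origin = c(0, 0), center = c(0, 0)) {
  mode <- match.arg(mode)
  stopifnot(length(origin) == 2, length(center) == 2, is.finite(origin), is.finite(center))
  normal_angle <- atan2(center[2] - origin[2], center[1] - origin[1])
  structure(
    list(mode = mode, origin = as.numeric(origin), normal_angle = normal_angle),
    class = "launch_spec"
  )
}

#' Sample launch headings
#'
#' @param launch a [launch_spec()].
#' @param n number of headings to draw.
#' @return Numeric vector of headings in radians (absolute, from the +x axis).
#' @export
sample_heading <- function(launch, n = 1) {
  stopifnot(inherits(launch, "launch_spec"), n >= 1)
  if (launch$mode == "isotropic") {
    runif(n, 0, 2 * pi)
  } else {
    launch$normal_angle + asin(2 * runif(n) - 1)
  }
}
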