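#' Invariance-property mean path length
#'
#' For a bounded convex or non-convex 2D domain of surface `S` and perimeter
#' `P`, the invariance property predicts a mean total path length
#' \deqn{\langle L \rangle_{IP} = \pi S / P}
#' for random walkers entering through the boundary with a Lambertian
#' (cosine) angular profile under statistical equilibrium, independent of the
#' step-length distribution. The ballistic special case is the Cauchy/Dirac
#' mean-chord theorem. For a disk of radius `R` this reduces to `pi * R / 2`;
#' for a square of side `a`, `pi * a / 4`.
#'
#' @param S surface area (mm^2, > 0).
#' @param P perimeter (mm, > 0).
#' @return The predicted mean path length, `pi * S / P`.
#' @examples
#' ip_mean(pi * 100^2, 2 * pi * 100) # disk R = 100: pi * 50
#' ip_mean(4, 8) # square of side 2: pi / 2
#' @export
ip_mean <- function(S, P) {
  if (!is.numeric(S) || !is.numeric(P) || any(S <= 0) || any(P <= 0)) {
    abort("S and P must be positive", class = "ipwalk_domain_error")
  }
  pi * S / P
}

#' @rdname ip_mean
#' @param R disk radius in mm (> 0).
#' @export
ip_mean_disk <- function(R) {
  if (!is.numeric(R) || any(R <= 0)) {
    abort("R must be positive", class = "ipwalk_domain_error")
  }
  pi * R / 2
}
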