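#' Tidy and glance methods for ipwalk result objects
#'
#' `tidy()` returns the per-cell / per-annulus / per-bin table as a plain
#' tibble; `glance()` returns a one-row summary.
#'
#' @param x an `ip_mpl`, `ip_density` or `ip_angles` object.
#' @param ... ignored.
#' @return A tibble.
#' @name ipwalk-tidiers
NULL

#' @rdname ipwalk-tidiers
#' @export
tidy.ip_mpl <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname ipwalk-tidiers
#' @export
glance.ip_mpl <- function(x, ...) {
  ok <- x$valid
  tibble(
    n_cells = nrow(x),
    n_valid = sum(ok),
    max_abs_ratio_dev = if (any(ok)) max(abs(x$ratio[ok] - 1)) else NA_real_,
    total_entries = sum(x$n_entries)
  )
}

#' @rdname ipwalk-tidiers
#' @export
tidy.ip_density <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname ipwalk-tidiers
#' @export
glance.ip_density <- function(x, ...) {
  tibble(
    n_annuli = nrow(x),
    total_length_mm = sum(x$length_mm),
    max_rel_dev = max(abs(x$density / mean(x$density) - 1)),
    norm_ok = attr(x, "norm_ok")
  )
}

#' @rdname ipwalk-tidiers
#' @export
tidy.ip_angles <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname ipwalk-tidiers
#' @export
glance.ip_angles <- function(x, ...) {
  tibble(
    n_events = attr(x, "n_events"),
    chisq = attr(x, "chisq"),
    df = attr(x, "df"),
    p_value = attr(x, "p_value")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
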