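#' Radionuclide decay parameters
#'
#' A nuclide carries the physical half-life (minutes) and the derived decay
#' constant used throughout decay correction and residence-time integration.
#'
#' @param name Label, e.g. `"Ga-68"`.
#' @param half_life_min Physical half-life in minutes; must be positive.
#'
#' @return An object of class `"nuclide"` with fields `name`,
#'   `half_life_min` and `lambda_per_min` (`log(2)/half_life_min`).
#' @examples
#' ga68()
#' nuclide("F-18", 109.77)
#' @export
nuclide <- function(name, half_life_min) {
  if (!is.numeric(half_life_min) || length(half_life_min) != 1L ||
      !is.finite(half_life_min) || half_life_min <= 0) {
    .stopf("physical half-life must be a single positive number (minutes)")
  }
  structure(
    list(name = as.character(name),
         half_life_min = half_life_min,
         lambda_per_min = log(2) / half_life_min),
    class = "nuclide"
  )
}

#' @rdname nuclide
#' @details `ga68()` is the bundled gallium-68 preset (68-min half-life),
#'   the label used by the analyses this package was written for.
#' @export
ga68 <- function() nuclide("Ga-68", 68)

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %.4g min, lambda = %.6g /min\n",
              x$name, x$half_life_min, x$lambda_per_min))
  invisible(x)
}

# Physical mean life expressed in hours; upper bound for any residence-time
# budget of this nuclide (1.635 h for Ga-68).
mean_life_hours <- function(nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  nuclide$half_life_min / log(2) / 60
}
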