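#' Time-integrated activity coefficient of a fitted model
#'
#' Integrates a fitted sum of exponentials (in fraction-of-injected-activity
#' units) from zero to infinity, applying physical decay exactly once:
#' for a model fitted in the decay-corrected domain,
#' `TIAC = sum_i A_i / (lambda_i + lambda_p)`; for a model fitted on raw
#' (decaying) data the fitted rates already contain physical decay and
#' `TIAC = sum_i A_i / lambda_i`.  The result is converted from minutes to
#' hours — the "normalized number of disintegrations" / residence time of
#' MIRD dosimetry.
#'
#' @param model An [fit_sum_of_exponentials()] result in `"FIA"` units.
#' @param nuclide The [nuclide()] supplying the physical decay constant.
#' @return TIAC in hours.
#' @examples
#' # constant retention (A = 1, lambda = 0): physical decay alone ->
#' # 68/log(2) min = 1.635 h for Ga-68
#' tt <- c(1, 10, 20, 40, 100, 200)
#' fit <- fit_sum_of_exponentials(tac("whole body", tt, rep(1, 6)))
#' compute_tiac(fit, ga68())
#' @export
compute_tiac <- function(model, nuclide) {
  stopifnot(inherits(model, "expfit"), inherits(nuclide, "nuclide"))
  if (!identical(model$units, "FIA")) {
    .stopf("TIAC requires a model in FIA units, got '%s'", model$units)
  }
  A <- model$terms$A
  lam <- model$terms$lambda_per_min
  denom <- lam + if (model$decay_corrected) nuclide$lambda_per_min else 0
  active <- A > 0
  if (any(active & denom <= 0)) {
    .stopf("divergent integral: term with A > 0 has lambda + lambda_p = 0")
  }
  sum(A[active] / denom[active]) / 60
}

#' Residence-time set for the source organs
#'
#' Container mapping source organs to their time-integrated activity
#' coefficients (hours), with an optional separately-held remainder-of-body
#' entry.
#'
#' @param organs Named numeric vector, organ -> TIAC in hours, all `>= 0`.
#' @param remainder_of_body Optional remainder-of-body TIAC, hours.
#' @return Object of class `"tiac_set"`.
#' @export
residence_time_set <- function(organs, remainder_of_body = NULL) {
  organs <- unlist(organs)
  if (is.null(names(organs)) || any(!nzchar(names(organs)))) {
    .stopf("organs must be a named vector (organ -> hours)")
  }
  if (any(!is.finite(organs)) || any(organs < 0)) {
    .stopf("all residence times must be finite and >= 0")
  }
  if (!is.null(remainder_of_body)) {
    stopifnot(is.numeric(remainder_of_body), remainder_of_body >= 0)
  }
  structure(list(organs = organs, remainder_of_body = remainder_of_body),
            class = "tiac_set")
}

#' @export
print.tiac_set <- function(x, ...) {
  cat("<tiac_set> residence times (h):\n")
  df <- data.frame(tiac_h = sprintf("%.4f", x$organs))
  rownames(df) <- names(x$organs)
  print(df)
  if (!is.null(x$remainder_of_body)) {
    cat(sprintf("Remainder of body: %.4f h\n", x$remainder_of_body))
  }
  cat(sprintf("Total: %.4f h\n", total_tiac(x)))
  invisible(x)
}

#' @rdname residence_time_set
#' @param x A `"tiac_set"`.
#' @export
total_tiac <- function(x) {
  stopifnot(inherits(x, "tiac_set"))
  sum(x$organs) + if (is.null(x$remainder_of_body)) 0 else x$remainder_of_body
}

#' Assert the physical residence-time bound
#'
#' The total of all residence times (remainder included) cannot exceed the
#' physical mean life of the nuclide expressed in hours (`T_p/ln 2`, i.e.
#' 1.635 h for a 68-min half-life): each disintegration happens once.
#'
#' @param x A [residence_time_set()].
#' @param nuclide A [nuclide()].
#' @param tol Numerical slack.
#' @return Invisibly `TRUE`; errors if the bound is violated.
#' @export
check_tiac_bound <- function(x, nuclide, tol = 1e-9) {
  bound <- mean_life_hours(nuclide)
  tot <- total_tiac(x)
  if (tot > bound + tol) {
    .stopf("total residence time %.4f h exceeds physical bound %.4f h",
           tot, bound)
  }
  invisible(TRUE)
}

#' Remainder-of-body residence time
#'
#' `remainder = whole-body TIAC - sum(source-organ TIACs)`, urinary bladder
#' included in the subtraction.  A negative remainder means the listed
#' organs integrate to more than the whole body and is rejected.
#'
#' @param whole_body_tiac Whole-body TIAC, hours.
#' @param organ_set A [residence_time_set()] of the listed source organs
#'   (its own remainder entry, if any, is ignored).
#' @return Remainder-of-body TIAC, hours.
#' @export
remainder_of_body_tiac <- function(whole_body_tiac, organ_set) {
  stopifnot(is.numeric(whole_body_tiac), length(whole_body_tiac) == 1L,
            inherits(organ_set, "tiac_set"))
  organ_sum <- sum(organ_set$organs)
  rem <- whole_body_tiac - organ_sum
  if (rem < 0) {
    biggest <- names(sort(organ_set$organs, decreasing = TRUE))
    .stopf(paste0("source organs integrate to %.4f h, exceeding the ",
                  "whole-body TIAC %.4f h (largest contributors: %s)"),
           organ_sum, whole_body_tiac,
           paste(utils::head(biggest, 3), collapse = ", "))
  }
  rem
}
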