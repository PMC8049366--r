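#' Time-activity curve
#'
#' Sampled activity of one organ (or blood/plasma) versus time after
#' injection.  Values are either fractions of injected activity (`"FIA"`,
#' dimensionless) or concentrations (`"kBq/mL"`).  The decay-correction
#' state is tracked explicitly so physical decay can never be applied (or
#' removed) twice.
#'
#' @param organ Organ label.
#' @param times Mid-frame times, minutes post-injection; strictly
#'   increasing, all `>= 0`.
#' @param values Activity values, same length as `times`, all `>= 0`.
#' @param units `"FIA"` or `"kBq/mL"`.
#' @param decay_corrected Logical flag; `TRUE` if physical decay has been
#'   removed from `values`.
#' @param frame_durations Optional acquisition durations per frame, seconds.
#'
#' @return An object of class `"tac"`.
#' @examples
#' tac("liver", c(1, 10, 20), c(0.05, 0.04, 0.03))
#' @export
tac <- function(organ, times, values, units = c("FIA", "kBq/mL"),
                decay_corrected = TRUE, frame_durations = NULL) {
  units <- match.arg(units)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    .stopf("times and values must have equal length")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    .stopf("times must be finite and >= 0 (minutes post-injection)")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    .stopf("times must be strictly increasing")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    .stopf("activity values must be finite and >= 0")
  }
  if (!is.null(frame_durations)) {
    frame_durations <- as.numeric(frame_durations)
    if (length(frame_durations) != length(times) || any(frame_durations <= 0)) {
      .stopf("frame_durations must be positive and match the number of frames")
    }
  }
  structure(
    list(organ = as.character(organ), times = times, values = values,
         units = units, decay_corrected = isTRUE(decay_corrected),
         frame_durations = frame_durations),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s: %d samples over %g-%g min [%s, %s]\n",
              x$organ, length(x$times), min(x$times), max(x$times), x$units,
              if (x$decay_corrected) "decay-corrected" else "not decay-corrected"))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(organ = x$organ, time_min = x$times, value = x$values,
             units = x$units, decay_corrected = x$decay_corrected,
             stringsAsFactors = FALSE)
}

#' Apply or remove physical decay correction
#'
#' Multiplies (`direction = "correct"`) or divides
#' (`direction = "uncorrect"`) each sample by `exp(lambda_p * t)`, where
#' `lambda_p` is the nuclide's physical decay constant, and toggles the
#' curve's `decay_corrected` flag.  Correcting an already-corrected curve
#' (or vice versa) is an error, which is the point of carrying the flag.
#'
#' @param curve A [tac()].
#' @param nuclide A [nuclide()].
#' @param direction `"correct"` or `"uncorrect"`.
#' @return The transformed [tac()] with the flag toggled; times unchanged.
#' @examples
#' raw <- tac("blood", c(0, 68), c(1, 0.5), decay_corrected = FALSE)
#' decay_correct(raw, ga68())  # value at one half-life doubles to 1.0
#' @export
decay_correct <- function(curve, nuclide, direction = c("correct", "uncorrect")) {
  stopifnot(inherits(curve, "tac"), inherits(nuclide, "nuclide"))
  direction <- match.arg(direction)
  if (direction == "correct" && curve$decay_corrected) {
    .stopf("curve '%s' is already decay-corrected; refusing double correction",
           curve$organ)
  }
  if (direction == "uncorrect" && !curve$decay_corrected) {
    .stopf("curve '%s' is not decay-corrected; nothing to uncorrect",
           curve$organ)
  }
  fac <- exp(nuclide$lambda_per_min * curve$times)
  curve$values <- if (direction == "correct") curve$values * fac
                  else curve$values / fac
  curve$decay_corrected <- !curve$decay_corrected
  curve
}

#' Standardized uptake value
#'
#' `SUV = concentration / (injected activity / body mass)`, with tissue
#' density taken as 1 g/mL, so a concentration numerically equal to the
#' injected activity spread over the body mass gives SUV = 1.
#'
#' @param concentration_kbq_ml Activity concentration(s), kBq/mL.
#' @param injected_activity_mbq Injected activity, MBq.
#' @param body_weight_kg Body weight, kg.
#' @return Dimensionless SUV, vectorized over `concentration_kbq_ml`.
#' @examples
#' compute_suv(231, 162, 80)  # ~114, a typical peak-bladder value
#' @export
compute_suv <- function(concentration_kbq_ml, injected_activity_mbq,
                        body_weight_kg) {
  if (!is.numeric(injected_activity_mbq) || injected_activity_mbq <= 0) {
    .stopf("injected activity must be > 0 MBq")
  }
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0) {
    .stopf("body weight must be > 0 kg")
  }
  if (any(concentration_kbq_ml < 0)) .stopf("concentration must be >= 0")
  # kBq/mL * (kg * 1000 g) / (MBq * 1000 kBq) with 1 g/mL density
  concentration_kbq_ml * body_weight_kg / injected_activity_mbq
}
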