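#' Venous blood sample series
#'
#' Holds the gamma-counter and radio-HPLC measurements from serial venous
#' sampling: whole-blood and plasma activity concentrations, the optional
#' protein-free supernatant concentration, and the optional parent
#' (unmetabolized tracer) fraction.
#'
#' @param times Sample times, minutes; strictly increasing.
#' @param whole_blood,plasma Activity concentrations (MBq/mL internally;
#'   any consistent unit works for the ratio operations), `>= 0`.
#' @param supernatant Optional protein-free supernatant concentration.
#' @param parent_fraction Optional parent fraction in `[0, 1]` (NA allowed
#'   where not assayed).
#' @param decay_corrected Logical flag for the concentration columns.
#' @return Object of class `"plasma_series"`.
#' @export
plasma_sample_series <- function(times, whole_blood, plasma,
                                 supernatant = NULL, parent_fraction = NULL,
                                 decay_corrected = TRUE) {
  times <- as.numeric(times)
  n <- length(times)
  if (is.unsorted(times, strictly = TRUE)) {
    .stopf("sample times must be strictly increasing")
  }
  chk <- function(x, nm, optional = FALSE) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != n) .stopf("%s must match the number of sample times", nm)
    if (any(!is.na(x) & x < 0)) .stopf("%s must be >= 0", nm)
    x
  }
  whole_blood <- chk(whole_blood, "whole_blood")
  plasma <- chk(plasma, "plasma")
  supernatant <- chk(supernatant, "supernatant")
  parent_fraction <- chk(parent_fraction, "parent_fraction")
  if (!is.null(parent_fraction) && any(parent_fraction > 1, na.rm = TRUE)) {
    .stopf("parent_fraction must be in [0, 1]")
  }
  structure(
    list(times = times, whole_blood = whole_blood, plasma = plasma,
         supernatant = supernatant, parent_fraction = parent_fraction,
         decay_corrected = isTRUE(decay_corrected)),
    class = "plasma_series"
  )
}

#' @export
print.plasma_series <- function(x, ...) {
  cat(sprintf("<plasma_series> %d samples over %g-%g min%s%s\n",
              length(x$times), min(x$times), max(x$times),
              if (is.null(x$supernatant)) "" else ", with supernatant",
              if (is.null(x$parent_fraction)) "" else ", with parent fraction"))
  invisible(x)
}

#' @export
as.data.frame.plasma_series <- function(x, ...) {
  data.frame(time_min = x$times, whole_blood = x$whole_blood,
             plasma = x$plasma,
             supernatant = if (is.null(x$supernatant)) NA_real_ else x$supernatant,
             parent_fraction = if (is.null(x$parent_fraction)) NA_real_
                               else x$parent_fraction)
}

#' Plasma-to-blood activity ratio
#'
#' Per-sample ratio `plasma / whole blood` plus its mean and SD.  Samples
#' with zero whole-blood activity are excluded with a warning.
#'
#' @param series A [plasma_sample_series()].
#' @return List with `ratios` (data frame time/ratio), `mean`, `sd`.
#' @export
plasma_to_blood_ratio <- function(series) {
  stopifnot(inherits(series, "plasma_series"))
  ok <- is.finite(series$whole_blood) & series$whole_blood > 0 &
        is.finite(series$plasma)
  if (any(!ok)) {
    .warnf("%d sample(s) with zero/missing whole-blood activity excluded",
           sum(!ok))
  }
  if (!any(ok)) .stopf("no usable samples for the plasma-to-blood ratio")
  r <- series$plasma[ok] / series$whole_blood[ok]
  list(ratios = data.frame(time_min = series$times[ok], ratio = r),
       mean = mean(r), sd = stats::sd(r))
}

#' Plasma protein-bound fraction
#'
#' Per-sample bound percentage `100 * (plasma - supernatant) / plasma`.
#' A supernatant exceeding plasma by more than 5% indicates an assay
#' inconsistency and is rejected.
#'
#' @param series A [plasma_sample_series()] with supernatant values.
#' @return Data frame with `time_min` and `bound_percent`.
#' @export
protein_bound_fraction <- function(series) {
  stopifnot(inherits(series, "plasma_series"))
  if (is.null(series$supernatant)) .stopf("series has no supernatant column")
  ok <- is.finite(series$plasma) & series$plasma > 0 &
        is.finite(series$supernatant)
  p <- series$plasma[ok]
  s <- series$supernatant[ok]
  if (any(s > p * 1.05)) {
    .stopf("supernatant exceeds plasma by > 5%%: assay inconsistency")
  }
  data.frame(time_min = series$times[ok], bound_percent = 100 * (p - s) / p)
}

#' Fit a monotone parent-fraction curve
#'
#' Fits the radio-HPLC parent fraction with the single-exponential-plus-
#' plateau form `f(t) = A exp(-k t) + c` (`A, k, c >= 0`), which is
#' monotone nonincreasing by construction; evaluation clamps to `[0, 1]`.
#' Non-monotone input beyond tolerance still yields a fit but is flagged.
#'
#' @param times Sample times, minutes.
#' @param fractions Parent fractions in `[0, 1]`.
#' @param plateau If non-`NULL`, fixes the plateau `c` at this value
#'   (e.g. 0), leaving a 2-parameter fit.
#' @return Object of class `"parent_fraction_fit"` with `params` (A, k, c),
#'   `support` (fitted time range), `residuals`, `monotone_flag`.
#' @examples
#' f <- fit_parent_fraction(c(1, 10), c(0.792, 0.043), plateau = 0)
#' predict(f, c(1, 10))
#' @export
fit_parent_fraction <- function(times, fractions, plateau = NULL) {
  times <- as.numeric(times)
  fractions <- as.numeric(fractions)
  ok <- is.finite(times) & is.finite(fractions)
  times <- times[ok]; fractions <- fractions[ok]
  if (any(fractions < 0 | fractions > 1)) {
    .stopf("parent fractions must lie in [0, 1]")
  }
  npar <- if (is.null(plateau)) 3L else 2L
  if (length(times) < npar) {
    .stopf("need at least %d samples for a %d-parameter fit", npar, npar)
  }
  monotone_flag <- any(diff(fractions[order(times)]) > 0.05)
  if (monotone_flag) {
    .warnf("parent fractions increase with time beyond tolerance; fit flagged")
  }

  if (max(fractions) - min(fractions) < 1e-12) {
    # degenerate constant data
    params <- c(A = 0, k = 0, c = fractions[1L])
  } else {
    resfun <- function(p) {
      cc <- if (is.null(plateau)) p[3L] else plateau
      fractions - (p[1L] * exp(-p[2L] * times) + cc)
    }
    # seedless multi-start over decay-rate guesses
    best <- NULL
    for (k0 in c(0.01, 0.05, 0.2, 0.5, 1)) {
      p0 <- c(max(fractions), k0, if (is.null(plateau)) min(fractions) else NULL)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = p0, fn = resfun, lower = rep(0, npar),
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-14, ptol = 1e-14, maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
        best <- fit
      }
    }
    if (is.null(best)) .stopf("parent-fraction fit failed")
    p <- best$par
    params <- c(A = p[1L], k = p[2L],
                c = if (is.null(plateau)) p[3L] else plateau)
  }
  obj <- structure(
    list(params = params, support = range(times),
         monotone_flag = monotone_flag,
         data = data.frame(time_min = times, fraction = fractions)),
    class = "parent_fraction_fit"
  )
  obj$residuals <- fractions - predict(obj, times)
  obj
}

#' @export
predict.parent_fraction_fit <- function(object, times = object$data$time_min,
                                        ...) {
  p <- object$params
  pmin(1, pmax(0, p[["A"]] * exp(-p[["k"]] * times) + p[["c"]]))
}

#' @export
print.parent_fraction_fit <- function(x, ...) {
  cat(sprintf(
    "<parent_fraction_fit> f(t) = %.4g exp(-%.4g t) + %.4g on [%g, %g] min%s\n",
    x$params[["A"]], x$params[["k"]], x$params[["c"]],
    x$support[1L], x$support[2L],
    if (x$monotone_flag) " [non-monotone data flagged]" else ""))
  invisible(x)
}

#' Metabolite-correct a plasma curve
#'
#' Pointwise product of the total plasma activity and the parent fraction,
#' yielding the concentration attributable to intact tracer.  Never
#' increases any value.
#'
#' @param plasma_tac A [tac()] of total plasma activity.
#' @param curve A [fit_parent_fraction()] result.
#' @return A [tac()] of parent-only concentration (organ label suffixed
#'   with `" (parent)"`).
#' @export
metabolite_correct <- function(plasma_tac, curve) {
  stopifnot(inherits(plasma_tac, "tac"), inherits(curve, "parent_fraction_fit"))
  out <- plasma_tac
  out$values <- plasma_tac$values * predict(curve, plasma_tac$times)
  out$organ <- paste0(plasma_tac$organ, " (parent)")
  out
}

#' Monoexponential tail fit
#'
#' Log-linear least squares on the samples at `t >= tail_start` with
#' positive values: `lambda_tail = -slope`, `t1/2 = ln 2 / lambda_tail`.
#' A nonpositive fitted rate is flagged (`"no_elimination"`) with an
#' infinite half-life.
#'
#' @param curve A decay-corrected [tac()] (concentration units).
#' @param tail_start Start of the elimination phase, minutes (default 60,
#'   past the fast distribution phase).
#' @return Object of class `"pk_parameters"` (rate part: `lambda_tail`,
#'   `half_life`, `intercept`, `n_tail`, `flags`, `analyte`).
#' @export
fit_monoexp_tail <- function(curve, tail_start = 60) {
  stopifnot(inherits(curve, "tac"))
  if (!curve$decay_corrected) {
    .stopf("tail fit expects a decay-corrected curve")
  }
  sel <- curve$times >= tail_start
  dropped <- sel & curve$values <= 0
  if (any(dropped)) {
    .warnf("%d nonpositive tail sample(s) excluded", sum(dropped))
  }
  sel <- sel & curve$values > 0
  if (sum(sel) < 3L) {
    .stopf("need >= 3 positive samples at t >= %g min for the tail fit",
           tail_start)
  }
  t <- curve$times[sel]
  ly <- log(curve$values[sel])
  fit <- stats::lm(ly ~ t)
  lambda <- -unname(stats::coef(fit)[2L])
  flags <- character(0)
  if (lambda <= 0) {
    flags <- "no_elimination"
    .warnf("tail rate <= 0: no elimination detected")
  }
  structure(
    list(lambda_tail = lambda,
         half_life = if (lambda > 0) log(2) / lambda else Inf,
         intercept = exp(unname(stats::coef(fit)[1L])),
         n_tail = sum(sel), tail_start = tail_start,
         analyte = curve$organ, flags = flags,
         auc = NA_real_, clearance = NA_real_,
         extrapolated_fraction = NA_real_),
    class = "pk_parameters"
  )
}

#' Plasma clearance by non-compartmental AUC
#'
#' `AUC(0->inf)` is the trapezoid over the sampled support plus the tail
#' extrapolation `C_last / lambda_tail`; `CL = injected activity / AUC`
#' (MBq divided by MBq/mL.min gives mL/min).  The extrapolated tail
#' fraction is recorded and the result flagged unreliable when it exceeds
#' 50%.
#'
#' @param curve Decay-corrected concentration [tac()] (MBq/mL).
#' @param injected_activity_mbq Injected activity, MBq; must be `> 0`.
#' @param lambda_tail Terminal elimination rate, 1/min; must be `> 0`.
#' @return A `"pk_parameters"` object with `auc`, `clearance`,
#'   `extrapolated_fraction`, `lambda_tail`, `half_life`, `flags`.
#' @export
clearance <- function(curve, injected_activity_mbq, lambda_tail) {
  stopifnot(inherits(curve, "tac"))
  if (!is.numeric(injected_activity_mbq) || injected_activity_mbq <= 0) {
    .stopf("injected activity must be > 0 MBq")
  }
  if (!is.numeric(lambda_tail) || lambda_tail <= 0) {
    .stopf("lambda_tail must be > 0 for tail extrapolation")
  }
  auc_obs <- .trapz(curve$times, curve$values)
  c_last <- curve$values[length(curve$values)]
  auc_tail <- c_last / lambda_tail
  auc <- auc_obs + auc_tail
  if (auc <= 0) .stopf("AUC is zero: cannot compute clearance")
  frac <- auc_tail / auc
  flags <- if (frac > 0.5) "extrapolation_unreliable" else character(0)
  structure(
    list(lambda_tail = lambda_tail, half_life = log(2) / lambda_tail,
         intercept = NA_real_, n_tail = NA_integer_, tail_start = NA_real_,
         analyte = curve$organ, flags = flags,
         auc = auc, clearance = injected_activity_mbq / auc,
         extrapolated_fraction = frac),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters> %s\n", x$analyte))
  cat(sprintf("  lambda_tail = %.6g /min, t1/2 = %.4g min\n",
              x$lambda_tail, x$half_life))
  if (is.finite(x$auc)) {
    cat(sprintf("  AUC(0->inf) = %.4g MBq.min/mL (%.1f%% extrapolated)\n",
                x$auc, 100 * x$extrapolated_fraction))
    cat(sprintf("  CL = %.4g mL/min\n", x$clearance))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
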