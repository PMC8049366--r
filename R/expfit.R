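#' Fit a sum of exponentials to a time-activity curve
#'
#' Nonnegativity-constrained least squares fit of
#' `A_1 exp(-l_1 t) + ... + A_m exp(-l_m t)` with `A_i >= 0`, `l_i >= 0`,
#' and the model order `m` selected among `1..max_terms` by the
#' small-sample corrected information criterion (AICc); ties go to the
#' smaller model.  Residuals are relative (scaled by the observation),
#' matching the roughly multiplicative noise of PET and gamma-counter
#' activity measurements.  Starting points come from a fixed (seedless)
#' log-spaced rate grid; for each candidate rate set the amplitudes are
#' seeded by nonnegative linear least squares and the full parameter
#' vector is then refined by bounded Levenberg-Marquardt.
#'
#' The fit records whether the curve was decay-corrected, so downstream
#' integration ([compute_tiac()]) can add physical decay exactly once.
#'
#' @param curve A [tac()]; needs at least `2 * m` samples for an `m`-term
#'   model.
#' @param max_terms Maximum number of exponential terms (1-3).
#' @return Object of class `"expfit"` with elements `terms` (data frame of
#'   `A`, `lambda_per_min`, sorted by rate), `order`, `rss`, `aicc` (per
#'   candidate order), `units`, `decay_corrected`, `organ`, and `data`.
#' @examples
#' tt <- c(1, 10, 20, 40, 100, 200)
#' fit <- fit_sum_of_exponentials(tac("liver", tt, 0.5 * exp(-0.01 * tt)))
#' coef(fit)
#' @export
fit_sum_of_exponentials <- function(curve, max_terms = 3) {
  stopifnot(inherits(curve, "tac"))
  max_terms <- as.integer(max_terms)
  if (max_terms < 1L || max_terms > 3L) .stopf("max_terms must be 1, 2 or 3")
  t <- curve$times
  y <- curve$values
  n <- length(t)
  if (n < 2L) .stopf("need at least 2 samples to fit one exponential term")

  if (all(y == 0)) {
    .warnf("all-zero curve '%s': returning zero model", curve$organ)
    return(.expfit(data.frame(A = 0, lambda_per_min = 0), 1L, 0,
                   c(`1` = NA_real_), curve))
  }

  orders <- seq_len(min(max_terms, n %/% 2L))
  # Orders whose AICc is undefined (n - k - 1 <= 0) are dropped when an
  # evaluable alternative exists; with very few samples the smallest order
  # is fitted anyway.
  evaluable <- orders[n - 2L * orders - 1L >= 1L]
  if (length(evaluable) == 0L) evaluable <- orders[1L]

  fits <- lapply(evaluable, function(m) .fit_exp_order(t, y, m))
  aicc <- vapply(seq_along(evaluable), function(i) {
    .aicc(fits[[i]]$rss, n, 2L * evaluable[i])
  }, numeric(1))
  best <- which.min(aicc)   # ties resolve to the smaller model (first index)
  fit <- fits[[best]]
  ord <- order(fit$lambda)
  terms <- data.frame(A = fit$A[ord], lambda_per_min = fit$lambda[ord])
  .expfit(terms, evaluable[best], fit$rss,
          stats::setNames(aicc, evaluable), curve)
}

.expfit <- function(terms, order, rss, aicc, curve) {
  structure(
    list(terms = terms, order = order, rss = rss, aicc = aicc,
         units = curve$units, decay_corrected = curve$decay_corrected,
         organ = curve$organ,
         data = data.frame(time_min = curve$times, value = curve$values)),
    class = "expfit"
  )
}

.aicc <- function(rss, n, k) {
  if (n - k - 1L <= 0L) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Fixed multi-start rate grid (per minute); deliberately seedless so fits
# are deterministic.
.rate_grid <- function(m) {
  g <- c(0, 10^seq(-4, 0, length.out = 6))
  if (m == 1L) {
    lapply(g, function(x) x)
  } else {
    utils::combn(g, m, simplify = FALSE)
  }
}

.fit_exp_order <- function(t, y, m) {
  # Relative (multiplicative-error) least squares: PET and gamma-counter
  # activity data carry noise roughly proportional to the signal, so
  # residuals are scaled by the observation (floored at 1e-3 of the peak
  # so near-zero samples cannot dominate).
  s <- pmax(y, 1e-3 * max(y))
  best <- NULL
  for (rates in .rate_grid(m)) {
    X <- exp(-outer(t, rates))
    A0 <- tryCatch(pracma::lsqnonneg(X / s, y / s)$x, error = function(e) NULL)
    if (is.null(A0)) A0 <- rep(max(y) / m, m)
    A0 <- pmax(A0, 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(A0, rates),
        fn = function(p) {
          (y - .eval_terms(t, p[seq_len(m)], p[m + seq_len(m)])) / s
        },
        lower = rep(0, 2 * m),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-14, ptol = 1e-14, gtol = 1e-14, maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss - 1e-15 * max(1, best$rss)) {
      p <- fit$par
      best <- list(A = p[seq_len(m)], lambda = p[m + seq_len(m)], rss = rss)
    }
  }
  if (is.null(best)) .stopf("exponential fit failed for all starting points")
  # rates this small are numerically zero over any physical support;
  # snapping restores the exact lambda = 0 semantics downstream
  best$lambda[best$lambda < 1e-10] <- 0
  best
}

.eval_terms <- function(t, A, lambda) {
  drop(exp(-outer(t, lambda)) %*% A)
}

#' @export
coef.expfit <- function(object, ...) {
  stats::setNames(
    c(object$terms$A, object$terms$lambda_per_min),
    c(paste0("A", seq_len(object$order)),
      paste0("lambda", seq_len(object$order)))
  )
}

#' Evaluate a fitted exponential model
#'
#' @param object An `"expfit"`.
#' @param times Times (minutes) at which to evaluate; defaults to the
#'   fitted sample times.
#' @param ... Unused.
#' @return Numeric vector of model values.
#' @export
predict.expfit <- function(object, times = object$data$time_min, ...) {
  .eval_terms(times, object$terms$A, object$terms$lambda_per_min)
}

#' @export
fitted.expfit <- function(object, ...) predict(object)

#' @export
residuals.expfit <- function(object, ...) object$data$value - fitted(object)

#' @export
print.expfit <- function(x, ...) {
  cat(sprintf("<expfit> %s: %d term(s), fitted on %s data [%s]\n",
              x$organ, x$order,
              if (x$decay_corrected) "decay-corrected" else "raw", x$units))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  A = %.6g, lambda = %.6g /min\n",
                x$terms$A[i], x$terms$lambda_per_min[i]))
  }
  cat(sprintf("  RSS = %.4g on %d samples\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
summary.expfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.expfit")
}

#' @export
print.summary.expfit <- function(x, ...) {
  print(x$fit)
  cat("  AICc by candidate order:\n")
  print(round(x$fit$aicc, 3))
  invisible(x)
}
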