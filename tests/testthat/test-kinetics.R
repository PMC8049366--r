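test_that("decay correction doubles one half-life, is identity at t = 0, and round-trips", {
  raw <- tac("blood", c(0, 68), c(1, 1), decay_corrected = FALSE)
  cor <- decay_correct(raw, ga68())
  expect_equal(cor$values, c(1, 2))
  expect_true(cor$decay_corrected)

  back <- decay_correct(cor, ga68(), "uncorrect")
  expect_equal(back$values, raw$values, tolerance = 1e-12)

  # flag mismatch is rejected in both directions
  expect_error(decay_correct(cor, ga68(), "correct"), "already decay-corrected")
  expect_error(decay_correct(raw, ga68(), "uncorrect"), "not decay-corrected")
})

test_that("decay round trip stays within 1e-12 relative on random curves", {
  set.seed(42)
  for (i in 1:20) {
    tt <- sort(runif(8, 0, 240))
    tt <- tt + seq_along(tt) * 1e-6  # ensure strict increase
    vv <- runif(8, 0.01, 1)
    raw <- tac("x", tt, vv, decay_corrected = FALSE)
    rt <- decay_correct(decay_correct(raw, ga68()), ga68(), "uncorrect")
    expect_lt(max(abs(rt$values - vv) / vv), 1e-12)
  }
})

test_that("single-exponential fits are recovered to 1e-6 on the 6-scan schedule", {
  fit <- fit_sum_of_exponentials(make_exp_tac(0.5, 0.01))
  expect_equal(fit$order, 1L)
  expect_equal(unname(coef(fit)), c(0.5, 0.01), tolerance = 1e-6)
})

test_that("biexponential fits recover both terms to 1e-4 from 12 samples", {
  tt <- seq(5, 300, length.out = 12)
  fit <- fit_sum_of_exponentials(make_exp_tac(c(0.3, 0.2), c(0.002, 0.05), tt))
  expect_equal(fit$order, 2L)
  expect_equal(fit$terms$A, c(0.3, 0.2), tolerance = 1e-4)
  expect_equal(fit$terms$lambda_per_min, c(0.002, 0.05), tolerance = 1e-4)
})

test_that("degenerate curves are handled: constant -> single lambda = 0 term; all-zero warns", {
  flat <- fit_sum_of_exponentials(tac("flat", scan6, rep(0.25, 6)))
  expect_equal(flat$order, 1L)
  expect_equal(flat$terms$A, 0.25, tolerance = 1e-8)
  expect_equal(flat$terms$lambda_per_min, 0, tolerance = 1e-8)

  expect_warning(zero <- fit_sum_of_exponentials(tac("z", scan6, rep(0, 6))),
                 "all-zero")
  expect_equal(zero$terms$A, 0)

  expect_error(fit_sum_of_exponentials(tac("short", 5, 1)), "at least 2")
})

test_that("TIAC closed form matches its trivial cases and errors on divergence", {
  # constant retention under physical decay alone: T_p/ln2 hours
  flat <- fit_sum_of_exponentials(tac("wb", scan6, rep(1, 6)))
  expect_equal(compute_tiac(flat, ga68()), 68 / log(2) / 60, tolerance = 1e-6)

  # non-FIA units rejected
  conc <- fit_sum_of_exponentials(tac("p", scan6, exp(-0.01 * scan6),
                                      units = "kBq/mL"))
  expect_error(compute_tiac(conc, ga68()), "FIA")

  # raw-domain model with a zero rate diverges
  raw_flat <- tac("wb", scan6, rep(1, 6), decay_corrected = FALSE)
  fit_raw <- fit_sum_of_exponentials(raw_flat)
  expect_error(compute_tiac(fit_raw, ga68()), "divergent")
})

test_that("closed-form TIAC agrees with adaptive quadrature on random models", {
  lp <- ga68()$lambda_per_min
  set.seed(7)
  for (i in 1:25) {
    m <- random_exp_model()
    fit <- fit_sum_of_exponentials(make_exp_tac(m$A, m$lambda,
                                                seq(1, 400, length.out = 14)))
    closed <- compute_tiac(fit, ga68())
    num <- integrate(function(t) {
      drop(exp(-outer(t, fit$terms$lambda_per_min)) %*% fit$terms$A) *
        exp(-lp * t)
    }, 0, Inf, rel.tol = 1e-12)$value / 60
    expect_lt(abs(closed - num) / num, 1e-8)
  }
})

test_that("bladder model: immediate voiding removes everything, no voiding hits the closed form", {
  nuc <- ga68()
  p0 <- bladder_model_params(1e-6, 1, biologic_half_life_min = 191)
  expect_lt(bladder_tiac(p0, nuc), 1e-4)

  pinf <- bladder_model_params(1e6, 1, biologic_half_life_min = 191)
  lb <- log(2) / 191; lp <- nuc$lambda_per_min
  closed <- lb / ((lb + lp) * lp) / 60
  expect_equal(bladder_tiac(pinf, nuc), closed, tolerance = 1e-6)
  expect_equal(closed, 0.429, tolerance = 1e-3)

  expect_error(bladder_model_params(0, 1, biologic_half_life_min = 191),
               "voiding interval")
})

test_that("bladder TIAC is monotone nondecreasing in voiding interval and excreted fraction", {
  nuc <- ga68()
  tv <- c(0.5, 1, 2, 3.5, 6, 12, 48)
  v <- vapply(tv, function(x) {
    bladder_tiac(bladder_model_params(x, 1, biologic_half_life_min = 191), nuc)
  }, numeric(1))
  expect_true(all(diff(v) > 0))

  fs <- seq(0.1, 1, by = 0.1)
  vf <- vapply(fs, function(f) {
    bladder_tiac(bladder_model_params(3.5, f, biologic_half_life_min = 191),
                 nuc)
  }, numeric(1))
  expect_true(all(diff(vf) > 0))
  # linearity in f, by construction
  expect_equal(vf, fs * vf[10], tolerance = 1e-10)
})

test_that("remainder-of-body subtraction works and rejects negative remainders", {
  organs <- residence_time_set(c(liver = 0.8, kidneys = 0.835))
  expect_equal(remainder_of_body_tiac(1.635, organs), 0, tolerance = 1e-12)

  t1 <- reference_summary("residence_times")
  listed <- setNames(t1$mean[t1$site != "Remainder of body"],
                     t1$site[t1$site != "Remainder of body"])
  expect_equal(sum(listed), 0.4654, tolerance = 1e-10)
  rem <- remainder_of_body_tiac(68 / log(2) / 60, residence_time_set(listed))
  expect_equal(rem, 1.170, tolerance = 1e-3)

  expect_error(remainder_of_body_tiac(0.5, organs), "exceeding")
})

test_that("SUV is the density-1 normalization with the expected linearity", {
  # concentration equal to injected activity per body mass -> 1
  expect_equal(compute_suv(162 / 80, 162, 80), 1)
  expect_equal(compute_suv(2 * 231, 162, 80), 2 * compute_suv(231, 162, 80))
  expect_equal(compute_suv(231, 162, 80), 114.1, tolerance = 1e-3)
  expect_error(compute_suv(1, 0, 80), "injected")
  expect_error(compute_suv(1, 162, 0), "weight")
})
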