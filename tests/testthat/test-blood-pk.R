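test_that("plasma-to-blood ratio handles identity, a fixed partition, and zero-blood samples", {
  tt <- c(2, 5, 10, 30)
  s_eq <- plasma_sample_series(tt, rep(3, 4), rep(3, 4))
  r <- plasma_to_blood_ratio(s_eq)
  expect_equal(r$mean, 1)
  expect_equal(r$sd, 0)

  s17 <- plasma_sample_series(tt, c(100, 80, 60, 40) / 1.7,
                              c(100, 80, 60, 40))
  expect_equal(plasma_to_blood_ratio(s17)$mean, 1.7, tolerance = 1e-12)

  s0 <- plasma_sample_series(tt, c(0, 80, 60, 40), c(10, 80, 60, 40))
  expect_warning(rz <- plasma_to_blood_ratio(s0), "excluded")
  expect_equal(nrow(rz$ratios), 3)
})

test_that("protein-bound fraction covers the 0/100% poles and the printed-mean arithmetic", {
  tt <- c(2, 5, 10)
  mk <- function(sup) plasma_sample_series(tt, rep(1, 3), rep(100, 3),
                                           supernatant = rep(sup, 3))
  expect_equal(protein_bound_fraction(mk(100))$bound_percent, rep(0, 3))
  expect_equal(protein_bound_fraction(mk(0))$bound_percent, rep(100, 3))
  expect_equal(protein_bound_fraction(mk(74.1))$bound_percent, rep(25.9, 3))
  expect_error(protein_bound_fraction(mk(110)), "inconsistency")
})

test_that("parent-fraction fitting: constants, exact recovery, and the 2-point plateau-0 case", {
  cst <- fit_parent_fraction(c(1, 10, 60), c(1, 1, 1))
  expect_equal(unname(cst$params), c(0, 0, 1))
  expect_equal(predict(cst, c(0, 500)), c(1, 1))

  tt <- c(1, 2, 4, 8, 15, 30, 60)
  truth <- 0.85 * exp(-0.3 * tt) + 0.02
  fit <- fit_parent_fraction(tt, truth)
  expect_equal(unname(fit$params), c(0.85, 0.3, 0.02), tolerance = 1e-6)

  two <- fit_parent_fraction(c(1, 10), c(0.792, 0.043), plateau = 0)
  expect_equal(predict(two, c(1, 10)), c(0.792, 0.043), tolerance = 1e-8)
  # evaluation clamps to [0, 1] even where the raw form exceeds 1
  expect_lte(predict(two, 0), 1)

  expect_warning(fit_parent_fraction(c(1, 5, 10), c(0.2, 0.5, 0.9)),
                 "flagged")
})

test_that("metabolite correction is a pointwise product that never increases activity", {
  tt <- c(2, 5, 10, 30, 60)
  total <- tac("plasma", tt, c(100, 80, 60, 30, 10), units = "kBq/mL")

  one <- fit_parent_fraction(tt, rep(1, 5))
  expect_equal(metabolite_correct(total, one)$values, total$values)

  zero <- fit_parent_fraction(tt, rep(0, 5))
  expect_equal(metabolite_correct(total, zero)$values, rep(0, 5))

  pf <- fit_parent_fraction(tt, 0.9 * exp(-0.2 * tt) + 0.05)
  corrected <- metabolite_correct(total, pf)
  expect_true(all(corrected$values <= total$values + 1e-12))
  # single-point arithmetic: total 100 at f = 0.25 -> 25
  quarter <- fit_parent_fraction(tt, rep(0.25, 5))
  expect_equal(metabolite_correct(total, quarter)$values[1], 25)
})

test_that("monoexponential tail fit is exact on noise-free input and flags flat tails", {
  lam <- log(2) / 106.9
  tt <- c(2, 5, 10, 30, 60, 90, 180, 240)
  cur <- tac("plasma", tt, 0.05 * exp(-lam * tt), units = "kBq/mL")
  pk <- fit_monoexp_tail(cur, tail_start = 60)
  expect_equal(pk$half_life, 106.9, tolerance = 1e-10)
  expect_lt(abs(pk$lambda_tail - lam) / lam, 1e-10)

  flat <- tac("plasma", tt, rep(1, 8), units = "kBq/mL")
  expect_warning(pkf <- fit_monoexp_tail(flat), "no elimination")
  expect_equal(pkf$lambda_tail, 0)
  expect_equal(pkf$half_life, Inf)
  expect_true("no_elimination" %in% pkf$flags)

  raw <- tac("plasma", tt, exp(-lam * tt), units = "kBq/mL",
             decay_corrected = FALSE)
  expect_error(fit_monoexp_tail(raw), "decay-corrected")
  expect_error(fit_monoexp_tail(tac("p", c(100, 200), c(1, 0.5),
                                    units = "kBq/mL")), ">= 3")
})

test_that("tail fit with 1% noise recovers the rate within 2% (median of 50 replicates)", {
  lam <- 0.006484
  tt <- c(60, 90, 120, 180, 240)
  set.seed(123)
  errs <- replicate(50, {
    y <- 0.05 * exp(-lam * tt) * exp(rnorm(5, 0, 0.01))
    pk <- fit_monoexp_tail(tac("p", tt, y, units = "kBq/mL"), 60)
    abs(pk$lambda_tail - lam) / lam
  })
  expect_lt(median(errs), 0.02)
})

test_that("clearance: dense monoexponential input approaches the closed form D*lambda/C0", {
  lam <- 0.01; C0 <- 0.05; D <- 162
  tt <- seq(0, 600, by = 1)
  cur <- tac("plasma", tt, C0 * exp(-lam * tt), units = "kBq/mL")
  cl <- clearance(cur, D, lam)
  expect_equal(cl$clearance, D * lam / C0, tolerance = 0.01)
  expect_error(clearance(cur, 0, lam), "> 0")

  # the tail extrapolation can only add area
  sparse <- tac("plasma", c(60, 120, 240), C0 * exp(-lam * c(60, 120, 240)),
                units = "kBq/mL")
  with_tail <- clearance(sparse, D, lam)$auc
  expect_gte(with_tail,
             sum(diff(c(60, 120, 240)) *
                 (head(sparse$values, -1) + tail(sparse$values, -1)) / 2))
})

test_that("trapezoid+tail AUC converges to the closed form with order >= 2", {
  lam <- 0.01; C0 <- 1
  auc_exact <- C0 / lam
  errs <- vapply(c(10, 20, 40), function(n) {
    tt <- seq(0, 400, length.out = n)
    cur <- tac("p", tt, C0 * exp(-lam * tt), units = "kBq/mL")
    abs(clearance(cur, 1, lam)$auc - auc_exact)
  }, numeric(1))
  # halving the step should cut the error ~4x
  expect_gt(log2(errs[1] / errs[2]), 1.7)
  expect_gt(log2(errs[2] / errs[3]), 1.7)
})

test_that("metabolite production makes parent clearance exceed total clearance", {
  subj <- generate_subject(noise_free_config())
  ser <- subj$plasma
  total <- tac("plasma total", ser$times, ser$plasma, units = "kBq/mL")
  pf <- fit_parent_fraction(ser$times, ser$parent_fraction)
  parent <- metabolite_correct(total, pf)
  lam_tot <- fit_monoexp_tail(total)$lambda_tail
  lam_par <- fit_monoexp_tail(parent)$lambda_tail
  inj <- subj$config$injected_activity_mbq
  expect_gt(clearance(parent, inj, lam_par)$clearance,
            clearance(total, inj, lam_tot)$clearance)
})
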