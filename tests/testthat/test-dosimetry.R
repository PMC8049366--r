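toy_svalues <- function() {
  m <- matrix(c(1.0, 0.01, 0.02,
                0.03, 2.0, 0.04,
                0.05, 0.06, 3.0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("liver", "kidneys", "spleen"),
                              c("liver", "kidneys", "spleen")))
  svalue_table(m, "hand-made 3x3")
}

test_that("dose engine: identity product, linearity, and a hand-computed 3x3 oracle", {
  s1 <- svalue_table(matrix(1, 1, 1, dimnames = list("liver", "liver")))
  r1 <- compute_absorbed_doses(residence_time_set(c(liver = 1)), s1)
  expect_equal(unname(r1$organ_doses), 1000)  # 1 h x 1 mSv/(MBq.h) = 1000 uSv/MBq

  tau <- c(liver = 0.3, kidneys = 0.05, spleen = 0.01)
  r <- compute_absorbed_doses(residence_time_set(tau), toy_svalues())
  # hand matrix-vector product (tau a row vector against the S matrix)
  hand <- c(liver = 0.3 * 1.0 + 0.05 * 0.03 + 0.01 * 0.05,
            kidneys = 0.3 * 0.01 + 0.05 * 2.0 + 0.01 * 0.06,
            spleen = 0.3 * 0.02 + 0.05 * 0.04 + 0.01 * 3.0) * 1000
  expect_equal(r$organ_doses, hand)

  r2 <- compute_absorbed_doses(residence_time_set(2 * tau), toy_svalues())
  expect_equal(r2$organ_doses, 2 * r$organ_doses)
})

test_that("dose engine is linear in residence-time combinations", {
  set.seed(11)
  sv <- generate_toy_svalue_table(5, seed = 3)
  organs <- rownames(sv$matrix)[1:5]
  for (i in 1:5) {
    t1 <- setNames(runif(5), organs); t2 <- setNames(runif(5), organs)
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    d1 <- compute_absorbed_doses(residence_time_set(t1), sv)$organ_doses
    d2 <- compute_absorbed_doses(residence_time_set(t2), sv)$organ_doses
    d12 <- compute_absorbed_doses(residence_time_set(a * t1 + b * t2),
                                  sv)$organ_doses
    expect_equal(d12, a * d1 + b * d2, tolerance = 1e-12)
  }
})

test_that("consistently permuting sources and targets leaves doses unchanged", {
  sv <- toy_svalues()
  tau <- c(liver = 0.3, kidneys = 0.05, spleen = 0.01)
  base <- compute_absorbed_doses(residence_time_set(tau), sv)$organ_doses
  perm <- c(3, 1, 2)
  svp <- svalue_table(sv$matrix[perm, perm], sv$phantom_id)
  got <- compute_absorbed_doses(residence_time_set(tau[perm]), svp)$organ_doses
  expect_equal(got[names(base)], base)
})

test_that("unresolvable source organs produce an informative error", {
  expect_error(
    compute_absorbed_doses(residence_time_set(c(gizzard = 0.1)), toy_svalues()),
    "gizzard.*available.*liver")
})

test_that("ICRP-103 weights sum to one and equal doses collapse to d/1000", {
  w <- icrp103_weights()
  expect_lt(abs(sum(w$weights) - 1), 1e-12)
  expect_true(all(w$weights >= 0))
  expect_length(w$remainder_tissues, 13)

  rep_eq <- dose_report(c("whole body" = 14, liver = 14, kidneys = 14))
  expect_equal(as.numeric(effective_dose(rep_eq)), 14 / 1000)
})

test_that("a custom 3-tissue weight set reproduces hand-computed E", {
  w <- tissue_weights(c(liver = 0.5, kidneys = 0.3, spleen = 0.2))
  rep3 <- dose_report(c(liver = 10, kidneys = 20, spleen = 30))
  e <- effective_dose(rep3, w, substitution = "omit")
  expect_equal(as.numeric(e), 17 / 1000)  # 0.5*10 + 0.3*20 + 0.2*30 = 17 uSv
})

test_that("effective dose lies between the min and max organ dose", {
  t2 <- reference_summary("dose_equivalents")
  rep <- dose_report(setNames(t2$mean, t2$site))
  e <- 1000 * as.numeric(effective_dose(rep))
  expect_gte(e, min(rep$organ_doses))
  expect_lte(e, max(rep$organ_doses))
})

test_that("substitution policies: whole_body needs its row, omit renormalizes", {
  rep_nowb <- dose_report(c(liver = 10, kidneys = 20))
  expect_error(effective_dose(rep_nowb, substitution = "whole_body"),
               "whole-body")
  e <- effective_dose(rep_nowb, substitution = "omit")
  # weighted tissues present: liver (0.04) + remainder (kidneys, 0.12)
  expect_equal(as.numeric(e), (0.04 * 10 + 0.12 * 20) / 0.16 / 1000)

  expect_error(tissue_weights(c(liver = 0.5, kidneys = 0.3)), "sum to 1")
})

test_that("administered dose is a guarded product reported at 2 s.f.", {
  expect_equal(signif(dose_for_administration(0.022, 150), 2), 3.3)
  expect_equal(dose_for_administration(0.5, 0), 0)
  expect_equal(signif(dose_for_administration(0.022, 162), 2), 3.6)
  expect_error(dose_for_administration(-1, 10), ">= 0")
})
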