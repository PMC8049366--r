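test_that("noise-free subjects conserve mass at every sampled instant", {
  cfg <- noise_free_config()
  subj <- generate_subject(cfg)
  scan <- cfg$scan_times_min
  organ_sum <- Reduce(`+`, lapply(subj$tacs, function(x) x$values))
  voided <- 1 - subj$whole_body_tac$values
  balance <- organ_sum + subj$remainder_tac$values + voided
  expect_lt(max(abs(balance - 1)), 1e-9)
  # whole body at the first frame is still the full injected activity
  expect_equal(subj$whole_body_tac$values[1], 1)
})

test_that("generation is deterministic per seed and differs across seeds", {
  a <- generate_subject(noisy_config(seed = 42))
  b <- generate_subject(noisy_config(seed = 42))
  expect_identical(a, b)
  c <- generate_subject(noisy_config(seed = 43))
  expect_false(identical(a$tacs[["kidneys"]]$values,
                         c$tacs[["kidneys"]]$values))
})

test_that("default calibration puts the peak bladder SUV in the expected range", {
  subj <- generate_subject(noise_free_config())
  suv <- compute_suv(subj$bladder$conc_kbq_ml,
                     subj$config$injected_activity_mbq,
                     subj$config$body_weight_kg)
  expect_gte(max(suv), 90)
  expect_lte(max(suv), 140)
  expect_equal(max(suv), subj$ground_truth$peak_bladder_suv)
})

test_that("the dehydrated outlier roughly doubles bladder SUV without touching other organs", {
  cfg <- noise_free_config()
  base <- generate_subject(cfg)
  out <- generate_outlier_subject(cfg)
  r <- out$ground_truth$peak_bladder_suv / base$ground_truth$peak_bladder_suv
  expect_gte(r, 1.5)
  expect_lte(r, 2.5)
  for (org in names(base$tacs)) {
    expect_equal(out$tacs[[org]]$values, base$tacs[[org]]$values)
  }
  # mass balance still holds
  organ_sum <- Reduce(`+`, lapply(out$tacs, function(x) x$values))
  expect_lt(max(abs(organ_sum + out$remainder_tac$values +
                    (1 - out$whole_body_tac$values) - 1)), 1e-9)
})

test_that("noise-free curves piped through the kinetics module recover ground-truth TIACs within 1%", {
  subj <- generate_subject(noise_free_config())
  truth <- subj$ground_truth$organ_tiacs_h
  for (org in names(truth)) {
    fit <- fit_sum_of_exponentials(subj$tacs[[org]])
    expect_lt(abs(compute_tiac(fit, ga68()) - truth[[org]]) / truth[[org]],
              0.01)
  }
})

test_that("infeasible configurations are rejected at validation", {
  organs <- default_organ_kinetics()
  organs$u <- organs$u * 20  # uptake + excretion > 1
  expect_error(subject_config(organs = organs), "infeasible")
  expect_error(subject_config(excreted_fraction = 1.2), "excreted fraction")
  expect_error(subject_config(urine_rate_ml_min = 0), "urine")
})

test_that("toy S-value tables are positive, diagonally dominant and reproducible", {
  s <- generate_toy_svalue_table(2, seed = 5)
  expect_equal(dim(s$matrix), c(3L, 2L))  # 2 organs + remainder row
  expect_true(all(s$matrix > 0))
  expect_identical(generate_toy_svalue_table(2, seed = 5), s)

  for (seed in 1:25) {
    m <- generate_toy_svalue_table(6, seed = seed)$matrix
    organ_rows <- m[seq_len(ncol(m)), , drop = FALSE]
    for (j in seq_len(ncol(m))) {
      cross <- c(organ_rows[-j, j], m[nrow(m), j])
      expect_gte(organ_rows[j, j] / max(cross), 10)
    }
  }
  expect_error(generate_toy_svalue_table(1), "at least 2")
})

test_that("generator output survives CSV round trips losslessly", {
  subj <- generate_subject(noise_free_config())
  tdir <- withr::local_tempdir()

  tac_path <- file.path(tdir, "tacs.csv")
  write_tac_csv(c(subj$tacs, list(subj$whole_body_tac)), tac_path)
  back <- read_tac_csv(tac_path)
  expect_equal(back[["kidneys"]]$values, subj$tacs[["kidneys"]]$values)
  expect_equal(back[["whole body"]]$times, subj$whole_body_tac$times)

  pl_path <- file.path(tdir, "plasma.csv")
  write_plasma_csv(subj$plasma, pl_path)
  pback <- read_plasma_csv(pl_path)
  expect_equal(pback$plasma, subj$plasma$plasma)
  expect_equal(pback$parent_fraction, subj$plasma$parent_fraction)
})
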