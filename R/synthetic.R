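#' Default organ kinetic parameters for the synthetic subject
#'
#' Each organ follows a biexponential decay-corrected washout
#' `u * (w exp(-mu_fast t) + (1 - w) exp(-mu_slow t))` in fraction of
#' injected activity.  The parameter choices are invented but calibrated to
#' the qualitative whole-body pattern of a renally excreted hydrophilic
#' peptide tracer (early heart/liver/kidney signal, later kidney/bladder
#' dominance) and keep every organ's residence time in the few-hundredths-
#' of-an-hour range typical for such tracers.
#'
#' @return Data frame with columns `organ`, `u`, `w_fast`, `mu_fast`,
#'   `mu_slow` (rates per minute).
#' @export
default_organ_kinetics <- function() {
  data.frame(
    organ = c("bone cortical", "bone trabecular", "brain", "heart contents",
              "kidneys", "liver", "lungs", "pancreas", "red marrow",
              "salivary glands", "spleen"),
    u = c(0.030, 0.005, 0.010, 0.040, 0.060, 0.055, 0.025, 0.003, 0.018,
          0.001, 0.006),
    w_fast = c(0.3, 0.3, 0.5, 0.9, 0.5, 0.5, 0.6, 0.5, 0.4, 0.5, 0.5),
    mu_fast = c(0.03, 0.03, 0.05, 0.08, 0.04, 0.05, 0.06, 0.05, 0.04,
                0.05, 0.05),
    mu_slow = c(0.0015, 0.0015, 0.004, 0.006, 0.004, 0.004, 0.005, 0.004,
                0.003, 0.004, 0.004),
    stringsAsFactors = FALSE
  )
}

#' Synthetic subject configuration
#'
#' Defines one simulated whole-body PET + venous-sampling session: organ
#' kinetics, renal excretion filling the bladder, blood/plasma kinetics,
#' parent-fraction and protein-binding trajectories, acquisition schedules
#' and the noise model.  Defaults emulate a healthy ~80-kg adult male given
#' ~162 MBq of a renally excreted Ga-68 peptide: biologic excretion
#' half-life 191 min, plasma-to-blood ratio 1.7, parent fraction 0.79 at
#' 1 min falling to 0.04 at 10 min, protein binding drifting from ~13% to
#' ~43%, six whole-body PET passes at 1-200 min and 13 venous samples at
#' 2-240 min.
#'
#' @param body_weight_kg,injected_activity_mbq Subject mass and dose.
#' @param nuclide A [nuclide()].
#' @param organs Organ kinetic table as in [default_organ_kinetics()].
#' @param excreted_fraction Fraction of injected activity excreted to
#'   urine; together with the organ uptake fractions it must not exceed 1.
#' @param biologic_half_life_min Excretion half-life (min).
#' @param urine_rate_ml_min,urine_initial_ml Urine production and initial
#'   bladder volume (dilution of the bladder activity, hence the bladder
#'   SUV calibration).
#' @param void_times_min Voiding times during the session (default none:
#'   subjects imaged continuously).
#' @param plasma_amplitudes,plasma_rates Biexponential total-plasma model
#'   (MBq/mL and 1/min); the slow rate sets the terminal plasma half-life.
#' @param partition_ratio Plasma-to-whole-blood activity ratio.
#' @param parent_params `c(A, k, c)` of the parent-fraction curve
#'   `min(1, A exp(-k t) + c)`.
#' @param protein_binding `c(b0, bmax, tau_min)`: bound percentage
#'   `b0 + (bmax - b0)(1 - exp(-t/tau))`.
#' @param pet_sigma,gamma_sigma Multiplicative lognormal noise scales:
#'   PET points use `pet_sigma * sqrt(60 / frame_s)`, gamma-counter points
#'   use `gamma_sigma` as is.  Set to 0 for noise-free output.
#' @param scan_times_min,frame_durations_s Whole-body PET schedule.
#' @param blood_times_min Venous sampling schedule.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return Object of class `"subject_config"`.
#' @export
subject_config <- function(body_weight_kg = 80,
                           injected_activity_mbq = 162,
                           nuclide = ga68(),
                           organs = default_organ_kinetics(),
                           excreted_fraction = 0.70,
                           biologic_half_life_min = 191,
                           urine_rate_ml_min = 1.2,
                           urine_initial_ml = 25,
                           void_times_min = numeric(0),
                           plasma_amplitudes = c(fast = 0.030, slow = 0.004),
                           plasma_rates = c(fast = 0.2,
                                            slow = log(2) / 106.9),
                           partition_ratio = 1.7,
                           parent_params = c(A = 1.10046, k = 0.333995,
                                             c = 0.004),
                           protein_binding = c(b0 = 13, bmax = 43,
                                               tau_min = 90),
                           pet_sigma = 0,
                           gamma_sigma = 0,
                           scan_times_min = c(1, 10, 20, 40, 100, 200),
                           frame_durations_s = c(30, 60, 120, 180, 300, 360),
                           blood_times_min = c(2, 3, 5, 6, 7, 10, 15, 20,
                                               30, 60, 90, 180, 240),
                           seed = 1L) {
  cfg <- structure(
    list(body_weight_kg = body_weight_kg,
         injected_activity_mbq = injected_activity_mbq,
         nuclide = nuclide, organs = organs,
         excreted_fraction = excreted_fraction,
         biologic_half_life_min = biologic_half_life_min,
         urine_rate_ml_min = urine_rate_ml_min,
         urine_initial_ml = urine_initial_ml,
         void_times_min = sort(void_times_min),
         plasma_amplitudes = plasma_amplitudes,
         plasma_rates = plasma_rates,
         partition_ratio = partition_ratio,
         parent_params = parent_params,
         protein_binding = protein_binding,
         pet_sigma = pet_sigma, gamma_sigma = gamma_sigma,
         scan_times_min = scan_times_min,
         frame_durations_s = frame_durations_s,
         blood_times_min = blood_times_min,
         seed = as.integer(seed)),
    class = "subject_config"
  )
  validate_subject_config(cfg)
  cfg
}

#' @rdname subject_config
#' @param config A `"subject_config"`.
#' @export
validate_subject_config <- function(config) {
  org <- config$organs
  req <- c("organ", "u", "w_fast", "mu_fast", "mu_slow")
  if (!all(req %in% names(org))) {
    .stopf("organ table must have columns %s", paste(req, collapse = ", "))
  }
  if (any(org$u < 0) || any(org$mu_fast < 0) || any(org$mu_slow < 0) ||
      any(org$w_fast < 0 | org$w_fast > 1)) {
    .stopf("organ kinetic parameters must be nonnegative (w_fast in [0,1])")
  }
  if (config$excreted_fraction < 0 || config$excreted_fraction > 1) {
    .stopf("excreted fraction must be in [0, 1]")
  }
  if (sum(org$u) + config$excreted_fraction > 1) {
    .stopf("infeasible fractions: organ uptake (%.3f) + excreted fraction (%.3f) > 1",
           sum(org$u), config$excreted_fraction)
  }
  if (config$biologic_half_life_min <= 0) .stopf("biologic half-life must be > 0")
  if (config$urine_rate_ml_min <= 0 || config$urine_initial_ml <= 0) {
    .stopf("urine parameters must be > 0")
  }
  if (length(config$frame_durations_s) != length(config$scan_times_min)) {
    .stopf("frame_durations_s must match scan_times_min")
  }
  # the remainder pool must stay nonnegative on a fine grid
  grid <- seq(0, 600, by = 1)
  if (any(.remainder_fia(config, grid) < -1e-12)) {
    .stopf("infeasible kinetics: remainder-of-body pool goes negative")
  }
  invisible(TRUE)
}

# --- noise-free model curves (decay-corrected FIA) -------------------------

.organ_fia <- function(config, times) {
  org <- config$organs
  m <- vapply(seq_len(nrow(org)), function(i) {
    org$u[i] * (org$w_fast[i] * exp(-org$mu_fast[i] * times) +
                (1 - org$w_fast[i]) * exp(-org$mu_slow[i] * times))
  }, numeric(length(times)))
  matrix(m, nrow = length(times), ncol = nrow(org))
}

# cumulative renal excretion reaching the bladder by time t
.excreted_fia <- function(config, times) {
  lb <- log(2) / config$biologic_half_life_min
  config$excreted_fraction * (1 - exp(-lb * times))
}

# cumulative activity voided out of the body by time t
.voided_fia <- function(config, times) {
  if (length(config$void_times_min) == 0L) return(rep(0, length(times)))
  vapply(times, function(t) {
    past <- config$void_times_min[config$void_times_min <= t]
    if (length(past) == 0L) 0 else .excreted_fia(config, max(past))
  }, numeric(1))
}

.bladder_fia <- function(config, times) {
  .excreted_fia(config, times) - .voided_fia(config, times)
}

# non-bladder tissue = everything not yet excreted
.tissue_fia <- function(config, times) 1 - .excreted_fia(config, times)

.remainder_fia <- function(config, times) {
  .tissue_fia(config, times) - rowSums(.organ_fia(config, times))
}

.urine_volume_ml <- function(config, times) {
  config$urine_initial_ml + config$urine_rate_ml_min * times
}

.plasma_conc <- function(config, times) {
  a <- config$plasma_amplitudes
  r <- config$plasma_rates
  a[["fast"]] * exp(-r[["fast"]] * times) +
    a[["slow"]] * exp(-r[["slow"]] * times)
}

.parent_fraction_true <- function(config, times) {
  p <- config$parent_params
  pmin(1, p[["A"]] * exp(-p[["k"]] * times) + p[["c"]])
}

.bound_percent_true <- function(config, times) {
  b <- config$protein_binding
  b[["b0"]] + (b[["bmax"]] - b[["b0"]]) * (1 - exp(-times / b[["tau_min"]]))
}

# --- closed-form ground truth ---------------------------------------------

.ground_truth <- function(config) {
  lp <- config$nuclide$lambda_per_min
  lb <- log(2) / config$biologic_half_life_min
  f <- config$excreted_fraction
  org <- config$organs
  organ_tiacs <- stats::setNames(vapply(seq_len(nrow(org)), function(i) {
    (org$u[i] * org$w_fast[i] / (org$mu_fast[i] + lp) +
     org$u[i] * (1 - org$w_fast[i]) / (org$mu_slow[i] + lp)) / 60
  }, numeric(1)), org$organ)
  tissue_tiac <- ((1 - f) / lp + f / (lb + lp)) / 60
  bladder_novoid <- f * lb / ((lb + lp) * lp) / 60
  p35 <- bladder_model_params(3.5, f, biologic_rate_per_min = lb)
  bladder_35h <- bladder_tiac(p35, config$nuclide)

  tt <- config$blood_times_min
  cp <- .plasma_conc(config, tt)
  fp <- .parent_fraction_true(config, tt)
  lam_slow <- config$plasma_rates[["slow"]]
  auc_design <- function(y) .trapz(tt, y) + y[length(y)] / lam_slow
  auc_total <- auc_design(cp)
  auc_parent <- auc_design(cp * fp)
  a <- config$plasma_amplitudes; r <- config$plasma_rates
  auc_model_exact <- a[["fast"]] / r[["fast"]] + a[["slow"]] / r[["slow"]]

  scan <- config$scan_times_min
  suv_peak <- max(compute_suv(
    .bladder_fia(config, scan) * config$injected_activity_mbq * 1000 /
      .urine_volume_ml(config, scan),
    config$injected_activity_mbq, config$body_weight_kg))

  list(
    organ_tiacs_h = organ_tiacs,
    tissue_tiac_h = tissue_tiac,
    remainder_tiac_h = tissue_tiac - sum(organ_tiacs),
    bladder_tiac_novoid_h = bladder_novoid,
    bladder_tiac_3.5h_void_h = bladder_35h,
    biologic_half_life_min = config$biologic_half_life_min,
    excreted_fraction = f,
    plasma_half_life_min = log(2) / lam_slow,
    cl_total_ml_min = config$injected_activity_mbq / auc_total,
    cl_parent_ml_min = config$injected_activity_mbq / auc_parent,
    auc_total_design = auc_total,
    auc_parent_design = auc_parent,
    auc_total_model_exact = auc_model_exact,
    partition_ratio = config$partition_ratio,
    parent_params = as.list(config$parent_params),
    peak_bladder_suv = suv_peak
  )
}

# --- generation ------------------------------------------------------------

#' Generate a complete synthetic subject
#'
#' Produces decay-corrected organ time-activity curves (including urinary
#' bladder, remainder of body and whole body), the venous blood/plasma
#' sample series with parent fractions and protein binding, a urine void
#' table, the bladder volume/concentration track, and the closed-form
#' ground truth of the generating kinetics.  At every instant the
#' noise-free curves satisfy the mass balance
#' `sum(organs) + remainder + bladder + voided = 1`.  Noise (if any) is
#' applied after mass balance; the same seed gives identical output.
#'
#' @param config A [subject_config()].
#' @return Object of class `"synth_subject"`: `tacs` (named list of source
#'   [tac()]s incl. `"urinary bladder"`), `remainder_tac`, `whole_body_tac`
#'   (everything still in the body), `plasma` ([plasma_sample_series()]),
#'   `bladder` (data frame time/volume/concentration), `voids` (data
#'   frame), `ground_truth`, `config`.
#' @examples
#' subj <- generate_subject(subject_config())
#' names(subj$tacs)
#' @export
generate_subject <- function(config) {
  stopifnot(inherits(config, "subject_config"))
  validate_subject_config(config)
  with_seed(config$seed, .generate_subject_impl(config))
}

.generate_subject_impl <- function(config) {
  scan <- config$scan_times_min
  frames <- config$frame_durations_s
  org <- config$organs

  pet_noise <- function(values) {
    if (config$pet_sigma == 0) return(values)
    sig <- config$pet_sigma * sqrt(60 / frames)
    values * exp(stats::rnorm(length(values), 0, sig))
  }
  gamma_noise <- function(values) {
    if (config$gamma_sigma == 0) return(values)
    values * exp(stats::rnorm(length(values), 0, config$gamma_sigma))
  }

  organ_mat <- .organ_fia(config, scan)
  tacs <- stats::setNames(lapply(seq_len(nrow(org)), function(i) {
    tac(org$organ[i], scan, pet_noise(organ_mat[, i]),
        units = "FIA", decay_corrected = TRUE, frame_durations = frames)
  }), org$organ)

  bladder_vals <- .bladder_fia(config, scan)
  tacs[["urinary bladder"]] <- tac("urinary bladder", scan,
                                   pet_noise(bladder_vals), units = "FIA",
                                   decay_corrected = TRUE,
                                   frame_durations = frames)

  remainder_vals <- .remainder_fia(config, scan)
  remainder_tac <- tac("remainder of body", scan, pet_noise(remainder_vals),
                       units = "FIA", decay_corrected = TRUE,
                       frame_durations = frames)

  wb_vals <- 1 - .voided_fia(config, scan)
  whole_body_tac <- tac("whole body", scan, pet_noise(wb_vals),
                        units = "FIA", decay_corrected = TRUE,
                        frame_durations = frames)

  bt <- config$blood_times_min
  cp <- gamma_noise(.plasma_conc(config, bt))
  wbld <- gamma_noise(.plasma_conc(config, bt) / config$partition_ratio)
  bound <- .bound_percent_true(config, bt)
  sup <- cp * (1 - bound / 100)
  fp <- .parent_fraction_true(config, bt)
  if (config$gamma_sigma > 0) {
    fp <- pmin(1, pmax(0, fp * exp(stats::rnorm(length(fp), 0,
                                                config$gamma_sigma))))
  }
  plasma <- plasma_sample_series(bt, wbld, cp, supernatant = sup,
                                 parent_fraction = fp,
                                 decay_corrected = TRUE)

  vol <- .urine_volume_ml(config, scan)
  conc_kbq_ml <- .bladder_fia(config, scan) *
    config$injected_activity_mbq * 1000 / vol
  bladder_df <- data.frame(time_min = scan, volume_ml = vol,
                           conc_kbq_ml = conc_kbq_ml)

  voids <- if (length(config$void_times_min)) {
    data.frame(time_min = config$void_times_min,
               volume_ml = .urine_volume_ml(config, config$void_times_min),
               activity_fia = diff(c(0, .excreted_fia(config,
                                                      config$void_times_min))))
  } else {
    data.frame(time_min = numeric(0), volume_ml = numeric(0),
               activity_fia = numeric(0))
  }

  structure(
    list(tacs = tacs, remainder_tac = remainder_tac,
         whole_body_tac = whole_body_tac, plasma = plasma,
         bladder = bladder_df, voids = voids,
         ground_truth = .ground_truth(config), config = config),
    class = "synth_subject"
  )
}

#' @export
print.synth_subject <- function(x, ...) {
  cat(sprintf(
    "<synth_subject> %d source organ curves + bladder, %d blood samples, seed %d%s\n",
    length(x$tacs) - 1L, length(x$plasma$times), x$config$seed,
    if (x$config$pet_sigma > 0 || x$config$gamma_sigma > 0) " (noisy)"
    else " (noise-free)"))
  invisible(x)
}

#' Generate the dehydrated (high bladder concentration) subject
#'
#' Same kinetics as [generate_subject()] but with halved urine production,
#' emulating a subject who fasted without water: the bladder activity is
#' diluted into less urine, roughly doubling the peak bladder
#' concentration/SUV while leaving every non-bladder curve unchanged.
#'
#' @param config A [subject_config()]; its urine production rate is scaled
#'   by `rate_factor`.
#' @param rate_factor Urine production multiplier (default 0.5).
#' @return A `"synth_subject"`.
#' @export
generate_outlier_subject <- function(config = subject_config(),
                                     rate_factor = 0.5) {
  stopifnot(inherits(config, "subject_config"), rate_factor > 0)
  config$urine_rate_ml_min <- config$urine_rate_ml_min * rate_factor
  generate_subject(config)
}

#' Generate a toy S-value table
#'
#' Random but reproducible source-by-target dose factor matrix for tests
#' and demos: strictly positive, diagonally dominant (self-dose at least
#' 10 times any cross-dose), with a "remainder of body" source row.
#'
#' @param n_organs Number of organs (>= 2); names are taken from the
#'   default organ set (recycled with suffixes if more are requested).
#' @param seed RNG seed; the same seed yields the identical table.
#' @return An [svalue_table()] labelled as a synthetic toy phantom.
#' @export
generate_toy_svalue_table <- function(n_organs, seed = 1L) {
  n_organs <- as.integer(n_organs)
  if (n_organs < 2L) .stopf("need at least 2 organs")
  base <- c(default_organ_kinetics()$organ, "urinary bladder")
  organs <- if (n_organs <= length(base)) base[seq_len(n_organs)] else {
    c(base, paste0("organ ", seq_len(n_organs - length(base))))
  }
  with_seed(seed, {
    cross <- matrix(stats::runif(n_organs^2, 0.001, 0.01),
                    nrow = n_organs)
    diag(cross) <- stats::runif(n_organs, 0.15, 1.0)
    remainder <- stats::runif(n_organs, 0.001, 0.01)
    m <- rbind(cross, remainder)
    rownames(m) <- c(organs, "remainder of body")
    colnames(m) <- organs
    svalue_table(m, phantom_id = sprintf("synthetic toy phantom (%d organs, seed %d)",
                                         n_organs, seed))
  })
}
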