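#' Pipeline configuration
#'
#' Analysis choices for [run_pipeline()].  The defaults reproduce the
#' conventional clinical dosimetry protocol for a short-lived renally
#' excreted tracer: 3.5-h bladder voiding interval, tail fit from 60 min,
#' whole-body substitution for tissues missing from the dose report.
#'
#' @param nuclide A [nuclide()].
#' @param voiding_interval_h Bladder voiding interval for the dynamic
#'   bladder model, hours.
#' @param tail_start_min Start of the terminal elimination phase for the
#'   plasma tail fit, minutes.
#' @param substitution Missing-tissue policy for [effective_dose()].
#' @param max_terms Maximum exponential terms per organ fit.
#' @param administered_activity_mbq Activity for the administered-dose line
#'   of the report, MBq.
#' @param seed Seed recorded in the manifest (the deterministic stages do
#'   not consume randomness themselves).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(nuclide = ga68(),
                            voiding_interval_h = 3.5,
                            tail_start_min = 60,
                            substitution = c("whole_body", "omit"),
                            max_terms = 3,
                            administered_activity_mbq = 150,
                            seed = 1L) {
  substitution <- match.arg(substitution)
  if (voiding_interval_h <= 0) .stopf("voiding interval must be > 0 h")
  if (tail_start_min < 0) .stopf("tail_start_min must be >= 0")
  structure(
    list(nuclide = nuclide, voiding_interval_h = voiding_interval_h,
         tail_start_min = tail_start_min, substitution = substitution,
         max_terms = max_terms,
         administered_activity_mbq = administered_activity_mbq,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# fit the bladder filling curve f * (1 - exp(-lambda_b t)) by bounded LM
.fit_bladder_filling <- function(curve) {
  t <- curve$times
  y <- curve$values
  f0 <- max(y)
  # crude half-rise rate guess
  half <- t[which(y >= f0 / 2)[1L]]
  l0 <- if (is.na(half) || half <= 0) 0.005 else log(2) / half
  fit <- minpack.lm::nls.lm(
    par = c(f = max(f0, 1e-6), lambda = l0),
    fn = function(p) y - p[1L] * (1 - exp(-p[2L] * t)),
    lower = c(0, 0), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 500))
  list(f = unname(fit$par[1L]), lambda = unname(fit$par[2L]),
       rss = fit$deviance)
}

#' Run the full kinetics-to-dose-and-PK pipeline
#'
#' Chains the analysis stages on one subject's data:
#' \enumerate{
#'   \item fit each source-organ TAC with [fit_sum_of_exponentials()] and
#'     integrate to residence times ([compute_tiac()]);
#'   \item fit the bladder filling curve `f (1 - exp(-lambda_b t))` and
#'     apply the dynamic voiding model ([bladder_tiac()]) at the configured
#'     voiding interval;
#'   \item whole-body residence time = fitted non-bladder tissue TIAC +
#'     bladder TIAC, from which the remainder of body follows by
#'     subtraction ([remainder_of_body_tiac()]);
#'   \item assert the physical residence-time bound ([check_tiac_bound()]);
#'   \item organ dose-equivalents ([compute_absorbed_doses()]), ICRP-103
#'     effective dose ([effective_dose()]) and the administered-dose line;
#'   \item blood-side PK: plasma-to-blood ratio, protein binding, parent
#'     fraction fit, metabolite correction, tail fits and clearances for
#'     total and parent plasma activity.
#' }
#' Identical inputs and config give identical output (all stages are
#' deterministic).
#'
#' @param subject A `"synth_subject"` from [generate_subject()], or a list
#'   with elements `tacs` (named list of FIA [tac()]s including
#'   `"urinary bladder"`), `whole_body_tac`, and optionally `plasma`.
#' @param svalues An [svalue_table()] resolving every source organ.
#' @param config A [pipeline_config()].
#' @return Object of class `"dose_pipeline_result"` with `tiacs`
#'   ([residence_time_set()]), `fits`, `bladder_fit`, `dose_report`
#'   (effective dose filled in), `administered_dose_msv`, `pk` (list of
#'   `"pk_parameters"`), `blood_summaries`, `manifest`.
#' @export
run_pipeline <- function(subject, svalues, config = pipeline_config()) {
  stopifnot(inherits(svalues, "svalue_table"),
            inherits(config, "pipeline_config"))
  tacs <- subject$tacs
  if (is.null(tacs) || is.null(names(tacs))) {
    .stopf("subject must carry a named list of source-organ TACs")
  }
  bl_name <- names(tacs)[.norm_name(names(tacs)) == "urinary bladder"]
  if (length(bl_name) != 1L) {
    .stopf("pipeline stage 'kinetics': need exactly one urinary bladder TAC")
  }
  organ_names <- setdiff(names(tacs), bl_name)

  # stage 1: organ fits -> TIACs
  fits <- lapply(tacs[organ_names], fit_sum_of_exponentials,
                 max_terms = config$max_terms)
  organ_tiacs <- vapply(fits, compute_tiac, numeric(1),
                        nuclide = config$nuclide)

  # stage 2: dynamic bladder model from the fitted filling curve
  bl_fit <- .fit_bladder_filling(tacs[[bl_name]])
  bl_params <- bladder_model_params(
    voiding_interval_h = config$voiding_interval_h,
    excreted_fraction = bl_fit$f,
    biologic_rate_per_min = bl_fit$lambda)
  bl_tiac <- bladder_tiac(bl_params, config$nuclide)

  # stage 3: whole body (non-bladder tissue fit + modelled bladder)
  if (is.null(subject$whole_body_tac)) {
    .stopf("pipeline stage 'whole body': whole_body_tac is required")
  }
  wb <- subject$whole_body_tac
  blv <- tacs[[bl_name]]
  if (!isTRUE(all.equal(wb$times, blv$times))) {
    .stopf("whole-body and bladder TACs must share the sampling grid")
  }
  tissue <- tac("non-bladder tissue", wb$times,
                pmax(wb$values - blv$values, 0), units = "FIA",
                decay_corrected = wb$decay_corrected)
  tissue_fit <- fit_sum_of_exponentials(tissue, max_terms = 2)
  wb_tiac <- compute_tiac(tissue_fit, config$nuclide) + bl_tiac

  sources <- c(organ_tiacs, stats::setNames(bl_tiac, bl_name))
  remainder <- remainder_of_body_tiac(wb_tiac, residence_time_set(sources))
  tiacs <- residence_time_set(sources, remainder_of_body = remainder)
  check_tiac_bound(tiacs, config$nuclide)

  # stage 5: dosimetry
  report <- compute_absorbed_doses(tiacs, svalues)
  ed <- tryCatch(
    effective_dose(report, substitution = config$substitution),
    error = function(e) {
      .warnf("effective dose not computed: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(ed)) report$effective_dose_msv_mbq <- as.numeric(ed)
  admin <- if (is.null(ed)) NULL else {
    dose_for_administration(as.numeric(ed), config$administered_activity_mbq)
  }

  # stage 6: blood PK
  pk <- NULL; blood <- NULL
  if (!is.null(subject$plasma)) {
    ser <- subject$plasma
    ratio <- plasma_to_blood_ratio(ser)
    bound <- if (is.null(ser$supernatant)) NULL else protein_bound_fraction(ser)
    total_tac <- tac("plasma total", ser$times, ser$plasma,
                     units = "kBq/mL", decay_corrected = ser$decay_corrected)
    pf_fit <- if (is.null(ser$parent_fraction)) NULL else {
      fit_parent_fraction(ser$times, ser$parent_fraction)
    }
    inj <- if (!is.null(subject$config)) {
      subject$config$injected_activity_mbq
    } else config$administered_activity_mbq
    tail_total <- fit_monoexp_tail(total_tac, config$tail_start_min)
    cl_total <- clearance(total_tac, inj, tail_total$lambda_tail)
    pk <- list(total = list(tail = tail_total, clearance = cl_total))
    if (!is.null(pf_fit)) {
      parent_tac <- metabolite_correct(total_tac, pf_fit)
      tail_parent <- fit_monoexp_tail(parent_tac, config$tail_start_min)
      pk$parent <- list(tail = tail_parent,
                        clearance = clearance(parent_tac, inj,
                                              tail_parent$lambda_tail))
    }
    blood <- list(plasma_to_blood = ratio, protein_binding = bound,
                  parent_fraction_fit = pf_fit)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tracerdose")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = list(nuclide = config$nuclide$name,
                  voiding_interval_h = config$voiding_interval_h,
                  tail_start_min = config$tail_start_min,
                  substitution = config$substitution,
                  max_terms = config$max_terms,
                  administered_activity_mbq = config$administered_activity_mbq),
    phantom = svalues$phantom_id
  )

  structure(
    list(tiacs = tiacs, fits = fits, tissue_fit = tissue_fit,
         bladder_fit = bl_fit, bladder_tiac_h = bl_tiac,
         whole_body_tiac_h = wb_tiac, dose_report = report,
         effective_dose_msv_mbq = if (is.null(ed)) NA_real_ else as.numeric(ed),
         administered_dose_msv = admin, pk = pk, blood_summaries = blood,
         manifest = manifest),
    class = "dose_pipeline_result"
  )
}

#' @export
print.dose_pipeline_result <- function(x, ...) {
  cat("== Residence times (h) ==\n")
  print(x$tiacs)
  cat("\n== Dose report ==\n")
  print(x$dose_report)
  if (!is.null(x$administered_dose_msv)) {
    cat(sprintf("Dose from %g MBq administered: %.2g mSv\n",
                x$manifest$config$administered_activity_mbq,
                x$administered_dose_msv))
  }
  if (!is.null(x$pk)) {
    cat("\n== Plasma pharmacokinetics ==\n")
    for (nm in names(x$pk)) {
      cat(sprintf("[%s] t1/2 = %.4g min, CL = %.4g mL/min\n", nm,
                  x$pk[[nm]]$tail$half_life,
                  x$pk[[nm]]$clearance$clearance))
    }
  }
  invisible(x)
}

#' Write a pipeline result as JSON
#'
#' Full-precision JSON mirroring the printed report: per-organ residence
#' times and dose-equivalents, effective dose, PK parameters, and the run
#' manifest.
#'
#' @param result A `"dose_pipeline_result"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_json <- function(result, path) {
  stopifnot(inherits(result, "dose_pipeline_result"))
  pkj <- if (is.null(result$pk)) NULL else lapply(result$pk, function(p) {
    list(lambda_tail_per_min = p$tail$lambda_tail,
         half_life_min = p$tail$half_life,
         auc = p$clearance$auc,
         clearance_ml_min = p$clearance$clearance,
         extrapolated_fraction = p$clearance$extrapolated_fraction,
         flags = c(p$tail$flags, p$clearance$flags))
  })
  jsonlite::write_json(
    list(residence_times_h = c(as.list(result$tiacs$organs),
                               list(`remainder of body` =
                                      result$tiacs$remainder_of_body)),
         organ_doses_usv_mbq = as.list(result$dose_report$organ_doses),
         effective_dose_msv_mbq = result$effective_dose_msv_mbq,
         administered_dose_msv = result$administered_dose_msv,
         pk = pkj,
         manifest = result$manifest),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
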