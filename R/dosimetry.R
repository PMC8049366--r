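#' S-value table
#'
#' Source-by-target matrix of dose factors `S(target <- source)` in
#' mSv/(MBq.h) for a reference phantom.  Any residence-time source the dose
#' engine sees must resolve to a row; a designated "remainder of body" row
#' is expected for whole-pipeline use.
#'
#' @param matrix Numeric matrix, rows = source organs, columns = target
#'   organs, all entries `>= 0`; dimnames required.
#' @param phantom_id Free-text phantom description (e.g. "adult male ~70 kg").
#' @return Object of class `"svalue_table"`.
#' @export
svalue_table <- function(matrix, phantom_id = "unspecified phantom") {
  if (!is.matrix(matrix) || !is.numeric(matrix)) .stopf("S values must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    .stopf("S-value matrix needs source rownames and target colnames")
  }
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    .stopf("all S values must be finite and >= 0")
  }
  structure(list(matrix = matrix, phantom_id = as.character(phantom_id)),
            class = "svalue_table")
}

#' @export
print.svalue_table <- function(x, ...) {
  cat(sprintf("<svalue_table> %s: %d sources x %d targets, mSv/(MBq.h)\n",
              x$phantom_id, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Per-organ dose report
#'
#' @param organ_doses Named numeric vector, target organ -> dose-equivalent
#'   in uSv/MBq, all `>= 0`.
#' @param effective_dose_msv_mbq Optional effective dose, mSv/MBq.
#' @param provenance Optional list (phantom, weights version, residence-time
#'   source) recorded verbatim.
#' @return Object of class `"dose_report"`.
#' @export
dose_report <- function(organ_doses, effective_dose_msv_mbq = NULL,
                        provenance = list()) {
  organ_doses <- unlist(organ_doses)
  if (is.null(names(organ_doses))) .stopf("organ_doses must be named")
  if (any(!is.finite(organ_doses)) || any(organ_doses < 0)) {
    .stopf("all doses must be finite and >= 0")
  }
  structure(list(organ_doses = organ_doses,
                 effective_dose_msv_mbq = effective_dose_msv_mbq,
                 provenance = provenance),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report> organ dose-equivalents (uSv/MBq):\n")
  df <- data.frame(dose = sprintf("%.1f", x$organ_doses))
  rownames(df) <- names(x$organ_doses)
  print(df)
  if (!is.null(x$effective_dose_msv_mbq)) {
    cat(sprintf("Effective dose: %.3f mSv/MBq\n", x$effective_dose_msv_mbq))
  }
  if (length(x$provenance)) {
    cat("Provenance:", paste(names(x$provenance),
                             unlist(x$provenance), sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.dose_report <- function(x, ...) {
  data.frame(organ = names(x$organ_doses), dose_usv_mbq = unname(x$organ_doses),
             stringsAsFactors = FALSE)
}

# resolve one residence-time source name against S-table rows
.resolve_source <- function(name, rows) {
  hit <- which(.norm_name(rows) == .norm_name(name))
  if (length(hit) != 1L) {
    .stopf("source organ '%s' not found in S-value table; available: %s",
           name, paste(rows, collapse = ", "))
  }
  hit
}

#' Organ dose-equivalents from residence times
#'
#' MIRD-style matrix-vector product: for each target,
#' `D(target) = sum_source tau(source) * S(target <- source)`, giving
#' uSv/MBq (the S table is mSv/(MBq.h), residence times are hours).  For a
#' pure positron/photon emitter the radiation weighting factor is 1, so
#' these absorbed doses double as equivalent doses.
#'
#' @param tiacs A [residence_time_set()]; its remainder entry (if present)
#'   must resolve to a "remainder of body" source row.
#' @param svalues An [svalue_table()].
#' @return A [dose_report()] (organ part only; effective dose is computed
#'   separately by [effective_dose()]).
#' @export
compute_absorbed_doses <- function(tiacs, svalues) {
  stopifnot(inherits(tiacs, "tiac_set"), inherits(svalues, "svalue_table"))
  S <- svalues$matrix
  tau <- tiacs$organs
  if (!is.null(tiacs$remainder_of_body)) {
    tau <- c(tau, "remainder of body" = tiacs$remainder_of_body)
  }
  rows <- vapply(names(tau), .resolve_source, integer(1), rows = rownames(S))
  doses <- drop(tau %*% S[rows, , drop = FALSE]) * 1000  # mSv -> uSv
  dose_report(doses, provenance = list(phantom = svalues$phantom_id))
}

#' ICRP-103 tissue weighting factors
#'
#' The bundled weights: gonads 0.08; red marrow, colon, lung, stomach and
#' breast 0.12 each; bladder, esophagus, liver and thyroid 0.04 each; bone
#' surface, brain, salivary glands and skin 0.01 each; remainder 0.12
#' shared as the arithmetic mean over the 13 male remainder tissues.
#' The factors sum to 1 exactly.
#'
#' @return Object of class `"tissue_weights"` with `weights` (named,
#'   `remainder` included) and `remainder_tissues`.
#' @export
icrp103_weights <- function() {
  w <- c(gonads = 0.08,
         red_marrow = 0.12, colon = 0.12, lung = 0.12, stomach = 0.12,
         breast = 0.12,
         bladder = 0.04, esophagus = 0.04, liver = 0.04, thyroid = 0.04,
         bone_surface = 0.01, brain = 0.01, salivary_glands = 0.01,
         skin = 0.01,
         remainder = 0.12)
  rem <- c("adrenals", "extrathoracic_region", "gallbladder", "heart_wall",
           "kidneys", "lymphatic_nodes", "muscle", "oral_mucosa", "pancreas",
           "prostate", "small_intestine", "spleen", "thymus")
  tissue_weights(w, rem)
}

#' @rdname icrp103_weights
#' @param weights Named numeric vector of weighting factors, optionally
#'   including a `remainder` entry; must sum to 1 (to 1e-12) with all
#'   entries `>= 0`.
#' @param remainder_tissues Character vector of remainder tissue keys
#'   (empty if there is no remainder weight).
#' @export
tissue_weights <- function(weights, remainder_tissues = character(0)) {
  if (any(weights < 0)) .stopf("tissue weighting factors must be >= 0")
  if (abs(sum(weights) - 1) > 1e-12) {
    .stopf("tissue weighting factors must sum to 1 (got %.15f)", sum(weights))
  }
  structure(list(weights = weights,
                 remainder_tissues = remainder_tissues),
            class = "tissue_weights")
}

# tissue key -> acceptable organ labels (normalized), in lookup order
.tissue_aliases <- list(
  gonads = c("gonads", "testes", "ovaries"),
  red_marrow = c("red marrow", "red bone marrow"),
  colon = c("colon"),
  lung = c("lungs", "lung"),
  stomach = c("stomach wall", "stomach"),
  breast = c("breast", "breasts"),
  bladder = c("urinary bladder wall", "urinary bladder", "bladder wall",
              "bladder"),
  esophagus = c("esophagus", "oesophagus"),
  liver = "liver",
  thyroid = "thyroid",
  bone_surface = c("osteogenic cells", "bone surfaces", "bone surface"),
  brain = "brain",
  salivary_glands = c("salivary glands", "salivary gland"),
  skin = "skin",
  adrenals = "adrenals",
  extrathoracic_region = c("extrathoracic region", "et region",
                           "extrathoracic airways"),
  gallbladder = c("gallbladder wall", "gall bladder wall", "gallbladder",
                  "gall bladder"),
  heart_wall = c("heart wall", "heart"),
  kidneys = "kidneys",
  lymphatic_nodes = c("lymphatic nodes", "lymph nodes"),
  muscle = "muscle",
  oral_mucosa = "oral mucosa",
  pancreas = "pancreas",
  prostate = "prostate",
  small_intestine = c("small intestine", "small intestine wall"),
  spleen = "spleen",
  thymus = "thymus"
)

# look up one tissue's dose in a named dose vector (normalized names);
# returns NA when absent.  "colon" falls back to the mean of left and
# right colon when no single colon entry exists.  Tissue keys without an
# alias entry (custom weight sets) match their own normalized name.
.tissue_dose <- function(tissue, doses) {
  nm <- names(doses)
  aliases <- .tissue_aliases[[tissue]]
  if (is.null(aliases)) aliases <- .norm_name(tissue)
  for (alias in aliases) {
    hit <- which(nm == alias)
    if (length(hit)) return(unname(doses[hit[1L]]))
  }
  if (tissue == "colon") {
    left <- which(nm %in% c("colon left", "left colon"))
    right <- which(nm %in% c("colon right", "right colon"))
    if (length(left) && length(right)) {
      return(mean(c(doses[left[1L]], doses[right[1L]])))
    }
  }
  NA_real_
}

#' ICRP-103 effective dose
#'
#' `E = sum_T w_T H_T` over the weighted tissues, with the standard
#' male-phantom mappings (colon = mean of left and right colon, gonads =
#' testes, bone surface = osteogenic cells, stomach = stomach wall,
#' bladder = urinary bladder wall) and the remainder contribution taken as
#' the arithmetic mean of the remainder tissues.  Tissues missing from the
#' report are handled by the substitution policy:
#' \describe{
#'   \item{`"whole_body"`}{(default) substitute the report's whole-body
#'     dose for every missing tissue (requires a whole-body entry);}
#'   \item{`"omit"`}{drop missing weighted tissues and renormalize the
#'     remaining weights; the remainder mean runs over present remainder
#'     tissues only.}
#' }
#'
#' @param report A [dose_report()] with organ doses in uSv/MBq.
#' @param weights A [tissue_weights()]; defaults to [icrp103_weights()].
#' @param substitution `"whole_body"` or `"omit"`.
#' @return Effective dose in mSv/MBq (numeric scalar) with attribute
#'   `"breakdown"` giving the per-tissue doses used (uSv/MBq).
#' @examples
#' rep <- dose_report(c("kidneys" = 20, "liver" = 20, "whole body" = 20))
#' effective_dose(rep)  # all equal doses -> 20/1000 = 0.02 mSv/MBq
#' @export
effective_dose <- function(report, weights = icrp103_weights(),
                           substitution = c("whole_body", "omit")) {
  stopifnot(inherits(report, "dose_report"), inherits(weights, "tissue_weights"))
  substitution <- match.arg(substitution)
  doses <- report$organ_doses
  names(doses) <- .norm_name(names(doses))
  w <- weights$weights

  wb <- NA_real_
  hit <- which(names(doses) %in% c("whole body", "total body"))
  if (length(hit)) wb <- unname(doses[hit[1L]])
  fill <- function(x) {
    if (!is.na(x)) return(x)
    if (substitution == "whole_body") {
      if (is.na(wb)) {
        .stopf("substitution policy 'whole_body' needs a whole-body dose entry")
      }
      wb
    } else NA_real_
  }

  weighted <- setdiff(names(w), "remainder")
  H <- vapply(weighted, function(tis) fill(.tissue_dose(tis, doses)),
              numeric(1))
  used_w <- w[weighted]
  used_H <- H
  if ("remainder" %in% names(w)) {
    rem_doses <- vapply(weights$remainder_tissues,
                        function(tis) fill(.tissue_dose(tis, doses)),
                        numeric(1))
    H_rem <- if (length(rem_doses) == 0L || all(is.na(rem_doses))) NA_real_
             else mean(rem_doses, na.rm = TRUE)
    used_w <- c(used_w, remainder = unname(w["remainder"]))
    used_H <- c(used_H, remainder = H_rem)
  }
  keep <- !is.na(used_H)
  if (substitution == "whole_body" && !all(keep)) {
    .stopf("internal error: unfilled tissue under whole_body policy")
  }
  if (!any(keep)) .stopf("no weighted tissue resolvable in the dose report")
  wk <- used_w[keep] / sum(used_w[keep])   # renormalize under 'omit'
  E <- sum(wk * used_H[keep]) / 1000       # uSv -> mSv
  structure(E, breakdown = used_H[keep], weights_used = wk)
}

#' Effective dose for an administered activity
#'
#' Product of the effective dose coefficient and the administered activity.
#' Human-readable reports round to 2 significant figures; the returned
#' value keeps full precision.
#'
#' @param effective_dose_coeff_msv_mbq Effective dose coefficient, mSv/MBq.
#' @param administered_activity_mbq Administered activity, MBq.
#' @return Dose in mSv.
#' @examples
#' dose_for_administration(0.022, 150)  # 3.3 mSv
#' @export
dose_for_administration <- function(effective_dose_coeff_msv_mbq,
                                    administered_activity_mbq) {
  if (effective_dose_coeff_msv_mbq < 0 || administered_activity_mbq < 0) {
    .stopf("dose coefficient and administered activity must be >= 0")
  }
  effective_dose_coeff_msv_mbq * administered_activity_mbq
}
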