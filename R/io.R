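#' Read and write time-activity curve CSV files
#'
#' The TAC format has the mandatory header
#' `organ,time_min,value,units,decay_corrected` (UTF-8, `.` decimal
#' separator); unknown extra columns are warned about, not fatal.
#'
#' @param path File path.
#' @return `read_tac_csv()`: a named list of [tac()] objects (one per
#'   organ); `write_tac_csv()`: the path, invisibly.
#' @export
read_tac_csv <- function(path) {
  df <- .read_checked_csv(path, c("organ", "time_min", "value", "units",
                                  "decay_corrected"))
  out <- lapply(split(df, df$organ), function(d) {
    d <- d[order(d$time_min), ]
    units <- unique(d$units)
    dc <- unique(d$decay_corrected)
    if (length(units) != 1L || length(dc) != 1L) {
      .stopf("organ '%s': units/decay_corrected must be constant per organ",
             d$organ[1L])
    }
    tac(d$organ[1L], d$time_min, d$value, units = units,
        decay_corrected = as.logical(dc))
  })
  out[unique(df$organ)]
}

#' @rdname read_tac_csv
#' @param tacs A [tac()] or list of them.
#' @export
write_tac_csv <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  df <- do.call(rbind, lapply(tacs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write plasma sample CSV files
#'
#' Format: `time_min,whole_blood,plasma,supernatant,parent_fraction`;
#' the two optional columns may be empty (parsed as missing).
#'
#' @param path File path.
#' @param decay_corrected Flag recorded on the series (the CSV carries
#'   concentrations only).
#' @return `read_plasma_csv()`: a [plasma_sample_series()];
#'   `write_plasma_csv()`: the path, invisibly.
#' @export
read_plasma_csv <- function(path, decay_corrected = TRUE) {
  df <- .read_checked_csv(path, c("time_min", "whole_blood", "plasma"),
                          optional = c("supernatant", "parent_fraction"))
  opt <- function(col) {
    if (!col %in% names(df) || all(is.na(df[[col]]))) NULL else df[[col]]
  }
  plasma_sample_series(df$time_min, df$whole_blood, df$plasma,
                       supernatant = opt("supernatant"),
                       parent_fraction = opt("parent_fraction"),
                       decay_corrected = decay_corrected)
}

#' @rdname read_plasma_csv
#' @param series A [plasma_sample_series()].
#' @export
write_plasma_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read and write S-value CSV files
#'
#' First column `source`, remaining columns the target organ names, cells
#' in mSv/(MBq.h).  Phantom metadata may sit in a sidecar JSON
#' (`<path>.json`) with a `phantom_id` field.
#'
#' @param path File path.
#' @param phantom_id Phantom label; if `NULL`, taken from the sidecar JSON
#'   when present.
#' @return `read_svalue_csv()`: an [svalue_table()]; `write_svalue_csv()`:
#'   the path, invisibly.
#' @export
read_svalue_csv <- function(path, phantom_id = NULL) {
  if (!file.exists(path)) .stopf("S-value file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "source") {
    .stopf("S-value CSV must have 'source' as its first column (got '%s')",
           names(df)[1L])
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$source
  if (is.null(phantom_id)) {
    sidecar <- paste0(path, ".json")
    phantom_id <- if (file.exists(sidecar)) {
      jsonlite::read_json(sidecar)$phantom_id
    } else "unspecified phantom"
  }
  svalue_table(m, phantom_id = phantom_id)
}

#' @rdname read_svalue_csv
#' @param svalues An [svalue_table()].
#' @export
write_svalue_csv <- function(svalues, path) {
  stopifnot(inherits(svalues, "svalue_table"))
  df <- data.frame(source = rownames(svalues$matrix),
                   svalues$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(phantom_id = svalues$phantom_id),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# read a CSV enforcing mandatory columns; warn on unknown ones
.read_checked_csv <- function(path, mandatory, optional = character(0)) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    .stopf("%s: missing mandatory column(s): %s", path,
           paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(df), c(mandatory, optional))
  if (length(unknown)) {
    .warnf("%s: ignoring unknown column(s): %s", path,
           paste(unknown, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[mandatory]))
  if (length(bad)) {
    .stopf("%s: malformed row(s) at line(s) %s", path,
           paste(bad + 1L, collapse = ", "))
  }
  df
}

#' Reference cohort summaries bundled with the package
#'
#' Transcribed published cohort summary tables (healthy adult males
#' injected with a renally excreted Ga-68-labelled Siglec-9 peptide
#' tracer), shipped as plain-CSV validation fixtures:
#' \describe{
#'   \item{`"residence_times"`}{per-source-organ normalized numbers of
#'     disintegrations (hours): mean, SD, min, max;}
#'   \item{`"dose_equivalents"`}{per-target-organ dose-equivalents
#'     (uSv/MBq): mean, SD, min, max, including a whole-body row.}
#' }
#'
#' @param which Which table to load.
#' @return Data frame with columns `site`, `mean`, `sd`, `min`, `max`.
#' @export
reference_summary <- function(which = c("residence_times",
                                        "dose_equivalents")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_healthy.csv"),
                      package = "tracerdose", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
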