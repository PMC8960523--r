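#' @keywords internal
"_PACKAGE"

# Canonical column orders for the two tabular interchange formats.
COHORT_COLUMNS <- c(
  "patient_id", "sex", "gfr_ml_min", "cycle", "aa_gbq", "weight_kg",
  "tumour_ad_gy", "kidney_ad_gy", "tumour_teff_h", "kidney_teff_h"
)
SERIES_COLUMNS <- c("patient_id", "cycle", "structure", "time_h", "rate_gy_per_h")
SERIES_STRUCTURES <- c("tumour", "kidney_left", "kidney_right")

#' Construct a patient course
#'
#' A patient course bundles the per-patient covariates (sex, glomerular
#' filtration rate) with an ordered table of per-cycle dosimetry records:
#' administered activity (GBq), weight (kg), tumour and kidney absorbed dose
#' (Gy, kidney as the mean of left and right), and tumour and kidney
#' effective half-life (h). Cycle indices are 1-based and must be contiguous.
#'
#' @param patient_id Short patient label (e.g. `"P1"`).
#' @param sex `"F"` or `"M"`.
#' @param gfr_ml_min Glomerular filtration rate in mL/min; must be positive.
#' @param cycles `data.frame` with columns `cycle`, `aa_gbq`, `weight_kg`,
#'   `tumour_ad_gy`, `kidney_ad_gy`, `tumour_teff_h`, `kidney_teff_h`.
#' @return An object of class `patient_course`.
#' @export
#' @examples
#' pc <- patient_course("X1", "F", 120,
#'   data.frame(cycle = 1:2, aa_gbq = c(2.0, 2.5), weight_kg = c(30, 31),
#'              tumour_ad_gy = c(15, 12), kidney_ad_gy = c(1.5, 1.4),
#'              tumour_teff_h = c(45, 40), kidney_teff_h = c(90, 95)))
#' validate_course(pc)
patient_course <- function(patient_id, sex, gfr_ml_min, cycles) {
  cycles <- as.data.frame(cycles)
  need <- setdiff(
    c("cycle", "aa_gbq", "weight_kg", "tumour_ad_gy", "kidney_ad_gy",
      "tumour_teff_h", "kidney_teff_h"),
    names(cycles)
  )
  if (length(need) > 0) {
    stop("patient_course: missing cycle columns: ", paste(need, collapse = ", "))
  }
  cycles <- cycles[order(cycles$cycle), , drop = FALSE]
  rownames(cycles) <- NULL
  obj <- structure(
    list(
      patient_id = as.character(patient_id),
      sex = as.character(sex),
      gfr_ml_min = as.numeric(gfr_ml_min),
      cycles = cycles
    ),
    class = "patient_course"
  )
  obj
}

#' @export
print.patient_course <- function(x, ...) {
  cat(sprintf(
    "<patient_course> %s (sex %s, GFR %g mL/min), %d cycle(s)\n",
    x$patient_id, x$sex, x$gfr_ml_min, nrow(x$cycles)
  ))
  print(x$cycles, row.names = FALSE)
  invisible(x)
}

#' Validate a patient course
#'
#' Checks the structural invariants of a [patient_course()]: contiguous
#' 1-based cycle indices, strictly positive administered activity and weight,
#' non-negative doses and half-lives, positive GFR, and a recognised sex
#' code. Returns findings rather than raising conditions, so that a whole
#' cohort can be screened and all defects reported at once.
#'
#' @param course A `patient_course`.
#' @return Character vector of human-readable findings; empty if the course
#'   is valid.
#' @export
validate_course <- function(course) {
  findings <- character(0)
  say <- function(fmt, ...) sprintf("%s: %s", course$patient_id, sprintf(fmt, ...))
  if (!course$sex %in% c("F", "M")) {
    findings <- c(findings, say("sex must be 'F' or 'M', got '%s'", course$sex))
  }
  if (!is.finite(course$gfr_ml_min) || course$gfr_ml_min <= 0) {
    findings <- c(findings, say("GFR must be > 0, got %s", format(course$gfr_ml_min)))
  }
  cy <- course$cycles
  if (nrow(cy) < 1) {
    return(c(findings, say("course has no cycles")))
  }
  if (anyDuplicated(cy$cycle)) {
    findings <- c(findings, say("duplicate cycle indices"))
  }
  if (!identical(as.integer(cy$cycle), seq_len(nrow(cy)))) {
    findings <- c(findings, say("non-contiguous cycles (expected 1..%d, got %s)",
                                nrow(cy), paste(cy$cycle, collapse = ",")))
  }
  num_cols <- c("aa_gbq", "weight_kg", "tumour_ad_gy", "kidney_ad_gy",
                "tumour_teff_h", "kidney_teff_h")
  for (col in num_cols) {
    v <- cy[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      findings <- c(findings, say("column %s has non-finite or non-numeric values", col))
      next
    }
    if (col %in% c("aa_gbq", "weight_kg")) {
      bad <- which(v <= 0)
      if (length(bad) > 0) {
        findings <- c(findings, say("column %s must be > 0 (cycle %s)",
                                    col, paste(cy$cycle[bad], collapse = ",")))
      }
    } else if (any(v < 0)) {
      bad <- which(v < 0)
      findings <- c(findings, say("column %s must be >= 0 (cycle %s)",
                                  col, paste(cy$cycle[bad], collapse = ",")))
    }
  }
  findings
}

cohort_from_table <- function(tab, source = "cohort") {
  missing_cols <- setdiff(COHORT_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing column(s): %s", source,
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) == 0) return(list())
  num_cols <- setdiff(COHORT_COLUMNS, c("patient_id", "sex"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) | is.na(tab[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric value in column '%s' at row %d",
                   source, col, bad[1]))
    }
    tab[[col]] <- v
  }
  key <- paste(tab$patient_id, tab$cycle, sep = "#")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("%s: duplicate (patient, cycle) record: %s", source,
                 sub("#", " cycle ", dup)))
  }
  ids <- unique(tab$patient_id)
  cohort <- lapply(ids, function(id) {
    rows <- tab[tab$patient_id == id, , drop = FALSE]
    patient_course(
      patient_id = id,
      sex = rows$sex[1],
      gfr_ml_min = rows$gfr_ml_min[1],
      cycles = rows[, c("cycle", "aa_gbq", "weight_kg", "tumour_ad_gy",
                        "kidney_ad_gy", "tumour_teff_h", "kidney_teff_h")]
    )
  })
  findings <- unlist(lapply(cohort, validate_course))
  if (length(findings) > 0) {
    stop(sprintf("%s: invalid cohort:\n  %s", source,
                 paste(findings, collapse = "\n  ")))
  }
  cohort
}

#' Load a cohort from a CSV or JSON file
#'
#' The CSV schema is one row per patient-cycle with columns `patient_id`,
#' `sex`, `gfr_ml_min`, `cycle`, `aa_gbq`, `weight_kg`, `tumour_ad_gy`,
#' `kidney_ad_gy`, `tumour_teff_h`, `kidney_teff_h` (UTF-8, dot decimal
#' separator). The JSON format is an array of objects with identical field
#' names. All course invariants are enforced; malformed input raises an
#' error naming the offending column or row.
#'
#' @param path Path to the cohort file.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @return List of [patient_course()] objects.
#' @seealso [write_cohort()], [ludo_fixture()]
#' @export
load_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("load_cohort: file not found: ", path)
  tab <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
  if (nrow(tab) == 0 && format == "csv") {
    missing_cols <- setdiff(COHORT_COLUMNS, names(tab))
    if (length(missing_cols) > 0) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(missing_cols, collapse = ", ")))
    }
    return(list())
  }
  cohort_from_table(tab, source = path)
}

#' Flatten a cohort to one row per patient-cycle
#'
#' @param cohort List of `patient_course` objects.
#' @return `data.frame` in the cohort CSV column order.
#' @export
cohort_table <- function(cohort) {
  if (length(cohort) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(COHORT_COLUMNS)))
    names(out) <- COHORT_COLUMNS
    return(out)
  }
  do.call(rbind, lapply(cohort, function(pc) {
    data.frame(
      patient_id = pc$patient_id, sex = pc$sex, gfr_ml_min = pc$gfr_ml_min,
      pc$cycles[, c("cycle", "aa_gbq", "weight_kg", "tumour_ad_gy",
                    "kidney_ad_gy", "tumour_teff_h", "kidney_teff_h")],
      stringsAsFactors = FALSE
    )
  }))
}

#' Write a cohort to CSV or JSON
#'
#' Numeric fields are written with full precision (`format(..., digits = 15)`
#' for CSV) so that a write/load round trip reproduces all values exactly.
#'
#' @inheritParams load_cohort
#' @param cohort List of `patient_course` objects.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  tab <- cohort_table(cohort)
  if (format == "csv") {
    out <- tab
    for (col in names(out)) {
      if (is.numeric(out[[col]])) {
        out[[col]] <- vapply(out[[col]], function(v) base::format(v, digits = 15), "")
      }
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' The six-patient reference cohort
#'
#' Returns the packaged fixture: six pediatric neuroblastoma patients who
#' each received four cycles of [177Lu]Lu-DOTATATE in the LuDO trial
#' (ISRCTN98918118), with per-cycle administered activity, weight, tumour
#' and kidney absorbed dose (kidney = mean of left and right) and effective
#' half-lives, at the precision printed in the trial report. These values
#' are the regression ground truth for the analysis functions.
#'
#' @return List of 6 [patient_course()] objects with 4 cycles each.
#' @export
#' @examples
#' cohort <- ludo_fixture()
#' cohort[[1]]$cycles$tumour_ad_gy
ludo_fixture <- function() {
  path <- system.file("extdata", "ludo_cohort.csv", package = "cyclodose",
                      mustWork = TRUE)
  load_cohort(path, format = "csv")
}

#' Construct a dose-rate series
#'
#' A dose-rate series holds the timestamped absorbed-dose-rate samples
#' (Gy/h) for one structure in one treatment cycle — the raw input of the
#' dosimetry pipeline, derived clinically from serial quantitative SPECT.
#' The nominal schedule is 4/24/48/72 h post injection but arbitrary
#' positive times are accepted; times must be unique and strictly
#' increasing.
#'
#' @param patient_id Patient label.
#' @param cycle 1-based cycle index.
#' @param structure One of `"tumour"`, `"kidney_left"`, `"kidney_right"`.
#' @param time_h Sample times in hours post injection (>= 0).
#' @param rate_gy_per_h Absorbed dose rates in Gy/h (>= 0, finite).
#' @return Object of class `dose_rate_series` (a list with a `samples`
#'   data.frame).
#' @export
dose_rate_series <- function(patient_id, cycle, structure, time_h, rate_gy_per_h) {
  structure_name <- match.arg(structure, SERIES_STRUCTURES)
  if (length(time_h) != length(rate_gy_per_h)) {
    stop("dose_rate_series: time and rate lengths differ")
  }
  if (any(!is.finite(time_h)) || any(!is.finite(rate_gy_per_h))) {
    stop("dose_rate_series: non-finite sample")
  }
  if (any(time_h < 0) || any(rate_gy_per_h < 0)) {
    stop("dose_rate_series: negative time or rate")
  }
  if (anyDuplicated(time_h)) stop("dose_rate_series: duplicate sample times")
  ord <- order(time_h)
  structure(
    list(
      patient_id = as.character(patient_id),
      cycle = as.integer(cycle),
      structure = structure_name,
      samples = data.frame(time_h = time_h[ord],
                           rate_gy_per_h = rate_gy_per_h[ord])
    ),
    class = "dose_rate_series"
  )
}

#' @export
print.dose_rate_series <- function(x, ...) {
  cat(sprintf("<dose_rate_series> %s cycle %d, %s, %d sample(s)\n",
              x$patient_id, x$cycle, x$structure, nrow(x$samples)))
  print(x$samples, row.names = FALSE)
  invisible(x)
}

#' Load dose-rate series from a long-format CSV or JSON file
#'
#' Expected columns: `patient_id`, `cycle`, `structure`, `time_h`,
#' `rate_gy_per_h`; one row per sample.
#'
#' @inheritParams load_cohort
#' @return List of [dose_rate_series()] objects, one per
#'   (patient, cycle, structure) group.
#' @export
load_series <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  tab <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
  missing_cols <- setdiff(SERIES_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  series_from_table(tab)
}

series_from_table <- function(tab) {
  if (nrow(tab) == 0) return(list())
  key <- interaction(tab$patient_id, tab$cycle, tab$structure, drop = TRUE)
  lapply(split(tab, key), function(g) {
    dose_rate_series(g$patient_id[1], g$cycle[1], g$structure[1],
                     g$time_h, g$rate_gy_per_h)
  })
}

series_table <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s) {
    data.frame(patient_id = s$patient_id, cycle = s$cycle,
               structure = s$structure, s$samples, stringsAsFactors = FALSE)
  }))
}

#' Write dose-rate series to a long-format CSV
#'
#' @param series_list List of `dose_rate_series` objects.
#' @param path Output path.
#' @export
write_series <- function(series_list, path) {
  utils::write.csv(series_table(series_list), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
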