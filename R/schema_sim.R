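#' Expected absorbed dose under the fixed dose-per-activity schema
#'
#' The fixed schema predicts the absorbed dose of a non-initial cycle by
#' assuming the biokinetics of the reference cycle persist: the delivered
#' dose-per-activity of cycle 1 (Gy/GBq) is multiplied by the activity
#' administered in the target cycle,
#' `AD_expected = (AD_1 / AA_1) * AA_cycle`.
#' By convention the expected dose of the reference cycle itself is its
#' delivered dose (ratio 1).
#'
#' @param course A [patient_course()].
#' @param structure `"tumour"` or `"kidney"`.
#' @param cycle Target cycle index.
#' @param reference_cycle Reference cycle (default 1, the schema as used in
#'   clinical planning).
#' @return Expected absorbed dose, Gy.
#' @export
#' @examples
#' p3 <- ludo_fixture()[[3]]
#' expected_ad(p3, "tumour", 2) # (8.12 / 1.54) * 2.00 = 10.5 Gy
expected_ad <- function(course, structure = c("tumour", "kidney"), cycle,
                        reference_cycle = 1) {
  structure <- match.arg(structure)
  cy <- course$cycles
  if (!reference_cycle %in% cy$cycle) {
    stop("expected_ad: no reference cycle ", reference_cycle, " for ",
         course$patient_id)
  }
  if (!cycle %in% cy$cycle) {
    stop("expected_ad: ", course$patient_id, " has no cycle ", cycle)
  }
  ad_ref <- metric_values(course, "ad_gy", structure, reference_cycle)
  if (cycle == reference_cycle) return(ad_ref)
  aa_ref <- cy$aa_gbq[cy$cycle == reference_cycle]
  if (is.na(ad_ref)) return(NA_real_) # estimation failure upstream
  if (ad_ref < 0 || aa_ref <= 0) {
    stop("expected_ad: reference-cycle dose and activity must be positive")
  }
  aa_target <- cy$aa_gbq[cy$cycle == cycle]
  (ad_ref / aa_ref) * aa_target
}

#' Delivered/expected absorbed-dose ratio for one patient-cycle
#'
#' @inheritParams expected_ad
#' @return Object of class `schema_result`: `patient_id`, `cycle_index`,
#'   `structure`, `ad_expected_gy`, `ad_delivered_gy`, `ratio`.
#' @export
delivered_expected_ratio <- function(course, structure = c("tumour", "kidney"),
                                     cycle, reference_cycle = 1) {
  structure <- match.arg(structure)
  expected <- expected_ad(course, structure, cycle, reference_cycle)
  if (!is.na(expected) && expected == 0) {
    stop("delivered_expected_ratio: expected dose is zero")
  }
  delivered <- metric_values(course, "ad_gy", structure, cycle)
  structure(
    list(patient_id = course$patient_id, cycle_index = cycle,
         structure = structure, ad_expected_gy = expected,
         ad_delivered_gy = delivered, ratio = delivered / expected),
    class = "schema_result"
  )
}

#' @export
print.schema_result <- function(x, ...) {
  cat(sprintf(
    "<schema_result> %s cycle %d %s: delivered %.3g / expected %.3g Gy = %.3g\n",
    x$patient_id, x$cycle_index, x$structure, x$ad_delivered_gy,
    x$ad_expected_gy, x$ratio))
  invisible(x)
}

#' Per-patient schema results for one structure and cycle
#'
#' @param cohort List of `patient_course` objects.
#' @inheritParams expected_ad
#' @return data.frame with one row per patient: `patient_id`, `cycle`,
#'   `structure`, `expected_gy`, `delivered_gy`, `ratio`.
#' @export
schema_ratios <- function(cohort, structure, cycle, reference_cycle = 1) {
  do.call(rbind, lapply(cohort, function(pc) {
    if (!all(c(reference_cycle, cycle) %in% pc$cycles$cycle)) return(NULL)
    r <- delivered_expected_ratio(pc, structure, cycle, reference_cycle)
    data.frame(patient_id = r$patient_id, cycle = r$cycle_index,
               structure = r$structure, expected_gy = r$ad_expected_gy,
               delivered_gy = r$ad_delivered_gy, ratio = r$ratio,
               stringsAsFactors = FALSE)
  }))
}

#' Cohort schema table (expected vs delivered absorbed dose per cycle)
#'
#' For each structure and cycle: the cohort median and range of the
#' expected dose, the delivered dose, and the delivered/expected ratio,
#' plus a two-tailed Wilcoxon-Mann-Whitney p-value comparing delivered with
#' expected doses as independent samples (continuity-corrected normal
#' approximation). Expected values are carried at full precision; rounding
#' happens only at report time. The reference cycle's ratio is 1 by
#' construction and its p-value is reported as `NA`.
#'
#' @param cohort List of `patient_course` objects.
#' @param structures Structures to include.
#' @param cycles Cycle indices; defaults to all cycles present.
#' @param reference_cycle Reference cycle for the schema (default 1).
#' @return data.frame with columns `structure`, `cycle`, `expected_median`,
#'   `expected_min`, `expected_max`, `delivered_median`, `delivered_min`,
#'   `delivered_max`, `ratio_median`, `ratio_min`, `ratio_max`, `p_value`.
#' @export
#' @examples
#' st <- schema_table(ludo_fixture())
#' subset(st, structure == "tumour" & cycle == 4)$ratio_median # 0.157
schema_table <- function(cohort, structures = c("tumour", "kidney"),
                         cycles = NULL, reference_cycle = 1) {
  if (is.null(cycles)) {
    cycles <- sort(unique(unlist(lapply(cohort, function(pc) pc$cycles$cycle))))
  }
  rows <- list()
  for (s in structures) {
    for (cc in cycles) {
      tab <- schema_ratios(cohort, s, cc, reference_cycle)
      if (is.null(tab) || nrow(tab) == 0) next
      em <- median_range(tab$expected_gy)
      dm <- median_range(tab$delivered_gy)
      rm <- median_range(tab$ratio)
      p <- if (cc == reference_cycle) NA_real_ else
        mann_whitney(tab$delivered_gy, tab$expected_gy)$p_value
      rows[[length(rows) + 1]] <- data.frame(
        structure = s, cycle = cc,
        expected_median = em[["median"]], expected_min = em[["min"]],
        expected_max = em[["max"]],
        delivered_median = dm[["median"]], delivered_min = dm[["min"]],
        delivered_max = dm[["max"]],
        ratio_median = rm[["median"]], ratio_min = rm[["min"]],
        ratio_max = rm[["max"]], p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
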