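#' Relative difference between a reference and a comparison cycle
#'
#' `100 * (v_ni - v1) / v1`, the signed percent change of a non-initial
#' cycle value relative to the initial cycle. The negation ("percent
#' decrease") is exposed separately because cohort reports mix both
#' conventions.
#'
#' @param v1 Reference (initial-cycle) value; must be > 0.
#' @param v_ni Comparison (non-initial-cycle) value.
#' @return Signed percent difference. Vectorised over `v_ni`.
#' @export
relative_difference <- function(v1, v_ni) {
  if (any(v1 <= 0)) stop("relative_difference: reference value must be > 0")
  100 * (v_ni - v1) / v1
}

#' @rdname relative_difference
#' @export
percent_decrease <- function(v1, v_ni) -relative_difference(v1, v_ni)

#' Extract a per-cycle metric from a patient course
#'
#' @param course A [patient_course()].
#' @param metric `"ad_gy"` (absorbed dose), `"ad_per_aa"` (Gy/GBq) or
#'   `"teff_h"` (effective half-life).
#' @param structure `"tumour"` or `"kidney"`.
#' @param cycle Optional cycle index; when omitted all cycles are returned
#'   in cycle order.
#' @return Numeric vector of metric values.
#' @export
metric_values <- function(course, metric = c("ad_gy", "ad_per_aa", "teff_h"),
                          structure = c("tumour", "kidney"), cycle = NULL) {
  metric <- match.arg(metric)
  structure <- match.arg(structure)
  cy <- course$cycles
  if (!is.null(cycle)) {
    cy <- cy[cy$cycle %in% cycle, , drop = FALSE]
    if (nrow(cy) == 0) {
      stop("metric_values: ", course$patient_id, " has no cycle ", cycle)
    }
  }
  ad <- cy[[paste0(structure, "_ad_gy")]]
  switch(metric,
    ad_gy = ad,
    ad_per_aa = dose_per_activity(ad, cy$aa_gbq),
    teff_h = cy[[paste0(structure, "_teff_h")]]
  )
}

#' Per-patient inter-cycle deltas across a cohort
#'
#' Computes the signed relative difference ([relative_difference()]) of a
#' metric between a reference cycle (normally cycle 1) and a comparison
#' cycle, for every patient that has both cycles.
#'
#' @param cohort List of `patient_course` objects.
#' @inheritParams metric_values
#' @param comparison_cycle Comparison (non-initial) cycle index.
#' @param reference_cycle Reference cycle index (default 1).
#' @return data.frame with `patient_id`, `metric`, `structure`,
#'   `reference_cycle`, `comparison_cycle`, `delta_pct`, `decrease_pct`.
#' @export
cohort_deltas <- function(cohort, metric, structure, comparison_cycle,
                          reference_cycle = 1) {
  if (comparison_cycle == reference_cycle) {
    stop("cohort_deltas: reference and comparison cycles must differ")
  }
  rows <- lapply(cohort, function(pc) {
    have <- pc$cycles$cycle
    if (!all(c(reference_cycle, comparison_cycle) %in% have)) return(NULL)
    v1 <- metric_values(pc, metric, structure, reference_cycle)
    vni <- metric_values(pc, metric, structure, comparison_cycle)
    d <- relative_difference(v1, vni)
    data.frame(patient_id = pc$patient_id, metric = metric,
               structure = structure, reference_cycle = reference_cycle,
               comparison_cycle = comparison_cycle, delta_pct = d,
               decrease_pct = -d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("cohort_deltas: no patient has both cycles")
  rownames(out) <- NULL
  out
}

#' Running cumulative absorbed dose of a course
#'
#' @inheritParams metric_values
#' @return Numeric vector of prefix sums of the per-cycle absorbed dose, in
#'   cycle order.
#' @export
cumulative_doses <- function(course, structure = c("tumour", "kidney")) {
  structure <- match.arg(structure)
  cumsum(metric_values(course, "ad_gy", structure))
}

#' Per-cycle contribution to the cumulative absorbed dose
#'
#' @inheritParams metric_values
#' @return Numeric vector of per-cycle percentages summing to 100.
#' @export
contribution_fractions <- function(course, structure = c("tumour", "kidney")) {
  structure <- match.arg(structure)
  ad <- metric_values(course, "ad_gy", structure)
  total <- sum(ad)
  if (total <= 0) stop("contribution_fractions: zero total absorbed dose")
  100 * ad / total
}

#' Cohort summary of a metric at one cycle
#'
#' Median (midpoint convention for even n) and range across the patients
#' that have the requested cycle.
#'
#' @param cohort List of `patient_course` objects.
#' @inheritParams metric_values
#' @param cycle Cycle index, or `NULL` to pool all patient-cycles (the
#'   "median row" of a per-cycle dosimetry table).
#' @return Object of class `cohort_summary`: a list with `metric`,
#'   `structure`, `cycle`, `n`, `median`, `range_min`, `range_max`.
#' @export
#' @examples
#' cohort_summary(ludo_fixture(), "ad_gy", "tumour", cycle = 1)$median # 15.6
cohort_summary <- function(cohort, metric, structure, cycle = NULL) {
  values <- unlist(lapply(cohort, function(pc) {
    if (!is.null(cycle) && !all(cycle %in% pc$cycles$cycle)) return(NULL)
    metric_values(pc, metric, structure, cycle)
  }))
  if (length(values) == 0) stop("cohort_summary: empty selection")
  mr <- median_range(values)
  structure(
    list(metric = metric, structure = structure,
         cycle = if (is.null(cycle)) NA_integer_ else cycle,
         n = length(values), median = mr[["median"]],
         range_min = mr[["min"]], range_max = mr[["max"]]),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s %s cycle %s: median %.3g (range %.3g-%.3g), n = %d\n",
              x$structure, x$metric,
              ifelse(is.na(x$cycle), "all", format(x$cycle)),
              x$median, x$range_min, x$range_max, x$n))
  invisible(x)
}

#' Per-cycle summary table across metrics and structures
#'
#' @param cohort List of `patient_course` objects.
#' @param metrics Metrics to summarise.
#' @param structures Structures to summarise.
#' @param cycles Cycle indices; defaults to all cycles present.
#' @param include_pooled Add a pooled all-cycles row per metric/structure
#'   (the "median row").
#' @return data.frame with columns `metric`, `structure`, `cycle`, `n`,
#'   `median`, `min`, `max`.
#' @export
summary_table <- function(cohort, metrics = c("ad_gy", "ad_per_aa", "teff_h"),
                          structures = c("tumour", "kidney"), cycles = NULL,
                          include_pooled = TRUE) {
  if (is.null(cycles)) {
    cycles <- sort(unique(unlist(lapply(cohort, function(pc) pc$cycles$cycle))))
  }
  rows <- list()
  for (m in metrics) {
    for (s in structures) {
      for (cc in cycles) {
        cs <- cohort_summary(cohort, m, s, cc)
        rows[[length(rows) + 1]] <- data.frame(
          metric = m, structure = s, cycle = cc, n = cs$n, median = cs$median,
          min = cs$range_min, max = cs$range_max, stringsAsFactors = FALSE)
      }
      if (include_pooled) {
        cs <- cohort_summary(cohort, m, s, cycle = NULL)
        rows[[length(rows) + 1]] <- data.frame(
          metric = m, structure = s, cycle = NA_integer_, n = cs$n,
          median = cs$median, min = cs$range_min, max = cs$range_max,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-cycle contribution table for a cohort
#'
#' One row per patient with the per-cycle percent contributions to the
#' cumulative absorbed dose and the combined first-two-cycle share.
#'
#' @param cohort List of `patient_course` objects.
#' @param structure `"tumour"` or `"kidney"`.
#' @return data.frame with `patient_id`, `cycle`, `ad_gy`, `cumulative_gy`,
#'   `contribution_pct`.
#' @export
contribution_table <- function(cohort, structure = c("tumour", "kidney")) {
  structure <- match.arg(structure)
  do.call(rbind, lapply(cohort, function(pc) {
    ad <- metric_values(pc, "ad_gy", structure)
    data.frame(patient_id = pc$patient_id, cycle = pc$cycles$cycle,
               ad_gy = ad, cumulative_gy = cumsum(ad),
               contribution_pct = contribution_fractions(pc, structure),
               stringsAsFactors = FALSE)
  }))
}
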