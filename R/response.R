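#' Percentage decrease between staging and interim values
#'
#' The delta change used throughout interim-PET response assessment:
#' `delta = (v1 - v2) / v1 * 100`, the percent decrease from the staging
#' scan (PET1) to the interim scan (PET2). Positive values mean a decrease;
#' 100 means complete disappearance; the baseline must be positive.
#'
#' @param v1 staging (PET1) value, > 0. Vectorised.
#' @param v2 interim (PET2) value, >= 0. Vectorised.
#' @return Percent decrease. `delta` is scale-invariant:
#'   `delta(a*v1, a*v2) == delta(v1, v2)` for any `a > 0`.
#' @examples
#' delta(10, 2.2) # 78
#' @export
delta <- function(v1, v2) {
  bad <- !is.na(v1) & (!is.finite(v1) | v1 <= 0)
  if (any(bad)) abort("`v1` must be strictly positive: the percent decrease is undefined at a non-positive baseline.")
  if (any(!is.na(v2) & v2 < 0)) abort("`v2` must be non-negative.")
  (v1 - v2) / v1 * 100
}

#' Classify a patient as PET-positive at a cutoff
#'
#' Dichotomises a semi-quantitative parameter. For absolute interim-scan
#' parameters high values flag residual disease (`"greater_positive"`, e.g.
#' SUVmax2 > 2.5); for percentage-decrease parameters a small decrease
#' flags non-response (`"less_positive"`, e.g. delta-SUVmax < 78%). Both
#' inequalities are strict; a value exactly at the cutoff is negative.
#'
#' @param value parameter value(s).
#' @param cutoff decision cutoff.
#' @param direction `"greater_positive"` or `"less_positive"`.
#' @return Character vector, `"positive"` (predicted non-responder /
#'   relapse) or `"negative"` (predicted responder).
#' @examples
#' classify_response(70, 78, "less_positive")  # positive
#' classify_response(2.5, 2.5, "greater_positive") # negative (strict)
#' @export
classify_response <- function(value, cutoff,
                              direction = c("greater_positive", "less_positive")) {
  direction <- match.arg(direction)
  pos <- if (direction == "greater_positive") value > cutoff else value < cutoff
  ifelse(pos, "positive", "negative")
}

#' Assemble per-patient records across timepoints
#'
#' Joins per-patient, per-scheme metrics at both timepoints into one long
#' record table and computes the percentage decreases. Patients whose
#' lesions are entirely below threshold already at the staging scan have no
#' meaningful baseline under that scheme: their deltas for MTV/TLG are set
#' to `NA` and a warning names them, so downstream ROC analyses exclude
#' them from that scheme's delta analysis.
#'
#' @param metrics long tibble from [quantify_cohort()] (or equivalent)
#'   with columns `patient_id`, `scheme`, `timepoint`, `suv_max`,
#'   `suv_mean`, `mtv_ml`, `tlg_g`, `below_threshold`.
#' @param outcomes tibble with `patient_id`, `outcome`
#'   (`"relapse"`/`"remission"`) and optionally `therapy_group`,
#'   `visual_score_pet2`.
#' @return Tibble, one row per patient x scheme: PET1 and PET2 values
#'   (suffixes `1`/`2`), `delta_suv_max`, `delta_suv_mean`, `delta_mtv`,
#'   `delta_tlg`, outcome columns.
#' @export
assemble_records <- function(metrics, outcomes) {
  needed <- c("patient_id", "scheme", "timepoint", "suv_max", "suv_mean",
              "mtv_ml", "tlg_g", "below_threshold")
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols)) {
    abort(paste0("`metrics` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  wide <- metrics |>
    dplyr::select(dplyr::all_of(needed)) |>
    tidyr::pivot_wider(
      names_from = "timepoint",
      values_from = c("suv_max", "suv_mean", "mtv_ml", "tlg_g",
                      "below_threshold"),
      names_sep = ""
    )
  baseline_neg <- wide$below_threshold1
  if (any(baseline_neg)) {
    warn(paste0(
      "patients below threshold already at PET1 excluded from delta analysis: ",
      paste(unique(wide$patient_id[baseline_neg]), collapse = ", ")
    ))
  }
  safe_delta <- function(v1, v2, valid) {
    out <- rep(NA_real_, length(v1))
    ok <- valid & !is.na(v1) & !is.na(v2) & v1 > 0
    out[ok] <- delta(v1[ok], v2[ok])
    out
  }
  wide |>
    dplyr::mutate(
      delta_suv_max = safe_delta(.data$suv_max1, .data$suv_max2, !baseline_neg),
      delta_suv_mean = safe_delta(.data$suv_mean1, .data$suv_mean2, !baseline_neg),
      delta_mtv = safe_delta(.data$mtv_ml1, .data$mtv_ml2, !baseline_neg),
      delta_tlg = safe_delta(.data$tlg_g1, .data$tlg_g2, !baseline_neg)
    ) |>
    dplyr::left_join(outcomes, by = "patient_id")
}
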