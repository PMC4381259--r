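#' Evaluate one parameter as a relapse predictor
#'
#' Full ROC workup of a single semi-quantitative parameter: DeLong AUC with
#' CI and test against 0.5, cutoff selection under the NPV = 100%
#' constraint (or a fixed, externally given cutoff such as the visual
#' score-3 boundary), the resulting confusion matrix and predictive values,
#' and the ROC curve itself.
#'
#' @param data data frame with one row per patient.
#' @param score bare column name of the parameter value.
#' @param outcome bare column name of the outcome
#'   (`"relapse"`/`"remission"`); default `outcome`.
#' @param direction `"greater_positive"` or `"less_positive"` (see
#'   [classify_response()]).
#' @param constraint cutoff constraint, `"npv_100"` (default) or `"none"`;
#'   ignored when `fixed_cutoff` is given.
#' @param parameter display name; defaults to the score column name.
#' @param fixed_cutoff optional externally fixed cutoff (no ROC search).
#' @param id optional bare column name of a patient identifier, kept for
#'   paired AUC comparisons.
#' @return A `pet_roc` object; [glance()] gives the one-row summary,
#'   [tidy()] the ROC curve points, [autoplot()] draws the curve.
#' @export
roc_evaluate <- function(data, score, outcome = outcome,
                         direction = c("greater_positive", "less_positive"),
                         constraint = c("npv_100", "none"),
                         parameter = NULL, fixed_cutoff = NULL,
                         id = NULL) {
  direction <- match.arg(direction)
  constraint <- match.arg(constraint)
  scores <- dplyr::pull(data, {{ score }})
  labels <- dplyr::pull(data, {{ outcome }})
  parameter <- parameter %||% rlang::as_name(rlang::enquo(score))
  ids <- tryCatch(dplyr::pull(data, {{ id }}), error = function(e) NULL)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  if (!is.null(ids)) ids <- ids[keep]
  auc <- auc_delong(scores, labels, direction)
  if (is.null(fixed_cutoff)) {
    cut <- select_cutoff(scores, labels, direction, constraint)
  } else {
    cc <- confusion_counts(classify_response(scores, fixed_cutoff, direction),
                           labels)
    cut <- dplyr::bind_cols(
      tibble::tibble(cutoff = fixed_cutoff), cc, confusion_metrics(cc)
    )
    cut <- dplyr::mutate(
      dplyr::select(cut, "cutoff", "TP", "TN", "FP", "FN", "accuracy",
                    "sensitivity", "specificity", "ppv", "npv"),
      degenerate = FALSE
    )
  }
  curve <- roc_curve_points(scores, labels, direction)
  structure(
    list(parameter = parameter, direction = direction,
         constraint = if (is.null(fixed_cutoff)) constraint else "fixed",
         n = length(scores), auc = auc, cutoff = cut, curve = curve,
         scores = scores, labels = labels, patient_id = ids),
    class = "pet_roc"
  )
}

roc_curve_points <- function(scores, labels, direction) {
  purrr::map_dfr(candidate_cutoffs(scores), function(ct) {
    cc <- confusion_counts(classify_response(scores, ct, direction), labels)
    m <- confusion_metrics(cc)
    tibble::tibble(
      cutoff = ct,
      tpr = m$sensitivity / 100,
      fpr = 1 - m$specificity / 100
    )
  }) |>
    dplyr::arrange(.data$fpr, .data$tpr)
}

#' @export
print.pet_roc <- function(x, ...) {
  cat(sprintf(
    "<pet_roc> %s (n = %d): AUC %.2f [%.2f-%.2f], p = %.2g; cutoff %.4g -> TP %d TN %d FP %d FN %d, acc %.1f%%\n",
    x$parameter, x$n, x$auc$auc, x$auc$ci_lo, x$auc$ci_hi, x$auc$p_vs_half,
    x$cutoff$cutoff, x$cutoff$TP, x$cutoff$TN, x$cutoff$FP, x$cutoff$FN,
    x$cutoff$accuracy
  ))
  invisible(x)
}

#' Paired DeLong comparison of two evaluated parameters
#'
#' Compares the AUCs of two [roc_evaluate()] results obtained on the same
#' patients; records are matched by patient id when both carry one.
#'
#' @param roc_a,roc_b `pet_roc` objects from the same cohort.
#' @return One-row tibble from [delong_compare()].
#' @export
compare_rocs <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "pet_roc"), inherits(roc_b, "pet_roc"))
  if (!is.null(roc_a$patient_id) && !is.null(roc_b$patient_id)) {
    common <- intersect(roc_a$patient_id, roc_b$patient_id)
    ia <- match(common, roc_a$patient_id)
    ib <- match(common, roc_b$patient_id)
    if (!identical(roc_a$labels[ia], roc_b$labels[ib])) {
      abort("outcome labels disagree between the two evaluations.")
    }
    delong_compare(roc_a$scores[ia], roc_b$scores[ib], roc_a$labels[ia],
                   roc_a$direction, roc_b$direction)
  } else {
    if (length(roc_a$scores) != length(roc_b$scores)) {
      abort("evaluations are unpaired and carry no patient ids to match on.")
    }
    if (!identical(roc_a$labels, roc_b$labels)) {
      abort("outcome labels disagree between the two evaluations.")
    }
    delong_compare(roc_a$scores, roc_b$scores, roc_a$labels,
                   roc_a$direction, roc_b$direction)
  }
}
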