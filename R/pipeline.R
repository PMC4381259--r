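scheme_threshold_label <- function(scheme) {
  switch(scheme,
    suv_bw_2.5 = "fixed SUV 2.5 (body weight)",
    suv_bsa_2.5 = "fixed 2.5 on the body-surface-area scale",
    sul_liver = "individual liver SUL mean + 2 SD",
    scheme
  )
}

#' Quantify every cohort patient under the threshold schemes
#'
#' Streams through the cohort patient by patient: realises the staging and
#' interim scans, converts each to the scheme's SUV normalization, derives
#' the scheme's segmentation threshold (fixed 2.5 for the body-weight and
#' body-surface-area schemes; per-scan liver mean + 2 SD for the
#' individualized SUL scheme), segments the PET1 lesion masks on both
#' scans (identically placed), and aggregates per-lesion metrics to one
#' value set per patient, scheme and timepoint.
#'
#' @param cohort a [make_cohort()] result.
#' @param schemes subset of `"suv_bw_2.5"`, `"suv_bsa_2.5"`, `"sul_liver"`.
#' @return Long tibble: `patient_id`, `scheme`, `timepoint`, `threshold`,
#'   `suv_max`, `suv_mean`, `mtv_ml`, `tlg_g`, `n_lesions`,
#'   `below_threshold`, and for the SUL scheme the measured liver
#'   `liver_mean`/`liver_sd`.
#' @export
quantify_cohort <- function(cohort,
                            schemes = c("suv_bw_2.5", "sul_liver")) {
  stopifnot(inherits(cohort, "pet_cohort"))
  schemes <- match.arg(schemes,
                       c("suv_bw_2.5", "suv_bsa_2.5", "sul_liver"),
                       several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(cohort$meta))) {
    pid <- cohort$meta$patient_id[i]
    meta <- cohort$meta[i, ]
    masks <- dplyr::filter(cohort$masks, .data$patient_id == !!pid)
    for (tp in 1:2) {
      ph <- realize_scan(cohort, pid, tp)
      for (sch in schemes) {
        norm <- switch(sch, suv_bw_2.5 = "bw", suv_bsa_2.5 = "bsa",
                       sul_liver = "lbm")
        img <- to_suv(ph$scan, meta, norm)
        liver_mean <- NA_real_; liver_sd <- NA_real_
        if (sch == "sul_liver") {
          ls <- liver_reference(img, cohort$anatomy$liver_center)
          thr <- sul_threshold(ls)
          liver_mean <- ls$mean_sul; liver_sd <- ls$sd_sul
        } else {
          thr <- 2.5
        }
        agg <- measure_lesions(img, masks, thr, cohort$exclusions,
                               scheme = sch) |>
          aggregate_lesions()
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(patient_id = pid, scheme = sch, timepoint = tp,
                         threshold = thr, liver_mean = liver_mean,
                         liver_sd = liver_sd),
          agg
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

default_parameter_set <- function(schemes, include_visual = TRUE) {
  defs <- list()
  if ("suv_bw_2.5" %in% schemes) {
    defs$bw <- tibble::tibble(
      parameter = c("SUVmax2", "SUVmean2", "MTV2", "TLGmean2",
                    "dSUVmax", "dSUVmean", "dMTV", "dTLGmean"),
      scheme = "suv_bw_2.5",
      column = c("suv_max2", "suv_mean2", "mtv_ml2", "tlg_g2",
                 "delta_suv_max", "delta_suv_mean", "delta_mtv", "delta_tlg"),
      analysis = rep(c("pet2", "delta"), each = 4),
      direction = rep(c("greater_positive", "less_positive"), each = 4)
    )
  }
  if ("suv_bsa_2.5" %in% schemes) {
    defs$bsa <- tibble::tibble(
      parameter = c("SUVmax2_bsa", "SUVmean2_bsa", "MTV2_bsa", "TLGmean2_bsa",
                    "dSUVmax_bsa", "dSUVmean_bsa", "dMTV_bsa", "dTLGmean_bsa"),
      scheme = "suv_bsa_2.5",
      column = c("suv_max2", "suv_mean2", "mtv_ml2", "tlg_g2",
                 "delta_suv_max", "delta_suv_mean", "delta_mtv", "delta_tlg"),
      analysis = rep(c("pet2", "delta"), each = 4),
      direction = rep(c("greater_positive", "less_positive"), each = 4)
    )
  }
  if ("sul_liver" %in% schemes) {
    defs$sul <- tibble::tibble(
      parameter = c("SULmax2", "SULmean2", "MTV2_liver", "TLGmean2_liver",
                    "dSULmax", "dSULmean", "dMTV_liver", "dTLGmean_liver"),
      scheme = "sul_liver",
      column = c("suv_max2", "suv_mean2", "mtv_ml2", "tlg_g2",
                 "delta_suv_max", "delta_suv_mean", "delta_mtv", "delta_tlg"),
      analysis = rep(c("pet2", "delta"), each = 4),
      direction = rep(c("greater_positive", "less_positive"), each = 4)
    )
  }
  out <- dplyr::bind_rows(defs)
  if (include_visual) {
    out <- dplyr::bind_rows(
      tibble::tibble(parameter = "visual", scheme = "visual",
                     column = "visual_score_pet2", analysis = "visual",
                     direction = "greater_positive"),
      out
    )
  }
  out
}

#' Run the full phantom-to-report response-prediction pipeline
#'
#' One seeded end-to-end run: generate the synthetic cohort, quantify every
#' patient under the requested threshold schemes, assemble per-patient
#' records with percentage decreases, and evaluate every parameter as a
#' relapse predictor (DeLong AUC, NPV-constrained cutoff, confusion matrix,
#' predictive values), with Benjamini-Hochberg correction of the AUC
#' p-values across the whole family evaluated in the run. The visual
#' (Deauville-type) interim score is evaluated at its fixed score >= 3
#' positivity boundary rather than a ROC-searched cutoff.
#'
#' @param design a [cohort_design()]; its seed fully determines the run.
#' @param schemes threshold schemes to quantify; default body-weight 2.5
#'   and individualized liver SUL (the body-surface-area scheme can be
#'   added but its fixed 2.5 threshold is far more stringent on that
#'   scale).
#' @param constraint cutoff constraint passed to [select_cutoff()].
#' @param fdr_q target false discovery rate for the AUC p-value family.
#' @param include_visual evaluate the synthetic visual score too?
#' @return A `pet_run` object: `report` (one row per parameter, the
#'   Table-2-shaped summary), `records`, `metrics`, `rocs` (named list of
#'   `pet_roc`), `cohort`, `log`. [tidy()] returns the report.
#' @export
run_pet_response <- function(design = cohort_design(),
                             schemes = c("suv_bw_2.5", "sul_liver"),
                             constraint = "npv_100",
                             fdr_q = 0.05,
                             include_visual = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- tibble::tibble(stage = stage, message = msg)
  }
  note("design", sprintf("seed %d, %d patients, %d relapse",
                         design$seed, design$n_patients, design$n_relapse))
  cohort <- make_cohort(design)
  note("phantom", sprintf("%d lesions placed; noise sd %.3g SUV",
                          nrow(cohort$lesions), design$noise_sd_suv))
  metrics <- quantify_cohort(cohort, schemes)
  for (sch in schemes) {
    note("quantify", sprintf("scheme %s: %s", sch, scheme_threshold_label(sch)))
  }
  records <- withCallingHandlers(
    assemble_records(metrics, cohort$outcomes),
    warning = function(w) {
      note("records", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  defs <- default_parameter_set(schemes, include_visual)
  rocs <- list()
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    if (d$analysis == "visual") {
      if (!"visual_score_pet2" %in% names(cohort$outcomes)) next
      dat <- cohort$outcomes
      rocs[[d$parameter]] <- roc_evaluate(
        dat, score = !!rlang::sym(d$column), outcome = !!rlang::sym("outcome"),
        direction = d$direction, parameter = d$parameter,
        fixed_cutoff = 2.5, id = !!rlang::sym("patient_id")
      )
    } else {
      dat <- dplyr::filter(records, .data$scheme == d$scheme)
      rocs[[d$parameter]] <- roc_evaluate(
        dat, score = !!rlang::sym(d$column), outcome = !!rlang::sym("outcome"),
        direction = d$direction, constraint = constraint,
        parameter = d$parameter, id = !!rlang::sym("patient_id")
      )
    }
  }
  report <- purrr::map_dfr(rocs, glance) |>
    dplyr::mutate(
      analysis = defs$analysis[match(.data$parameter, defs$parameter)],
      scheme = defs$scheme[match(.data$parameter, defs$parameter)],
      .after = "parameter"
    )
  adj <- fdr_adjust(report$p_vs_half, q = fdr_q)
  report$p_fdr <- adj$p_adj
  report$significant <- adj$significant
  note("stats", sprintf("%d parameters evaluated; FDR q = %.3g; %d significant",
                        nrow(report), fdr_q, sum(report$significant)))
  structure(
    list(design = design, cohort = cohort, metrics = metrics,
         records = records, report = report, rocs = rocs,
         log = dplyr::bind_rows(log)),
    class = "pet_run"
  )
}

#' @export
print.pet_run <- function(x, ...) {
  cat(sprintf("<pet_run> %d patients (%d relapse), %d parameters, seed %d\n",
              x$design$n_patients, x$design$n_relapse, nrow(x$report),
              x$design$seed))
  print(dplyr::select(x$report, "parameter", "n", "auc", "ci_lo", "ci_hi",
                      "p_vs_half", "cutoff", "TP", "TN", "FP", "FN",
                      "accuracy"))
  invisible(x)
}

#' Confusion matrix of a subgroup at the cohort-wide cutoff
#'
#' Re-applies a parameter's globally selected cutoff inside a patient
#' subgroup (e.g. the intensified-treatment groups TG2/TG3) and reports the
#' subgroup confusion matrix and predictive values.
#'
#' @param run a [run_pet_response()] result.
#' @param parameter parameter name as in `run$report$parameter`.
#' @param therapy_groups subgroup to keep, e.g. `c("TG2", "TG3")`.
#' @return One-row tibble: subgroup size, cutoff, confusion counts and
#'   rates.
#' @export
subgroup_confusion <- function(run, parameter = "dSUVmax",
                               therapy_groups = c("TG2", "TG3")) {
  stopifnot(inherits(run, "pet_run"))
  roc <- run$rocs[[parameter]]
  if (is.null(roc)) abort(sprintf("parameter '%s' was not evaluated in this run.", parameter))
  keep_ids <- run$cohort$outcomes$patient_id[
    run$cohort$outcomes$therapy_group %in% therapy_groups
  ]
  idx <- roc$patient_id %in% keep_ids
  scores <- roc$scores[idx]; labels <- roc$labels[idx]
  cc <- confusion_counts(
    classify_response(scores, roc$cutoff$cutoff, roc$direction), labels
  )
  dplyr::bind_cols(
    tibble::tibble(parameter = parameter,
                   therapy_groups = paste(therapy_groups, collapse = "+"),
                   n = sum(idx), cutoff = roc$cutoff$cutoff),
    cc, confusion_metrics(cc)
  )
}
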