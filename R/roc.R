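#' Confusion counts from predicted and actual labels
#'
#' Relapse during follow-up is the positive event: a PET-positive call in a
#' patient who relapses is a true positive (TP), in a patient in ongoing
#' complete remission a false positive (FP); a PET-negative call is a true
#' negative (TN) in remission and a false negative (FN) in relapse.
#'
#' @param predicted `"positive"`/`"negative"` calls (from
#'   [classify_response()]).
#' @param actual `"relapse"`/`"remission"` outcomes.
#' @return One-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length.")
  }
  if (!all(predicted %in% c("positive", "negative"))) {
    abort('`predicted` must be "positive"/"negative".')
  }
  if (!all(actual %in% c("relapse", "remission"))) {
    abort('`actual` must be "relapse"/"remission".')
  }
  tibble::tibble(
    TP = sum(predicted == "positive" & actual == "relapse"),
    TN = sum(predicted == "negative" & actual == "remission"),
    FP = sum(predicted == "positive" & actual == "remission"),
    FN = sum(predicted == "negative" & actual == "relapse")
  )
}

#' Predictive values and accuracy from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive
#' value TP/(TP+FP), negative predictive value TN/(TN+FN) and accuracy
#' (TP+TN)/n, all as percentages. A zero denominator yields `NA` for that
#' rate (an explicit undefined-rate flag, never a silent zero).
#'
#' @param tp true positives, or a one-row data frame/list with columns
#'   `TP`, `TN`, `FP`, `FN` (then the other arguments are ignored).
#' @param tn,fp,fn remaining counts.
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` in percent (full precision; round to one decimal for
#'   reporting).
#' @examples
#' confusion_metrics(6, 41, 7, 0) # the headline delta-SUVmax row
#' @export
confusion_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    c0 <- tp
    tp <- c0$TP; tn <- c0$TN; fp <- c0$FP; fn <- c0$FN
  }
  counts <- c(tp, tn, fp, fn)
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("confusion counts must be four non-negative integers.")
  }
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    accuracy = rate(tp + tn, tp + tn + fp + fn)
  )
}

orient_scores <- function(scores, direction) {
  direction <- match.arg(direction, c("greater_positive", "less_positive"))
  if (direction == "greater_positive") scores else -scores
}

check_labels <- function(labels) {
  if (!all(labels %in% c("relapse", "remission"))) {
    abort('`labels` must be "relapse"/"remission".')
  }
  if (length(unique(labels)) < 2L) {
    abort("both outcome classes must be present for ROC analysis.")
  }
  labels
}

delong_placements <- function(scores, labels, direction) {
  s <- orient_scores(scores, direction)
  x <- s[labels == "relapse"]   # positives
  y <- s[labels == "remission"] # negatives
  gt <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  list(
    v10 = rowMeans(gt), # per-positive placements
    v01 = colMeans(gt), # per-negative placements
    auc = mean(gt)
  )
}

#' DeLong AUC with variance, confidence interval and test against 0.5
#'
#' Nonparametric AUC (Mann-Whitney concordance, ties counted 1/2) with the
#' DeLong structural-component variance estimator, a normal-approximation
#' 95% CI truncated to `[0, 1]`, and a two-sided normal test of AUC = 0.5.
#'
#' @param scores numeric predictor values, one per patient.
#' @param labels `"relapse"`/`"remission"` per patient; relapse is the
#'   positive class. Both classes must be present.
#' @param direction `"greater_positive"` if large scores indicate relapse,
#'   `"less_positive"` if small scores do (e.g. percentage decreases).
#' @return One-row tibble: `auc`, `se`, `ci_lo`, `ci_hi`, `p_vs_half`,
#'   `n_pos`, `n_neg`.
#' @export
auc_delong <- function(scores, labels,
                       direction = c("greater_positive", "less_positive")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- check_labels(labels[keep])
  n_pos <- sum(labels == "relapse"); n_neg <- sum(labels == "remission")
  if (n_pos < 2L || n_neg < 2L) {
    abort("DeLong variance needs at least two patients per class.")
  }
  pl <- delong_placements(scores, labels, direction)
  v <- var(pl$v10) / n_pos + var(pl$v01) / n_neg
  se <- sqrt(max(v, 0))
  if (se > 0) {
    p <- 2 * pnorm(-abs((pl$auc - 0.5) / se))
  } else {
    p <- if (pl$auc == 0.5) 1 else 0
  }
  tibble::tibble(
    auc = pl$auc,
    se = se,
    ci_lo = max(0, pl$auc - 1.96 * se),
    ci_hi = min(1, pl$auc + 1.96 * se),
    p_vs_half = p,
    n_pos = n_pos,
    n_neg = n_neg
  )
}

#' Compare two correlated AUCs (paired DeLong test)
#'
#' Two predictors measured on the same patients yield correlated AUCs; the
#' paired DeLong test uses the estimated covariance of their
#' structural components to form a z-statistic for the AUC difference.
#'
#' @param scores_a,scores_b paired predictor values on identical patients.
#' @param labels `"relapse"`/`"remission"` per patient.
#' @param direction_a,direction_b score orientation per predictor (see
#'   [auc_delong()]).
#' @return One-row tibble: `auc_a`, `auc_b`, `auc_diff`, `se_diff`, `z`,
#'   `p_value` (two-sided).
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           direction_a = "greater_positive",
                           direction_b = direction_a) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("`scores_a`, `scores_b` and `labels` must be paired (equal length).")
  }
  keep <- !is.na(scores_a) & !is.na(scores_b)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]
  labels <- check_labels(labels[keep])
  n_pos <- sum(labels == "relapse"); n_neg <- sum(labels == "remission")
  pa <- delong_placements(scores_a, labels, direction_a)
  pb <- delong_placements(scores_b, labels, direction_b)
  v <- var(pa$v10) / n_pos + var(pa$v01) / n_neg +
    var(pb$v10) / n_pos + var(pb$v01) / n_neg -
    2 * (cov(pa$v10, pb$v10) / n_pos + cov(pa$v01, pb$v01) / n_neg)
  d <- pa$auc - pb$auc
  se <- sqrt(max(v, 0))
  if (se > 0) {
    z <- d / se
    p <- 2 * pnorm(-abs(z))
  } else {
    z <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, auc_diff = d,
                 se_diff = se, z = z, p_value = p)
}

candidate_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(u[1] - 1, mids, u[length(u)] + 1)
}

#' ROC cutoff selection, optionally constrained to NPV = 100%
#'
#' Scans candidate cutoffs at the midpoints between adjacent distinct
#' observed scores (plus one beyond each extreme) and returns the cutoff
#' with the highest accuracy. Under `constraint = "npv_100"` only cutoffs
#' producing zero false negatives are eligible — the study requirement that
#' the already optimal negative predictive value be maintained while
#' improving the positive predictive value. Ties in accuracy are broken by
#' higher specificity, then toward the more stringent cutoff (fewer
#' positive calls). If only the degenerate call-everyone-positive cutoff
#' keeps NPV at 100%, it is returned with a warning.
#'
#' @inheritParams auc_delong
#' @param constraint `"npv_100"` or `"none"`.
#' @return One-row tibble: `cutoff`, `TP`, `TN`, `FP`, `FN`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `degenerate`.
#' @export
select_cutoff <- function(scores, labels,
                          direction = c("greater_positive", "less_positive"),
                          constraint = c("npv_100", "none")) {
  direction <- match.arg(direction)
  constraint <- match.arg(constraint)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- check_labels(labels[keep])
  cands <- candidate_cutoffs(scores)
  rows <- purrr::map_dfr(cands, function(ct) {
    cc <- confusion_counts(classify_response(scores, ct, direction), labels)
    dplyr::bind_cols(tibble::tibble(cutoff = ct), cc, confusion_metrics(cc))
  })
  if (constraint == "npv_100") rows <- dplyr::filter(rows, .data$FN == 0L)
  n_calls <- rows$TP + rows$FP # fewer positive calls = more stringent
  best <- rows[order(-rows$accuracy,
                     -dplyr::coalesce(rows$specificity, -Inf),
                     n_calls)[1], ]
  degenerate <- best$TN + best$FN == 0L
  if (degenerate && constraint == "npv_100") {
    warn("NPV = 100% is only attainable by calling every patient positive; returning the degenerate all-positive cutoff.")
  }
  dplyr::mutate(
    dplyr::select(best, "cutoff", "TP", "TN", "FP", "FN", "accuracy",
                  "sensitivity", "specificity", "ppv", "npv"),
    degenerate = degenerate
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a family of p-values with reject/accept calls
#' at a target FDR level.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q target false discovery rate; default 0.05.
#' @return Tibble: `p`, `p_adj`, `significant`.
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1].")
  p_adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = p_adj, significant = !is.na(p_adj) & p_adj <= q)
}

#' Logistic regression of outcome on interim-scan parameters
#'
#' Maximum-likelihood logistic fit of relapse on interim-scan uptake and
#' size parameters with per-coefficient Wald tests. Complete or
#' quasi-complete separation is detected (fitted probabilities numerically
#' 0/1 or non-convergence) and flagged instead of reporting a spurious
#' finite estimate.
#'
#' @param records data frame with an `outcome` column
#'   (`"relapse"`/`"remission"`) and the feature columns.
#' @param features character vector of predictor column names, e.g.
#'   `c("suv_max2", "suv_mean2", "mtv_ml2")`.
#' @param outcome name of the outcome column; default `"outcome"`.
#' @return Object of class `pet_logistic`: use [tidy()] for the coefficient
#'   table (`term`, `estimate`, `std_error`, `statistic`, `p_value`) and
#'   [glance()] for fit-level summaries including the `separation` flag.
#' @export
logistic_response_model <- function(records, features,
                                    outcome = "outcome") {
  missing_cols <- setdiff(c(features, outcome), names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- records[stats::complete.cases(records[, c(features, outcome)]), ]
  if (nrow(df) < 10L) abort("logistic regression needs at least 10 complete records.")
  y <- as.integer(df[[outcome]] == "relapse")
  if (length(unique(y)) < 2L) abort("outcome must have both classes.")
  X <- df[, features, drop = FALSE]
  dat <- cbind(data.frame(.y = y), X)
  fml <- stats::as.formula(paste(".y ~", paste(features, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) separation <- TRUE
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std_error = sm[, 2],
    statistic = sm[, 3],
    p_value = sm[, 4]
  )
  structure(
    list(model = fit, coefficients = coefs, separation = separation,
         n = nrow(df), features = features),
    class = "pet_logistic"
  )
}

#' @export
print.pet_logistic <- function(x, ...) {
  cat(sprintf("<pet_logistic> relapse ~ %s (n = %d)%s\n",
              paste(x$features, collapse = " + "), x$n,
              if (x$separation) " [separation detected]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Power of the one-sided one-sample proportion test
#'
#' Normal-approximation power (no continuity correction) of testing
#' H0: p = p0 against the one-sided alternative p = p1 > p0 with n
#' observations: the study's design question of raising a predictive value
#' from 60% to 80%.
#'
#' @param p0 null proportion, in (0, 1).
#' @param p1 alternative proportion, p0 < p1 < 1.
#' @param alpha one-sided type I error; default 0.05.
#' @param n sample size (>= 1).
#' @return Power in `[0, 1]`.
#' @examples
#' power_one_proportion(0.60, 0.80, 0.05, 44) # about 0.90
#' @export
power_one_proportion <- function(p0, p1, alpha = 0.05, n) {
  if (!is.finite(p0) || !is.finite(p1) || p0 <= 0 || p0 >= 1 ||
      p1 <= p0 || p1 >= 1) {
    abort("need 0 < p0 < p1 < 1.")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (any(n < 1)) abort("`n` must be >= 1.")
  za <- qnorm(1 - alpha)
  pnorm((sqrt(n) * (p1 - p0) - za * sqrt(p0 * (1 - p0))) / sqrt(p1 * (1 - p1)))
}

#' @rdname power_one_proportion
#' @param power target power for the inverse problem; default 0.90.
#' @return `sample_size_one_proportion()`: the smallest integer n whose
#'   power reaches the target.
#' @export
sample_size_one_proportion <- function(p0, p1, alpha = 0.05, power = 0.90) {
  zb <- qnorm(power); za <- qnorm(1 - alpha)
  n0 <- ((za * sqrt(p0 * (1 - p0)) + zb * sqrt(p1 * (1 - p1))) / (p1 - p0))^2
  n <- max(1L, floor(n0) - 2L)
  while (power_one_proportion(p0, p1, alpha, n) < power) n <- n + 1L
  n
}
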