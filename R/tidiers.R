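#' Tidy and glance methods
#'
#' `glance()` on a `pet_roc` returns the one-row Table-style summary (AUC,
#' CI, p, cutoff, confusion counts, predictive values); `tidy()` returns
#' the ROC curve points. On a `pet_logistic`, `tidy()` is the coefficient
#' table and `glance()` the fit-level summary including the separation
#' flag. On a `pet_run`, `tidy()` returns the full report table.
#'
#' @param x a `pet_roc`, `pet_logistic` or `pet_run` object.
#' @param ... unused.
#' @return A tibble.
#' @name petresponse-tidiers
NULL

#' @rdname petresponse-tidiers
#' @method glance pet_roc
#' @export
glance.pet_roc <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(parameter = x$parameter, n = x$n),
    x$auc[, c("auc", "se", "ci_lo", "ci_hi", "p_vs_half")],
    tibble::tibble(direction = x$direction, constraint = x$constraint),
    x$cutoff
  )
}

#' @rdname petresponse-tidiers
#' @method tidy pet_roc
#' @export
tidy.pet_roc <- function(x, ...) x$curve

#' @rdname petresponse-tidiers
#' @method tidy pet_logistic
#' @export
tidy.pet_logistic <- function(x, ...) x$coefficients

#' @rdname petresponse-tidiers
#' @method glance pet_logistic
#' @export
glance.pet_logistic <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    deviance = x$model$deviance,
    null_deviance = x$model$null.deviance,
    aic = x$model$aic,
    separation = x$separation
  )
}

#' @rdname petresponse-tidiers
#' @method tidy pet_run
#' @export
tidy.pet_run <- function(x, ...) x$report
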