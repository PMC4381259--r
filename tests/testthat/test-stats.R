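test_that("confusion metrics reproduce hand-computed predictive values", {
  # visual-assessment style matrix
  v <- confusion_metrics(4, 34, 14, 2)
  expect_equal(round(v$sensitivity, 1), 66.7)
  expect_equal(round(v$specificity, 1), 70.8)
  expect_equal(round(v$ppv, 1), 22.2)
  expect_equal(round(v$npv, 1), 94.4)
  expect_equal(round(v$accuracy, 1), 70.4)
  # NPV-constrained delta-SUVmax style matrix
  d <- confusion_metrics(list(TP = 6, TN = 41, FP = 7, FN = 0))
  expect_equal(round(unlist(d), 1),
               c(sensitivity = 100, specificity = 85.4, ppv = 46.2,
                 npv = 100, accuracy = 87.0))
  # zero denominators flag as NA, never as 0
  z <- confusion_metrics(0, 0, 0, 0)
  expect_true(all(is.na(unlist(z))))
  expect_error(confusion_metrics(-1, 2, 3, 4), "non-negative")
})

test_that("DeLong AUC equals the pairwise concordance oracle", {
  set.seed(101)
  for (i in 1:30) {
    n_pos <- sample(2:12, 1); n_neg <- sample(2:25, 1)
    scores <- round(c(rnorm(n_pos, 1), rnorm(n_neg)), 1) # rounding forces ties
    labels <- rep(c("relapse", "remission"), c(n_pos, n_neg))
    dir <- sample(c("greater_positive", "less_positive"), 1)
    got <- auc_delong(scores, labels, dir)
    expect_equal(got$auc, brute_auc(scores, labels, dir))
    expect_gte(got$auc, got$ci_lo)
    expect_lte(got$auc, got$ci_hi)
  }
  expect_equal(auc_delong(c(5, 6, 1, 2), c("relapse", "relapse", "remission",
                                           "remission"))$auc, 1.0)
  expect_error(auc_delong(1:4, rep("remission", 4)), "both")
})

test_that("DeLong AUC and variance agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:5) {
    scores <- rnorm(40, rep(c(1, 0), c(15, 25)))
    labels <- rep(c("relapse", "remission"), c(15, 25))
    ours <- auc_delong(scores, labels)
    ref <- pROC::roc(labels, scores, levels = c("remission", "relapse"),
                     direction = "<", quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
    expect_equal(ours$se^2, pROC::var(ref, method = "delong"))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(19)
  scores <- rnorm(30); labels <- rep(c("relapse", "remission"), c(10, 20))
  a0 <- auc_delong(scores, labels)$auc
  expect_equal(auc_delong(exp(scores), labels)$auc, a0)
  expect_equal(auc_delong(3 * scores - 7, labels)$auc, a0)
})

test_that("cutoff selection separates, constrains NPV, and matches the scan oracle", {
  # perfectly separable case: the midpoint of the gap is returned
  sc <- c(55, 60, 70, 80, 90, 95)
  lb <- rep(c("relapse", "remission"), each = 3)
  res <- select_cutoff(sc, lb, "less_positive", "npv_100")
  expect_equal(res$cutoff, 75)
  expect_equal(res$accuracy, 100)
  expect_equal(unlist(res[, c("TP", "TN", "FP", "FN")]),
               c(TP = 3L, TN = 3L, FP = 0L, FN = 0L))

  # ranks mirroring the constrained delta-SUVmax analysis: 6 non-responders
  # below the boundary, 7 of 48 responders interleaved below it too
  nonresp <- c(35, 48, 55, 62, 70, 76)
  resp <- c(c(50, 57, 60, 64, 68, 72, 75), seq(80, 99, length.out = 41))
  scores <- c(nonresp, resp)
  labels <- rep(c("relapse", "remission"), c(6, 48))
  sel <- select_cutoff(scores, labels, "less_positive", "npv_100")
  expect_equal(unlist(sel[, c("TP", "TN", "FP", "FN")]),
               c(TP = 6L, TN = 41L, FP = 7L, FN = 0L))
  expect_equal(round(sel$ppv, 1), 46.2)
  expect_equal(round(sel$npv, 1), 100)

  # relaxing the constraint can only help accuracy
  rel <- select_cutoff(scores, labels, "less_positive", "none")
  expect_gte(rel$accuracy, sel$accuracy)

  # oracle equivalence on random instances, both constraints
  set.seed(303)
  for (i in 1:30) {
    n_pos <- sample(2:10, 1); n_neg <- sample(3:30, 1)
    s <- round(c(rnorm(n_pos, 1.2), rnorm(n_neg)), 1)
    l <- rep(c("relapse", "remission"), c(n_pos, n_neg))
    dir <- sample(c("greater_positive", "less_positive"), 1)
    for (constr in c("npv_100", "none")) {
      got <- suppressWarnings(select_cutoff(s, l, dir, constr))
      want <- brute_best_cutoff(s, l, dir, npv100 = constr == "npv_100")
      expect_equal(unname(unlist(got[, c("TP", "TN", "FP", "FN")])),
                   c(want$tp, want$tn, want$fp, want$fn))
      expect_equal(got$cutoff, want$cutoff)
    }
  }
})

test_that("only-degenerate NPV constraint warns and calls everyone positive", {
  # the sole relapse sits at the extreme 'responder' end
  s <- c(99, 1, 2, 3)
  l <- c("relapse", rep("remission", 3))
  expect_warning(res <- select_cutoff(s, l, "less_positive", "npv_100"),
                 "degenerate|all-positive")
  expect_equal(res$FN, 0L)
  expect_equal(res$TN, 0L)
  expect_true(res$degenerate)
})

test_that("paired DeLong comparison: identity, rank invariance, bootstrap", {
  set.seed(55)
  scores <- rnorm(30); labels <- rep(c("relapse", "remission"), c(12, 18))
  same <- delong_compare(scores, scores, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_compare(scores, exp(scores) + 2, labels)
  expect_equal(mono$auc_diff, 0)
  expect_equal(mono$p_value, 1)
  expect_error(delong_compare(scores, scores[-1], labels), "paired")

  # bootstrap oracle on a handful of correlated instances
  set.seed(404)
  for (i in 1:3) {
    inst <- random_paired_instance()
    ours <- delong_compare(inst$a, inst$b, inst$labels)
    p_boot <- boot_auc_diff_p(inst$a, inst$b, inst$labels, B = 4000)
    expect_lt(abs(ours$p_value - p_boot), 0.1)
  }
})

test_that("paired comparison agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  for (i in 1:4) {
    inst <- random_paired_instance()
    ours <- delong_compare(inst$a, inst$b, inst$labels)
    ra <- pROC::roc(inst$labels, inst$a, levels = c("remission", "relapse"),
                    direction = "<", quiet = TRUE)
    rb <- pROC::roc(inst$labels, inst$b, levels = c("remission", "relapse"),
                    direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(ours$p_value, as.numeric(ref$p.value))
  }
})

test_that("FDR adjustment equals the step-up definition and is monotone", {
  single <- fdr_adjust(0.03)
  expect_equal(single$p_adj, 0.03)
  expect_true(single$significant)
  expect_false(any(fdr_adjust(rep(1, 6))$significant))
  expect_error(fdr_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(202)
  for (i in 1:20) {
    p <- runif(sample(2:15, 1))^sample(1:3, 1)
    adj <- fdr_adjust(p)$p_adj
    expect_equal(adj, brute_bh(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("logistic regression recovers designed effects and flags separation", {
  set.seed(91)
  n <- 400
  suv_max2 <- rlnorm(n, log(2), 0.5)
  mtv2 <- rlnorm(n, log(5), 0.8)
  eta <- -4 + 1.6 * suv_max2 # outcome driven by uptake only
  y <- rbinom(n, 1, plogis(eta))
  rec <- tibble::tibble(
    suv_max2 = suv_max2, mtv_ml2 = mtv2,
    outcome = ifelse(y == 1, "relapse", "remission")
  )
  fit <- logistic_response_model(rec, c("suv_max2", "mtv_ml2"))
  td <- tidy(fit)
  expect_lt(td$p_value[td$term == "suv_max2"], 0.001)
  expect_gt(td$p_value[td$term == "mtv_ml2"], 0.05)
  expect_false(glance(fit)$separation)

  # null feature: coefficient near zero, not significant
  rec_null <- tibble::tibble(
    x = rnorm(n), outcome = sample(c("relapse", "remission"), n, TRUE)
  )
  fit0 <- logistic_response_model(rec_null, "x")
  expect_gt(tidy(fit0)$p_value[2], 0.01)
  expect_lt(abs(tidy(fit0)$estimate[2]), 0.5)

  # complete separation is flagged, not reported as a finite effect
  rec_sep <- tibble::tibble(
    x = c(1:10, 21:30),
    outcome = rep(c("remission", "relapse"), each = 10)
  )
  fit_sep <- logistic_response_model(rec_sep, "x")
  expect_true(fit_sep$separation)

  # a constant extra feature does not change the informative coefficient
  rec$const <- 1.7
  fit2 <- logistic_response_model(rec, c("suv_max2", "const"))
  fit1 <- logistic_response_model(rec, "suv_max2")
  expect_equal(
    tidy(fit2)$estimate[tidy(fit2)$term == "suv_max2"],
    tidy(fit1)$estimate[tidy(fit1)$term == "suv_max2"],
    tolerance = 1e-6
  )
})

test_that("one-sided proportion power behaves as designed", {
  # at the null the rejection rate is alpha
  expect_equal(power_one_proportion(0.6, 0.6 + 1e-12, 0.05, 44), 0.05,
               tolerance = 1e-6)
  # nondecreasing in n
  pw <- power_one_proportion(0.6, 0.8, 0.05, 10:200)
  expect_true(all(diff(pw) >= 0))
  # the study design point: 44 patients give at least 90% power
  expect_gte(power_one_proportion(0.6, 0.8, 0.05, 44), 0.90)
  # inverse round trip
  n_min <- sample_size_one_proportion(0.6, 0.8, 0.05, 0.90)
  expect_gte(power_one_proportion(0.6, 0.8, 0.05, n_min), 0.90)
  expect_lt(power_one_proportion(0.6, 0.8, 0.05, n_min - 1), 0.90)
  expect_error(power_one_proportion(0.8, 0.6, 0.05, 44), "p0 < p1")
})
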