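#' Area under the ROC curve
#'
#' The Mann-Whitney pair statistic: the fraction of (positive, negative)
#' pairs with the positive scored higher, ties counted one half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1 = event).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (one per event), V01 (one per non-event).
delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1L]; y <- scores[labels == 0L]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong confidence interval for one AUC
#'
#' Normal-theory CI from the DeLong structural-component variance.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return Named vector `auc`, `lo`, `hi`, `se`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  dc <- delong_components(scores, labels)
  se <- sqrt(var(dc$v10) / length(dc$v10) + var(dc$v01) / length(dc$v01))
  z <- qnorm(1 - (1 - level) / 2)
  c(auc = dc$auc, lo = max(0, dc$auc - z * se), hi = min(1, dc$auc + z * se),
    se = se)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided normal test of the AUC difference of two risk scores on the
#' same patients, using the paired structural-component variance. If the
#' variance of the difference is degenerate (e.g. identical scores), p = 1
#' is returned with a warning.
#'
#' @param scores_a,scores_b Paired scores on identical patients.
#' @inheritParams roc_auc
#' @return List: `auc_a`, `auc_b`, `diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  vd <- var(da$v10 - db$v10) / length(da$v10) +
    var(da$v01 - db$v01) / length(da$v01)
  d <- da$auc - db$auc
  if (vd <= 0 || !is.finite(vd)) {
    if (d != 0) warning("degenerate DeLong variance with nonzero AUC difference")
    return(list(auc_a = da$auc, auc_b = db$auc, diff = d, z = 0, p_value = 1))
  }
  z <- d / sqrt(vd)
  list(auc_a = da$auc, auc_b = db$auc, diff = d, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Youden-optimal cutoff
#'
#' The threshold maximizing sensitivity + specificity - 1, searched over the
#' midpoints of consecutive distinct observed scores (a score counts as
#' test-positive when it is >= the cutoff). Ties in J are broken toward the
#' higher threshold, i.e. higher specificity. If all scores are identical,
#' that value is returned with a warning (J = 0 everywhere).
#'
#' @inheritParams roc_auc
#' @return The cutoff value.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("all scores identical; Youden index is 0 at every threshold")
    return(u)
  }
  cand <- (u[-1L] + u[-length(u)]) / 2
  j <- vapply(cand, function(th) {
    sens <- mean(scores[labels == 1L] >= th)
    spec <- mean(scores[labels == 0L] < th)
    sens + spec - 1
  }, numeric(1))
  best <- which(j == max(j))
  cand[max(best)]
}

#' Confusion-matrix metrics with Clopper-Pearson intervals
#'
#' Sensitivity, specificity, PPV, NPV and accuracy as count ratios, each
#' with an exact (Clopper-Pearson) binomial 95% CI. A metric whose
#' denominator is zero is reported as `NA`.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @param level Confidence level (default 0.95).
#' @return Tibble `metric`, `estimate`, `ci_low`, `ci_high`, `numerator`,
#'   `denominator`.
#' @export
#' @examples
#' confusion_metrics(tp = 49, fp = 89, fn = 38, tn = 215)
confusion_metrics <- function(tp, fp, fn, tn, level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  a <- (1 - level) / 2
  cp <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
    hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
    c(x / n, lo, hi)
  }
  rows <- list(sensitivity = cp(tp, tp + fn), specificity = cp(tn, tn + fp),
               ppv = cp(tp, tp + fp), npv = cp(tn, tn + fn),
               accuracy = cp(tp + tn, tp + fp + fn + tn))
  dens <- c(tp + fn, tn + fp, tp + fp, tn + fn, tp + fp + fn + tn)
  nums <- c(tp, tn, tp, tn, tp + tn)
  tibble::tibble(metric = names(rows),
                 estimate = unname(vapply(rows, `[`, numeric(1), 1L)),
                 ci_low = unname(vapply(rows, `[`, numeric(1), 2L)),
                 ci_high = unname(vapply(rows, `[`, numeric(1), 3L)),
                 numerator = as.integer(nums), denominator = as.integer(dens))
}

#' McNemar test of two paired classifiers
#'
#' Exact binomial version when the discordant count is below 25, otherwise
#' the chi-square approximation with continuity correction. Zero discordant
#' pairs give p = 1.
#'
#' @param correct_a,correct_b Paired binary indicators (e.g. "classifier
#'   correct") for the same patients.
#' @return List `b` (A only), `c` (B only), `p_value`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  a <- as.logical(correct_a); b <- as.logical(correct_b)
  n10 <- sum(a & !b); n01 <- sum(!a & b)
  nd <- n10 + n01
  if (nd == 0L) return(list(b = 0L, c = 0L, p_value = 1, method = "exact"))
  if (nd < 25L) {
    p <- min(1, 2 * pbinom(min(n10, n01), nd, 0.5))
    return(list(b = n10, c = n01, p_value = p, method = "exact"))
  }
  stat <- (abs(n10 - n01) - 1)^2 / nd
  list(b = n10, c = n01, p_value = pchisq(stat, 1, lower.tail = FALSE),
       method = "chi-square")
}

#' Continuous (category-free) net reclassification improvement
#'
#' `NRI = [P(up | event) - P(down | event)] + [P(down | nonevent) -
#' P(up | nonevent)]`, where "up" means the new model assigns a higher
#' probability than the old, with the usual asymptotic z-test.
#'
#' @param probs_old,probs_new Paired predicted probabilities.
#' @param labels Binary outcome (1 = event).
#' @return List: `nri`, `nri_event`, `nri_nonevent`, `z`, `p_value`.
#' @export
nri <- function(probs_old, probs_new, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both events and non-events are required")
  up <- probs_new > probs_old; down <- probs_new < probs_old
  e <- labels == 1L
  pe_up <- mean(up[e]); pe_dn <- mean(down[e])
  pn_up <- mean(up[!e]); pn_dn <- mean(down[!e])
  nri_e <- pe_up - pe_dn
  nri_n <- pn_dn - pn_up
  v <- (pe_up + pe_dn - nri_e^2) / sum(e) + (pn_up + pn_dn - nri_n^2) / sum(!e)
  total <- nri_e + nri_n
  if (v <= 0) return(list(nri = total, nri_event = nri_e, nri_nonevent = nri_n,
                          z = 0, p_value = 1))
  z <- total / sqrt(v)
  list(nri = total, nri_event = nri_e, nri_nonevent = nri_n, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Hosmer-Lemeshow goodness of fit and calibration curve
#'
#' Patients are grouped into risk deciles of the predicted probability
#' (groups with tied boundaries are merged, with a warning); the statistic
#' is `sum((O - E)^2 / (E * (1 - E / n_g)))` on `n_groups - 2` degrees of
#' freedom. Also returns the calibration points (mean predicted vs observed
#' rate per group).
#'
#' @param probs Predicted probabilities.
#' @param labels Binary outcome.
#' @param n_groups Number of risk groups (default 10).
#' @return List: `chi2`, `dof`, `p_value`, `calibration` (tibble `group`,
#'   `n`, `mean_predicted`, `observed_rate`).
#' @export
hosmer_lemeshow <- function(probs, labels, n_groups = 10) {
  labels <- as.integer(labels)
  stopifnot(length(probs) >= 2 * n_groups)
  br <- unique(quantile(probs, seq(0, 1, length.out = n_groups + 1L)))
  if (length(br) < n_groups + 1L)
    warning("tied probability deciles; merged into ", length(br) - 1L, " groups")
  g <- cut(probs, br, include.lowest = TRUE, labels = FALSE)
  ng <- tapply(labels, g, length)
  o <- tapply(labels, g, sum)
  e <- tapply(probs, g, sum)
  denom <- e * (1 - e / ng)
  keep <- denom > 0
  chi2 <- sum((o[keep] - e[keep])^2 / denom[keep])
  dof <- sum(keep) - 2L
  p <- if (dof > 0) pchisq(chi2, dof, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, dof = dof, p_value = p,
       calibration = tibble::tibble(group = as.integer(names(ng)),
                                    n = as.integer(ng),
                                    mean_predicted = as.numeric(tapply(probs, g, mean)),
                                    observed_rate = as.numeric(o / ng)))
}

#' Decision curve: net benefit across threshold probabilities
#'
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)` for the model that treats
#' patients with predicted probability >= `pt`, alongside the treat-all
#' reference `prevalence - (1 - prevalence) * pt / (1 - pt)` and the
#' treat-none reference 0.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary outcome.
#' @param thresholds Threshold grid, strictly inside (0, 1).
#' @return Tibble `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds >= 1) || any(thresholds <= 0))
    stop("thresholds must lie strictly inside (0, 1)")
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  rows <- vapply(thresholds, function(pt) {
    treat <- probs >= pt
    tp <- sum(treat & labels == 1L); fp <- sum(treat & labels == 0L)
    w <- pt / (1 - pt)
    c(tp / n - fp / n * w, prev - (1 - prev) * w)
  }, numeric(2))
  tibble::tibble(threshold = thresholds, net_benefit = rows[1L, ],
                 treat_all = rows[2L, ], treat_none = 0)
}

#' Cohen's kappa (unweighted)
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` of two paired
#' categorical ratings; `NA` when the expected agreement is 1.
#'
#' @param ratings1,ratings2 Paired ratings over the same category space.
#' @return Kappa.
#' @export
cohen_kappa <- function(ratings1, ratings2) {
  stopifnot(length(ratings1) == length(ratings2))
  lev <- sort(unique(c(as.character(ratings1), as.character(ratings2))))
  r1 <- factor(as.character(ratings1), levels = lev)
  r2 <- factor(as.character(ratings2), levels = lev)
  tab <- table(r1, r2) / length(r1)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Full evaluation report for one model on one cohort
#'
#' AUC with DeLong CI, the Youden cutoff (derived from the supplied scores
#' unless `cutoff` is given, e.g. the primary-cohort cutoff applied to
#' validation data), the confusion matrix at that cutoff, and all confusion
#' metrics with Clopper-Pearson CIs.
#'
#' @param scores Risk scores or probabilities.
#' @param labels Binary outcome.
#' @param cutoff Optional fixed cutoff; default: Youden on these data.
#' @param subgroup Label stored with the report.
#' @return An `evaluation_report`.
#' @export
evaluate_model <- function(scores, labels, cutoff = NULL, subgroup = "all") {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(structure(list(subgroup = subgroup, n = length(labels),
                          n_pos = n1, auc = NULL, cutoff = cutoff,
                          confusion = NULL, metrics = NULL,
                          reason = "single-class subgroup; AUC and rate metrics undefined"),
                     class = "evaluation_report"))
  }
  ci <- delong_ci(scores, labels)
  if (is.null(cutoff)) cutoff <- youden_cutoff(scores, labels)
  pos <- scores >= cutoff
  tp <- sum(pos & labels == 1L); fp <- sum(pos & labels == 0L)
  fn <- sum(!pos & labels == 1L); tn <- sum(!pos & labels == 0L)
  structure(list(subgroup = subgroup, n = length(labels), n_pos = n1,
                 auc = ci, cutoff = cutoff,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 metrics = confusion_metrics(tp, fp, fn, tn),
                 roc = roc_points(scores, labels),
                 reason = NA_character_),
            class = "evaluation_report")
}

roc_points <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  labels <- as.integer(labels)
  tibble::tibble(
    threshold = th,
    tpr = vapply(th, function(t) mean(scores[labels == 1L] >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(scores[labels == 0L] >= t), numeric(1))
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> subgroup ", x$subgroup, ", n = ", x$n,
      " (", x$n_pos, " events)\n", sep = "")
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g\n",
                x$auc["auc"], x$auc["lo"], x$auc["hi"], x$cutoff))
    m <- x$metrics
    for (k in seq_len(nrow(m)))
      cat(sprintf("  %-12s %5.1f%% (%4.1f-%5.1f%%)\n", m$metric[k],
                  100 * m$estimate[k], 100 * m$ci_low[k], 100 * m$ci_high[k]))
  } else {
    cat("  ", x$reason, "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn evaluate_model Metrics as a tidy tibble.
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) {
  if (is.null(x$auc))
    return(tibble::tibble(subgroup = x$subgroup, metric = character(0),
                          estimate = numeric(0), ci_low = numeric(0),
                          ci_high = numeric(0)))
  dplyr::bind_rows(
    tibble::tibble(metric = "auc", estimate = unname(x$auc["auc"]),
                   ci_low = unname(x$auc["lo"]), ci_high = unname(x$auc["hi"])),
    x$metrics[, c("metric", "estimate", "ci_low", "ci_high")]
  ) |> dplyr::mutate(subgroup = x$subgroup, .before = 1L)
}

#' @describeIn evaluate_model One-row summary.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(subgroup = x$subgroup, n = x$n, n_pos = x$n_pos,
                 auc = if (is.null(x$auc)) NA_real_ else unname(x$auc["auc"]),
                 cutoff = if (is.null(x$cutoff)) NA_real_ else x$cutoff)
}

#' @describeIn evaluate_model ROC curve.
#' @param object An `evaluation_report`.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  if (is.null(object$roc)) stop("no ROC available: ", object$reason)
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (%s), AUC %.3f", object$subgroup,
                                  object$auc["auc"]))
}

#' Stratified evaluation by post-therapy tumor stage
#'
#' Separate reports for the ymrT1-2 and ymrT3-4 subgroups. Cutoffs are
#' derived within each subgroup unless fixed cutoffs are supplied (the
#' pipeline passes primary-cohort subgroup cutoffs when evaluating
#' validation data). Subgroups with fewer than 10 patients or a single
#' class are flagged and their rate metrics reported as missing.
#'
#' @param scores Risk scores or probabilities.
#' @param labels Binary outcome.
#' @param ymrT Integer stage (1-4) per patient.
#' @param cutoffs Optional named list/vector with entries `ymrT1-2`,
#'   `ymrT3-4`.
#' @return Named list of `evaluation_report`s.
#' @export
stratified_report <- function(scores, labels, ymrT, cutoffs = NULL) {
  groups <- list(`ymrT1-2` = ymrT <= 2, `ymrT3-4` = ymrT >= 3)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (sum(idx) < 10L)
      return(structure(list(subgroup = g, n = sum(idx),
                            n_pos = sum(labels[idx] == 1L), auc = NULL,
                            cutoff = NULL, confusion = NULL, metrics = NULL,
                            reason = "subgroup smaller than 10 patients"),
                       class = "evaluation_report"))
    evaluate_model(scores[idx], labels[idx],
                   cutoff = if (is.null(cutoffs)) NULL else cutoffs[[g]],
                   subgroup = g)
  })
  names(out) <- names(groups)
  out
}

#' Calibration plot for a fitted risk model
#'
#' @param hl A [hosmer_lemeshow()] result.
#' @return A ggplot.
#' @export
plot_calibration <- function(hl) {
  ggplot2::ggplot(hl$calibration,
                  ggplot2::aes(.data$mean_predicted, .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = 0:1, ylim = 0:1) +
    ggplot2::labs(x = "mean predicted probability", y = "observed LNM+ rate",
                  title = sprintf("Calibration (Hosmer-Lemeshow p = %.3f)",
                                  hl$p_value),
                  size = "patients")
}

#' Decision-curve plot
#'
#' @param dc A [decision_curve()] tibble.
#' @return A ggplot.
#' @export
plot_decision_curve <- function(dc) {
  long <- tidyr::pivot_longer(dc, c("net_benefit", "treat_all", "treat_none"),
                              names_to = "strategy", values_to = "nb")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$nb,
                                     color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit",
                  title = "Decision curve")
}
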