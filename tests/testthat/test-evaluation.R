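test_that("AUC equals the all-pairs count, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(40)
  for (rep in 1:50) {
    n <- sample(20:60, 1)
    sc <- sample(round(rnorm(n), 1))   # rounded -> ties occur
    lab <- rbinom(n, 1, 0.4)
    if (sum(lab) == 0 || sum(lab) == n) next
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab), tolerance = 1e-12)
  }

  set.seed(41)
  sc <- rnorm(10000); lab <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(sc, lab) - 0.5), 0.02)
})

test_that("DeLong inference matches pROC and bootstrap variability", {
  set.seed(42)
  n <- 150
  x <- rnorm(n); lab <- rbinom(n, 1, plogis(x))
  ci <- delong_ci(x, lab)
  proc_ci <- as.numeric(pROC::ci.auc(pROC::roc(lab, x, quiet = TRUE),
                                     method = "delong"))
  expect_equal(unname(ci["auc"]), proc_ci[2], tolerance = 1e-10)
  expect_equal(unname(ci["lo"]), proc_ci[1], tolerance = 1e-10)
  expect_equal(unname(ci["hi"]), proc_ci[3], tolerance = 1e-10)

  y <- x + rnorm(n, sd = 2)
  dt <- delong_test(x, y, lab)
  proc_p <- pROC::roc.test(pROC::roc(lab, x, quiet = TRUE),
                           pROC::roc(lab, y, quiet = TRUE),
                           method = "delong", paired = TRUE)$p.value
  expect_equal(dt$p_value, proc_p, tolerance = 1e-10)

  # identical scores: difference 0, p = 1
  same <- delong_test(x, x, lab)
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)

  # swapping the two models flips the sign but not the p-value
  dt2 <- delong_test(y, x, lab)
  expect_equal(dt2$p_value, dt$p_value, tolerance = 1e-12)
  expect_equal(dt2$z, -dt$z, tolerance = 1e-12)

  # DeLong variance tracks the bootstrap variance of the AUC
  set.seed(43)
  ratios <- replicate(8, {
    n <- 120
    x <- rnorm(n); lab <- rbinom(n, 1, plogis(1.2 * x))
    while (sum(lab) < 10 || sum(lab) > n - 10) lab <- rbinom(n, 1, plogis(1.2 * x))
    dl_var <- delong_ci(x, lab)["se"]^2
    boot <- replicate(2000, {
      idx <- sample(n, replace = TRUE)
      if (length(unique(lab[idx])) < 2) NA else roc_auc(x[idx], lab[idx])
    })
    var(boot, na.rm = TRUE) / dl_var
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)

  # CI width shrinks roughly like 1/sqrt(n)
  set.seed(44)
  width <- vapply(c(200, 800), function(n) {
    w <- replicate(30, {
      x <- rnorm(n); lab <- rbinom(n, 1, plogis(x))
      ci <- delong_ci(x, lab)
      ci["hi"] - ci["lo"]
    })
    mean(w)
  }, numeric(1))
  expect_equal(width[1] / width[2], 2, tolerance = 0.25)
})

test_that("Youden cutoff maximizes J with ties broken toward specificity", {
  expect_equal(youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2.5)
  expect_warning(cut1 <- youden_cutoff(rep(2, 8), c(0, 1, 0, 1, 0, 1, 0, 1)),
                 "identical")
  expect_equal(cut1, 2)

  set.seed(45)
  for (rep in 1:20) {
    sc <- round(rnorm(40), 1)
    lab <- rbinom(40, 1, plogis(2 * sc))
    if (length(unique(lab)) < 2 || length(unique(sc)) < 2) next
    got <- youden_cutoff(sc, lab)
    u <- sort(unique(sc))
    cand <- (u[-1] + u[-length(u)]) / 2
    j <- vapply(cand, function(th) {
      tp <- sum(sc >= th & lab == 1); fn <- sum(sc < th & lab == 1)
      tn <- sum(sc < th & lab == 0); fp <- sum(sc >= th & lab == 0)
      tp / (tp + fn) + tn / (tn + fp) - 1
    }, numeric(1))
    expect_equal(got, max(cand[j == max(j)]))
  }
})

test_that("confusion metrics reproduce the printed restaging tables exactly", {
  # node restaging: ymrN vs pathological N
  node <- confusion_metrics(tp = 49, fp = 89, fn = 38, tn = 215)
  est <- setNames(node$estimate, node$metric)
  expect_equal(round(100 * est[["sensitivity"]], 1), 56.3)
  expect_equal(round(100 * est[["specificity"]], 1), 70.7)
  expect_equal(round(100 * est[["ppv"]], 1), 35.5)
  # 215/253 = 84.98%; the printed 84.9% truncates the last digit
  expect_lt(abs(100 * est[["npv"]] - 84.9), 0.1)

  # tumor restaging accuracy
  tum <- confusion_metrics(tp = 120, fp = 14, fn = 32, tn = 225)
  expect_equal(round(100 * tum$estimate[tum$metric == "accuracy"], 1), 88.2)

  perfect <- confusion_metrics(tp = 5, fp = 0, fn = 0, tn = 7)
  expect_true(all(perfect$estimate == 1))

  # counts reconstruct from the reported numerators/denominators
  expect_equal(node$numerator[node$metric == "sensitivity"], 49)
  expect_equal(node$denominator[node$metric == "sensitivity"], 87)
  expect_equal(node$denominator[node$metric == "accuracy"], 391)

  # zero denominators give missing metrics
  nodeg <- confusion_metrics(tp = 0, fp = 0, fn = 0, tn = 10)
  expect_true(is.na(nodeg$estimate[nodeg$metric == "sensitivity"]))
  expect_false(is.na(nodeg$estimate[nodeg$metric == "npv"]))

  # Clopper-Pearson agrees with binom.test
  bt <- binom.test(49, 87)$conf.int
  expect_equal(node$ci_low[node$metric == "sensitivity"], bt[1],
               tolerance = 1e-10)
  expect_equal(node$ci_high[node$metric == "sensitivity"], bt[2],
               tolerance = 1e-10)
})

test_that("McNemar switches between exact and corrected chi-square forms", {
  a <- rep(TRUE, 30)
  expect_equal(mcnemar_test(a, a)$p_value, 1)

  # 10 vs 0 discordant: exact two-sided p = 2 * 0.5^10
  a <- c(rep(TRUE, 10), rep(TRUE, 20)); b <- c(rep(FALSE, 10), rep(TRUE, 20))
  m <- mcnemar_test(a, b)
  expect_equal(m$p_value, 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(m$method, "exact")

  # 15 vs 5: two-sided binomial tail sum
  a <- c(rep(TRUE, 15), rep(FALSE, 5), rep(TRUE, 10))
  b <- c(rep(FALSE, 15), rep(TRUE, 5), rep(TRUE, 10))
  m2 <- mcnemar_test(a, b)
  expect_equal(m2$p_value, 2 * pbinom(5, 20, 0.5), tolerance = 1e-12)

  # large discordant count: continuity-corrected chi-square
  a <- c(rep(TRUE, 20), rep(FALSE, 15), rep(TRUE, 30))
  b <- c(rep(FALSE, 20), rep(TRUE, 15), rep(TRUE, 30))
  m3 <- mcnemar_test(a, b)
  expect_equal(m3$method, "chi-square")
  expect_equal(m3$p_value,
               pchisq((abs(20 - 15) - 1)^2 / 35, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(m3$p_value,
               mcnemar.test(table(a, b))$p.value, tolerance = 1e-12)
})

test_that("continuous NRI matches hand enumeration", {
  p <- rep(0.4, 10); lab <- rep(0:1, 5)
  same <- nri(p, p, lab)
  expect_equal(same$nri, 0)
  expect_equal(same$p_value, 1)

  up_all <- nri(p, p + 0.1 * (2 * lab - 1), lab)  # events up, nonevents down
  expect_equal(up_all$nri, 2)

  # 8 patients, enumerated by hand:
  # events (4): new-old = +, +, -, 0  -> P(up|e)=2/4, P(down|e)=1/4
  # nonevents (4): new-old = -, -, +, + -> P(down|ne)=2/4, P(up|ne)=2/4
  old <- c(0.5, 0.4, 0.6, 0.3, 0.2, 0.3, 0.1, 0.4)
  new <- c(0.6, 0.5, 0.5, 0.3, 0.1, 0.2, 0.3, 0.6)
  lab8 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  res <- nri(old, new, lab8)
  expect_equal(res$nri_event, 2 / 4 - 1 / 4)
  expect_equal(res$nri_nonevent, 2 / 4 - 2 / 4)
  expect_equal(res$nri, 0.25)

  expect_error(nri(p, p, rep(1, 10)), "non-events")
})

test_that("Hosmer-Lemeshow is zero under perfect grouping and uniform under the null", {
  # two groups whose observed rate equals the mean prediction -> chi2 = 0
  probs <- c(rep(0.2, 10), rep(0.8, 10))
  lab <- c(rep(0, 8), rep(1, 2), rep(1, 8), rep(0, 2))
  hl <- hosmer_lemeshow(probs, lab, n_groups = 2)
  expect_equal(hl$chi2, 0, tolerance = 1e-12)

  # hand-computed two-group example
  probs2 <- c(rep(0.3, 10), rep(0.6, 10))
  lab2 <- c(rep(1, 5), rep(0, 5), rep(1, 4), rep(0, 6))
  hl2 <- hosmer_lemeshow(probs2, lab2, n_groups = 2)
  chi_manual <- (5 - 3)^2 / (3 * (1 - 3 / 10)) + (4 - 6)^2 / (6 * (1 - 6 / 10))
  expect_equal(hl2$chi2, chi_manual, tolerance = 1e-12)
  expect_equal(hl2$dof, 0)

  # fitted probabilities of a correctly specified model: p approximately
  # uniform (the g - 2 degrees of freedom assume estimated parameters)
  set.seed(46)
  ps <- replicate(400, {
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(x - 0.5))
    pr <- fitted(glm(y ~ x, family = binomial()))
    hosmer_lemeshow(pr, y)$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 1e-3)
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("decision curve matches its closed forms", {
  set.seed(47)
  lab <- rbinom(200, 1, 0.25)
  while (mean(lab) == 0) lab <- rbinom(200, 1, 0.25)
  pr <- runif(200)
  dc <- decision_curve(pr, lab, thresholds = c(0.25, 0.5, 0.75))
  expect_true(all(dc$treat_none == 0))
  prev <- mean(lab)
  expect_equal(dc$treat_all[dc$threshold == 0.5], prev - (1 - prev) * 1,
               tolerance = 1e-12)
  expect_error(decision_curve(pr, lab, thresholds = c(0.2, 1)), "inside")

  # perfect model: NB = prevalence at every threshold
  perf <- decision_curve(ifelse(lab == 1, 0.99, 0.01), lab,
                         thresholds = seq(0.05, 0.95, 0.05))
  expect_equal(perf$net_benefit, rep(prev, nrow(perf)), tolerance = 1e-12)

  # a model predicting 1 for everyone coincides with treat-all
  const <- decision_curve(rep(1, 200), lab, thresholds = seq(0.1, 0.9, 0.1))
  expect_equal(const$net_benefit, const$treat_all, tolerance = 1e-12)
})

test_that("Cohen's kappa matches closed forms and the e1071 cross-check", {
  expect_equal(cohen_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1)

  # printed 2x2 agreement table: 45/45 agree, 5/5 disagree -> kappa 0.8
  r1 <- c(rep("yes", 45), rep("no", 45), rep("yes", 5), rep("no", 5))
  r2 <- c(rep("yes", 45), rep("no", 45), rep("no", 5), rep("yes", 5))
  expect_equal(cohen_kappa(r1, r2), 0.8, tolerance = 1e-12)

  set.seed(48)
  a <- sample(1:4, 10000, TRUE); b <- sample(1:4, 10000, TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.03)

  expect_equal(cohen_kappa(r1, r2),
               e1071::classAgreement(table(r1, r2))$kappa, tolerance = 1e-12)

  expect_true(is.na(cohen_kappa(rep(1, 5), rep(1, 5))))
})

test_that("evaluation reports assemble consistently and stratify additively", {
  set.seed(49)
  n <- 200
  sc <- rnorm(n)
  lab <- rbinom(n, 1, plogis(1.5 * sc))
  ymrT <- sample(1:4, n, TRUE)
  rep_all <- evaluate_model(sc, lab)
  cm <- rep_all$confusion
  expect_equal(sum(cm), n)
  expect_equal(unname(cm["tp"] + cm["fn"]), sum(lab))
  expect_equal(unname(rep_all$auc["auc"]), roc_auc(sc, lab))
  td <- tidy(rep_all)
  expect_true(all(c("auc", "sensitivity", "npv") %in% td$metric))

  strat <- stratified_report(sc, lab, ymrT)
  cm12 <- strat$`ymrT1-2`$confusion; cm34 <- strat$`ymrT3-4`$confusion
  # with the pooled cutoff applied, subgroup confusion counts partition the
  # pooled ones
  strat_fixed <- stratified_report(sc, lab, ymrT,
                                   cutoffs = list(`ymrT1-2` = rep_all$cutoff,
                                                  `ymrT3-4` = rep_all$cutoff))
  expect_equal(strat_fixed$`ymrT1-2`$confusion + strat_fixed$`ymrT3-4`$confusion,
               rep_all$confusion)

  # all-negative subgroup: sensitivity missing, NPV defined
  repneg <- evaluate_model(sc[1:20], rep(0, 20))
  expect_true(!is.null(repneg$reason))
  sc2 <- sc[1:30]; lab2 <- c(rep(0, 29), 1)
  r2 <- evaluate_model(sc2, lab2, cutoff = max(sc2) + 1)
  m2 <- r2$metrics
  expect_true(is.na(m2$estimate[m2$metric == "ppv"]))
  expect_false(is.na(m2$estimate[m2$metric == "npv"]))

  small <- stratified_report(sc[1:12], lab[1:12], c(rep(1, 3), rep(3, 9)))
  expect_match(small$`ymrT1-2`$reason, "smaller than 10")
})
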