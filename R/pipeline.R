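#' End-to-end run configuration
#'
#' Bundles the cohort (or an already-generated one), the extraction
#' configuration, the selection thresholds and the master seed. The master
#' seed drives the LASSO fold assignment; the cohort carries its own seed so
#' the split is frozen at cohort creation and never re-randomized.
#'
#' @param cohort A [cohort_config()] or an `mri_cohort`.
#' @param extraction An [extraction_config()].
#' @param alpha Wilcoxon retention threshold (default 0.1).
#' @param r_threshold Spearman pruning threshold (default 0.9).
#' @param n_folds LASSO cross-validation folds (default 10).
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes tables, models and reports there.
#' @param seed Master seed for the selection stage.
#' @return A `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), extraction = extraction_config(),
                       alpha = 0.1, r_threshold = 0.9, n_folds = 10,
                       out_dir = NULL, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, r_threshold > 0, r_threshold < 1,
            n_folds >= 2)
  structure(list(cohort = cohort, extraction = extraction, alpha = alpha,
                 r_threshold = r_threshold, n_folds = n_folds,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Check a cohort against the exclusion criteria
#'
#' Report-only recruitment-style exclusion check: a patient passes if
#' all four sequences are present, every mask has at least 16 foreground
#' pixels, the clinical record is complete, and the node label is present.
#'
#' @param cohort An `mri_cohort`.
#' @return Tibble `patient_id`, `pass`, `reason` (`NA` when passing).
#' @export
validate_inputs <- function(cohort) {
  need_clin <- c("sex", "age", "cea", "radiation", "cT", "cN", "ymrT", "ymrN")
  rows <- lapply(cohort$samples, function(s) {
    reason <- NA_character_
    miss_seq <- setdiff(RADNODE_SEQUENCES, names(s$images))
    if (length(miss_seq) > 0L) {
      reason <- paste("missing sequence:", paste(miss_seq, collapse = ", "))
    } else if (any(vapply(s$masks, function(m) is.null(m) || sum(m) < 16L,
                          logical(1)))) {
      reason <- "insufficient ROI"
    } else if (!all(need_clin %in% names(s$clinical)) ||
               anyNA(s$clinical[need_clin])) {
      reason <- "incomplete clinical record"
    } else if (is.null(s$label) || is.na(s$label)) {
      reason <- "missing pathology label"
    }
    tibble::tibble(patient_id = s$patient_id, pass = is.na(reason),
                   reason = reason)
  })
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, apply the exclusion criteria, extract
#' features, normalize on primary-cohort statistics, run the three-step
#' selection, fit the radiomic signature, screen clinical variables, fit the
#' combined and clinical-only models, and evaluate everything on both
#' cohorts: AUCs with DeLong CIs, Youden-cutoff confusion metrics (the
#' primary-cohort cutoff is applied to the validation cohort), DeLong tests
#' between models, McNemar and NRI against the simulated radiologist and the
#' clinical model, Hosmer-Lemeshow calibration and the decision curve on the
#' validation cohort, and ymrT-stratified subgroup reports. Only primary
#' patients ever influence normalization, selection and model fits.
#'
#' @param config A [run_config()].
#' @return A `radnode_run` (list of all intermediate and final objects).
#'   When `config$out_dir` is set, CSV/JSON outputs and a manifest are
#'   written there as a side effect.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (inherits(config$cohort, "mri_cohort")) config$cohort
            else generate_cohort(config$cohort)

  checks <- validate_inputs(cohort)
  excluded <- checks[!checks$pass, ]
  if (nrow(excluded) > 0L) {
    keep <- checks$pass
    cohort$samples <- cohort$samples[keep]
    cohort$clinical <- cohort$clinical[keep, ]
    message(nrow(excluded), " patient(s) excluded: ",
            paste(excluded$patient_id, collapse = ", "))
  }

  features <- extract_feature_table(cohort, config$extraction)
  clin <- cohort$clinical
  is_primary <- clin$split == "primary"

  normalizer <- fit_normalizer(features[is_primary, ])
  norm <- apply_normalizer(features, normalizer)

  selection <- select_features(norm[is_primary, ], clin$label[is_primary],
                               alpha = config$alpha,
                               r_threshold = config$r_threshold,
                               n_folds = config$n_folds, seed = config$seed)

  # ridge = TRUE: under strong class signal the ML fit can hit separation;
  # the documented fallback is a tiny (1e-6) L2 penalty
  sig_model <- fit_signature_model(norm[is_primary, ],
                                   clin$label[is_primary],
                                   features = selection$stage3_kept,
                                   ridge = TRUE)
  signature <- compute_signature(sig_model, norm)
  clin$signature <- signature

  uni <- univariate_screen(clin[is_primary, ], clin$label[is_primary])
  combined <- fit_combined_model(clin[is_primary, ], clin$label[is_primary],
                                 ridge = TRUE)
  clinical_only <- fit_clinical_model(clin[is_primary, ], clin$label[is_primary],
                                      ridge = TRUE)
  nomogram <- export_nomogram(combined, data = clin[is_primary, ])

  prob <- list(signature = predict_probability(sig_model, norm),
               combined = predict_probability(combined, clin),
               clinical = predict_probability(clinical_only, clin))

  evals <- list()
  cuts <- list()
  for (m in names(prob)) {
    cuts[[m]] <- youden_cutoff(prob[[m]][is_primary], clin$label[is_primary])
    evals[[paste0(m, "_primary")]] <-
      evaluate_model(prob[[m]][is_primary], clin$label[is_primary],
                     cutoff = cuts[[m]], subgroup = "all")
    evals[[paste0(m, "_validation")]] <-
      evaluate_model(prob[[m]][!is_primary], clin$label[!is_primary],
                     cutoff = cuts[[m]], subgroup = "all")
  }

  # radiologist (ymrN >= 1) vs signature on the validation cohort
  val <- !is_primary
  rad_call <- clin$ymrN >= 1L
  sig_call <- prob$signature >= cuts$signature
  comparisons <- list(
    delong_combined_vs_clinical_validation =
      delong_test(prob$combined[val], prob$clinical[val], clin$label[val]),
    delong_signature_vs_clinical_validation =
      delong_test(prob$signature[val], prob$clinical[val], clin$label[val]),
    mcnemar_signature_vs_radiologist_validation =
      mcnemar_test(sig_call[val] == (clin$label[val] == 1L),
                   rad_call[val] == (clin$label[val] == 1L)),
    nri_combined_vs_clinical_validation =
      nri(prob$clinical[val], prob$combined[val], clin$label[val]),
    radiologist_validation = {
      tp <- sum(rad_call[val] & clin$label[val] == 1L)
      fp <- sum(rad_call[val] & clin$label[val] == 0L)
      fn <- sum(!rad_call[val] & clin$label[val] == 1L)
      tn <- sum(!rad_call[val] & clin$label[val] == 0L)
      confusion_metrics(tp, fp, fn, tn)
    }
  )

  # risk deciles where the validation cohort supports them, fewer otherwise
  n_val <- sum(val)
  hl <- if (n_val >= 4) {
    hosmer_lemeshow(prob$combined[val], clin$label[val],
                    n_groups = min(10L, max(2L, n_val %/% 5L)))
  } else NULL
  dc <- decision_curve(prob$combined[val], clin$label[val])

  strat_cuts <- lapply(stratified_report(prob$combined[is_primary],
                                         clin$label[is_primary],
                                         clin$ymrT[is_primary]),
                       function(r) r$cutoff)
  stratified <- list(
    primary = stratified_report(prob$combined[is_primary],
                                clin$label[is_primary],
                                clin$ymrT[is_primary]),
    validation = stratified_report(prob$combined[val], clin$label[val],
                                   clin$ymrT[val], cutoffs = strat_cuts)
  )

  run <- structure(list(
    config = config, cohort_table = clin, exclusions = excluded,
    features = features, normalizer = normalizer, normalized = norm,
    selection = selection, signature_model = sig_model,
    univariate = uni, combined_model = combined,
    clinical_model = clinical_only, nomogram = nomogram,
    probabilities = prob, cutoffs = cuts, evaluations = evals,
    comparisons = comparisons, hosmer_lemeshow = hl, decision_curve = dc,
    stratified = stratified
  ), class = "radnode_run")

  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' @export
print.radnode_run <- function(x, ...) {
  cat("<radnode_run> ", nrow(x$cohort_table), " patients, ",
      length(x$selection$stage3_kept), " selected features\n", sep = "")
  for (nm in c("signature_validation", "combined_validation",
               "clinical_validation")) {
    e <- x$evaluations[[nm]]
    if (!is.null(e$auc))
      cat(sprintf("  %-22s AUC %.3f (%.3f-%.3f)\n", nm, e$auc["auc"],
                  e$auc["lo"], e$auc["hi"]))
  }
  invisible(x)
}

# Deterministic CSV/JSON outputs plus a manifest; figures are not written
# here (use the autoplot/plot_* functions).
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, na = "null")
  readr::write_csv(run$cohort_table, file.path(dir, "cohort.csv"))
  readr::write_csv(run$features, file.path(dir, "features.csv"))
  readr::write_csv(tidy(run$selection), file.path(dir, "selection.csv"))
  readr::write_csv(run$univariate, file.path(dir, "univariate.csv"))
  readr::write_csv(
    tibble::tibble(patient_id = run$cohort_table$patient_id,
                   split = run$cohort_table$split,
                   signature = run$cohort_table$signature,
                   probability = run$probabilities$combined),
    file.path(dir, "predictions.csv"))
  readr::write_csv(run$decision_curve, file.path(dir, "decision_curve.csv"))
  if (!is.null(run$hosmer_lemeshow))
    readr::write_csv(run$hosmer_lemeshow$calibration,
                     file.path(dir, "calibration.csv"))
  wj(list(features = run$signature_model$features,
          coefficients = as.list(run$signature_model$coefficients),
          intercept = run$signature_model$intercept),
     "signature_model.json")
  wj(list(features = run$combined_model$features,
          coefficients = as.list(run$combined_model$coefficients),
          intercept = run$combined_model$intercept),
     "combined_model.json")
  wj(list(variables = run$nomogram$variables, const = run$nomogram$const,
          slope = run$nomogram$slope), "nomogram.json")
  wj(lapply(run$evaluations, function(e) {
    if (is.null(e$auc)) return(list(subgroup = e$subgroup, reason = e$reason))
    list(subgroup = e$subgroup, n = e$n, n_pos = e$n_pos,
         auc = as.list(e$auc), cutoff = e$cutoff,
         confusion = as.list(e$confusion), metrics = e$metrics)
  }), "evaluations.json")
  cfg <- run$config
  wj(list(seed = cfg$seed, alpha = cfg$alpha, r_threshold = cfg$r_threshold,
          n_folds = cfg$n_folds,
          cohort_seed = if (inherits(cfg$cohort, "cohort_config"))
            cfg$cohort$seed else NA,
          n_patients = nrow(run$cohort_table),
          n_excluded = nrow(run$exclusions),
          package_version = as.character(utils::packageVersion("radnode"))),
     "manifest.json")
  invisible(dir)
}
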