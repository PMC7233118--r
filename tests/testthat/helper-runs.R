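# End-to-end replicate runs shared by several acceptance checks.
# Strong-effect runs use large per-sequence effects; zero-effect runs switch
# every effect off. Results are memoized so each replicate set is computed
# once per test session.

.run_cache <- new.env(parent = emptyenv())

pipeline_replicates <- function(kind = c("strong", "zero"), n_seeds = 20) {
  kind <- match.arg(kind)
  key <- paste0(kind, "_", n_seeds)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  eff <- switch(kind,
                strong = c(texture = 1.0, intensity = 0.6),
                zero = c(texture = 0, intensity = 0))
  runs <- lapply(seq_len(n_seeds), function(s) {
    cfg <- run_config(
      cohort = cohort_config(n_patients = 391,
                             texture_effect = eff[["texture"]],
                             intensity_effect = eff[["intensity"]],
                             seed = 1000 + s),
      seed = 1000 + s)
    run <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
    list(
      clinical = run$cohort_table[, c("patient_id", "split", "label")],
      selected = run$selection$stage3_kept,
      sig_auc_val = unname(run$evaluations$signature_validation$auc["auc"]),
      comb_auc_val = unname(run$evaluations$combined_validation$auc["auc"]),
      clin_auc_val = unname(run$evaluations$clinical_validation$auc["auc"]),
      nri_val = run$comparisons$nri_combined_vs_clinical_validation$nri
    )
  })
  .run_cache[[key]] <- runs
  runs
}
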