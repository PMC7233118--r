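#' Fit the min-max normalizer on the primary cohort
#'
#' Records, per feature, the minimum and maximum over the primary cohort so
#' that every feature can be mapped linearly to \[0, 1\] by
#' `(x - min) / (max - min)`. Validation data are normalized with these
#' primary-cohort parameters and may legitimately fall outside \[0, 1\];
#' no clipping is applied.
#'
#' @param primary_table Feature tibble (primary cohort only, >= 2 patients).
#' @return A `normalization_params` object: tibble with `feature`, `min`,
#'   `max`.
#' @export
fit_normalizer <- function(primary_table) {
  feats <- feature_columns(primary_table)
  stopifnot(nrow(primary_table) >= 2)
  params <- tibble::tibble(
    feature = feats,
    min = unname(vapply(feats, function(f) min(primary_table[[f]]), numeric(1))),
    max = unname(vapply(feats, function(f) max(primary_table[[f]]), numeric(1)))
  )
  structure(params, class = c("normalization_params", class(params)))
}

#' Apply min-max normalization
#'
#' Elementwise `(x - min) / (max - min)` with the fitted primary-cohort
#' parameters. Features constant in the primary cohort (`max == min`) map to
#' 0 with a warning.
#'
#' @param table Feature tibble to normalize.
#' @param params A [fit_normalizer()] result covering all feature columns.
#' @return Tibble of the same shape with normalized feature columns.
#' @export
apply_normalizer <- function(table, params) {
  feats <- feature_columns(table)
  unknown <- setdiff(feats, params$feature)
  if (length(unknown) > 0L)
    stop("no normalization parameters for feature(s): ",
         paste(head(unknown, 3), collapse = ", "))
  p <- params[match(feats, params$feature), ]
  degenerate <- p$max == p$min
  if (any(degenerate))
    warning(sum(degenerate), " feature(s) constant in the primary cohort; ",
            "normalized to 0")
  out <- table
  for (k in seq_along(feats)) {
    f <- feats[k]
    out[[f]] <- if (degenerate[k]) rep(0, nrow(table)) else
      (table[[f]] - p$min[k]) / (p$max[k] - p$min[k])
  }
  out
}

#' Per-feature Wilcoxon rank-sum screen
#'
#' Two-sided rank-sum test of each feature between the LNM+ and LNM- groups;
#' features with `p <= alpha` (inclusive) are kept. The exact distribution is
#' used when both groups have at most 25 patients and the feature is tie-free;
#' otherwise the normal approximation with midranks and tie correction.
#'
#' @param table Feature tibble.
#' @param labels Binary vector (1 = LNM+), one per row of `table`.
#' @param alpha Retention threshold on the p-value (default 0.1).
#' @return Tibble `feature`, `p_value`, `kept`, ordered as the input columns.
#' @export
wilcoxon_screen <- function(table, labels, alpha = 0.1) {
  labels <- as.integer(labels)
  if (min(table(labels)) < 2) stop("each class needs at least 2 patients")
  feats <- feature_columns(table)
  exact_ok <- max(table(labels)) <= 25
  p <- vapply(feats, function(f) {
    x <- table[[f]][labels == 1L]
    y <- table[[f]][labels == 0L]
    use_exact <- exact_ok && !any(duplicated(c(x, y)))
    suppressWarnings(
      wilcox.test(x, y, exact = use_exact, correct = FALSE)$p.value
    )
  }, numeric(1))
  tibble::tibble(feature = feats, p_value = unname(p), kept = p <= alpha)
}

#' Spearman-correlation redundancy pruning
#'
#' Among all candidate pairs with `|rho| > r_threshold`, the member with the
#' larger screening p-value is dropped. Pairs are processed in descending
#' `|rho|` (ties broken lexicographically on the name pair); a pair with an
#' already-dropped member is skipped, which makes the survivor set
#' deterministic.
#'
#' @param table Feature tibble containing the candidate columns.
#' @param pvalues Tibble `feature`, `p_value` covering every candidate
#'   (as from [wilcoxon_screen()]).
#' @param r_threshold Absolute Spearman correlation above which a pair is
#'   considered redundant (default 0.9).
#' @return Character vector of surviving feature names.
#' @export
spearman_prune <- function(table, pvalues, r_threshold = 0.9) {
  feats <- intersect(feature_columns(table), pvalues$feature)
  missing_p <- setdiff(feature_columns(table), pvalues$feature)
  if (length(missing_p) > 0L)
    stop("p-value missing for feature(s): ", paste(head(missing_p, 3), collapse = ", "))
  if (length(feats) < 2L) return(feats)
  m <- as.matrix(table[, feats])
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[is.na(rho)] <- 0
  pv <- setNames(pvalues$p_value, pvalues$feature)[feats]
  ij <- which(upper.tri(rho) & abs(rho) > r_threshold, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(feats)
  ord <- order(-abs(rho[ij]), feats[ij[, 1L]], feats[ij[, 2L]])
  ij <- ij[ord, , drop = FALSE]
  dropped <- character(0)
  for (r in seq_len(nrow(ij))) {
    a <- feats[ij[r, 1L]]; b <- feats[ij[r, 2L]]
    if (a %in% dropped || b %in% dropped) next
    # drop the larger p-value; break exact ties against the later name
    loser <- if (pv[a] > pv[b]) a else if (pv[b] > pv[a]) b else max(a, b)
    dropped <- c(dropped, loser)
  }
  setdiff(feats, dropped)
}

#' LASSO selection with the one-standard-error rule
#'
#' L1-penalized logistic path with binomial-deviance 10-fold cross-validation
#' on label-stratified, seed-fixed folds. `lambda_1se` is the largest lambda
#' whose CV deviance is within one standard error of the minimum; the
#' selected features are the nonzero coefficients at `lambda_1se`. Features
#' are used as supplied (already min-max normalized), without re-standardization.
#'
#' @param table Feature tibble restricted to the candidate columns.
#' @param labels Binary outcome vector.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed fixing the fold assignment.
#' @return List: `selected`, `lambda_grid`, `cv_mean_deviance`, `cv_se`,
#'   `lambda_min`, `lambda_1se`, `coefficients` (at `lambda_1se`), `seed`.
#' @export
lasso_select <- function(table, labels, n_folds = 10, seed = 1L) {
  feats <- feature_columns(table)
  if (length(feats) == 0L) stop("empty candidate set")
  labels <- as.integer(labels)
  x <- as.matrix(table[, feats])
  if (length(feats) == 1L) x <- cbind(x, `..const` = 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cvfit <- glmnet::cv.glmnet(x, labels, family = "binomial",
                             type.measure = "deviance", foldid = foldid,
                             standardize = FALSE)
  cf <- coef(cvfit, s = "lambda.1se")
  nz <- rownames(cf)[which(as.vector(cf) != 0)]
  nz <- setdiff(nz, c("(Intercept)", "..const"))
  list(selected = nz,
       lambda_grid = cvfit$lambda,
       cv_mean_deviance = cvfit$cvm,
       cv_se = cvfit$cvsd,
       lambda_min = cvfit$lambda.min,
       lambda_1se = cvfit$lambda.1se,
       coefficients = setNames(as.vector(cf), rownames(cf)),
       seed = as.integer(seed))
}

#' Run the three-step feature-selection chain
#'
#' Wilcoxon rank-sum screen (`p <= alpha`), Spearman redundancy pruning
#' (`|rho| > r_threshold` drops the larger-p member), then LASSO logistic
#' regression with lambda chosen by the one-standard-error rule under
#' 10-fold stratified cross-validation. All three stages see the primary
#' cohort only; the stage sets are nested.
#'
#' @param table Normalized feature tibble (primary cohort).
#' @param labels Binary outcome vector.
#' @param alpha Wilcoxon retention threshold (default 0.1).
#' @param r_threshold Spearman pruning threshold (default 0.9).
#' @param n_folds CV folds for the LASSO (default 10).
#' @param seed Integer seed (fold assignment).
#' @return A `feature_selection` object with `stage1` (tibble of all features
#'   and p-values, `kept` flag), `stage1_kept`, `stage2_kept`, `stage3_kept`,
#'   and the LASSO path metadata of [lasso_select()].
#' @export
select_features <- function(table, labels, alpha = 0.1, r_threshold = 0.9,
                            n_folds = 10, seed = 1L) {
  stage1 <- wilcoxon_screen(table, labels, alpha)
  s1 <- stage1$feature[stage1$kept]
  if (length(s1) == 0L) stop("empty candidate set: no feature passed the Wilcoxon screen")
  s2 <- spearman_prune(table[, s1, drop = FALSE], stage1, r_threshold)
  lres <- lasso_select(table[, s2, drop = FALSE], labels, n_folds, seed)
  structure(list(stage1 = stage1, stage1_kept = s1, stage2_kept = s2,
                 stage3_kept = lres$selected,
                 lambda_grid = lres$lambda_grid,
                 cv_mean_deviance = lres$cv_mean_deviance,
                 cv_se = lres$cv_se,
                 lambda_min = lres$lambda_min, lambda_1se = lres$lambda_1se,
                 seed = lres$seed),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> ", nrow(x$stage1), " features -> ",
      length(x$stage1_kept), " (Wilcoxon) -> ", length(x$stage2_kept),
      " (Spearman) -> ", length(x$stage3_kept), " (LASSO 1-SE)\n", sep = "")
  cat("  lambda_min = ", signif(x$lambda_min, 4),
      ", lambda_1se = ", signif(x$lambda_1se, 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn select_features Per-feature tibble with the furthest stage
#'   each feature survived (`none`, `wilcoxon`, `spearman`, `lasso`).
#' @param x A `feature_selection` object.
#' @param ... Unused.
#' @export
tidy.feature_selection <- function(x, ...) {
  x$stage1 |>
    dplyr::mutate(stage = dplyr::case_when(
      .data$feature %in% x$stage3_kept ~ "lasso",
      .data$feature %in% x$stage2_kept ~ "spearman",
      .data$kept ~ "wilcoxon",
      TRUE ~ "none"
    ))
}

#' @describeIn select_features One-row summary of the selection chain.
#' @export
glance.feature_selection <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$stage1),
                 n_wilcoxon = length(x$stage1_kept),
                 n_spearman = length(x$stage2_kept),
                 n_selected = length(x$stage3_kept),
                 lambda_min = x$lambda_min, lambda_1se = x$lambda_1se,
                 seed = x$seed)
}

#' @describeIn select_features Cross-validated deviance against lambda with
#'   the min and 1-SE choices marked.
#' @param object A `feature_selection` object.
#' @export
autoplot.feature_selection <- function(object, ...) {
  df <- tibble::tibble(lambda = object$lambda_grid,
                       cvm = object$cv_mean_deviance,
                       cvsd = object$cv_se)
  ggplot2::ggplot(df, ggplot2::aes(log(.data$lambda), .data$cvm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cvm - .data$cvsd,
                                      ymax = .data$cvm + .data$cvsd),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(c(object$lambda_min, object$lambda_1se)),
                        linetype = c("dashed", "dotted")) +
    ggplot2::labs(x = "log(lambda)", y = "CV binomial deviance",
                  title = "LASSO cross-validation path")
}
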