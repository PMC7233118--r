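#' Fit the radiomic-signature logistic model
#'
#' Maximum-likelihood logistic regression of the node label on the selected
#' (normalized) features, fitted on the primary cohort. The radiomic
#' signature of a patient is the linear predictor
#' `sum(C_i * X_i) + b`; the predicted LNM+ probability is its logistic
#' transform. With an empty feature set the model degenerates to
#' intercept-only (a constant signature), which is the honest outcome when
#' the LASSO selects nothing. Under (quasi-)separation the fit errors by
#' default and can be rescued with a small ridge penalty.
#'
#' @param table Feature tibble containing `features` columns.
#' @param labels Binary outcome (1 = LNM+).
#' @param features Feature names to include; defaults to all feature columns.
#' @param ridge If `TRUE`, refit with a tiny L2 penalty (1e-6) on separation
#'   instead of erroring.
#' @param fitted_on Cohort tag stored with the model.
#' @return A `signature_model`: `features`, `coefficients`, `intercept`,
#'   underlying `fit`, `fitted_on`.
#' @export
fit_signature_model <- function(table, labels, features = feature_columns(table),
                                ridge = FALSE, fitted_on = "primary") {
  labels <- as.integer(labels)
  if (length(features) == 0L) {
    b <- qlogis(mean(labels))
    return(new_signature_model(character(0), numeric(0), b, NULL, fitted_on))
  }
  df <- as.data.frame(table[, features, drop = FALSE])
  safe <- paste0("x", seq_along(features))
  names(df) <- safe
  df$.y <- labels
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                              control = list(epsilon = 1e-8, maxit = 100)))
  cf_raw <- coef(fit)
  separated <- !fit$converged || any(abs(cf_raw[!is.na(cf_raw)]) > 15)
  if (any(is.na(cf_raw)))
    warning("aliased (collinear) features in the signature fit; ",
            "their coefficients are dropped as NA")
  if (separated) {
    if (!ridge)
      stop("perfect or quasi-perfect separation in the logistic fit; ",
           "refit with ridge = TRUE for a small (1e-6) L2 penalty")
    x <- as.matrix(df[, safe, drop = FALSE])
    if (ncol(x) == 1L) x <- cbind(x, `..const` = 0)
    rfit <- glmnet::glmnet(x, labels, family = "binomial", alpha = 0,
                           lambda = 1e-6, standardize = FALSE)
    cf <- coef(rfit)
    co <- setNames(as.vector(cf)[-1L][seq_along(features)], features)
    return(new_signature_model(features, co, as.vector(cf)[1L], NULL, fitted_on))
  }
  cf <- coef(fit)
  co <- setNames(unname(cf[safe]), features)
  co[is.na(co)] <- 0
  new_signature_model(features, co, unname(cf["(Intercept)"]), fit, fitted_on)
}

new_signature_model <- function(features, coefficients, intercept, fit,
                                fitted_on) {
  structure(list(features = features, coefficients = coefficients,
                 intercept = intercept, fit = fit, fitted_on = fitted_on),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> ", length(x$features), " features, intercept ",
      signif(x$intercept, 4), ", fitted on ", x$fitted_on, " cohort\n", sep = "")
  invisible(x)
}

#' Radiomic signature: the model's linear predictor
#'
#' `sum(C_i * X_i) + b` for each patient.
#'
#' @param model A `signature_model`.
#' @param table Feature tibble containing every model feature.
#' @return Numeric vector, one signature per row.
#' @export
compute_signature <- function(model, table) {
  missing_f <- setdiff(model$features, names(table))
  if (length(missing_f) > 0L)
    stop("missing feature(s): ", paste(head(missing_f, 3), collapse = ", "))
  if (length(model$features) == 0L)
    return(rep(model$intercept, nrow(table)))
  x <- as.matrix(table[, model$features, drop = FALSE])
  as.vector(x %*% model$coefficients) + model$intercept
}

#' Predicted LNM+ probability
#'
#' The logistic transform `1 / (1 + exp(-signature))` of
#' [compute_signature()].
#'
#' @inheritParams compute_signature
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(model, table) {
  plogis(compute_signature(model, table))
}

#' @describeIn fit_signature_model Coefficient table (term, estimate, OR,
#'   Wald CI and p-value).
#' @param x A `signature_model`.
#' @param ... Unused.
#' @export
tidy.signature_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("(Intercept)", x$features),
                          estimate = c(x$intercept, unname(x$coefficients)),
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  rn <- rownames(s)
  terms <- rn
  is_feat <- rn != "(Intercept)"
  terms[is_feat] <- x$features[as.integer(sub("^x", "", rn[is_feat]))]
  tibble::tibble(term = terms, estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4],
                 odds_ratio = exp(s[, 1]),
                 ci_low = exp(s[, 1] - qnorm(0.975) * s[, 2]),
                 ci_high = exp(s[, 1] + qnorm(0.975) * s[, 2]))
}

#' @describeIn fit_signature_model One-row model summary.
#' @export
glance.signature_model <- function(x, ...) {
  if (is.null(x$fit))
    return(tibble::tibble(n_features = length(x$features), nobs = NA_integer_,
                          deviance = NA_real_, AIC = NA_real_))
  tibble::tibble(n_features = length(x$features), nobs = stats::nobs(x$fit),
                 null.deviance = x$fit$null.deviance,
                 deviance = x$fit$deviance, AIC = x$fit$aic)
}

#' Univariate logistic screen of clinical variables and the signature
#'
#' One single-predictor logistic fit per candidate on the primary cohort,
#' reporting the odds ratio with Wald 95% CI and p-value. Ordinal stages
#' (ymrT, ymrN) enter as numeric scores, so their OR is per stage unit; sex
#' is coded female = 0 / male = 1. Constant variables are flagged and
#' skipped.
#'
#' @param data Tibble holding the candidate columns.
#' @param labels Binary outcome.
#' @param variables Candidate column names (default: sex, age, cea,
#'   radiation, ymrT, ymrN, signature — intersected with `data`).
#' @return Tibble `variable`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `note`.
#' @export
univariate_screen <- function(data, labels,
                              variables = intersect(
                                c("sex", "age", "cea", "radiation",
                                  "ymrT", "ymrN", "signature"),
                                names(data))) {
  labels <- as.integer(labels)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.character(x) || is.factor(x))
      x <- as.numeric(factor(x, levels = sort(unique(as.character(x))))) - 1
    x <- as.numeric(x)
    if (length(unique(x)) < 2L)
      return(tibble::tibble(variable = v, odds_ratio = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_, note = "constant; skipped"))
    fit <- suppressWarnings(glm(labels ~ x, family = binomial()))
    s <- summary(fit)$coefficients
    est <- s["x", 1]; se <- s["x", 2]
    tibble::tibble(variable = v, odds_ratio = exp(est),
                   ci_low = exp(est - qnorm(0.975) * se),
                   ci_high = exp(est + qnorm(0.975) * se),
                   p_value = s["x", 4], note = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Fit the combined (signature + ymrT + ymrN) or clinical-only model
#'
#' Multivariate logistic regression on the primary cohort. The combined
#' model enters the radiomic signature as its raw linear predictor together
#' with the numeric ymrT and ymrN stages; the clinical model omits the
#' signature. Returned as a `signature_model` over the corresponding
#' columns, so [compute_signature()] / [predict_probability()] and the
#' `tidy()`/`glance()` methods apply unchanged.
#'
#' @param data Tibble with columns `signature`, `ymrT`, `ymrN`.
#' @param labels Binary outcome.
#' @param terms Model terms (default combined model).
#' @param ... Passed to [fit_signature_model()].
#' @return A `signature_model`.
#' @export
fit_combined_model <- function(data, labels,
                               terms = c("signature", "ymrT", "ymrN"), ...) {
  miss <- setdiff(terms, names(data))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- dplyr::mutate(data[, terms, drop = FALSE],
                      dplyr::across(dplyr::everything(), as.numeric))
  fit_signature_model(df, labels, features = terms, ...)
}

#' @rdname fit_combined_model
#' @export
fit_clinical_model <- function(data, labels, terms = c("ymrT", "ymrN"), ...) {
  fit_combined_model(data, labels, terms = terms, ...)
}
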