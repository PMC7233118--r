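#' Convert a fitted logistic model to a nomogram
#'
#' Standard points construction: each variable's contribution
#' `|beta_v| * (x - x_ref,v)` is rescaled so that the widest-range variable
#' spans exactly 0–100 points; the reference `x_ref,v` is the variable value
#' of minimal risk within its range (the minimum for positive coefficients,
#' the maximum for negative ones), so total points are an increasing affine
#' function of the linear predictor and the total-points-to-probability
#' mapping is exactly the model's logistic prediction. Zero-range variables
#' are excluded with a warning. The construction is invariant to jointly
#' doubling all coefficients and halving all variable ranges.
#'
#' @param model A `signature_model` (typically the combined model).
#' @param ranges Named list of `c(lo, hi)` per model variable; defaults to
#'   the observed range in `data`.
#' @param data Optional tibble from which to take variable ranges.
#' @return A `nomogram_spec`: `variables` (tibble with `variable`, `beta`,
#'   `ref`, `lo`, `hi`, `points_per_unit`), `slope`/`const` of the
#'   total-points-to-linear-predictor map, and `prob_map` (a 101-point grid).
#' @export
export_nomogram <- function(model, ranges = NULL, data = NULL) {
  stopifnot(inherits(model, "signature_model"))
  if (is.null(ranges)) {
    if (is.null(data)) stop("supply `ranges` or `data`")
    ranges <- lapply(model$features, function(v) range(as.numeric(data[[v]])))
    names(ranges) <- model$features
  }
  miss <- setdiff(model$features, names(ranges))
  if (length(miss) > 0L) stop("range missing for: ", paste(miss, collapse = ", "))
  vars <- tibble::tibble(
    variable = model$features,
    beta = unname(model$coefficients[model$features]),
    lo = vapply(model$features, function(v) ranges[[v]][1L], numeric(1)),
    hi = vapply(model$features, function(v) ranges[[v]][2L], numeric(1))
  )
  zero_rng <- vars$hi == vars$lo | vars$beta == 0
  if (any(zero_rng)) {
    warning("excluded from the nomogram (zero range or zero coefficient): ",
            paste(vars$variable[zero_rng], collapse = ", "))
    vars <- vars[!zero_rng, , drop = FALSE]
  }
  if (nrow(vars) == 0L) stop("no variable with nonzero range and coefficient")
  span <- abs(vars$beta) * (vars$hi - vars$lo)
  m <- max(span)
  vars$ref <- ifelse(vars$beta >= 0, vars$lo, vars$hi)
  vars$points_per_unit <- 100 * abs(vars$beta) / m
  # lp = intercept + sum(beta * ref) + (m / 100) * total_points
  const <- model$intercept + sum(vars$beta * vars$ref)
  slope <- m / 100
  total_max <- sum(vars$points_per_unit * (vars$hi - vars$lo))
  grid <- seq(0, total_max, length.out = 101L)
  prob_map <- tibble::tibble(total_points = grid,
                             probability = plogis(const + slope * grid))
  structure(list(variables = vars, const = const, slope = slope,
                 total_points_max = total_max, prob_map = prob_map,
                 model = model),
            class = "nomogram_spec")
}

#' Points assigned by a nomogram
#'
#' @param spec A `nomogram_spec`.
#' @param data Tibble with the nomogram variables.
#' @return Tibble of per-variable points plus `total_points` and
#'   `probability` (which equals the model's predicted probability).
#' @export
nomogram_points <- function(spec, data) {
  vs <- spec$variables
  pts <- vapply(seq_len(nrow(vs)), function(k) {
    x <- as.numeric(data[[vs$variable[k]]])
    vs$points_per_unit[k] * abs(x - vs$ref[k])
  }, numeric(nrow(data)))
  pts <- matrix(pts, nrow = nrow(data))
  colnames(pts) <- paste0("points_", vs$variable)
  total <- rowSums(pts)
  dplyr::bind_cols(tibble::as_tibble(pts),
                   tibble::tibble(total_points = total,
                                  probability = plogis(spec$const + spec$slope * total)))
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat("<nomogram_spec> ", nrow(x$variables), " variables, total points 0-",
      round(x$total_points_max, 1), "\n", sep = "")
  invisible(x)
}

#' @describeIn export_nomogram Draw the nomogram: one points axis per
#'   variable plus the total-points-to-probability axis.
#' @param object A `nomogram_spec`.
#' @param ... Unused.
#' @export
autoplot.nomogram_spec <- function(object, ...) {
  vs <- object$variables
  axes <- purrr::pmap_dfr(vs, function(variable, beta, lo, hi, ref,
                                       points_per_unit) {
    x <- seq(lo, hi, length.out = 25L)
    tibble::tibble(axis = variable, value = x,
                   points = points_per_unit * abs(x - ref))
  })
  prob_axis <- object$prob_map |>
    dplyr::mutate(axis = "probability")
  n_axes <- nrow(vs)
  axes$y <- n_axes + 1 - match(axes$axis, vs$variable)
  ggplot2::ggplot(axes, ggplot2::aes(.data$points, .data$y, group = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_line(data = dplyr::mutate(prob_axis,
                                            points = .data$total_points /
                                              max(.data$total_points) * 100 *
                                              n_axes / n_axes,
                                            y = 0),
                       ggplot2::aes(.data$points, .data$y)) +
    ggplot2::scale_y_continuous(breaks = c(n_axes:1, 0),
                                labels = c(vs$variable, "total points / probability")) +
    ggplot2::labs(x = "points", y = NULL, title = "Nomogram") +
    ggplot2::theme_minimal()
}
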