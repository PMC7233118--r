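#' Feature-extraction configuration
#'
#' Controls discretization, the Laplacian-of-Gaussian filter bank and the
#' texture-matrix conventions. The default registry computes, per sequence,
#' 4 filters (original image plus LoG at sigmas 1/2/3 px, named
#' `orig`/`LoG1`/`LoG2`/`LoG3`) x (24 first-order + 26 GLCM + 16 GLSZM) =
#' 264 features, on the single supplied 2D slice.
#'
#' @param n_gray_levels Gray levels for discretization (>= 2, default 32).
#' @param log_sigmas Strictly increasing positive LoG scales in pixels.
#' @param glcm_offsets List of `c(dx, dy)` unit offsets (default: four
#'   distance-1 directions, symmetrized and averaged).
#' @return An `extraction_config` object.
#' @export
extraction_config <- function(n_gray_levels = 32,
                              log_sigmas = c(1, 2, 3),
                              glcm_offsets = list(c(1L, 0L), c(0L, 1L),
                                                  c(1L, 1L), c(1L, -1L))) {
  stopifnot(n_gray_levels >= 2, all(log_sigmas > 0),
            !is.unsorted(log_sigmas, strictly = TRUE))
  structure(list(n_gray_levels = n_gray_levels, log_sigmas = log_sigmas,
                 glcm_offsets = glcm_offsets),
            class = "extraction_config")
}

filter_names <- function(config) {
  c("orig", paste0("LoG", seq_along(config$log_sigmas)))
}

# All features for one filtered image restricted to `mask`.
extract_one_image <- function(img, mask, config) {
  v <- img[mask]
  fos <- first_order_features(v, config$n_gray_levels)
  lev_img <- matrix(0L, nrow(img), ncol(img))
  lev_img[mask] <- discretize(v, config$n_gray_levels)
  glcm <- glcm_features(glcm_matrix(lev_img, config$n_gray_levels,
                                    config$glcm_offsets))
  szm <- glszm_matrix(lev_img, config$n_gray_levels)
  glszm <- glszm_features(szm)
  c(setNames(fos, paste0("FOS_", names(fos))),
    setNames(glcm, paste0("GLCM_", names(glcm))),
    setNames(glszm, paste0("GLSZM_", names(glszm))))
}

#' Extract the radiomic feature vector for one patient
#'
#' For each of the four sequences, features are computed on the original
#' image and on each LoG-filtered image; filters are applied to the full
#' image before masking and discretization. Feature names follow
#' `"<seq>:<filter>-<class>_<stat>"`, e.g. `"T2w:LoG2-GLSZM_LZLGE"`, and the
#' ordering is deterministic for a fixed configuration. All features are
#' computed relative to the mask, so jointly translating image and mask
#' leaves the vector unchanged.
#'
#' @param sample An `mri_sample` (see [generate_cohort()]): images and masks
#'   for all four sequences.
#' @param config An [extraction_config()].
#' @return Named numeric vector, `4 * 264 = 1056` values with defaults.
#' @export
extract_features <- function(sample, config = extraction_config()) {
  missing_seq <- setdiff(RADNODE_SEQUENCES, names(sample$images))
  if (length(missing_seq) > 0L)
    stop("missing sequence(s): ", paste(missing_seq, collapse = ", "))
  out <- lapply(RADNODE_SEQUENCES, function(sq) {
    img <- sample$images[[sq]]
    mask <- sample$masks[[sq]]
    if (is.null(mask) || sum(mask) < 16L)
      stop("insufficient ROI for sequence ", sq)
    per_filter <- lapply(seq_along(filter_names(config)), function(k) {
      fimg <- if (k == 1L) img else log_filter(img, config$log_sigmas[k - 1L])
      f <- extract_one_image(fimg, mask, config)
      setNames(f, paste0(sq, ":", filter_names(config)[k], "-", names(f)))
    })
    unlist(per_filter)
  })
  unlist(out)
}

#' Extract the patients-by-features table for a cohort
#'
#' @param cohort An `mri_cohort`.
#' @param config An [extraction_config()].
#' @return A tibble: `patient_id` first, then one column per feature.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 20, prevalence = 0.25,
#'                                     seed = 3))
#' ft <- extract_feature_table(co)
#' dim(ft)
extract_feature_table <- function(cohort, config = extraction_config()) {
  stopifnot(inherits(cohort, "mri_cohort"))
  rows <- lapply(cohort$samples, extract_features, config = config)
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(
    tibble::tibble(patient_id = vapply(cohort$samples, `[[`, "", "patient_id")),
    tibble::as_tibble(mat)
  )
}

feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "split", "label"))
}

#' Inter-rater agreement of extracted features (ICC)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (ICC(2,1)) per feature, between the same feature table
#' extracted from two raters' delineations. Features with zero variance
#' across patients in both raters are reported as `NA`.
#'
#' @param table_rater1,table_rater2 Feature tibbles with identical
#'   `patient_id` and feature columns.
#' @return A tibble with `feature` and `icc`.
#' @export
feature_agreement_icc <- function(table_rater1, table_rater2) {
  stopifnot(identical(table_rater1$patient_id, table_rater2$patient_id),
            identical(feature_columns(table_rater1),
                      feature_columns(table_rater2)))
  feats <- feature_columns(table_rater1)
  icc <- vapply(feats, function(f) {
    icc_a1(cbind(table_rater1[[f]], table_rater2[[f]]))
  }, numeric(1))
  tibble::tibble(feature = feats, icc = unname(icc))
}

# ICC(A,1): two-way random effects, absolute agreement, single rater.
icc_a1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_total <- sum((x - g)^2)
  ss_rows <- k * sum((row_m - g)^2)
  ss_cols <- n * sum((col_m - g)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  (msr - mse) / denom
}
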