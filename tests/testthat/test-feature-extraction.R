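test_that("discretization follows the equal-width, right-closed convention", {
  expect_identical(discretize(c(0, 0.5, 1), 2), c(1L, 1L, 2L))
  expect_identical(discretize(rep(3.7, 10), 8), rep(1L, 10))
  expect_error(discretize(numeric(0), 4), "empty ROI")

  set.seed(1)
  v <- runif(10000)
  lev <- discretize(v, 32)
  counts <- tabulate(lev, 32)
  chi2 <- sum((counts - 10000 / 32)^2 / (10000 / 32))
  expect_gt(pchisq(chi2, 31, lower.tail = FALSE), 1e-3)
})

test_that("LoG filter: zero on constants, extremum at an impulse, scale optimum", {
  img <- matrix(5, 40, 40)
  expect_lt(max(abs(log_filter(img, 2))), 1e-8)

  img2 <- matrix(0, 41, 41)
  img2[21, 21] <- 1
  resp <- log_filter(img2, 1.5)
  expect_equal(which.max(abs(resp)), which.max(abs(img2)))

  # Gaussian blob of scale s: |scale-normalized response| peaks near sigma = s
  s <- 3
  g <- outer(-32:32, -32:32, function(x, y) exp(-(x^2 + y^2) / (2 * s^2)))
  sigmas <- seq(1, 6, by = 0.5)
  center_resp <- vapply(sigmas,
                        function(sg) abs(log_filter(g, sg)[33, 33]),
                        numeric(1))
  expect_true(abs(sigmas[which.max(center_resp)] - s) <= 0.5)
})

test_that("first-order statistics match their textbook definitions", {
  f <- first_order_features(c(1, 2, 3))
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["SD"]), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(f["Skewness"]), 0)

  fc <- first_order_features(rep(4, 50))
  expect_equal(unname(fc["Variance"]), 0)
  expect_equal(unname(fc["Entropy"]), 0)
  expect_equal(unname(fc["Skewness"]), 0)
  expect_equal(unname(fc["Kurtosis"]), 0)

  set.seed(2)
  z <- rnorm(1000)
  fz <- first_order_features(z)
  expect_lt(abs(fz["Skewness"]), 0.25)
  expect_lt(abs(fz["Kurtosis"]), 0.5)
  expect_equal(unname(fz["Energy"]), sum(z^2))
})

test_that("GLCM trivial cases follow direct enumeration", {
  lv <- matrix(c(1L, 2L, 1L, 2L), 2, 2)  # rows: (1,1) / (2,2)
  g <- glcm_matrix(lv, 2, offsets = list(c(1L, 0L)))
  expect_equal(g$matrix, matrix(c(0.5, 0, 0, 0.5), 2, 2))

  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) + 1L)
  storage.mode(cb) <- "integer"
  gcb <- glcm_matrix(cb, 2, offsets = list(c(1L, 0L)))
  expect_equal(gcb$matrix[1, 1], 0)
  expect_equal(gcb$matrix[2, 2], 0)
  expect_equal(gcb$matrix[1, 2] + gcb$matrix[2, 1], 1)

  expect_error(glcm_matrix(matrix(c(1L, 0L, 0L, 0L), 2, 2), 2,
                           offsets = list(c(1L, 0L))),
               "degenerate ROI")
})

test_that("GLCM builder equals the brute-force pair-enumeration oracle", {
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  set.seed(3)
  for (rep in 1:100) {
    lv <- matrix(sample(1:6, 256, replace = TRUE), 16, 16)
    lv[matrix(runif(256) < 0.2, 16, 16)] <- 0L  # irregular mask
    storage.mode(lv) <- "integer"
    g <- glcm_matrix(lv, 6, offsets = offsets)
    expect_equal(g$matrix, oracle_glcm(lv, 6, offsets), tolerance = 1e-14)
    expect_equal(sum(g$matrix), 1, tolerance = 1e-9)
    expect_equal(g$matrix, t(g$matrix), tolerance = 1e-14)
  }
})

test_that("co-occurrence features match a direct-summation oracle to 1e-10", {
  g0 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  f0 <- glcm_features(g0)
  expect_equal(unname(f0["contrast"]), 0)
  expect_equal(unname(f0["cshade"]), 0)

  g1 <- matrix(0, 3, 3); g1[2, 2] <- 1
  f1 <- glcm_features(g1)
  expect_equal(unname(f1["entropy"]), 0)
  expect_equal(unname(f1["energy"]), 1)
  expect_equal(unname(f1["maxprob"]), 1)

  set.seed(4)
  for (rep in 1:20) {
    m <- matrix(runif(64), 8, 8)
    m <- m + t(m)            # symmetric, like a real GLCM
    m <- m / sum(m)
    got <- glcm_features(m)
    want <- oracle_glcm_features(m)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("GLSZM zones match the flood-fill oracle and conserve pixels", {
  uni <- matrix(1L, 4, 4)
  z <- glszm_matrix(uni, 1)
  expect_equal(z$matrix[1, 16], 1)
  expect_equal(sum(z$matrix), 1)

  # 8-connectivity joins diagonal same-level cells: a two-level checkerboard
  # collapses into one zone per level
  cb <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1L)
  storage.mode(cb) <- "integer"
  zcb <- glszm_matrix(cb, 2)
  expect_equal(zcb$matrix[1, 8], 1)
  expect_equal(zcb$matrix[2, 8], 1)
  expect_equal(sum(zcb$matrix), 2)

  expect_error(glszm_matrix(matrix(0L, 3, 3), 2), "empty ROI")

  set.seed(5)
  for (rep in 1:100) {
    lv <- matrix(sample(1:4, 256, replace = TRUE), 16, 16)
    lv[matrix(runif(256) < 0.25, 16, 16)] <- 0L
    if (!any(lv > 0)) next
    storage.mode(lv) <- "integer"
    z <- glszm_matrix(lv, 4)
    want <- oracle_glszm(lv, 4)
    expect_equal(z$matrix, want)
    svec <- matrix(seq_len(ncol(z$matrix)), nrow(z$matrix), ncol(z$matrix),
                   byrow = TRUE)
    expect_equal(sum(svec * z$matrix), sum(lv > 0))
  }
})

test_that("size-zone features match the direct-summation oracle", {
  single <- matrix(0, 3, 20); single[2, 16] <- 1
  f <- glszm_features(structure(list(kind = "GLSZM", matrix = single,
                                     normalized = FALSE),
                                class = "texture_matrix"),
                      n_pixels = 16)
  expect_equal(unname(f["ZP"]), 1 / 16)
  expect_equal(unname(f["SZE"]), 1 / 16^2)
  expect_equal(unname(f["LZE"]), 16^2)

  ones <- matrix(0, 2, 3); ones[1, 1] <- 5   # five zones, size 1, level 1
  f1 <- glszm_features(structure(list(kind = "GLSZM", matrix = ones,
                                      normalized = FALSE),
                                 class = "texture_matrix"),
                       n_pixels = 5)
  expect_equal(unname(f1["LZLGE"]), 1)

  set.seed(6)
  for (rep in 1:20) {
    z <- matrix(rpois(5 * 12, 0.8), 5, 12)
    if (sum(z) == 0) z[1, 1] <- 1
    got <- glszm_features(structure(list(kind = "GLSZM", matrix = z,
                                         normalized = FALSE),
                                    class = "texture_matrix"),
                          n_pixels = 100)
    want <- oracle_glszm_features(z, 100)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("per-patient extraction yields 264 features per sequence, deterministically", {
  set.seed(7)
  img <- matrix(rnorm(64 * 64), 64, 64)
  mask <- generate_tumor_mask(64, seed = 3)
  images <- list(T1w = img, T2w = img + 1, CET1w = img * 2, ADC = img - 5)
  s <- make_sample(images, mask)
  v1 <- extract_features(s)
  v2 <- extract_features(s)
  expect_identical(v1, v2)
  expect_length(v1, 4 * 264)
  expect_false(any(duplicated(names(v1))))
  expect_equal(sum(startsWith(names(v1), "T2w:")), 264)
  expect_true("T2w:LoG2-GLSZM_LZLGE" %in% names(v1))
  expect_true("ADC:LoG3-GLCM_cshade" %in% names(v1))
  expect_true("CET1w:LoG3-FOS_Mean" %in% names(v1))

  s_missing <- s
  s_missing$images$ADC <- NULL
  expect_error(extract_features(s_missing), "ADC")
})

test_that("features are invariant to joint translation and to background edits", {
  set.seed(8)
  img <- matrix(rnorm(64 * 64), 64, 64)
  mask <- matrix(FALSE, 64, 64)
  mask[25:38, 24:39] <- TRUE      # well inside, so reflection padding is inert
  s <- make_sample(list(T1w = img, T2w = img, CET1w = img, ADC = img), mask)
  v <- extract_features(s)

  shift <- function(m, di, dj) {
    out <- m * 0
    out[(1 + di):64, (1 + dj):64] <- m[1:(64 - di), 1:(64 - dj)]
    out
  }
  img_s <- shift(img, 4, 5); mask_s <- shift(mask, 4, 5) > 0
  s2 <- make_sample(list(T1w = img_s, T2w = img_s, CET1w = img_s, ADC = img_s),
                    mask_s)
  v2 <- extract_features(s2)
  expect_equal(v, v2, tolerance = 1e-8)

  img_bg <- img
  img_bg[!mask] <- 0   # relabel everything outside the mask
  s3 <- make_sample(list(T1w = img_bg, T2w = img_bg, CET1w = img_bg,
                         ADC = img_bg), mask)
  v3 <- extract_features(s3)
  # unfiltered features never see outside the mask
  orig <- grepl(":orig-", names(v))
  expect_equal(v[orig], v3[orig], tolerance = 1e-10)
})

test_that("monotone intensity rescaling leaves discretized texture unchanged", {
  set.seed(9)
  img <- matrix(rnorm(48 * 48), 48, 48)
  mask <- generate_tumor_mask(48, seed = 2)
  v <- img[mask]
  expect_identical(discretize(v, 32), discretize(3.2 * v + 17, 32))
  lv <- matrix(0L, 48, 48); lv[mask] <- discretize(v, 32)
  lv2 <- matrix(0L, 48, 48); lv2[mask] <- discretize(3.2 * v + 17, 32)
  expect_equal(glcm_features(glcm_matrix(lv, 32)),
               glcm_features(glcm_matrix(lv2, 32)))
})

test_that("feature-table extraction returns the patients-by-features tibble", {
  co <- generate_cohort(cohort_config(n_patients = 20, prevalence = 0.25,
                                      image_size = 32, seed = 10))
  ft <- extract_feature_table(co)
  expect_s3_class(ft, "tbl_df")
  expect_equal(dim(ft), c(20, 1 + 4 * 264))
  expect_identical(ft$patient_id, co$clinical$patient_id)
})

test_that("inter-rater ICC behaves as the variance components dictate", {
  set.seed(11)
  n <- 400
  truth <- rnorm(n, sd = 3)
  t1 <- tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                       fA = truth + rnorm(n, sd = 1),
                       fB = rnorm(n))
  t2 <- tibble::tibble(patient_id = t1$patient_id,
                       fA = truth + rnorm(n, sd = 1),
                       fB = rnorm(n))

  same <- feature_agreement_icc(t1, t1)
  expect_equal(same$icc, c(1, 1), tolerance = 1e-12)

  # noise variance = 1/9 of signal variance in each rater -> ICC ~ 0.9
  sig <- rnorm(n, sd = 3)
  r1 <- tibble::tibble(patient_id = t1$patient_id, f = sig + rnorm(n, sd = 1))
  r2 <- tibble::tibble(patient_id = t1$patient_id, f = sig + rnorm(n, sd = 1))
  icc9 <- feature_agreement_icc(r1, r2)$icc
  expect_equal(icc9, 0.9, tolerance = 0.05)

  # independent raters -> ICC ~ 0
  both <- feature_agreement_icc(t1, t2)
  expect_lt(abs(both$icc[2]), 0.15)

  const1 <- tibble::tibble(patient_id = t1$patient_id[1:10], f = rep(1, 10))
  expect_true(is.na(feature_agreement_icc(const1, const1)$icc))
})
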