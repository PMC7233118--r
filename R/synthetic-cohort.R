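#' Configuration for a synthetic rectal-MRI cohort
#'
#' Defines the statistical conditions under which a synthetic cohort is drawn:
#' size, lymph-node-metastasis (LNM) prevalence, per-sequence class effect
#' sizes, the radiologist's nodal restaging operating point, and the
#' primary:validation split ratio. Defaults mirror a post-neoadjuvant locally
#' advanced rectal cancer cohort: 391 patients with 87 LNM+ (prevalence
#' 87/391), a 2:1 primary:validation split, and a radiologist ymrN read with
#' sensitivity 0.563 and specificity 0.707 against pathological node status.
#'
#' Class signal enters the images through two per-sequence knobs:
#' `texture_effect` (increase, in pixels, of the Gaussian correlation length
#' of the intratumoral random field for LNM+ patients — picked up by
#' co-occurrence and size-zone features) and `intensity_effect` (mean shift,
#' in units of the field's standard deviation, inside the tumor for LNM+
#' patients — picked up by first-order features). The T1w channel carries no
#' class signal: both effects are forced to zero for it, emulating an
#' uninformative sequence.
#'
#' @param n_patients Number of patients (>= 20).
#' @param prevalence Fraction of LNM+ patients, strictly in (0, 1).
#' @param image_size Image side length in pixels (>= 32).
#' @param texture_effect Either a single number applied to T2w/CET1w/ADC, or a
#'   named vector over sequences. T1w is always forced to 0.
#' @param intensity_effect Same conventions as `texture_effect`.
#' @param radiologist_sens P(ymrN >= 1 | LNM+) of the simulated radiologist.
#' @param radiologist_spec P(ymrN == 0 | LNM-) of the simulated radiologist.
#' @param split_ratio Primary:validation ratio (2 means 2:1).
#' @param seed Integer seed; fully determines the cohort.
#' @return A `cohort_config` object (a named list).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 60, seed = 1)
#' cfg$prevalence
cohort_config <- function(n_patients = 391,
                          prevalence = 87 / 391,
                          image_size = 64,
                          texture_effect = 0.05,
                          intensity_effect = 0.08,
                          radiologist_sens = 0.563,
                          radiologist_spec = 0.707,
                          split_ratio = 2,
                          seed = 1L) {
  stopifnot(is.numeric(n_patients), n_patients == round(n_patients),
            prevalence > 0, prevalence < 1,
            image_size >= 32,
            radiologist_sens > 0, radiologist_sens < 1,
            radiologist_spec > 0, radiologist_spec < 1,
            split_ratio > 0)
  if (n_patients < 20)
    stop("n_patients < 20: the selection stages are undefined on cohorts this small")
  n_pos <- round(n_patients * prevalence)
  if (n_pos < 5)
    stop("prevalence yields fewer than 5 LNM+ patients; increase n_patients or prevalence")
  structure(list(
    n_patients = as.integer(n_patients),
    prevalence = prevalence,
    image_size = as.integer(image_size),
    sequences = RADNODE_SEQUENCES,
    texture_effect = expand_effect(texture_effect, "texture_effect"),
    intensity_effect = expand_effect(intensity_effect, "intensity_effect"),
    radiologist_sens = radiologist_sens,
    radiologist_spec = radiologist_spec,
    split_ratio = split_ratio,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

expand_effect <- function(x, what) {
  if (length(x) == 1L && is.null(names(x))) {
    eff <- setNames(rep(x, 4L), RADNODE_SEQUENCES)
  } else {
    if (is.null(names(x)) || !all(names(x) %in% RADNODE_SEQUENCES))
      stop(what, " must be a scalar or a vector named after the sequences")
    eff <- setNames(numeric(4L), RADNODE_SEQUENCES)
    eff[names(x)] <- x
  }
  eff[["T1w"]] <- 0  # the uninformative channel, by construction
  eff
}

#' Draw a random elliptical tumor mask
#'
#' A filled ellipse with randomized center, semi-axes in
#' `[image_size/8, image_size/3]` and random orientation. Being a convex
#' region intersected with the image rectangle, the mask is always a single
#' connected foreground component.
#'
#' @param image_size Side length in pixels (>= 32).
#' @param seed Optional integer seed; the same seed reproduces the same mask.
#' @return A logical `image_size` x `image_size` matrix.
#' @export
generate_tumor_mask <- function(image_size, seed = NULL) {
  stopifnot(image_size >= 32)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  cx <- runif(1, image_size / 3, 2 * image_size / 3)
  cy <- runif(1, image_size / 3, 2 * image_size / 3)
  a  <- runif(1, image_size / 8, image_size / 3)
  b  <- runif(1, image_size / 8, image_size / 3)
  th <- runif(1, 0, pi)
  xg <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE)
  yg <- matrix(seq_len(image_size), image_size, image_size)
  xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
  yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
  (xr / a)^2 + (yr / b)^2 <= 1
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Stationary Gaussian random field on the image torus: white noise smoothed
# with a periodic Gaussian kernel of length-scale `ell`, rescaled to unit
# marginal variance.
gaussian_random_field <- function(n, ell) {
  noise <- matrix(rnorm(n * n), n, n)
  if (ell <= 0) return(noise)
  d <- c(0:(n %/% 2), -((n - 1) %/% 2):-1)
  k1 <- exp(-d^2 / (2 * ell^2))
  ker <- outer(k1, k1)
  ker <- ker / sum(ker)
  f <- Re(fft(fft(noise) * fft(ker), inverse = TRUE)) / (n * n)
  f / sqrt(sum(ker^2))
}

#' Generate a synthetic cohort of multi-sequence MRI samples
#'
#' Draws `n_patients` samples, each with four co-registered 2D sequence
#' images (T1w, T2w, CE-T1w, ADC), a shared elliptical tumor mask, a clinical
#' record, and a pathological node label. Exactly
#' `round(n_patients * prevalence)` patients are LNM+. Each image is a
#' stationary correlated Gaussian random field; inside the mask the field's
#' correlation length and mean depend on the label through the per-sequence
#' effect sizes, which is what downstream texture and first-order features
#' can detect. The simulated radiologist's ymrN stage reproduces the
#' configured sensitivity/specificity in expectation; ymrT is positively
#' associated with the label; sex, age, CEA and concurrent radiation are
#' independent of it.
#'
#' Patients are split once into primary and validation cohorts at the
#' configured ratio; the split travels with the cohort table.
#'
#' @param config A [cohort_config()].
#' @return An `mri_cohort`: a list with `samples` (list of `mri_sample`s),
#'   `clinical` (a tibble with one row per patient: `patient_id`, `split`,
#'   `label`, and the clinical covariates), and `config`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 30, seed = 2))
#' table(co$clinical$split, co$clinical$label)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_patients
  n_pos <- round(n * config$prevalence)
  label <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  n_primary <- round(n * config$split_ratio / (config$split_ratio + 1))
  split <- sample(rep(c("primary", "validation"), c(n_primary, n - n_primary)))
  ids <- sprintf("P%04d", seq_len(n))

  clin <- draw_clinical(n, label, config)
  size <- config$image_size
  ell_bg <- 1.5  # baseline correlation length, pixels

  samples <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- generate_tumor_mask(size)
    images <- lapply(RADNODE_SEQUENCES, function(sq) {
      ell_tum <- ell_bg + config$texture_effect[[sq]] * label[i]
      shift <- config$intensity_effect[[sq]] * label[i]
      img <- gaussian_random_field(size, ell_bg)
      tum <- gaussian_random_field(size, ell_tum) + shift
      img[mask] <- tum[mask]
      img
    })
    names(images) <- RADNODE_SEQUENCES
    masks <- setNames(rep(list(mask), 4L), RADNODE_SEQUENCES)
    samples[[i]] <- structure(list(
      patient_id = ids[i], images = images, masks = masks,
      clinical = clin[i, ], label = label[i]
    ), class = "mri_sample")
  }

  clinical <- tibble::tibble(patient_id = ids, split = split, label = label) |>
    dplyr::bind_cols(clin)
  structure(list(samples = samples, clinical = clinical, config = config),
            class = "mri_cohort")
}

# Clinical covariates. ymrN reproduces the radiologist operating point;
# ymrT and cN are label-associated; the rest are independent of the label.
draw_clinical <- function(n, label, config) {
  sex <- ifelse(runif(n) < 0.71, "male", "female")
  age <- round(rnorm(n, 54, 12))
  cea <- rbinom(n, 1L, 0.20)
  radiation <- rbinom(n, 1L, 0.41)
  cT <- sample(c(2L, 3L, 4L), n, replace = TRUE, prob = c(0.07, 0.74, 0.19))

  cN <- integer(n)
  pos <- label == 1L
  cN[pos]  <- sample(0:2, sum(pos),  TRUE, prob = c(0.13, 0.31, 0.56))
  cN[!pos] <- sample(0:2, sum(!pos), TRUE, prob = c(0.24, 0.43, 0.33))

  ymrT <- integer(n)
  ymrT[pos]  <- sample(1:4, sum(pos),  TRUE, prob = c(0.011, 0.161, 0.678, 0.149))
  ymrT[!pos] <- sample(1:4, sum(!pos), TRUE, prob = c(0.105, 0.286, 0.533, 0.076))

  ymrN <- integer(n)
  called_pos <- logical(n)
  called_pos[pos]  <- runif(sum(pos))  < config$radiologist_sens
  called_pos[!pos] <- runif(sum(!pos)) >= config$radiologist_spec
  # N1 vs N2 split among node-positive calls differs by true status
  n2prob <- ifelse(label == 1L, 0.41, 0.15)
  ymrN[called_pos] <- 1L + rbinom(sum(called_pos), 1L, n2prob[called_pos])

  tibble::tibble(sex = sex, age = as.numeric(age), cea = cea,
                 radiation = radiation, cT = cT, cN = cN,
                 ymrT = ymrT, ymrN = ymrN)
}

#' @export
print.mri_cohort <- function(x, ...) {
  cat("<mri_cohort> ", length(x$samples), " patients (",
      sum(x$clinical$label), " LNM+), ",
      sum(x$clinical$split == "primary"), " primary / ",
      sum(x$clinical$split == "validation"), " validation, image size ",
      x$config$image_size, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk as NIfTI images plus a cohort table
#'
#' One NIfTI file per patient per sequence plus one mask file, and
#' `cohort.csv` with the split, label and clinical covariates.
#'
#' @param cohort An `mri_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mri_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$samples) {
    for (sq in names(s$images)) {
      RNifti::writeNifti(s$images[[sq]],
                         file.path(dir, paste0(s$patient_id, "_", sq, ".nii.gz")))
    }
    RNifti::writeNifti(s$masks[[1L]] * 1,
                       file.path(dir, paste0(s$patient_id, "_mask.nii.gz")))
  }
  readr::write_csv(cohort$clinical, file.path(dir, "cohort.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the NIfTI files and `cohort.csv`.
#' @return An `mri_cohort`.
#' @export
read_cohort <- function(dir) {
  clinical <- readr::read_csv(file.path(dir, "cohort.csv"),
                              show_col_types = FALSE)
  samples <- lapply(seq_len(nrow(clinical)), function(i) {
    pid <- clinical$patient_id[i]
    images <- lapply(RADNODE_SEQUENCES, function(sq) {
      f <- file.path(dir, paste0(pid, "_", sq, ".nii.gz"))
      if (!file.exists(f)) return(NULL)
      arr <- RNifti::readNifti(f)
      matrix(arr, nrow = dim(arr)[1L])
    })
    names(images) <- RADNODE_SEQUENCES
    images <- images[!vapply(images, is.null, logical(1))]
    mf <- file.path(dir, paste0(pid, "_mask.nii.gz"))
    mask <- if (file.exists(mf)) {
      arr <- RNifti::readNifti(mf)
      matrix(arr, nrow = dim(arr)[1L]) > 0.5
    } else NULL
    structure(list(
      patient_id = pid, images = images,
      masks = if (is.null(mask)) list() else setNames(rep(list(mask), length(images)), names(images)),
      clinical = clinical[i, setdiff(names(clinical), c("patient_id", "split", "label"))],
      label = clinical$label[i]
    ), class = "mri_sample")
  })
  structure(list(samples = samples, clinical = clinical, config = NULL),
            class = "mri_cohort")
}
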