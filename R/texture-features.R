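#' Discretize ROI intensities into equal-width gray levels
#'
#' Equal-width binning between the ROI minimum and maximum, the usual
#' fixed-bin-count radiomics scheme. Bins are right-closed: with 2 levels,
#' values `c(0, 0.5, 1)` map to levels `c(1, 1, 2)`. A constant input maps
#' every pixel to level 1. Because binning is relative to the ROI min/max,
#' any monotone rescaling `a*x + b` (a > 0) leaves the levels unchanged.
#'
#' @param values Numeric vector of in-ROI intensities.
#' @param n_gray_levels Number of levels (>= 2).
#' @return Integer vector of levels in `1..n_gray_levels`.
#' @export
discretize <- function(values, n_gray_levels = 32) {
  stopifnot(n_gray_levels >= 2)
  if (length(values) == 0L) stop("empty ROI")
  mn <- min(values); mx <- max(values)
  if (mx == mn) return(rep(1L, length(values)))
  w <- (mx - mn) / n_gray_levels
  lev <- ceiling((values - mn) / w)
  as.integer(pmin(pmax(lev, 1L), n_gray_levels))
}

#' Scale-normalized Laplacian-of-Gaussian filter
#'
#' Band-pass filters the image with a zero-mean, scale-normalized
#' (`sigma^2`-weighted) LoG kernel; image boundaries are handled by
#' reflection. The response to a constant image is identically zero, and for
#' a Gaussian blob of scale `s` the absolute response at the blob center is
#' maximal near `sigma = s`.
#'
#' @param image 2D numeric matrix.
#' @param sigma Kernel scale in pixels (> 0).
#' @return Filtered matrix, same shape as `image`.
#' @export
log_filter <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  r <- max(2L, ceiling(4 * sigma))
  d <- -r:r
  x <- matrix(d, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  ker <- (x^2 + y^2 - 2 * sigma^2) / sigma^4 * g
  ker <- sigma^2 * ker / sum(g)       # scale normalization
  ker <- ker - mean(ker)              # exact zero response to constants
  padded <- reflect_pad(image, r)
  conv2_fft(padded, ker)[(r + 1):(r + nrow(image)), (r + 1):(r + ncol(image)),
                         drop = FALSE]
}

reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

# Circular convolution via FFT with the kernel centered at the origin.
conv2_fft <- function(m, ker) {
  nr <- nrow(m); nc <- ncol(m)
  r <- (nrow(ker) - 1L) / 2L
  kp <- matrix(0, nr, nc)
  idx <- function(v, n) ((v - 1L) %% n) + 1L
  kp[idx(seq_len(nrow(ker)) - r - 1L + 1L, nr),
     idx(seq_len(ncol(ker)) - r - 1L + 1L, nc)] <- ker
  Re(fft(fft(m) * fft(kp), inverse = TRUE)) / (nr * nc)
}

#' First-order statistics of ROI intensities
#'
#' Twenty-four first-order descriptors of the in-ROI intensity distribution.
#' Variance/SD are population moments; kurtosis is excess kurtosis; skewness
#' and kurtosis of a constant input are defined as 0; entropy (bits) and
#' uniformity are computed on the equal-width discretized histogram; CV is 0
#' when the mean is 0.
#'
#' @param values Numeric vector of in-ROI intensities (length >= 1).
#' @param n_gray_levels Levels for the histogram-based statistics.
#' @return Named numeric vector of length 24.
#' @export
first_order_features <- function(values, n_gray_levels = 32) {
  if (length(values) == 0L) stop("empty ROI")
  n <- length(values)
  m <- mean(values)
  cen <- values - m
  m2 <- mean(cen^2)
  skew <- if (m2 > 0) mean(cen^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cen^4) / m2^2 - 3 else 0
  q <- quantile(values, c(.05, .10, .25, .50, .75, .90, .95), names = FALSE)
  in_core <- values >= q[2] & values <= q[6]
  rmad <- if (any(in_core)) mean(abs(values[in_core] - mean(values[in_core]))) else 0
  lev <- discretize(values, n_gray_levels)
  p <- tabulate(lev, n_gray_levels) / n
  p <- p[p > 0]
  c(Mean = m, Median = q[4], Min = min(values), Max = max(values),
    Range = max(values) - min(values),
    P5 = q[1], P10 = q[2], P25 = q[3], P75 = q[5], P90 = q[6], P95 = q[7],
    IQR = q[5] - q[3], Variance = m2, SD = sqrt(m2),
    Skewness = skew, Kurtosis = kurt,
    Energy = sum(values^2), RMS = sqrt(mean(values^2)),
    Entropy = -sum(p * log2(p)), Uniformity = sum(p^2),
    MAD = mean(abs(cen)), rMAD = rmad,
    MedAD = median(abs(values - q[4])),
    CV = if (m != 0) sqrt(m2) / m else 0)
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of discretized gray levels at the given pixel
#' offsets, restricted to pairs whose both pixels lie inside the ROI. Each
#' offset's count matrix is symmetrized (offset plus its negation), the
#' matrices are averaged over offsets, and the result is normalized to sum
#' to one.
#'
#' @param levels Integer matrix of gray levels (1..`n_gray_levels`) with `NA`
#'   or 0 outside the ROI.
#' @param n_gray_levels Number of gray levels.
#' @param offsets List of `c(dx, dy)` offsets; default is the four distance-1
#'   directions (0, 45, 90, 135 degrees).
#' @return A `texture_matrix` of kind `"GLCM"` (normalized, symmetric).
#' @export
glcm_matrix <- function(levels, n_gray_levels = max(levels, na.rm = TRUE),
                        offsets = list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
  stopifnot(is.matrix(levels))
  lv <- levels
  lv[is.na(lv)] <- 0L
  storage.mode(lv) <- "integer"
  acc <- matrix(0, n_gray_levels, n_gray_levels)
  total_pairs <- 0
  for (off in offsets) {
    cnt <- cpp_glcm_counts(lv, n_gray_levels, off[1L], off[2L])
    acc <- acc + (cnt + t(cnt))
    total_pairs <- total_pairs + sum(cnt)
  }
  if (total_pairs == 0) stop("degenerate ROI for GLCM")
  p <- acc / length(offsets)
  p <- p / sum(p)
  structure(list(kind = "GLCM", matrix = p, normalized = TRUE),
            class = "texture_matrix")
}

#' Co-occurrence features
#'
#' Twenty-six statistics of a normalized symmetric GLCM: the standard
#' co-occurrence set (angular second moment, contrast, correlation,
#' dissimilarity, joint/sum/difference moments and entropies, inverse
#' difference family, information measures of correlation, autocorrelation
#' and the cluster moments — cluster shade is the third moment
#' `sum((i + j - mu_i - mu_j)^3 p(i,j))`) plus the sum-energy second moment.
#' Correlation is defined as 0 when either marginal is degenerate.
#'
#' @param m A `texture_matrix` of kind `"GLCM"` (normalized), or a plain
#'   normalized matrix.
#' @return Named numeric vector of length 26.
#' @export
glcm_features <- function(m) {
  p <- if (inherits(m, "texture_matrix")) m$matrix else m
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  autoc <- sum(i * j * p)
  ent_term <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }

  # sum (k = i + j) and difference (k = |i - j|) marginal distributions
  ksum <- 2:(2 * ng)
  kdiff <- 0:(ng - 1)
  psum <- numeric(2 * ng - 1)
  rs <- rowsum(as.vector(p), as.vector(i + j))
  psum[as.integer(rownames(rs)) - 1L] <- rs
  pdiff <- numeric(ng)
  rd <- rowsum(as.vector(p), as.vector(abs(i - j)))
  pdiff[as.integer(rownames(rd)) + 1L] <- rd
  savg <- sum(ksum * psum)
  davg <- sum(kdiff * pdiff)

  hxy <- ent_term(p)
  hx <- ent_term(px); hy <- ent_term(py)
  pxpy <- outer(px, py)
  ok <- pxpy > 0
  hxy1 <- -sum(p[ok] * log2(pxpy[ok]))
  hxy2 <- -sum(pxpy[ok] * log2(pxpy[ok]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))

  cdev <- i + j - mux - muy
  c(autocorr = autoc,
    javg = mux,
    jvar = sum((i - mux)^2 * p),
    entropy = hxy,
    cprom = sum(cdev^4 * p),
    cshade = sum(cdev^3 * p),
    ctend = sum(cdev^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = if (sx > 0 && sy > 0) (autoc - mux * muy) / (sx * sy) else 0,
    davg = davg,
    dentropy = ent_term(pdiff),
    dvar = sum((kdiff - davg)^2 * pdiff),
    dissimilarity = sum(abs(i - j) * p),
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    idm = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    idn = sum(p / (1 + abs(i - j) / ng)),
    imc1 = imc1,
    imc2 = imc2,
    invvar = sum(p[i != j] / (i - j)[i != j]^2),
    maxprob = max(p),
    savg = savg,
    sentropy = ent_term(psum),
    svar = sum((ksum - savg)^2 * psum),
    senergy = sum(psum^2))
}

#' Gray-level size-zone matrix
#'
#' Entry `(i, s)` counts the 8-connected zones of gray level `i` with exactly
#' `s` pixels, restricted to the ROI. Zone counts conserve ROI pixels:
#' `sum(s * count(i, s)) == mask area`.
#'
#' @param levels Integer matrix of gray levels with `NA` or 0 outside the ROI.
#' @param n_gray_levels Number of gray levels.
#' @return A `texture_matrix` of kind `"GLSZM"` holding the raw zone counts
#'   (`n_gray_levels` rows, max zone size columns) with the ROI pixel count
#'   attached as attribute `n_pixels`.
#' @export
glszm_matrix <- function(levels, n_gray_levels = max(levels, na.rm = TRUE)) {
  stopifnot(is.matrix(levels))
  lv <- levels
  lv[is.na(lv)] <- 0L
  storage.mode(lv) <- "integer"
  if (!any(lv > 0L)) stop("empty ROI")
  zones <- cpp_glszm_zones(lv)
  smax <- max(zones$size)
  z <- matrix(tabulate((zones$size - 1L) * n_gray_levels + zones$level,
                       n_gray_levels * smax),
              n_gray_levels, smax)
  out <- structure(list(kind = "GLSZM", matrix = z, normalized = FALSE),
                   class = "texture_matrix")
  attr(out, "n_pixels") <- sum(lv > 0L)
  out
}

#' Size-zone features
#'
#' Sixteen standard size-zone statistics normalized by the total zone count:
#' small/large zone emphasis, low/high gray-level emphasis and their four
#' joint variants (LZLGE is `sum(p(i,s) * s^2 / i^2)`), gray-level and
#' zone-size nonuniformity (raw and normalized), zone percentage, gray-level
#' and zone-size variance, and zone entropy.
#'
#' @param m A `texture_matrix` of kind `"GLSZM"` (raw zone counts).
#' @param n_pixels ROI pixel count for the zone-percentage denominator;
#'   defaults to the attribute recorded by [glszm_matrix()].
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(m, n_pixels = attr(m, "n_pixels")) {
  z <- if (inherits(m, "texture_matrix")) m$matrix else m
  nz <- sum(z)
  if (nz < 1) stop("GLSZM has no zones")
  p <- z / nz
  ivec <- seq_len(nrow(z)); svec <- seq_len(ncol(z))
  i <- matrix(ivec, nrow(z), ncol(z))
  s <- matrix(svec, nrow(z), ncol(z), byrow = TRUE)
  gl_counts <- rowSums(z); sz_counts <- colSums(z)
  mui <- sum(i * p); mus <- sum(s * p)
  pe <- p[p > 0]
  c(SZE = sum(p / s^2), LZE = sum(p * s^2),
    LGZE = sum(p / i^2), HGZE = sum(p * i^2),
    SZLGE = sum(p / (s^2 * i^2)), SZHGE = sum(p * i^2 / s^2),
    LZLGE = sum(p * s^2 / i^2), LZHGE = sum(p * s^2 * i^2),
    GLN = sum(gl_counts^2) / nz, GLNN = sum(gl_counts^2) / nz^2,
    ZSN = sum(sz_counts^2) / nz, ZSNN = sum(sz_counts^2) / nz^2,
    ZP = nz / n_pixels,
    GLV = sum((i - mui)^2 * p), ZSV = sum((s - mus)^2 * p),
    ZE = -sum(pe * log2(pe)))
}
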