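# Independent brute-force oracles used to verify the fast implementations.

# Pairwise AUC by explicit enumeration of all (positive, negative) pairs.
oracle_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y) tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# Directed co-occurrence counts by an explicit double loop over pixels.
oracle_glcm_counts <- function(levels, ng, dx, dy) {
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, ng, ng)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + dy; j2 <- j + dx
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    a <- levels[i, j]; b <- levels[i2, j2]
    if (!is.na(a) && !is.na(b) && a > 0 && b > 0)
      counts[a, b] <- counts[a, b] + 1
  }
  counts
}

# Full GLCM (symmetrized over offsets and negations, averaged, normalized).
oracle_glcm <- function(levels, ng, offsets) {
  acc <- matrix(0, ng, ng)
  for (off in offsets) {
    cnt <- oracle_glcm_counts(levels, ng, off[1], off[2])
    acc <- acc + cnt + t(cnt)
  }
  acc / sum(acc)
}

# 8-connected same-level zones by queue-based flood fill in plain R.
oracle_glszm <- function(levels, ng) {
  nr <- nrow(levels); nc <- ncol(levels)
  lv <- levels
  lv[is.na(lv)] <- 0
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (lv[i, j] <= 0 || seen[i, j]) next
    g <- lv[i, j]
    queue <- list(c(i, j)); seen[i, j] <- TRUE; size <- 0
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      size <- size + 1
      for (di in -1:1) for (dj in -1:1) {
        ni <- cur[1] + di; nj <- cur[2] + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (!seen[ni, nj] && lv[ni, nj] == g) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  smax <- max(vapply(zones, `[`, numeric(1), 2))
  z <- matrix(0, ng, smax)
  for (zn in zones) z[zn[1], zn[2]] <- z[zn[1], zn[2]] + 1
  z
}

# Direct-summation GLCM features, written independently of the package code.
oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- sqrt(sum((1:ng - mux)^2 * px)); sy <- sqrt(sum((1:ng - muy)^2 * py))
  acc <- 0; contrast <- 0; dissim <- 0; homog <- 0; idm <- 0; idmn <- 0
  idn <- 0; invvar <- 0; cs2 <- 0; cs3 <- 0; cs4 <- 0; jvar <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    acc <- acc + i * j * pij
    contrast <- contrast + (i - j)^2 * pij
    dissim <- dissim + abs(i - j) * pij
    homog <- homog + pij / (1 + abs(i - j))
    idm <- idm + pij / (1 + (i - j)^2)
    idmn <- idmn + pij / (1 + (i - j)^2 / ng^2)
    idn <- idn + pij / (1 + abs(i - j) / ng)
    if (i != j) invvar <- invvar + pij / (i - j)^2
    d <- i + j - mux - muy
    cs2 <- cs2 + d^2 * pij; cs3 <- cs3 + d^3 * pij; cs4 <- cs4 + d^4 * pij
    jvar <- jvar + (i - mux)^2 * pij
  }
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  savg <- sum((1:(2 * ng)) * psum)
  davg <- sum((0:(ng - 1)) * pdiff)
  h <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- h(p); hx <- h(px); hy <- h(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (px[i] * py[j] > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  c(autocorr = acc, javg = mux, jvar = jvar, entropy = hxy,
    cprom = cs4, cshade = cs3, ctend = cs2, contrast = contrast,
    correlation = if (sx > 0 && sy > 0) (acc - mux * muy) / (sx * sy) else 0,
    davg = davg, dentropy = h(pdiff),
    dvar = sum((0:(ng - 1) - davg)^2 * pdiff),
    dissimilarity = dissim, energy = sum(p^2), homogeneity = homog,
    idm = idm, idmn = idmn, idn = idn,
    imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    invvar = invvar, maxprob = max(p), savg = savg,
    sentropy = h(psum), svar = sum(((1:(2 * ng)) - savg)^2 * psum),
    senergy = sum(psum^2))
}

# Direct-summation size-zone features.
oracle_glszm_features <- function(z, n_pixels) {
  nz <- sum(z)
  out <- setNames(numeric(16), c("SZE", "LZE", "LGZE", "HGZE", "SZLGE",
                                 "SZHGE", "LZLGE", "LZHGE", "GLN", "GLNN",
                                 "ZSN", "ZSNN", "ZP", "GLV", "ZSV", "ZE"))
  mui <- 0; mus <- 0
  for (i in seq_len(nrow(z))) for (s in seq_len(ncol(z))) {
    pr <- z[i, s] / nz
    mui <- mui + i * pr; mus <- mus + s * pr
  }
  for (i in seq_len(nrow(z))) for (s in seq_len(ncol(z))) {
    pr <- z[i, s] / nz
    if (pr == 0) next
    out["SZE"] <- out["SZE"] + pr / s^2
    out["LZE"] <- out["LZE"] + pr * s^2
    out["LGZE"] <- out["LGZE"] + pr / i^2
    out["HGZE"] <- out["HGZE"] + pr * i^2
    out["SZLGE"] <- out["SZLGE"] + pr / (s^2 * i^2)
    out["SZHGE"] <- out["SZHGE"] + pr * i^2 / s^2
    out["LZLGE"] <- out["LZLGE"] + pr * s^2 / i^2
    out["LZHGE"] <- out["LZHGE"] + pr * s^2 * i^2
    out["GLV"] <- out["GLV"] + pr * (i - mui)^2
    out["ZSV"] <- out["ZSV"] + pr * (s - mus)^2
    out["ZE"] <- out["ZE"] - pr * log2(pr)
  }
  out["GLN"] <- sum(rowSums(z)^2) / nz
  out["GLNN"] <- sum(rowSums(z)^2) / nz^2
  out["ZSN"] <- sum(colSums(z)^2) / nz
  out["ZSNN"] <- sum(colSums(z)^2) / nz^2
  out["ZP"] <- nz / n_pixels
  out
}

# A small in-memory sample with fully controlled images/masks.
make_sample <- function(images, mask, label = 0L, id = "S01") {
  structure(list(patient_id = id, images = images,
                 masks = setNames(rep(list(mask), length(images)), names(images)),
                 clinical = tibble::tibble(sex = "male", age = 55, cea = 0,
                                           radiation = 0, cT = 3, cN = 1,
                                           ymrT = 3, ymrN = 0),
                 label = label),
            class = "mri_sample")
}
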